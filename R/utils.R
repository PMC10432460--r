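# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a reproducible child seed from a parent seed and a stream label,
# kept inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  sum(utf8ToInt(as.character(stream))) * 1009L %% 1000003L + as.integer(seed)
}

DNA_BASES <- c("A", "C", "G", "T")

# reverse complement without per-call S4 dispatch overhead
revcomp <- function(seq) {
  paste(rev(chars(chartr("ACGTacgt", "TGCAtgca", seq))), collapse = "")
}

# Split a sequence string into a character vector of single letters.
chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

stopf <- function(...) abort(sprintf(...))

assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < lo) || any(x > hi)) {
    stopf("`%s` must lie in [%g, %g]", name, lo, hi)
  }
  invisible(x)
}

# Validate a square labelled distance matrix: symmetric, zero diagonal,
# values in [0, 1] (intergenomic distances are fractions; general
# dissimilarities, e.g. additive tree distances for NJ, may opt out of
# the range check). No metricity is assumed or checked.
validate_distance_matrix <- function(dm, unit_range = TRUE) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    stopf("distance matrix must be square")
  }
  if (is.null(rownames(dm)) || is.null(colnames(dm)) ||
      !identical(rownames(dm), colnames(dm))) {
    stopf("distance matrix must carry identical row and column labels")
  }
  if (anyDuplicated(rownames(dm))) stopf("distance matrix labels must be unique")
  if (any(dm < 0) || (unit_range && any(dm > 1))) {
    stopf("distances must lie in [0, 1]")
  }
  if (any(abs(diag(dm)) > 1e-12)) stopf("distance matrix diagonal must be zero")
  if (max(abs(dm - t(dm))) > 1e-12) stopf("distance matrix must be symmetric")
  dm
}

# Partitions are two-column tibbles (genome_id, cluster).
as_partition <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("genome_id", "cluster") %in% names(x)))
    out <- tibble(genome_id = as.character(x$genome_id),
                  cluster = as.character(x$cluster))
  } else if (!is.null(names(x))) {
    out <- tibble(genome_id = names(x), cluster = as.character(x))
  } else {
    stopf("a partition must be a (genome_id, cluster) data frame or named vector")
  }
  if (anyDuplicated(out$genome_id)) {
    stopf("every genome must carry exactly one cluster label")
  }
  out
}

n_clusters <- function(partition) length(unique(as_partition(partition)$cluster))
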