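#' GBDP-style intergenomic distance from fragment matches
#'
#' Converts a set of ungapped fragment matches between two genomes into a
#' single intergenomic distance, using one of two formulas analogous to
#' the coverage- and identity-based variants of genome-BLAST distance
#' phylogeny:
#'
#' * `"identity"`: `d = 1 - sum(identities) / sum(length)` over all
#'   matches — the per-site divergence within homologous segments;
#'   `d = 1` when there are no matches.
#' * `"coverage"`: `d = 1 - 2 * sum(length) / (len_a + len_b)` — the
#'   fraction of the two genomes not covered by matches.
#'
#' The result is clamped to \[0, 1\].
#'
#' @param matches Tibble from [find_fragment_matches()].
#' @param len_a,len_b Total genome lengths (bp), positive.
#' @param formula `"identity"` or `"coverage"`.
#' @return A distance in \[0, 1\].
#' @export
gbdp_distance <- function(matches, len_a, len_b,
                          formula = c("identity", "coverage")) {
  formula <- match.arg(formula)
  if (len_a <= 0 || len_b <= 0) stopf("genome lengths must be positive")
  if (nrow(matches) == 0) return(1)
  d <- if (formula == "identity") {
    1 - sum(matches$identities) / sum(matches$length)
  } else {
    1 - 2 * sum(matches$length) / (len_a + len_b)
  }
  min(1, max(0, d))
}

#' Pairwise distance matrix over a genome collection
#'
#' Runs the fragment-match kernel on every unordered genome pair (on the
#' canonically ordered pair, so the matrix is exactly symmetric) and
#' assembles a labelled distance matrix with zero diagonal.
#'
#' @param genomes Named list of [genome_record()]s (or a
#'   `synthetic_collection`).
#' @param formula,k,min_len Passed to [find_fragment_matches()] and
#'   [gbdp_distance()].
#' @return A labelled symmetric matrix of distances in \[0, 1\].
#' @export
build_distance_matrix <- function(genomes, formula = c("identity", "coverage"),
                                  k = 12L, min_len = 50L) {
  formula <- match.arg(formula)
  if (inherits(genomes, "synthetic_collection")) genomes <- genomes$genomes
  ids <- map_chr(genomes, function(g) g$id)
  if (anyDuplicated(ids)) stopf("genome ids must be unique")
  if (length(genomes) < 2) stopf("need at least two genomes")
  names(genomes) <- ids
  n <- length(ids)
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pair <- sort(c(ids[i], ids[j]))  # canonical order for symmetry
      m <- find_fragment_matches(genomes[[pair[1]]], genomes[[pair[2]]],
                                 k = k, min_len = min_len)
      d <- gbdp_distance(m, genome_length(genomes[[pair[1]]]),
                         genome_length(genomes[[pair[2]]]), formula)
      dm[i, j] <- dm[j, i] <- d
    }
  }
  validate_distance_matrix(dm)
}

#' Distance-to-dDDH calibration curve
#'
#' The digital DNA-DNA hybridization surrogate is tied to intergenomic
#' distance through a logistic curve in log-distance,
#' `dDDH(d) = 100 / (1 + exp(a + b * log(d)))`, with `dDDH(0) = 100`
#' taken as the limiting value. The two coefficients are fitted exactly
#' through two anchors: the species-boundary anchor (distance 0.036 maps
#' to dDDH 70%) and a configurable far anchor shaping the tail (default:
#' distance 0.25 maps to dDDH 25%).
#'
#' @param anchor Species anchor, `c(distance, ddh)`; default
#'   `c(0.036, 70)`.
#' @param far_anchor Second anchor, `c(distance, ddh)`.
#' @return A `ddh_calibration` object (coefficients `a`, `b`).
#' @export
ddh_calibration <- function(anchor = c(0.036, 70), far_anchor = c(0.25, 25)) {
  stopifnot(length(anchor) == 2, length(far_anchor) == 2)
  d <- c(anchor[1], far_anchor[1]); y <- c(anchor[2], far_anchor[2])
  if (any(d <= 0) || any(d > 1)) stopf("anchor distances must lie in (0, 1]")
  if (any(y <= 0) || any(y >= 100)) stopf("anchor dDDH values must lie in (0, 100)")
  z <- log(100 / y - 1)                 # logit scale
  b <- (z[2] - z[1]) / (log(d[2]) - log(d[1]))
  a <- z[1] - b * log(d[1])
  if (b <= 0) stopf("calibration must be strictly decreasing (anchors inconsistent)")
  structure(list(a = a, b = b, anchor = anchor, far_anchor = far_anchor),
            class = "ddh_calibration")
}

#' Convert an intergenomic distance to digital DDH
#'
#' Strictly decreasing in `d`; returns 100 at `d = 0` and passes exactly
#' through the calibration anchors (70.0 at `d = 0.036` by default).
#'
#' @param d Distance(s) in \[0, 1\].
#' @param calibration A [ddh_calibration()]; default anchors.
#' @return dDDH percentage(s) in \[0, 100\].
#' @export
ddh_from_distance <- function(d, calibration = ddh_calibration()) {
  if (any(d < 0) || any(d > 1) || any(is.na(d))) {
    stopf("distances must lie in [0, 1]")
  }
  out <- ifelse(d == 0, 100,
                100 / (1 + exp(calibration$a + calibration$b * log(d))))
  unname(out)
}

#' Invert the dDDH calibration
#'
#' @param ddh dDDH percentage(s) in (0, 100).
#' @param calibration A [ddh_calibration()].
#' @return Distance(s) in (0, 1].
#' @export
distance_from_ddh <- function(ddh, calibration = ddh_calibration()) {
  if (any(ddh <= 0) || any(ddh >= 100)) stopf("dDDH must lie in (0, 100)")
  unname(exp((log(100 / ddh - 1) - calibration$a) / calibration$b))
}

#' Filter a genome collection by distance to a query genome
#'
#' Keeps genomes whose distance to the query is at or below `threshold`
#' (inclusive, matching the subgroup-selection rule that retained genomes
#' *at* a distance threshold of 0.135). The query itself, at distance 0,
#' is kept if present.
#'
#' @param distances_to_query Named numeric vector: genome id -> distance.
#' @param threshold Inclusive distance cutoff; default 0.135.
#' @return Character vector of retained ids, sorted by distance then id.
#' @export
filter_by_query <- function(distances_to_query, threshold = 0.135) {
  if (!length(distances_to_query)) return(character())
  assert_fraction(unname(distances_to_query), "distances_to_query")
  keep <- distances_to_query[distances_to_query <= threshold]
  names(keep)[order(keep, names(keep))]
}

#' Read/write square distance matrices
#'
#' TSV layout: a header row of genome ids and a first column of ids,
#' values formatted `%.6f`. The PHYLIP square layout (taxon count on the
#' first line, then one labelled row per taxon) is also supported.
#'
#' @param dm Labelled symmetric matrix.
#' @param path File path.
#' @return `write_*` return `path` invisibly; `read_*` return the matrix.
#' @name distance_io
NULL

#' @rdname distance_io
#' @export
write_distance_matrix <- function(dm, path) {
  validate_distance_matrix(dm)
  df <- data.frame(genome_id = rownames(dm),
                   apply(dm, 2, function(x) sprintf("%.6f", x)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname distance_io
#' @export
read_distance_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  dm <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(dm) <- "double"
  rownames(dm) <- labels
  # tolerate rounding asymmetry from the %.6f serialisation
  dm <- (dm + t(dm)) / 2
  diag(dm) <- 0
  validate_distance_matrix(dm)
}

#' @rdname distance_io
#' @export
write_distance_phylip <- function(dm, path) {
  validate_distance_matrix(dm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste(c(sprintf("%-10s", rownames(dm)[i]),
                       sprintf("%.6f", dm[i, ])), collapse = "  "), con)
  }
  invisible(path)
}

#' @rdname distance_io
#' @export
read_distance_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  parts <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  labels <- map_chr(parts, 1)
  dm <- do.call(rbind, map(parts, function(p) as.numeric(p[-1])))
  dimnames(dm) <- list(labels, labels)
  dm <- (dm + t(dm)) / 2
  diag(dm) <- 0
  validate_distance_matrix(dm)
}
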