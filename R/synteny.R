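#' Define a query multi-gene cluster
#'
#' A query cluster is an ordered set of named protein sequences taken
#' from a source genome region (e.g. the eight-gene insecticidal toxin
#' island), in genomic order.
#'
#' @param name Cluster name.
#' @param proteins Named character vector of amino-acid sequences, in
#'   genomic order; at least 2 genes.
#' @param source Optional list describing the source span
#'   (`genome_id`, `replicon`, `start`, `end`).
#' @return A `query_cluster`.
#' @export
query_cluster <- function(name, proteins, source = NULL) {
  if (length(proteins) < 2 || is.null(names(proteins))) {
    stopf("a query cluster needs at least 2 named genes")
  }
  structure(list(name = name,
                 genes = tibble(gene_name = names(proteins),
                                protein = unname(proteins)),
                 source = source),
            class = "query_cluster")
}

#' Query cluster for a collection's planted island
#'
#' Builds the island query from the first island-bearing genome (or a
#' chosen one), with its island proteins in island gene order — the
#' synthetic analogue of using the type strain's toxin cluster as the
#' search query.
#'
#' @param collection A `synthetic_collection`.
#' @param genome_id Source genome; defaults to the first island bearer.
#' @param name Cluster name.
#' @return A `query_cluster`.
#' @export
island_query_cluster <- function(collection, genome_id = NULL,
                                 name = "fit_island") {
  bearers <- names(collection$island_truth)[collection$island_truth]
  if (!length(bearers)) stopf("the collection was simulated without an island")
  genome_id <- genome_id %||% bearers[1]
  g <- collection$genomes[[genome_id]]
  pids <- paste0(genome_id, ".", collection$island_og_ids)
  query_cluster(name, setNames(g$proteome[pids], collection$island_og_ids),
                source = list(genome_id = genome_id))
}

# Full-length ungapped identity of a candidate protein against a query
# protein: equal positions over the *query* length (so truncations are
# penalised by the full-length denominator).
full_length_identity <- function(query, target) {
  n <- min(nchar(query), nchar(target))
  if (n == 0) return(0)
  matches <- sum(chars(substr(query, 1, n)) == chars(substr(target, 1, n)))
  matches / nchar(query)
}

#' Locate a query gene cluster in an annotated genome
#'
#' Each query gene matches a genome protein when the ungapped global
#' identity, computed over the full query CDS length, reaches
#' `min_identity` (default 0.70) — a gene truncated below the threshold
#' share of the query length can never match. A locus is reported when at
#' least half of the query genes match as a colinear run: same replicon,
#' at most `max_gene_gap` intervening non-matching genes between
#' consecutive matches, one consistent strand, and query order preserved
#' (forward or reversed, which fixes the locus orientation). The
#' best-scoring locus (highest summed identity; ties to the leftmost) is
#' returned, or `NULL` when no locus qualifies.
#'
#' @param genome An annotated [genome_record()].
#' @param query A [query_cluster()].
#' @param min_identity Per-gene identity threshold in (0, 1\].
#' @param max_gene_gap Maximum intervening genes between consecutive
#'   matched genes (default 5).
#' @return An `island_locus` (list with `genome_id`, `replicon`, `start`,
#'   `end`, `strand`, `orientation`, `matches` tibble) or `NULL`.
#' @export
find_cluster <- function(genome, query, min_identity = 0.70,
                         max_gene_gap = 5L) {
  if (!nrow(genome$genes)) stopf("genome '%s' carries no annotation", genome$id)
  if (min_identity <= 0 || min_identity > 1) {
    stopf("`min_identity` must lie in (0, 1]")
  }
  qn <- nrow(query$genes)
  genes <- arrange(genome$genes, .data$replicon, .data$start)
  # per-gene best query assignment above threshold
  cand <- list()
  for (gi in seq_len(nrow(genes))) {
    target <- genome$proteome[[genes$protein_id[gi]]]
    ident <- map_dbl(query$genes$protein, full_length_identity,
                     target = target)
    best_q <- which.max(ident)
    if (ident[best_q] >= min_identity) {
      cand[[length(cand) + 1L]] <- tibble(
        gene_row = gi, query_idx = best_q, identity = ident[best_q])
    }
  }
  if (!length(cand)) return(NULL)
  cand <- bind_rows(cand)
  cand$replicon <- genes$replicon[cand$gene_row]
  cand$strand <- genes$strand[cand$gene_row]

  best_locus <- NULL
  # runs: same replicon + strand, gaps bounded by max_gene_gap
  groups <- split(seq_len(nrow(cand)),
                  paste(cand$replicon, cand$strand, sep = "\r"))
  for (grp in groups) {
    grp <- grp[order(cand$gene_row[grp])]
    run_start <- 1L
    runs <- list()
    if (length(grp) > 1) {
      gaps <- diff(cand$gene_row[grp]) - 1L
      breaks <- which(gaps > max_gene_gap)
      bounds <- c(0L, breaks, length(grp))
      runs <- map(seq_len(length(bounds) - 1L), function(b) {
        grp[(bounds[b] + 1L):bounds[b + 1L]]
      })
    } else {
      runs <- list(grp)
    }
    for (run in runs) {
      qidx <- cand$query_idx[run]
      # colinearity: longest monotone subsequence of query indices,
      # forward ( + orientation) or reversed ( - orientation)
      for (dir in c(1L, -1L)) {
        sub <- longest_monotone_subsequence(dir * qidx)
        take <- run[sub]
        if (length(unique(cand$query_idx[take])) * 2 < qn) next
        rows <- cand$gene_row[take]
        score <- sum(cand$identity[take])
        locus <- list(
          genome_id = genome$id,
          replicon = genes$replicon[rows[1]],
          start = min(genes$start[rows]),
          end = max(genes$end[rows]),
          strand = cand$strand[take[1]],
          orientation = if (dir == 1L) "+" else "-",
          score = score,
          matches = tibble(
            gene_name = query$genes$gene_name[cand$query_idx[take]],
            protein_id = genes$protein_id[rows],
            identity = cand$identity[take])
        )
        if (is.null(best_locus) ||
            score > best_locus$score + 1e-12 ||
            (abs(score - best_locus$score) <= 1e-12 &&
             (locus$start < best_locus$start ||
              (locus$start == best_locus$start &&
               locus$replicon < best_locus$replicon)))) {
          best_locus <- locus
        }
      }
    }
  }
  if (is.null(best_locus)) return(NULL)
  structure(best_locus, class = "island_locus")
}

# Indices of the longest strictly increasing subsequence (ties broken
# towards earlier elements; O(n^2), runs are short).
longest_monotone_subsequence <- function(x) {
  n <- length(x)
  if (n == 0) return(integer())
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] < x[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  end <- which.max(len)
  out <- integer()
  while (end != 0L) {
    out <- c(end, out)
    end <- prev[end]
  }
  out
}

#' @export
print.island_locus <- function(x, ...) {
  cat(sprintf(
    "<island_locus> %s %s:%d-%d (%s), %d/%s genes matched, mean identity %.1f%%\n",
    x$genome_id, x$replicon, x$start, x$end, x$orientation,
    nrow(x$matches), "query", 100 * mean(x$matches$identity)))
  invisible(x)
}

#' Locate a query cluster across a genome collection
#'
#' @param genomes Named list of [genome_record()]s or a
#'   `synthetic_collection`.
#' @param query A [query_cluster()].
#' @param ... Passed to [find_cluster()].
#' @return A list with `loci` (named list of `island_locus`, absent
#'   genomes omitted) and `table` (tibble: one row per genome with
#'   presence, span and match statistics).
#' @export
find_cluster_all <- function(genomes, query, ...) {
  if (inherits(genomes, "synthetic_collection")) genomes <- genomes$genomes
  loci <- list()
  rows <- list()
  for (g in genomes) {
    locus <- find_cluster(g, query, ...)
    if (!is.null(locus)) loci[[g$id]] <- locus
    rows[[g$id]] <- tibble(
      genome_id = g$id,
      present = !is.null(locus),
      replicon = if (is.null(locus)) NA_character_ else locus$replicon,
      start = if (is.null(locus)) NA_integer_ else locus$start,
      end = if (is.null(locus)) NA_integer_ else locus$end,
      strand = if (is.null(locus)) NA_character_ else locus$strand,
      n_matched = if (is.null(locus)) 0L else nrow(locus$matches),
      mean_identity = if (is.null(locus)) NA_real_
                      else 100 * mean(locus$matches$identity))
  }
  list(loci = loci, table = bind_rows(rows))
}

#' Extract flanking sequence around a located cluster
#'
#' Returns up to `flank_length` bp upstream and downstream of the locus,
#' truncated silently at replicon ends. When the locus orientation is
#' `-`, both flanks are reverse-complemented and swapped so they are
#' reported in the query cluster's orientation.
#'
#' @param genome The [genome_record()] the locus was found in.
#' @param locus An `island_locus`.
#' @param flank_length Flank window in bp (default 70000, the
#'   conventional island-context window).
#' @return List with `upstream` and `downstream` DNA strings.
#' @export
extract_flanks <- function(genome, locus, flank_length = 70000) {
  rep_seq <- genome$replicons[[locus$replicon]]
  if (is.null(rep_seq)) stopf("locus replicon not present in genome")
  n <- nchar(rep_seq)
  up <- substr(rep_seq, max(1, locus$start - flank_length), locus$start - 1)
  dn <- substr(rep_seq, locus$end + 1, min(n, locus$end + flank_length))
  if (identical(locus$orientation, "-")) {
    list(upstream = if (nchar(dn)) revcomp(dn) else "",
         downstream = if (nchar(up)) revcomp(up) else "")
  } else {
    list(upstream = up, downstream = dn)
  }
}

#' Pairwise nucleotide identity of located clusters
#'
#' Extracts each locus's full cluster span (orientation-normalised) and
#' computes pairwise percent identity with the fragment-match kernel:
#' `100 * sum(identities) / sum(matched length)`, 0 when no fragments
#' match. The matrix is symmetric with a 100 diagonal.
#'
#' @param loci Named list of `island_locus` (>= 2).
#' @param genomes Named list of [genome_record()]s or a
#'   `synthetic_collection`.
#' @param k,min_len Fragment kernel parameters.
#' @return Labelled symmetric matrix of identities in \[0, 100\].
#' @export
cluster_identity_matrix <- function(loci, genomes, k = 12L, min_len = 50L) {
  if (length(loci) < 2) stopf("need at least 2 loci")
  if (inherits(genomes, "synthetic_collection")) genomes <- genomes$genomes
  seqs <- imap(loci, function(locus, id) {
    s <- substr(genomes[[id]]$replicons[[locus$replicon]],
                locus$start, locus$end)
    if (identical(locus$orientation, "-")) s <- revcomp(s) else s
  })
  ids <- names(seqs)
  m <- matrix(100, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      pair <- sort(c(ids[i], ids[j]))
      mt <- find_fragment_matches(seqs[[pair[1]]], seqs[[pair[2]]],
                                  k = k, min_len = min_len)
      ident <- if (nrow(mt)) 100 * sum(mt$identities) / sum(mt$length) else 0
      m[i, j] <- m[j, i] <- ident
    }
  }
  m
}

#' Neighbour-joining tree of concatenated cluster proteins
#'
#' Concatenates each locus's matched proteins in query gene order (genes
#' a locus lacks contribute gap-only blocks), computes pairwise
#' p-distances over mutually non-gap positions and returns the
#' neighbour-joining tree — a distance-based surrogate for a
#' maximum-likelihood tree of the concatenated cluster proteins.
#'
#' @param loci Named list of `island_locus` (>= 3, sharing at least one
#'   matched gene).
#' @param query The [query_cluster()] used to find the loci.
#' @param genomes Named list of [genome_record()]s or a
#'   `synthetic_collection` (source of the matched protein sequences).
#' @return An `ape` `phylo`.
#' @export
cluster_protein_tree <- function(loci, query, genomes) {
  if (length(loci) < 3) stopf("need at least 3 loci for a cluster tree")
  if (inherits(genomes, "synthetic_collection")) genomes <- genomes$genomes
  qgenes <- query$genes$gene_name
  qlens <- nchar(query$genes$protein)
  aligned <- imap(loci, function(locus, id) {
    blocks <- map2(qgenes, qlens, function(gn, ql) {
      hit <- locus$matches[locus$matches$gene_name == gn, ]
      if (!nrow(hit)) return(strrep("-", ql))
      aa <- genomes[[id]]$proteome[[hit$protein_id[1]]]
      aa <- substr(aa, 1, ql)
      paste0(aa, strrep("-", max(0, ql - nchar(aa))))
    })
    paste(unlist(blocks), collapse = "")
  })
  shared <- Reduce(intersect, map(loci, function(l) l$matches$gene_name))
  if (!length(shared)) stopf("loci share no matched gene")
  ids <- names(aligned)
  n <- length(ids)
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  mats <- map(aligned, chars)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- mats[[i]]; b <- mats[[j]]
      ok <- a != "-" & b != "-"
      d <- if (any(ok)) mean(a[ok] != b[ok]) else 1
      dm[i, j] <- dm[j, i] <- d
    }
  }
  neighbour_joining(dm)
}
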