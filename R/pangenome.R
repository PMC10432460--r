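#' Build orthologous groups from proteomes
#'
#' Reciprocal-best-hit orthology: proteins are compared across genomes
#' with an ungapped k-mer-anchored kernel (percent identity over the
#' shorter sequence, coverage = aligned overlap over the shorter
#' sequence). An edge joins two proteins when identity and coverage both
#' clear their thresholds and the hit is reciprocal-best between the two
#' genomes (ties broken by protein id). Orthologous groups are the
#' connected components of the edge graph; proteins with no edge become
#' singleton OGs. OG ids are assigned in order of each group's smallest
#' member protein id, so the grouping is deterministic.
#'
#' @param proteomes Named list (genome id -> named character vector of
#'   amino-acid sequences), or a `synthetic_collection`.
#' @param min_identity Minimum fraction identity (default 0.5).
#' @param min_coverage Minimum fraction coverage (default 0.5).
#' @param kmer Anchor word size in residues.
#' @return An `ortholog_matrix`: integer matrix (OG x genome) of copy
#'   counts with a `membership` attribute tibble (`og_id`, `genome_id`,
#'   `protein_id`).
#' @export
build_orthologs <- function(proteomes, min_identity = 0.5, min_coverage = 0.5,
                            kmer = 4L) {
  if (inherits(proteomes, "synthetic_collection")) {
    proteomes <- collection_proteomes(proteomes)
  }
  if (length(proteomes) < 2) stopf("need proteomes from at least 2 genomes")
  for (g in names(proteomes)) {
    if (!length(proteomes[[g]])) stopf("genome '%s' has an empty proteome", g)
  }
  prot <- bind_rows(imap(proteomes, function(seqs, g) {
    tibble(genome = g, protein_id = names(seqs), seq = unname(seqs))
  }))
  np <- nrow(prot)
  prot_chars <- map(prot$seq, chars)
  lens <- nchar(prot$seq)

  # k-mer inverted index -> candidate cross-genome pairs
  km <- map(seq_len(np), function(i) {
    s <- prot$seq[[i]]
    if (nchar(s) < kmer) return(character())
    unique(substring(s, seq_len(nchar(s) - kmer + 1),
                     seq_len(nchar(s) - kmer + 1) + kmer - 1))
  })
  idx <- tibble(kmer = unlist(km),
                i = rep(seq_len(np), lengths(km)))
  by_kmer <- split(idx$i, idx$kmer)
  pair_keys <- unique(unlist(map(by_kmer, function(v) {
    if (length(v) < 2) return(integer())
    v <- sort(v)
    pr <- combn(v, 2)
    keep <- prot$genome[pr[1, ]] != prot$genome[pr[2, ]]
    (pr[1, keep] - 1L) * np + pr[2, keep]
  }), use.names = FALSE))
  if (length(pair_keys)) {
    pi <- (pair_keys - 1L) %/% np + 1L
    pj <- (pair_keys - 1L) %% np + 1L
  } else {
    pi <- pj <- integer()
  }

  # ungapped identity at the zero-offset diagonal: identity over the
  # shorter protein, coverage = shorter / longer (guards against
  # length-discordant hits such as truncations)
  score_pair <- function(i, j) {
    n <- min(lens[i], lens[j])
    matches <- sum(prot_chars[[i]][seq_len(n)] == prot_chars[[j]][seq_len(n)])
    c(identity = matches / n, coverage = n / max(lens[i], lens[j]))
  }
  hits <- NULL
  if (length(pi)) {
    sc <- matrix(0, nrow = length(pi), ncol = 2)
    for (h in seq_along(pi)) sc[h, ] <- score_pair(pi[h], pj[h])
    keep <- sc[, 1] >= min_identity & sc[, 2] >= min_coverage
    hits <- tibble(i = pi[keep], j = pj[keep], identity = sc[keep, 1])
  }

  edges <- NULL
  if (!is.null(hits) && nrow(hits)) {
    both <- bind_rows(hits,
                      tibble(i = hits$j, j = hits$i, identity = hits$identity))
    both$target_genome <- prot$genome[both$j]
    both <- arrange(both, .data$i, .data$target_genome,
                    dplyr::desc(.data$identity), prot$protein_id[both$j])
    best <- both[!duplicated(paste(both$i, both$target_genome)), ]
    key <- paste(pmin(best$i, best$j), pmax(best$i, best$j))
    reciprocal <- key[duplicated(key)]
    bk <- paste(pmin(best$i, best$j), pmax(best$i, best$j))
    edges <- best[bk %in% reciprocal & best$i < best$j, c("i", "j")]
  }

  # union-find over proteins
  parent <- seq_len(np)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (!is.null(edges) && nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      ri <- find(edges$i[e]); rj <- find(edges$j[e])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(np), find, integer(1))
  groups <- split(seq_len(np), comp)
  first_member <- map_chr(groups, function(g) min(prot$protein_id[g]))
  groups <- groups[order(first_member)]
  og_ids <- sprintf("OG%06d", seq_along(groups))

  membership <- bind_rows(map2(og_ids, groups, function(og, g) {
    tibble(og_id = og, genome_id = prot$genome[g],
           protein_id = prot$protein_id[g])
  }))
  genomes <- names(proteomes)
  counts <- matrix(0L, nrow = length(og_ids), ncol = length(genomes),
                   dimnames = list(og_ids, genomes))
  tab <- table(membership$og_id, membership$genome_id)
  counts[rownames(tab), colnames(tab)] <- as.integer(tab)
  structure(counts, membership = membership, class = c("ortholog_matrix", "matrix"))
}

#' Rarefaction of core-genome, pangenome and new-gene curves
#'
#' For each of `replicates` uniformly random genome orderings and each
#' prefix size `g`, computes the core genome (OGs present in all of the
#' first `g` genomes), the pangenome (OGs present in at least one) and
#' the genome-specific fraction (OGs the `g`-th genome adds that none of
#' the first `g - 1` carry). Per-position means and standard deviations
#' across replicates summarise the curves; `pan(g) = pan(g-1) + new(g)`
#' holds within every replicate.
#'
#' @param om An OG count matrix (OG x genome).
#' @param replicates Number of random orderings (default 100).
#' @param seed Integer seed controlling the orderings.
#' @return A `rarefaction` object: `replicates` (long tibble `replicate`,
#'   `g`, `metric`, `value`) and `summary` (tibble `g`, `metric`, `mean`,
#'   `sd`).
#' @export
rarefy <- function(om, replicates = 100, seed = 1) {
  if (replicates < 1) stopf("`replicates` must be at least 1")
  P <- om >= 1
  N <- ncol(P)
  tri <- upper.tri(matrix(0, N, N), diag = TRUE)  # cumulative presence
  tri <- matrix(as.numeric(tri), N, N)
  rows <- with_seed(seed, {
    map(seq_len(replicates), function(r) {
      perm <- sample.int(N)
      cum <- P[, perm, drop = FALSE] %*% tri  # og x g: count among first g
      pan <- colSums(cum >= 1)
      core <- colSums(cum == matrix(seq_len(N), nrow(P), N, byrow = TRUE))
      new <- diff(c(0L, pan))
      tibble(replicate = r, g = rep(seq_len(N), 3),
             metric = rep(c("core", "pan", "new"), each = N),
             value = c(core, pan, new))
    })
  })
  reps <- bind_rows(rows)
  summary <- summarise(group_by(reps, .data$g, .data$metric),
                       mean = mean(.data$value),
                       sd = if (dplyr::n() > 1) sd(.data$value) else 0,
                       .groups = "drop")
  structure(list(replicates = reps, summary = summary,
                 n_genomes = N, n_replicates = replicates, seed = seed),
            class = "rarefaction")
}

#' @export
print.rarefaction <- function(x, ...) {
  fin <- x$summary[x$summary$g == x$n_genomes, ]
  core <- fin$mean[fin$metric == "core"]
  pan <- fin$mean[fin$metric == "pan"]
  cat(sprintf(
    "<rarefaction> %d genomes, %d replicates; core(N)=%d, pan(N)=%d\n",
    x$n_genomes, x$n_replicates, as.integer(core), as.integer(pan)))
  invisible(x)
}

#' @rdname rarefy
#' @param x,object A `rarefaction`.
#' @param ... Unused.
#' @export
tidy.rarefaction <- function(x, ...) x$summary

#' @rdname rarefy
#' @export
glance.rarefaction <- function(x, ...) {
  fin <- x$summary[x$summary$g == x$n_genomes, ]
  tibble(n_genomes = x$n_genomes, n_replicates = x$n_replicates,
         core_final = fin$mean[fin$metric == "core"],
         pan_final = fin$mean[fin$metric == "pan"],
         new_final_mean = fin$mean[fin$metric == "new"])
}

#' @rdname rarefy
#' @export
autoplot.rarefaction <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$g, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "genomes sampled",
                  y = "orthologous groups (mean ± sd)") +
    ggplot2::theme_minimal()
}

#' Single-copy core orthologous groups
#'
#' OGs with exactly one copy in every genome, ordered by OG id — the gene
#' set a concatenated core-genome phylogeny is built from.
#'
#' @param om An OG count matrix (OG x genome).
#' @return Character vector of OG ids.
#' @export
single_copy_core <- function(om) {
  sort(rownames(om)[apply(om == 1, 1, all)])
}

#' Read/write OG count tables
#'
#' TSV with OG ids in the first column and one column per genome
#' (OrthoFinder `Orthogroups.GeneCount.tsv` layout; a trailing `Total`
#' column is dropped on read).
#'
#' @param om OG count matrix.
#' @param path File path.
#' @name og_io
NULL

#' @rdname og_io
#' @export
write_og_table <- function(om, path) {
  df <- data.frame(Orthogroup = rownames(om), om, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname og_io
#' @export
read_og_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (tolower(names(df)[ncol(df)]) == "total") df <- df[, -ncol(df)]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write OG membership (og_id, genome_id, protein_id) as TSV
#'
#' @param om An `ortholog_matrix` from [build_orthologs()].
#' @param path File path.
#' @export
write_og_membership <- function(om, path) {
  membership <- attr(om, "membership")
  if (is.null(membership)) stopf("this OG table carries no membership detail")
  write.table(membership, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
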