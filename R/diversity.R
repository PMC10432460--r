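#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree spanning a set of tips.
#' With `include_root = TRUE` (the default, matching the convention of
#' the classic community-phylogenetics implementations) the path from
#' the spanned clade up to the root is included; with `FALSE` only edges
#' strictly below the most recent common ancestor of the tips count.
#'
#' @param tree An `ape` `phylo` with branch lengths.
#' @param tips Character vector of tip labels (non-empty, all present).
#' @param include_root Include the path to the root (default `TRUE`).
#' @return Total branch length of the spanning subtree.
#' @export
faith_pd <- function(tree, tips, include_root = TRUE) {
  if (!length(tips)) stopf("`tips` must be non-empty")
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) {
    stopf("unknown tip(s): %s", paste(unknown, collapse = ", "))
  }
  sel <- tree$tip.label %in% tips
  counts <- edge_tip_counts(tree, matrix(as.numeric(sel), ncol = 1))
  pd_from_counts(tree, counts, k = sum(sel), include_root = include_root)[1]
}

# Per-edge count of selected tips below the child node of each edge.
# `membership` is an n_tip x C numeric matrix; returns an n_edge x C
# matrix aligned with tree$edge rows.
edge_tip_counts <- function(tree, membership) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  C <- ncol(membership)
  acc <- matrix(0, nrow = nt + nn, ncol = C)
  acc[seq_len(nt), ] <- membership
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    acc[parent, ] <- acc[parent, ] + acc[child, ]
  }
  acc[tree$edge[, 2], , drop = FALSE]
}

# PD per membership column from per-edge counts. For include_root, every
# edge with at least one selected tip below contributes; otherwise edges
# carrying all k selected tips (the MRCA-to-root path) are excluded.
pd_from_counts <- function(tree, counts, k, include_root) {
  len <- tree$edge.length
  if (include_root) {
    as.numeric(crossprod(counts >= 1, len))
  } else {
    contrib <- (counts >= 1) & (counts < matrix(k, nrow(counts), ncol(counts),
                                                byrow = TRUE))
    as.numeric(crossprod(contrib, len))
  }
}

#' Standardised effect size of Faith's PD per species cluster
#'
#' For every cluster of the partition, compares the observed PD of its
#' member tips with a null distribution obtained by shuffling taxon
#' labels uniformly across the tree's tips (`randomisations` independent
#' shuffles, all clusters evaluated on the same shuffle). The
#' standardised effect size is `SES = (obs - null_mean) / null_sd`; a
#' negative SES means the cluster's tips span less branch length than
#' random tip sets of the same size (phylogenetic clustering). When the
#' null is degenerate (zero variance, e.g. a cluster containing every
#' tip) SES is reported as 0 with `degenerate = TRUE`.
#'
#' @param tree An `ape` `phylo` with branch lengths.
#' @param partition Partition tibble (`genome_id`, `cluster`); ids must
#'   be tree tips.
#' @param randomisations Number of label shuffles (default 999).
#' @param seed Integer seed.
#' @param include_root Passed to the PD computation.
#' @return A `pd_result` tibble: `cluster`, `n_tips`, `pd_obs`,
#'   `null_mean`, `null_sd`, `ses`, `p_lower`, `degenerate`, with the
#'   randomisation count as attribute `randomisations`.
#' @export
ses_pd <- function(tree, partition, randomisations = 999, seed = 1,
                   include_root = TRUE) {
  partition <- as_partition(partition)
  unknown <- setdiff(partition$genome_id, tree$tip.label)
  if (length(unknown)) {
    stopf("partition ids missing from tree: %s", paste(unknown, collapse = ", "))
  }
  clusters <- sort(unique(partition$cluster))
  sizes <- table(partition$cluster)[clusters]
  if (any(sizes == 0)) {
    warn("empty cluster(s) skipped")
    clusters <- clusters[sizes > 0]
  }
  nt <- length(tree$tip.label)
  membership <- matrix(0, nrow = nt, ncol = length(clusters),
                       dimnames = list(tree$tip.label, clusters))
  for (ci in seq_along(clusters)) {
    ids <- partition$genome_id[partition$cluster == clusters[ci]]
    membership[ids, ci] <- 1
  }
  k <- colSums(membership)
  obs <- pd_for_membership(tree, membership, k, include_root)
  null_mat <- with_seed(seed, {
    vapply(seq_len(randomisations), function(r) {
      perm <- sample.int(nt)
      pd_for_membership(tree, membership[perm, , drop = FALSE], k, include_root)
    }, numeric(length(clusters)))
  })
  null_mat <- matrix(null_mat, nrow = length(clusters))
  null_mean <- rowMeans(null_mat)
  null_sd <- apply(null_mat, 1, sd)
  degenerate <- null_sd < 1e-12
  ses <- ifelse(degenerate, 0, (obs - null_mean) / null_sd)
  p_lower <- (rowSums(null_mat <= obs + 1e-12) + 1) / (randomisations + 1)
  out <- tibble(cluster = clusters, n_tips = as.integer(k), pd_obs = obs,
                null_mean = null_mean, null_sd = null_sd, ses = ses,
                p_lower = p_lower, degenerate = degenerate)
  attr(out, "randomisations") <- randomisations
  attr(out, "include_root") <- include_root
  class(out) <- c("pd_result", class(out))
  out
}

pd_for_membership <- function(tree, membership, k, include_root) {
  counts <- edge_tip_counts(tree, membership)
  pd_from_counts(tree, counts, k, include_root)
}

#' @rdname ses_pd
#' @param object A `pd_result`.
#' @param ... Unused.
#' @export
autoplot.pd_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cluster, y = .data$ses)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "species cluster", y = "SES of Faith's PD") +
    ggplot2::theme_minimal()
}

#' Score multi-gene characters across genomes
#'
#' A character (e.g. a biosynthetic or toxin gene cluster) is defined by
#' the set of orthologous groups its genes belong to. For each genome the
#' score is the percentage of the character's OGs with at least one copy;
#' the character is called present when the percentage is at least 50
#' (inclusive), the conventional presence rule for cluster heatmaps. OG
#' ids absent from the table count as absent everywhere; copy number
#' beyond presence does not change the score.
#'
#' @param om OG count matrix (OG x genome).
#' @param specs Named list: character name -> character vector of OG ids.
#' @param exclude Optional named list of OG ids to drop from the
#'   corresponding spec (removal of non-specific wider groups).
#' @param presence_threshold Presence cutoff in percent (default 50).
#' @return A `character_calls` tibble: `genome_id`, `character`,
#'   `percentage`, `present`.
#' @export
score_characters <- function(om, specs, exclude = NULL,
                             presence_threshold = 50) {
  if (!length(specs) || is.null(names(specs))) {
    stopf("`specs` must be a non-empty named list of OG id vectors")
  }
  rows <- imap(specs, function(og_ids, name) {
    og_ids <- unique(og_ids)
    if (!is.null(exclude[[name]])) og_ids <- setdiff(og_ids, exclude[[name]])
    if (!length(og_ids)) stopf("character '%s' has an empty OG set", name)
    present_ogs <- intersect(og_ids, rownames(om))
    hit <- if (length(present_ogs)) {
      colSums(om[present_ogs, , drop = FALSE] >= 1)
    } else {
      setNames(rep(0L, ncol(om)), colnames(om))
    }
    pct <- 100 * hit / length(og_ids)
    tibble(genome_id = colnames(om), character = name,
           percentage = unname(pct),
           present = unname(pct >= presence_threshold))
  })
  out <- bind_rows(rows)
  class(out) <- c("character_calls", class(out))
  out
}

#' @rdname score_characters
#' @param object A `character_calls`.
#' @param ... Unused.
#' @export
autoplot.character_calls <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$character, y = .data$genome_id,
                                       fill = .data$percentage)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "% genes\npresent") +
    ggplot2::theme_minimal()
}

#' Write SES-PD and character tables as TSV
#'
#' @param x A `pd_result` or `character_calls`.
#' @param path File path.
#' @export
write_tsv_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
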