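#' Neighbour-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomerative algorithm: at each step join the pair
#' `(i, j)` minimising `Q(i, j) = (n - 2) d(i, j) - r_i - r_j` (with
#' `r_i` the row sum over active nodes). Ties in `Q` (within 1e-12) are
#' broken by the lexicographically smallest label pair, where an internal
#' node inherits the smallest tip label beneath it, so the output is
#' fully deterministic. Negative branch-length estimates are clamped to
#' zero with a warning. The result is the standard unrooted NJ topology,
#' returned as an [ape::read.tree()] `phylo` with a basal trifurcation.
#'
#' @param dm Labelled symmetric distance matrix with at least 3 taxa.
#' @return An `ape` `phylo` tree whose tips are the matrix labels.
#' @export
neighbour_joining <- function(dm) {
  validate_distance_matrix(dm, unit_range = FALSE)
  n <- nrow(dm)
  if (n < 3) stopf("neighbour joining needs at least 3 taxa")
  labels <- rownames(dm)
  quote_tip <- function(x) {
    if (grepl("[ ()\\[\\]:;,']", x)) paste0("'", gsub("'", "''", x), "'") else x
  }
  # active nodes: newick fragment + ordering label (smallest tip below)
  newick <- setNames(as.list(vapply(labels, quote_tip, character(1))), labels)
  ord_label <- setNames(labels, labels)
  D <- dm
  clamped <- FALSE
  fmt <- function(x) {
    if (x < 0) { clamped <<- TRUE; x <- 0 }
    sprintf("%.12g", x)
  }
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      pair <- sort(c(ord_label[rownames(D)[ij[1]]], ord_label[rownames(D)[ij[2]]]))
      paste(pair, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- rownames(D)[pick[1]]; j <- rownames(D)[pick[2]]
    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    others <- setdiff(rownames(D), c(i, j))
    dnew <- (D[i, others] + D[j, others] - dij) / 2
    node_lab <- min(ord_label[i], ord_label[j])
    nw <- paste0("(", newick[[i]], ":", fmt(li), ",",
                 newick[[j]], ":", fmt(lj), ")")
    D <- D[others, others, drop = FALSE]
    D <- rbind(cbind(D, new = dnew[others]), new = c(dnew[others], 0))
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- node_lab
    # replace bookkeeping (node label may collide with the tip it inherits
    # from; the tip itself has been consumed, so reuse is safe)
    newick[c(i, j)] <- NULL
    newick[[node_lab]] <- nw
    ord_label <- ord_label[names(ord_label) %in% names(newick)]
    ord_label[node_lab] <- node_lab
    D <- D[names(newick), names(newick), drop = FALSE]
  }
  # closed-form resolution of the final three nodes
  abc <- rownames(D)
  la <- (D[abc[1], abc[2]] + D[abc[1], abc[3]] - D[abc[2], abc[3]]) / 2
  lb <- (D[abc[1], abc[2]] + D[abc[2], abc[3]] - D[abc[1], abc[3]]) / 2
  lc <- (D[abc[1], abc[3]] + D[abc[2], abc[3]] - D[abc[1], abc[2]]) / 2
  tree_str <- paste0("(", newick[[abc[1]]], ":", fmt(la), ",",
                     newick[[abc[2]]], ":", fmt(lb), ",",
                     newick[[abc[3]]], ":", fmt(lc), ");")
  if (clamped) warn("negative neighbour-joining branch length(s) clamped to 0")
  tree <- ape::read.tree(text = tree_str)
  tree
}

#' Cut hierarchical clusterings at a distance threshold
#'
#' Agglomerative clustering of an intergenomic distance matrix with the
#' three linkages of the species-delimitation scan, parameterised as
#' `F = 0` (single), `F = 0.5` (average/UPGMA) and `F = 1` (complete).
#' The dendrogram is cut at height `T`: merges at height <= `T` are
#' applied (inclusive, consistent with the inclusive distance thresholds
#' used throughout).
#'
#' @param dm Labelled symmetric distance matrix.
#' @param F Linkage selector: 0, 0.5 or 1.
#' @param T Cut height (distance threshold), >= 0.
#' @return A partition tibble (`genome_id`, `cluster`).
#' @export
linkage_cluster <- function(dm, F, T) {
  validate_distance_matrix(dm)
  if (T < 0) stopf("`T` must be non-negative")
  method <- linkage_method(F)
  hc <- hclust(as.dist(dm), method = method)
  as_partition(cutree_at(hc, T))
}

linkage_method <- function(F) {
  if (isTRUE(all.equal(F, 0))) return("single")
  if (isTRUE(all.equal(F, 0.5))) return("average")
  if (isTRUE(all.equal(F, 1))) return("complete")
  stopf("`F` must be 0 (single), 0.5 (average) or 1 (complete)")
}

# cutree with inclusive height semantics robust to floating noise.
cutree_at <- function(hc, T) {
  cutree(hc, h = T + 1e-12)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two partitions of the same genomes:
#' `ARI = (sum_ij C(n_ij, 2) - E) / (M - E)` with
#' `E = sum_i C(a_i, 2) * sum_j C(b_j, 2) / C(n, 2)` and
#' `M = (sum_i C(a_i, 2) + sum_j C(b_j, 2)) / 2`. In the degenerate case
#' `M = E` (e.g. all singletons in both, or a single cluster in both) the
#' index is defined as 1 when the partitions are identical up to
#' relabelling and 0 otherwise.
#'
#' @param p,q Partitions (tibbles `genome_id`/`cluster` or named
#'   vectors) over the same genome ids.
#' @return ARI in \[-1, 1\]; 1 iff the partitions agree up to labels.
#' @export
adjusted_rand_index <- function(p, q) {
  p <- as_partition(p); q <- as_partition(q)
  if (!setequal(p$genome_id, q$genome_id)) {
    stopf("partitions must cover the same genome ids")
  }
  q <- q[match(p$genome_id, q$genome_id), ]
  ari_vec(p$cluster, q$cluster)
}

# ARI on two aligned label vectors (the formula core shared with the
# delimitation scan's inner loop)
ari_vec <- function(x, y) {
  tab <- table(x, y)
  ch2 <- function(v) v * (v - 1) / 2
  n <- sum(tab)
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  E <- sum_a * sum_b / ch2(n)
  M <- (sum_a + sum_b) / 2
  if (isTRUE(all.equal(M, E))) {
    same <- sum_ij == sum_a && sum_ij == sum_b
    return(as.numeric(same))
  }
  (sum_ij - E) / (M - E)
}

#' Reference species partition at the dDDH-70% threshold
#'
#' The reference partition for the delimitation scan: connected
#' components of the graph joining genomes at distance <= `T_ref`
#' (equivalently, a single-linkage cut at `T_ref`). The default
#' `T_ref = 0.036` is the distance equivalent of dDDH 70%, the
#' conventional same-species boundary.
#'
#' @param dm Labelled symmetric distance matrix.
#' @param T_ref Inclusive threshold; default 0.036.
#' @return A partition tibble (`genome_id`, `cluster`).
#' @export
reference_partition <- function(dm, T_ref = 0.036) {
  linkage_cluster(dm, F = 0, T = T_ref)
}

#' Species-delimitation scan over linkages and thresholds
#'
#' Evaluates hierarchical clusterings for every linkage
#' `F in {0, 0.5, 1}` over a grid of distance thresholds `T` from 0 to
#' the maximum observed distance in steps of `step` (default 0.0005),
#' scoring each partition against the reference partition with the
#' adjusted Rand index. The best record maximises ARI; ties go to the
#' smallest `T`, then the smallest `F`.
#'
#' @param dm Labelled symmetric distance matrix (>= 2 genomes).
#' @param step Threshold grid step; default 0.0005.
#' @param T_ref Reference threshold passed to [reference_partition()].
#' @param reference Optional user-supplied reference partition replacing
#'   the dDDH-70% single-linkage reference.
#' @param linkages Linkage selectors to scan; default `c(0, 0.5, 1)`.
#' @return A `species_scan` object: `grid` (tibble `F`, `T`, `k`,
#'   `ari`), `best` (one-row tibble), `best_partition`, `reference`.
#' @export
delimit_species <- function(dm, step = 0.0005, T_ref = 0.036,
                            reference = NULL, linkages = c(0, 0.5, 1)) {
  validate_distance_matrix(dm)
  if (nrow(dm) < 2) stopf("need at least 2 genomes to delimit species")
  if (step <= 0) stopf("`step` must be positive")
  reference <- if (is.null(reference)) reference_partition(dm, T_ref)
               else as_partition(reference)
  tmax <- max(dm)
  grid_T <- seq(0, tmax + step, by = step)  # spans 0..max(distance)
  grid_T <- grid_T[grid_T <= tmax + step / 2]
  ref_labels <- reference$cluster[match(rownames(dm), reference$genome_id)]
  rows <- list()
  for (F in linkages) {
    hc <- hclust(as.dist(dm), method = linkage_method(F))
    cuts <- cutree(hc, h = grid_T + 1e-12)
    if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = length(grid_T))
    k <- unname(apply(cuts, 2, function(v) length(unique(v))))
    ari <- unname(apply(cuts, 2, ari_vec, y = ref_labels))
    rows[[length(rows) + 1L]] <- tibble(F = F, T = grid_T, k = k, ari = ari)
  }
  grid <- bind_rows(rows)
  # tie resolution: maximal ARI, then smallest T, then smallest F
  top <- grid[grid$ari >= max(grid$ari) - 1e-12, ]
  top <- top[order(top$T, top$F), ][1, ]
  best_hc <- hclust(as.dist(dm), method = linkage_method(top$F))
  best_partition <- as_partition(cutree_at(best_hc, top$T))
  structure(
    list(grid = grid, best = top, best_partition = best_partition,
         reference = reference, step = step, T_ref = T_ref),
    class = "species_scan"
  )
}

#' @export
print.species_scan <- function(x, ...) {
  cat(sprintf(paste0(
    "<species_scan> %d grid points; best: F=%g, T=%g -> k=%d, ARI=%.4f\n"),
    nrow(x$grid), x$best$F, x$best$T, x$best$k, x$best$ari))
  invisible(x)
}

#' @rdname delimit_species
#' @param x A `species_scan`.
#' @param ... Unused.
#' @export
tidy.species_scan <- function(x, ...) x$grid

#' @rdname delimit_species
#' @export
glance.species_scan <- function(x, ...) {
  mutate(x$best, n_genomes = nrow(x$reference), step = x$step,
         T_ref = x$T_ref)
}

#' @rdname delimit_species
#' @param object A `species_scan`.
#' @export
autoplot.species_scan <- function(object, ...) {
  grid <- mutate(object$grid, linkage = factor(
    .data$F, levels = c(0, 0.5, 1),
    labels = c("single (F=0)", "average (F=0.5)", "complete (F=1)")))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$T, y = .data$ari,
                                     colour = .data$linkage)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best$T, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "distance threshold T", y = "adjusted Rand index",
                  colour = NULL,
                  title = sprintf("best: k = %d clusters at T = %g (ARI = %.3f)",
                                  object$best$k, object$best$T,
                                  object$best$ari)) +
    ggplot2::theme_minimal()
}

#' Write/read delimitation outputs
#'
#' The scan grid as TSV (`F`, `T`, `k`, `ari`) and partitions as
#' two-column TSV (`genome_id`, `cluster`).
#'
#' @param scan A `species_scan`.
#' @param partition A partition tibble.
#' @param path Output path.
#' @name clustering_io
NULL

#' @rdname clustering_io
#' @export
write_scan_grid <- function(scan, path) {
  write.table(scan$grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname clustering_io
#' @export
write_partition <- function(partition, path) {
  write.table(as_partition(partition), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname clustering_io
#' @export
read_partition <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  names(df)[1:2] <- c("genome_id", "cluster")
  as_partition(df)
}
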