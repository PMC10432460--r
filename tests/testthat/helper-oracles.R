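# Independent oracles and shared fixtures for the test suite.

# Small collections are reused across files; build lazily and cache.
.fixture_env <- new.env(parent = emptyenv())

tiny_collection <- function() {
  if (is.null(.fixture_env$tiny)) {
    .fixture_env$tiny <- simulate_collection(simulation_config(
      n_species = 3, genomes_per_species = c(2, 2, 2),
      core_pool_size = 8, species_pool_size = 3, strain_pool_rate = 1,
      island_bearing_species = c(1, 3), island_gene_count = 4,
      flank_length = 400, seed = 101))
  }
  .fixture_env$tiny
}

island_collection <- function() {
  if (is.null(.fixture_env$island)) {
    .fixture_env$island <- simulate_collection(simulation_config(
      n_species = 4, genomes_per_species = c(2, 2, 2, 2),
      core_pool_size = 10, species_pool_size = 3, strain_pool_rate = 1,
      island_bearing_species = c(1, 3), island_gene_count = 8,
      flank_length = 500, seed = 202))
  }
  .fixture_env$island
}

# --- ARI oracle: direct pair-counting evaluation ------------------------
# Counts the four pair categories over all unordered item pairs and
# applies the Hubert-Arabie adjusted index in its 2x2 pair-table form --
# an independent route from the contingency-sum formula in the package.
ari_pair_counting <- function(x, y) {
  n <- length(x)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- x[i] == x[j]; sy <- y[i] == y[j]
      if (sx && sy) a <- a + 1
      else if (sx && !sy) b <- b + 1
      else if (!sx && sy) c_ <- c_ + 1
      else d <- d + 1
    }
  }
  num <- 2 * (a * d - b * c_)
  den <- (a + b) * (b + d) + (a + c_) * (c_ + d)
  if (den == 0) return(as.numeric(b == 0 && c_ == 0))
  num / den
}

# All set partitions of n items as a list of label vectors.
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- all_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    k <- max(p)
    for (lab in seq_len(k + 1L)) out[[length(out) + 1L]] <- c(p, lab)
  }
  out
}

# --- brute-force agglomerative clustering oracle ------------------------
# Recomputes the linkage value between every pair of clusters from the
# raw distances at each merge, rather than via Lance-Williams updates.
brute_linkage_cut <- function(dm, method, T) {
  clusters <- as.list(rownames(dm))
  link <- function(c1, c2) {
    vals <- dm[c1, c2, drop = FALSE]
    switch(method, single = min(vals), complete = max(vals),
           average = mean(vals))
  }
  repeat {
    if (length(clusters) == 1) break
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        v <- link(clusters[[i]], clusters[[j]])
        if (is.null(best) || v < best$v - 1e-12) best <- list(i = i, j = j, v = v)
      }
    }
    if (best$v > T + 1e-12) break
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  lab <- rep(NA_integer_, nrow(dm))
  names(lab) <- rownames(dm)
  for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
  tibble::tibble(genome_id = names(lab), cluster = as.character(lab))
}

random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("t%02d", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.01, 0.99)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Random additive (tree-derived) distance matrix plus its source tree.
random_additive_matrix <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  list(tree = tr, dm = d[ord, ord] / max(d))
}

partitions_equal <- function(p, q) {
  isTRUE(all.equal(adjusted_rand_index(p, q), 1))
}
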