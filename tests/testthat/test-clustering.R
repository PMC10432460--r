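test_that("neighbour joining resolves the 4-taxon additive worked example", {
  ids <- c("A", "B", "C", "D")
  dm <- matrix(c(0, 3, 3, 4,
                 3, 0, 4, 5,
                 3, 4, 0, 3,
                 4, 5, 3, 0), 4, 4, dimnames = list(ids, ids))
  tr <- neighbour_joining(dm)
  # additivity: the tree's path lengths reproduce the matrix exactly
  co <- ape::cophenetic.phylo(tr)[ids, ids]
  expect_equal(co, dm, tolerance = 1e-9)
  # topology AB|CD with internal branch length 1
  internal <- tr$edge.length[tr$edge[, 2] > ape::Ntip(tr)]
  expect_equal(internal, 1, tolerance = 1e-9)
  expect_true(ape::is.monophyletic(tr, c("A", "B")))
  expect_error(neighbour_joining(dm[1:2, 1:2]), "3")
})

test_that("neighbour joining exactly recovers random additive matrices", {
  for (seed in 1:50) {
    fx <- random_additive_matrix(8, seed)
    tr <- neighbour_joining(fx$dm)
    co <- ape::cophenetic.phylo(tr)[rownames(fx$dm), colnames(fx$dm)]
    expect_equal(co, fx$dm, tolerance = 1e-8)
  }
})

test_that("neighbour joining agrees with the reference NJ implementation", {
  fx <- random_distance_matrix(10, 31)
  ours <- suppressWarnings(neighbour_joining(fx))
  ref <- ape::nj(as.dist(fx))
  expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
  # same estimates up to the clamping of negative branch lengths
  expect_equal(sum(ours$edge.length), sum(pmax(ref$edge.length, 0)),
               tolerance = 1e-8)
})

test_that("linkage cuts behave at the extremes and on block matrices", {
  ids <- c("a1", "a2", "b1", "b2")
  dm <- matrix(0.2, 4, 4, dimnames = list(ids, ids))
  dm[1:2, 1:2] <- 0.01; dm[3:4, 3:4] <- 0.01
  diag(dm) <- 0
  truth <- tibble::tibble(genome_id = ids, cluster = c("A", "A", "B", "B"))
  for (F in c(0, 0.5, 1)) {
    expect_true(partitions_equal(linkage_cluster(dm, F, 0.036), truth))
  }
  rnd <- random_distance_matrix(6, 7)
  expect_equal(n_clusters(linkage_cluster(rnd, 0.5, 0)), 6)      # T = 0
  expect_equal(n_clusters(linkage_cluster(rnd, 1, max(rnd))), 1) # T >= max
  expect_error(linkage_cluster(rnd, 0.3, 0.1), "F")
})

test_that("linkage clustering matches a from-scratch agglomerative oracle", {
  for (seed in 1:6) {
    dm <- random_distance_matrix(8, 100 + seed)
    for (spec in list(c(0, NA), c(0.5, NA), c(1, NA))) {
      F <- spec[1]
      method <- c(`0` = "single", `0.5` = "average", `1` = "complete")[
        as.character(F)]
      for (T in c(0.2, 0.4, 0.6, 0.8)) {
        ours <- linkage_cluster(dm, F, T)
        oracle <- brute_linkage_cut(dm, method, T)
        expect_true(partitions_equal(ours, oracle),
                    label = sprintf("seed %d, F=%s, T=%s", seed, F, T))
      }
    }
  }
})

test_that("ARI matches its worked values and is symmetric", {
  ids <- c("A", "B", "C", "D")
  p <- tibble::tibble(genome_id = ids, cluster = c("1", "1", "2", "2"))
  q <- tibble::tibble(genome_id = ids, cluster = c("1", "2", "1", "2"))
  expect_equal(adjusted_rand_index(p, p), 1)
  expect_equal(adjusted_rand_index(p, q), -0.5)
  expect_equal(adjusted_rand_index(q, p), -0.5)
  singletons <- tibble::tibble(genome_id = ids, cluster = ids)
  lumped <- tibble::tibble(genome_id = ids, cluster = rep("x", 4))
  expect_equal(adjusted_rand_index(singletons, lumped), 0)
  # degenerate identical cases agree up to relabelling -> 1
  expect_equal(adjusted_rand_index(singletons, singletons), 1)
  expect_equal(adjusted_rand_index(lumped, lumped), 1)
  expect_error(adjusted_rand_index(p, p[1:3, ]), "same genome ids")
})

test_that("ARI agrees with an independent pair-counting oracle", {
  set.seed(99)
  ids <- sprintf("i%d", 1:8)
  for (r in 1:60) {
    x <- sample(1:3, 8, replace = TRUE)
    y <- sample(1:4, 8, replace = TRUE)
    ours <- adjusted_rand_index(
      tibble::tibble(genome_id = ids, cluster = as.character(x)),
      tibble::tibble(genome_id = ids, cluster = as.character(y)))
    expect_equal(ours, ari_pair_counting(x, y), tolerance = 1e-12)
    if (requireNamespace("mclust", quietly = TRUE)) {
      expect_equal(ours, mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
    }
  }
})

test_that("the reference partition is single-linkage chaining at 0.036", {
  ids <- c("a", "b", "c")
  dm <- matrix(c(0, 0.03, 0.05,
                 0.03, 0, 0.03,
                 0.05, 0.03, 0), 3, 3, dimnames = list(ids, ids))
  # chaining: a-b and b-c linked, so one component despite d(a,c) > T
  ref <- reference_partition(dm, 0.036)
  expect_equal(n_clusters(ref), 1)
  far <- matrix(c(0, 0.1, 0.1, 0.1, 0, 0.1, 0.1, 0.1, 0), 3, 3,
                dimnames = list(ids, ids))
  expect_equal(n_clusters(reference_partition(far, 0.036)), 3)
})

test_that("the delimitation scan recovers planted species and obeys its invariants", {
  col <- tiny_collection()
  scan <- delimit_species(col$planted_distances)
  expect_equal(scan$best$ari, 1)
  expect_equal(scan$best$k, col$config$n_species)
  expect_true(partitions_equal(scan$best_partition, col$planted_partition))
  grid <- tidy(scan)
  # monotone coarsening: k non-increasing in T for fixed linkage
  for (F in unique(grid$F)) {
    ks <- grid$k[grid$F == F][order(grid$T[grid$F == F])]
    expect_true(all(diff(ks) <= 0))
  }
  # linkage ordering at every threshold
  wide <- tidyr::pivot_wider(grid[, c("F", "T", "k")], names_from = "F",
                             values_from = "k")
  expect_true(all(wide$`0` <= wide$`0.5`))
  expect_true(all(wide$`0.5` <= wide$`1`))
  expect_error(delimit_species(col$planted_distances, step = 0), "step")
  expect_error(delimit_species(col$planted_distances[1, 1, drop = FALSE]),
               "square|2 genomes")
  # glance/tidy expose the scan surface
  expect_named(glance(scan),
               c("F", "T", "k", "ari", "n_genomes", "step", "T_ref"))
  expect_s3_class(autoplot(scan), "ggplot")
})
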