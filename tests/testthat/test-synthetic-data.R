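test_that("configuration errors name the offending field", {
  expect_error(simulation_config(n_species = 3, genomes_per_species = c(2, 2)),
               "genomes_per_species")
  expect_error(simulation_config(mutation_rate_within = 1.5),
               "mutation_rate_within")
  expect_error(simulation_config(island_gene_count = 0), "island_gene_count")
  expect_error(simulation_config(n_species = 2, genomes_per_species = c(2, 0)),
               "genomes_per_species")
})

test_that("mutate_sequence honours the substitution model", {
  s <- strrep("ACGT", 25)
  expect_identical(mutate_sequence(s, 0, seed = 1), s)
  # rate 1: with a 3-letter substitution alphabet no site keeps its base
  m1 <- mutate_sequence(s, 1, seed = 2)
  expect_equal(nchar(m1), nchar(s))
  expect_false(any(strsplit(m1, "")[[1]] == strsplit(s, "")[[1]]))
  # binomial oracle: observed mismatch fraction within 3 SE of the rate
  long <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                collapse = "")
  m2 <- mutate_sequence(long, 0.1, seed = 3)
  frac <- mean(strsplit(m2, "")[[1]] != strsplit(long, "")[[1]])
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(frac - 0.1), 3 * se)
  expect_error(mutate_sequence(s, -0.1), "rate")
  # determinism under seed
  expect_identical(mutate_sequence(s, 0.3, seed = 9),
                   mutate_sequence(s, 0.3, seed = 9))
})

test_that("the generator is byte-deterministic under its seed", {
  cfg <- simulation_config(n_species = 2, genomes_per_species = c(2, 2),
                           core_pool_size = 5, species_pool_size = 2,
                           strain_pool_rate = 1, island_bearing_species = 1,
                           island_gene_count = 3, flank_length = 200, seed = 77)
  a <- simulate_collection(cfg)
  b <- simulate_collection(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("planted structure matches the configuration", {
  col <- tiny_collection()
  cfg <- col$config
  expect_equal(n_clusters(col$planted_partition), cfg$n_species)
  expect_equal(nrow(col$planted_partition), sum(cfg$genomes_per_species))
  # distance matrix invariants
  dm <- col$planted_distances
  expect_true(all(diag(dm) == 0))
  expect_equal(dm, t(dm))
  # island truth exactly covers island-bearing species
  sp <- col$planted_partition$cluster[match(names(col$island_truth),
                                            col$planted_partition$genome_id)]
  bearing <- sprintf("sp%02d", cfg$island_bearing_species)
  expect_identical(unname(col$island_truth), sp %in% bearing)
  # OG ground truth: OGs present in every genome = the core pool
  core_ogs <- rownames(col$planted_og_table)[
    apply(col$planted_og_table >= 1, 1, all)]
  expect_equal(length(core_ogs), cfg$core_pool_size)
  expect_true(all(grepl("^core", core_ogs)))
})

test_that("one species yields a single planted block", {
  col <- simulate_collection(simulation_config(
    n_species = 1, genomes_per_species = 3, core_pool_size = 5,
    species_pool_size = 2, strain_pool_rate = 0,
    island_bearing_species = integer(), island_gene_count = 1,
    flank_length = 0, seed = 5))
  expect_equal(n_clusters(col$planted_partition), 1)
  expect_equal(nrow(col$planted_partition), 3)
  expect_false(any(col$island_truth))
})

test_that("species-separable planted distances are recovered by all linkages", {
  col <- tiny_collection()
  expect_true(is_species_separable(col$config))
  for (F in c(0, 0.5, 1)) {
    part <- linkage_cluster(col$planted_distances, F = F, T = 0.036)
    expect_equal(adjusted_rand_index(part, col$planted_partition), 1)
  }
})

test_that("written genomes round-trip through FASTA/GFF3", {
  col <- tiny_collection()
  dir <- withr::local_tempdir()
  write_collection(col, dir)
  g0 <- col$genomes[[1]]
  g1 <- read_genome(file.path(dir, "genomes", paste0(g0$id, ".fna")),
                    file.path(dir, "genomes", paste0(g0$id, ".gff")),
                    file.path(dir, "genomes", paste0(g0$id, ".faa")),
                    id = g0$id)
  expect_identical(g1$replicons, g0$replicons)
  expect_identical(g1$proteome[names(g0$proteome)], g0$proteome)
  ord <- order(g0$genes$start)
  expect_equal(g1$genes[order(g1$genes$start), c("protein_id", "start", "end", "strand")],
               g0$genes[ord, c("protein_id", "start", "end", "strand")],
               ignore_attr = TRUE)
  # planted tables round-trip
  dm <- read_distance_matrix(file.path(dir, "planted_distances.tsv"))
  expect_equal(dm, col$planted_distances, tolerance = 1e-5)
  part <- read_partition(file.path(dir, "planted_partition.tsv"))
  expect_true(partitions_equal(part, col$planted_partition))
})

test_that("genome records reject inconsistent annotations", {
  expect_error(genome_record("g", c(chr = "ACGTACGT"),
                             tibble::tibble(protein_id = "p1", replicon = "chr",
                                            start = 5L, end = 20L, strand = "+")),
               "bounds")
  expect_error(genome_record("g", c(chr = "ACGTACGT"),
                             tibble::tibble(protein_id = c("p1", "p1"),
                                            replicon = "chr",
                                            start = c(1L, 2L), end = c(3L, 4L),
                                            strand = "+")),
               "unique")
})
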