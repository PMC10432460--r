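aa_random <- function(n, seed) {
  set.seed(seed)
  paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")), n,
               replace = TRUE), collapse = "")
}

test_that("reciprocal-best-hit orthology groups shared and private genes", {
  x <- aa_random(80, 1); y <- aa_random(80, 2); z <- aa_random(60, 3)
  tweak <- function(s, k) {  # a few substitutions, identity stays high
    cs <- strsplit(s, "")[[1]]
    set.seed(k)
    idx <- sample(length(cs), 3)
    cs[idx] <- "W"
    paste(cs, collapse = "")
  }
  proteomes <- list(
    g1 = c(g1.x = x, g1.y = y),
    g2 = c(g2.x = tweak(x, 4), g2.y = tweak(y, 5)),
    g3 = c(g3.x = tweak(x, 6), g3.y = tweak(y, 7), g3.z = z)
  )
  om <- build_orthologs(proteomes)
  expect_equal(nrow(om), 3)  # x-family, y-family, private z
  shared <- rownames(om)[apply(om >= 1, 1, all)]
  expect_equal(length(shared), 2)
  expect_true(all(om[shared, ] == 1))
  private <- rownames(om)[rowSums(om >= 1) == 1]
  memb <- attr(om, "membership")
  expect_equal(memb$protein_id[memb$og_id == private], "g3.z")
  expect_error(build_orthologs(list(g1 = c(p = x), g2 = character())),
               "g2")
})

test_that("orthology on synthetic proteomes reproduces the planted pools", {
  col <- tiny_collection()
  om <- build_orthologs(col)
  expect_equal(nrow(om), nrow(col$planted_og_table))
  expect_equal(sort(colnames(om)), sort(colnames(col$planted_og_table)))
  # per-genome OG presence counts agree with the planted table
  expect_equal(unname(colSums(om >= 1)[colnames(col$planted_og_table)]),
               unname(colSums(col$planted_og_table >= 1)))
  # single-copy core equals the planted core pool size
  expect_equal(length(single_copy_core(om)), col$config$core_pool_size)
})

test_that("rarefaction matches the exhaustive-ordering oracle", {
  om <- matrix(0L, 5, 3,
               dimnames = list(paste0("og", 1:5), c("A", "B", "C")))
  om[c(1, 2, 3), "A"] <- 1L
  om[c(1, 2, 4), "B"] <- 1L
  om[c(1, 5), "C"] <- 1L
  r <- rarefy(om, replicates = 600, seed = 11)
  reps <- r$replicates
  # order-independent totals in every replicate
  expect_true(all(reps$value[reps$g == 3 & reps$metric == "pan"] == 5))
  expect_true(all(reps$value[reps$g == 3 & reps$metric == "core"] == 1))
  # mean new(2): enumeration over all 6 orderings gives 8/6
  # (AB:1, AC:1, BA:1, BC:1, CA:2, CB:2); sd of the 6 values is 0.516,
  # so 600 draws put the sample mean within ~0.07 of 8/6 at 3 SE
  mean_new2 <- r$summary$mean[r$summary$g == 2 & r$summary$metric == "new"]
  expect_lt(abs(mean_new2 - 8 / 6), 3 * 0.5164 / sqrt(600))
  # core(1) = pan(1) = sampled genome's OG count in every replicate
  first <- reps[reps$g == 1, ]
  expect_true(all(first$value[first$metric == "core"] ==
                  first$value[first$metric == "pan"]))
})

test_that("rarefaction curves are monotone and internally consistent", {
  set.seed(42)
  for (r in 1:20) {
    m <- matrix(rbinom(20 * 5, 1, 0.5), 20, 5,
                dimnames = list(sprintf("og%02d", 1:20), sprintf("g%d", 1:5)))
    res <- rarefy(m, replicates = 5, seed = r)
    for (rep_id in unique(res$replicates$replicate)) {
      sub <- res$replicates[res$replicates$replicate == rep_id, ]
      pan <- sub$value[sub$metric == "pan"][order(sub$g[sub$metric == "pan"])]
      core <- sub$value[sub$metric == "core"][order(sub$g[sub$metric == "core"])]
      new <- sub$value[sub$metric == "new"][order(sub$g[sub$metric == "new"])]
      expect_true(all(diff(pan) >= 0))
      expect_true(all(diff(core) <= 0))
      expect_true(all(core <= pan))
      expect_equal(pan, cumsum(new))
    }
  }
})

test_that("identical genomes give flat curves and no new genes", {
  m <- matrix(1L, 6, 4, dimnames = list(sprintf("og%d", 1:6),
                                        sprintf("g%d", 1:4)))
  res <- rarefy(m, replicates = 3, seed = 1)
  s <- res$summary
  expect_true(all(s$mean[s$metric == "core"] == 6))
  expect_true(all(s$mean[s$metric == "pan"] == 6))
  expect_true(all(s$mean[s$metric == "new" & s$g >= 2] == 0))
  # final core/pan identical across replicates (permutation invariance)
  fin <- res$replicates[res$replicates$g == 4, ]
  expect_equal(length(unique(fin$value[fin$metric == "pan"])), 1)
  expect_equal(length(unique(fin$value[fin$metric == "core"])), 1)
})

test_that("rarefaction is deterministic under its seed", {
  om <- tiny_collection()$planted_og_table
  a <- rarefy(om, replicates = 10, seed = 3)
  b <- rarefy(om, replicates = 10, seed = 3)
  expect_identical(a$replicates, b$replicates)
})

test_that("single-copy core applies the strict copy-number rule", {
  m <- matrix(1L, 3, 3, dimnames = list(c("a", "b", "c"), c("g1", "g2", "g3")))
  m["b", "g2"] <- 2L  # duplicated in one genome -> excluded
  m["c", "g3"] <- 0L  # missing in one genome -> excluded
  expect_identical(single_copy_core(m), "a")
})

test_that("OG tables round-trip and accept the GeneCount layout", {
  om <- tiny_collection()$planted_og_table
  path <- withr::local_tempfile(fileext = ".tsv")
  write_og_table(om, path)
  expect_equal(read_og_table(path), om)
  # tolerated: an OrthoFinder-style trailing Total column
  df <- data.frame(Orthogroup = rownames(om), om, Total = rowSums(om),
                   check.names = FALSE)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_og_table(path2), om)
})
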