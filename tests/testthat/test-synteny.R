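# Build a genome carrying (a possibly modified copy of) the island of the
# shared fixture collection, reusing its query cluster as ground truth.

test_that("an exact island copy is found with all genes at 100%", {
  col <- island_collection()
  q <- island_query_cluster(col)
  src <- names(col$island_truth)[col$island_truth][1]
  locus <- find_cluster(col$genomes[[src]], q)
  expect_false(is.null(locus))
  expect_equal(nrow(locus$matches), 8)
  expect_equal(locus$matches$identity, rep(1, 8))
  expect_identical(locus$orientation, "+")
  expect_error(find_cluster(genome_record("empty", c(chr = "ACGT")), q),
               "annotation")
})

test_that("islands below the identity threshold are not called", {
  col <- island_collection()
  q <- island_query_cluster(col)
  src <- names(col$island_truth)[col$island_truth][1]
  g <- col$genomes[[src]]
  # degrade every protein to ~60% identity (below the 70% rule)
  degraded <- g
  set.seed(5)
  degraded$proteome <- vapply(g$proteome, function(aa) {
    cs <- strsplit(aa, "")[[1]]
    idx <- sample(length(cs), ceiling(0.4 * length(cs)))
    cs[idx] <- ifelse(cs[idx] == "W", "Y", "W")
    paste(cs, collapse = "")
  }, character(1))
  expect_null(find_cluster(degraded, q))
})

test_that("a truncated gene is unmatched but the locus survives", {
  col <- island_collection()
  q <- island_query_cluster(col)
  src <- names(col$island_truth)[col$island_truth][1]
  g <- col$genomes[[src]]
  # halve one island protein: full-length identity can reach at most 50%
  pid <- paste0(src, ".", col$island_og_ids[3])
  g$proteome[[pid]] <- substr(g$proteome[[pid]], 1,
                              nchar(g$proteome[[pid]]) %/% 2)
  locus <- find_cluster(g, q)
  expect_false(is.null(locus))
  expect_equal(nrow(locus$matches), 7)
  expect_false(col$island_og_ids[3] %in% locus$matches$gene_name)
})

test_that("cluster finding is orientation invariant", {
  col <- island_collection()
  q <- island_query_cluster(col)
  src <- names(col$island_truth)[col$island_truth][2]
  g <- col$genomes[[src]]
  fwd <- find_cluster(g, q)
  # reverse-complement the replicon and flip the annotation
  n <- nchar(g$replicons[["chr"]])
  rc <- genome_record(
    paste0(g$id, "_rc"),
    c(chr = paste(rev(strsplit(chartr("ACGT", "TGCA", g$replicons[["chr"]]),
                               "")[[1]]), collapse = "")),
    tibble::tibble(protein_id = g$genes$protein_id, replicon = "chr",
                   start = n - g$genes$end + 1L, end = n - g$genes$start + 1L,
                   strand = ifelse(g$genes$strand == "+", "-", "+")),
    g$proteome)
  rev_hit <- find_cluster(rc, q)
  expect_false(is.null(rev_hit))
  expect_identical(rev_hit$orientation, "-")
  ord <- order(fwd$matches$gene_name)
  ord2 <- order(rev_hit$matches$gene_name)
  expect_equal(rev_hit$matches$identity[ord2], fwd$matches$identity[ord])
})

test_that("island presence agrees with character scoring and island truth", {
  col <- island_collection()
  hits <- find_cluster_all(col, island_query_cluster(col))
  expect_identical(setNames(hits$table$present, hits$table$genome_id),
                   col$island_truth[hits$table$genome_id])
  calls <- score_characters(col$planted_og_table, island_character_spec(col))
  merged <- merge(hits$table[, c("genome_id", "present")],
                  as.data.frame(calls)[, c("genome_id", "present")],
                  by = "genome_id")
  expect_identical(merged$present.x, merged$present.y)
})

test_that("flank extraction truncates at replicon ends and respects strand", {
  g <- genome_record("g", c(chr = strrep("ACGT", 2500)))  # 10 kb
  locus <- structure(list(genome_id = "g", replicon = "chr", start = 2001L,
                          end = 3000L, strand = "+", orientation = "+"),
                     class = "island_locus")
  fl <- extract_flanks(g, locus, flank_length = 5000)
  expect_equal(nchar(fl$upstream), 2000)   # truncated at the start
  expect_equal(nchar(fl$downstream), 5000)
  expect_identical(fl$upstream, substr(g$replicons[["chr"]], 1, 2000))
  # at the far end the downstream flank empties
  locus_end <- structure(list(genome_id = "g", replicon = "chr", start = 9001L,
                              end = 10000L, strand = "+", orientation = "+"),
                         class = "island_locus")
  fl2 <- extract_flanks(g, locus_end, flank_length = 1000)
  expect_identical(fl2$downstream, "")
  # minus orientation: flanks swapped and reverse-complemented
  locus_rc <- structure(list(genome_id = "g", replicon = "chr", start = 2001L,
                             end = 3000L, strand = "-", orientation = "-"),
                        class = "island_locus")
  fl3 <- extract_flanks(g, locus_rc, flank_length = 1000)
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  expect_identical(fl3$upstream, rc(substr(g$replicons[["chr"]], 3001, 4000)))
  expect_identical(fl3$downstream, rc(substr(g$replicons[["chr"]], 1001, 2000)))
})

test_that("cluster identity matrix tracks planted divergence", {
  col <- island_collection()
  hits <- find_cluster_all(col, island_query_cluster(col))
  im <- cluster_identity_matrix(hits$loci, col)
  expect_true(all(diag(im) == 100))
  expect_equal(im, t(im))
  # same-species island copies differ only by the within-species rate
  # (~1% per genome); cross-species pairs add the scaled island rate
  ids <- names(hits$loci)
  sp <- sub("_g\\d+$", "", ids)
  same <- outer(sp, sp, "==") & upper.tri(im)
  cross <- (!outer(sp, sp, "==")) & upper.tri(im)
  expect_gt(min(im[same]), 95)
  expect_gt(min(im[cross]), 82)   # conserved island: high identity overall
  expect_gt(mean(im[same]), mean(im[cross]))
  expect_error(cluster_identity_matrix(hits$loci[1], col), "2 loci")
})

test_that("the island protein tree separates planted variants", {
  col <- island_collection()
  q <- island_query_cluster(col)
  hits <- find_cluster_all(col, q)
  tr <- cluster_protein_tree(hits$loci, q, col)
  expect_setequal(tr$tip.label, names(hits$loci))
  # genomes of the same species must be sisters on the island tree
  sp_groups <- split(names(hits$loci), sub("_g\\d+$", "", names(hits$loci)))
  for (grp in sp_groups) {
    if (length(grp) >= 2) expect_true(ape::is.monophyletic(tr, grp))
  }
  expect_error(cluster_protein_tree(hits$loci[1:2], q, col), "3 loci")
})

test_that("identical loci give a zero-length star tree", {
  col <- island_collection()
  q <- island_query_cluster(col)
  src <- names(col$island_truth)[col$island_truth][1]
  locus <- find_cluster(col$genomes[[src]], q)
  loci <- list(a = locus, b = locus, c = locus)
  genomes <- list(a = col$genomes[[src]], b = col$genomes[[src]],
                  c = col$genomes[[src]])
  genomes <- lapply(genomes, function(g) g)
  tr <- cluster_protein_tree(loci, q, genomes)
  expect_equal(sum(tr$edge.length), 0)
})
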