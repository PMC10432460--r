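#' Configure a synthetic genome collection
#'
#' Builds the configuration for [simulate_collection()]. The generator
#' plants a known species structure: genomes fall into species whose
#' pairwise intergenomic distances sit below the dDDH-70% species
#' threshold (0.036) within species and above it between species, so the
#' species-delimitation scan has a recoverable ground truth. Gene content
#' follows a three-pool model — a core pool shared by every genome, a
#' species pool shared within each species, and strain-private genes —
#' plus an optional contiguous multi-gene toxin island with flanking
#' context carried by a configurable subset of species.
#'
#' Defaults emulate the structure of the *P. protegens* subgroup study
#' system at desk scale: 12 species of unequal size, an 8-gene
#' insecticidal-island analogue absent from three species, and mutation
#' rates calibrated so sequence-derived distances respect the planted
#' within/between ranges.
#'
#' @param n_species Number of planted species.
#' @param genomes_per_species Integer vector (length `n_species`) of
#'   genomes per species.
#' @param within_distance_range Range (pair of fractions) for planted
#'   within-species distances.
#' @param between_distance_min,between_distance_max Range for planted
#'   between-species distances.
#' @param core_pool_size Genes present in every genome.
#' @param species_pool_size Genes private to each species.
#' @param strain_pool_rate Strain-private genes per genome.
#' @param island_bearing_species Indices of species carrying the island.
#' @param island_gene_count Genes in the island (contiguous, strand
#'   consistent).
#' @param flank_length Length (bp) of the conserved flanks either side of
#'   the island.
#' @param mutation_rate_within Per-site substitution probability from a
#'   species ancestor to each genome.
#' @param mutation_rate_between Per-site substitution probability from the
#'   root ancestor to each species.
#' @param island_mutation_scale Multiplier applied to
#'   `mutation_rate_between` for island genes and flanks. The island is
#'   modelled as a recently acquired, strongly conserved genomic island:
#'   across real island-bearing strains the cluster retains high
#'   nucleotide identity and full-length protein homology, so its
#'   between-species divergence is a fraction of the genome background
#'   (default 0.25).
#' @param gene_length Gene length in bp (multiple of 3; genes are forced
#'   ORFs with no internal stop so translation is well defined).
#' @param spacer_length Intergenic spacer per gene cassette (bp).
#' @param seed Integer seed; fully determines all generator output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_species = 12,
                              genomes_per_species = c(8, 6, 5, 5, 4, 4, 3, 3, 2, 2, 2, 2),
                              within_distance_range = c(0.005, 0.03),
                              between_distance_min = 0.08,
                              between_distance_max = 0.14,
                              core_pool_size = 30,
                              species_pool_size = 8,
                              strain_pool_rate = 2,
                              island_bearing_species = setdiff(seq_len(n_species), c(2, 8, 9)),
                              island_gene_count = 8,
                              flank_length = 2000,
                              mutation_rate_within = 0.01,
                              mutation_rate_between = 0.06,
                              island_mutation_scale = 0.25,
                              gene_length = 300,
                              spacer_length = 30,
                              seed = 1) {
  cfg <- list(
    n_species = as.integer(n_species),
    genomes_per_species = as.integer(genomes_per_species),
    within_distance_range = within_distance_range,
    between_distance_min = between_distance_min,
    between_distance_max = between_distance_max,
    core_pool_size = as.integer(core_pool_size),
    species_pool_size = as.integer(species_pool_size),
    strain_pool_rate = as.integer(strain_pool_rate),
    island_bearing_species = as.integer(island_bearing_species),
    island_gene_count = as.integer(island_gene_count),
    flank_length = as.integer(flank_length),
    mutation_rate_within = mutation_rate_within,
    mutation_rate_between = mutation_rate_between,
    island_mutation_scale = island_mutation_scale,
    gene_length = as.integer(gene_length),
    spacer_length = as.integer(spacer_length),
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_species < 1) stopf("`n_species` must be a positive integer")
  if (length(cfg$genomes_per_species) != cfg$n_species) {
    stopf("`genomes_per_species` must have length `n_species` (%d != %d)",
          length(cfg$genomes_per_species), cfg$n_species)
  }
  if (any(cfg$genomes_per_species < 1)) {
    stopf("`genomes_per_species` entries must be positive")
  }
  if (length(cfg$within_distance_range) != 2 ||
      cfg$within_distance_range[1] > cfg$within_distance_range[2]) {
    stopf("`within_distance_range` must be an increasing pair")
  }
  assert_fraction(cfg$within_distance_range, "within_distance_range", 0, 1)
  assert_fraction(cfg$between_distance_min, "between_distance_min", 0, 1)
  if (cfg$between_distance_max < cfg$between_distance_min) {
    stopf("`between_distance_max` must be >= `between_distance_min`")
  }
  if (length(cfg$island_bearing_species) &&
      (min(cfg$island_bearing_species) < 1 ||
       max(cfg$island_bearing_species) > cfg$n_species)) {
    stopf("`island_bearing_species` indices must lie in 1..n_species")
  }
  if (cfg$island_gene_count < 1) stopf("`island_gene_count` must be positive")
  if (cfg$flank_length < 0) stopf("`flank_length` must be non-negative")
  if (cfg$core_pool_size < 0 || cfg$species_pool_size < 0 ||
      cfg$strain_pool_rate < 0) {
    stopf("gene pool sizes must be non-negative")
  }
  assert_fraction(cfg$mutation_rate_within, "mutation_rate_within")
  assert_fraction(cfg$mutation_rate_between, "mutation_rate_between")
  if (cfg$island_mutation_scale < 0 || cfg$island_mutation_scale > 1) {
    stopf("`island_mutation_scale` must lie in [0, 1]")
  }
  if (cfg$gene_length %% 3 != 0 || cfg$gene_length < 6) {
    stopf("`gene_length` must be a multiple of 3 and at least 6")
  }
  invisible(cfg)
}

#' Is a configuration species-separable?
#'
#' A configuration is species-separable when every planted within-species
#' distance is below the dDDH-70% threshold (0.036) and every
#' between-species distance is at or above it, so any of the three
#' linkages cut at 0.036 must recover the planted partition.
#'
#' @param config A [simulation_config()].
#' @param threshold Species threshold; default 0.036.
#' @return Logical.
#' @export
is_species_separable <- function(config, threshold = 0.036) {
  max(config$within_distance_range) < threshold &&
    config$between_distance_min >= threshold
}

#' Mutate a DNA sequence at a fixed per-site substitution rate
#'
#' Each position is substituted independently with probability `rate`; a
#' substituted base is drawn uniformly from the three alternatives, so a
#' mutated position never retains its original letter. Output length
#' equals input length and the result is fully determined by `seed`.
#'
#' @param seq DNA string (A/C/G/T).
#' @param rate Substitution probability per site, in \[0, 1\].
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return The mutated DNA string.
#' @export
mutate_sequence <- function(seq, rate, seed = NULL) {
  assert_fraction(rate, "rate")
  with_seed(seed, {
    cs <- chars(seq)
    n <- length(cs)
    if (n == 0) return("")
    hit <- runif(n) < rate
    if (any(hit)) {
      idx <- match(cs[hit], DNA_BASES)
      shift <- sample.int(3, sum(hit), replace = TRUE)
      cs[hit] <- DNA_BASES[(idx - 1 + shift) %% 4 + 1]
    }
    paste(cs, collapse = "")
  })
}

# A random forced ORF: ATG start then non-stop codons (standard table).
random_orf <- function(length_bp) {
  n_codons <- length_bp / 3 - 1
  codons <- apply(matrix(sample(DNA_BASES, 3 * n_codons, replace = TRUE),
                         nrow = 3), 2, paste, collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  while (any(codons %in% stops)) {
    bad <- codons %in% stops
    codons[bad] <- apply(matrix(sample(DNA_BASES, 3 * sum(bad), replace = TRUE),
                                nrow = 3), 2, paste, collapse = "")
  }
  paste0("ATG", paste(codons, collapse = ""))
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# standard-table translation via direct codon lookup (fast path for the
# generator's forced ORFs; substitution mutations may introduce stops,
# retained as "*")
translate_cds <- function(dna) {
  n <- nchar(dna) %/% 3
  codons <- substring(dna, 3 * seq_len(n) - 2, 3 * seq_len(n))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

#' Simulate a genome collection with planted species structure
#'
#' Generates annotated genomes, proteomes, a planted species partition, a
#' planted pairwise distance matrix and a ground-truth ortholog table.
#' Sequences descend from a common ancestor: each species mutates every
#' ancestral gene cassette at `mutation_rate_between`, and each genome
#' mutates its species version at `mutation_rate_within`, so
#' sequence-derived distances approximate the planted ones. Planted
#' distances themselves are drawn directly from the configured
#' within/between ranges, decoupling clustering tests from the fidelity
#' of the distance estimator. Gene order is randomised per genome except
#' the island, which stays contiguous and strand-consistent with
#' conserved flanks.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_collection`: list with elements `genomes` (named
#'   list of [genome_record()]s), `planted_partition` (tibble
#'   `genome_id`, `cluster`), `planted_distances` (labelled symmetric
#'   matrix), `planted_og_table` (OG x genome count matrix),
#'   `island_truth` (named logical), `island_og_ids` (ordered character)
#'   and `config`.
#' @export
simulate_collection <- function(config) {
  validate_simulation_config(config)
  with_seed(config$seed, {
    species_ids <- sprintf("sp%02d", seq_len(config$n_species))
    genome_ids <- unlist(map2(species_ids, config$genomes_per_species,
                              function(s, n) sprintf("%s_g%d", s, seq_len(n))))
    species_of <- rep(species_ids, config$genomes_per_species)
    names(species_of) <- genome_ids

    # --- ortholog pools -------------------------------------------------
    core_ogs <- sprintf("core%04d", seq_len(config$core_pool_size))
    species_ogs <- setNames(
      map(species_ids, function(s)
        if (config$species_pool_size > 0)
          sprintf("%s.acc%03d", s, seq_len(config$species_pool_size))
        else character()),
      species_ids)
    island_ogs <- if (length(config$island_bearing_species))
      sprintf("fit%02d", seq_len(config$island_gene_count)) else character()
    private_ogs <- setNames(
      map(genome_ids, function(g)
        if (config$strain_pool_rate > 0)
          sprintf("%s.pvt%03d", g, seq_len(config$strain_pool_rate))
        else character()),
      genome_ids)

    # --- ancestral sequences -------------------------------------------
    shared_ogs <- c(core_ogs, unlist(species_ogs, use.names = FALSE), island_ogs)
    anc_gene <- setNames(
      map_chr(shared_ogs, function(.) random_orf(config$gene_length)),
      shared_ogs)
    anc_spacer <- setNames(
      map_chr(shared_ogs, function(.) random_dna(config$spacer_length)),
      shared_ogs)
    og_strand <- setNames(sample(c("+", "-"), length(shared_ogs), replace = TRUE),
                          shared_ogs)
    og_strand[island_ogs] <- "+"  # island is strand-consistent
    anc_flank_up <- random_dna(config$flank_length)
    anc_flank_dn <- random_dna(config$flank_length)

    island_species <- species_ids[config$island_bearing_species]

    # species-level cassettes: one mutation pass from the root ancestor;
    # the island diverges slower than the genome background
    island_rate <- config$mutation_rate_between * config$island_mutation_scale
    species_gene <- map(species_ids, function(s) {
      ogs <- c(core_ogs, species_ogs[[s]],
               if (s %in% island_species) island_ogs)
      rates <- ifelse(ogs %in% island_ogs, island_rate,
                      config$mutation_rate_between)
      g <- map2(anc_gene[ogs], rates, function(sq, r) mutate_sequence(sq, r))
      setNames(unlist(g), ogs)
    })
    names(species_gene) <- species_ids
    species_spacer <- map(species_ids, function(s) {
      ogs <- names(species_gene[[s]])
      setNames(map_chr(anc_spacer[ogs], mutate_sequence,
                       rate = config$mutation_rate_between), ogs)
    })
    names(species_spacer) <- species_ids
    species_flanks <- map(species_ids, function(s) {
      if (!(s %in% island_species) || config$flank_length == 0) {
        return(list(up = "", dn = ""))
      }
      list(up = mutate_sequence(anc_flank_up, island_rate),
           dn = mutate_sequence(anc_flank_dn, island_rate))
    })
    names(species_flanks) <- species_ids

    # --- assemble genomes ----------------------------------------------
    genomes <- list()
    for (g in genome_ids) {
      s <- species_of[[g]]
      ogs <- names(species_gene[[s]])
      gene_seq <- map_chr(species_gene[[s]], mutate_sequence,
                          rate = config$mutation_rate_within)
      spacer_seq <- map_chr(species_spacer[[s]], mutate_sequence,
                            rate = config$mutation_rate_within)
      for (p in private_ogs[[g]]) {
        gene_seq[[p]] <- random_orf(config$gene_length)
        spacer_seq[[p]] <- random_dna(config$spacer_length)
        og_strand[[p]] <- sample(c("+", "-"), 1)
      }
      ogs <- names(gene_seq)
      has_island <- s %in% island_species
      non_island <- setdiff(ogs, island_ogs)
      order_non_island <- sample(non_island)

      flank_up <- flank_dn <- ""
      if (has_island && config$flank_length > 0) {
        flank_up <- mutate_sequence(species_flanks[[s]]$up,
                                    config$mutation_rate_within)
        flank_dn <- mutate_sequence(species_flanks[[s]]$dn,
                                    config$mutation_rate_within)
      }

      # cassette layout: shuffled non-island genes with the island block
      # (upstream flank + genes + downstream flank) spliced in contiguously
      insert_at <- if (has_island) sample.int(length(order_non_island) + 1, 1) else 0L
      layout <- list()
      for (i in seq_along(order_non_island)) {
        if (has_island && i == insert_at) layout <- c(layout, list("__ISLAND__"))
        layout <- c(layout, list(order_non_island[[i]]))
      }
      if (has_island && insert_at == length(order_non_island) + 1) {
        layout <- c(layout, list("__ISLAND__"))
      }

      seq_parts <- character()
      gene_rows <- list()
      pos <- 0L
      emit_cassette <- function(og) {
        strand <- og_strand[[og]]
        coding <- gene_seq[[og]]
        dna <- if (strand == "+") coding else revcomp(coding)
        seq_parts[[length(seq_parts) + 1L]] <<- paste0(dna, spacer_seq[[og]])
        gene_rows[[length(gene_rows) + 1L]] <<- tibble(
          protein_id = paste0(g, ".", og), replicon = "chr",
          start = pos + 1L, end = pos + nchar(coding), strand = strand)
        pos <<- pos + nchar(coding) + nchar(spacer_seq[[og]])
      }
      for (item in layout) {
        if (identical(item, "__ISLAND__")) {
          if (nchar(flank_up)) {
            seq_parts[[length(seq_parts) + 1L]] <- flank_up
            pos <- pos + nchar(flank_up)
          }
          for (og in island_ogs) emit_cassette(og)
          if (nchar(flank_dn)) {
            seq_parts[[length(seq_parts) + 1L]] <- flank_dn
            pos <- pos + nchar(flank_dn)
          }
        } else {
          emit_cassette(item)
        }
      }
      genes <- bind_rows(gene_rows)
      proteome <- setNames(map_chr(gene_seq[sub("^.*?\\.", "", genes$protein_id)],
                                   translate_cds),
                           genes$protein_id)
      genomes[[g]] <- genome_record(
        g, c(chr = paste(seq_parts, collapse = "")), genes, proteome)
    }

    # --- planted ground truth ------------------------------------------
    n <- length(genome_ids)
    dm <- matrix(0, n, n, dimnames = list(genome_ids, genome_ids))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        same <- species_of[[i]] == species_of[[j]]
        d <- if (same) {
          runif(1, config$within_distance_range[1], config$within_distance_range[2])
        } else {
          runif(1, config$between_distance_min, config$between_distance_max)
        }
        dm[i, j] <- dm[j, i] <- d
      }
    }

    all_ogs <- c(core_ogs, unlist(species_ogs, use.names = FALSE), island_ogs,
                 unlist(private_ogs, use.names = FALSE))
    og_table <- matrix(0L, nrow = length(all_ogs), ncol = n,
                       dimnames = list(all_ogs, genome_ids))
    for (g in genome_ids) {
      s <- species_of[[g]]
      present <- c(core_ogs, species_ogs[[s]],
                   if (s %in% island_species) island_ogs, private_ogs[[g]])
      og_table[present, g] <- 1L
    }

    structure(
      list(
        genomes = genomes,
        planted_partition = tibble(genome_id = genome_ids,
                                   cluster = unname(species_of)),
        planted_distances = dm,
        planted_og_table = og_table,
        island_truth = setNames(species_of %in% island_species, genome_ids),
        island_og_ids = island_ogs,
        config = config
      ),
      class = "synthetic_collection"
    )
  })
}

#' @export
print.synthetic_collection <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_collection> %d genomes in %d planted species; %d OGs; ",
    "island in %d genome(s)\n"),
    length(x$genomes), n_clusters(x$planted_partition),
    nrow(x$planted_og_table), sum(x$island_truth)))
  invisible(x)
}

#' Extract per-genome proteomes from a collection
#'
#' @param collection A `synthetic_collection`.
#' @return Named list: genome id -> named character vector of proteins.
#' @export
collection_proteomes <- function(collection) {
  map(collection$genomes, function(g) g$proteome)
}

#' Ground-truth character specification for the planted island
#'
#' @param collection A `synthetic_collection`.
#' @param name Character name; defaults to `"fit_island"`.
#' @return A named list suitable for [score_characters()].
#' @export
island_character_spec <- function(collection, name = "fit_island") {
  if (!length(collection$island_og_ids)) {
    stopf("the collection was simulated without an island")
  }
  setNames(list(collection$island_og_ids), name)
}

#' Write a synthetic collection to disk
#'
#' Writes one FASTA/GFF3/protein-FASTA trio per genome plus the planted
#' distance matrix (square TSV), the planted partition (two-column TSV)
#' and the planted OG count table (TSV).
#'
#' @param collection A `synthetic_collection`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in collection$genomes) write_genome(g, file.path(dir, "genomes"))
  write_distance_matrix(collection$planted_distances,
                        file.path(dir, "planted_distances.tsv"))
  write.table(collection$planted_partition,
              file.path(dir, "planted_partition.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_og_table(collection$planted_og_table,
                 file.path(dir, "planted_og_counts.tsv"))
  invisible(dir)
}
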