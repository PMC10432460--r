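#' Configure an end-to-end pipeline run
#'
#' Collects every stage parameter with defaults mirroring the standard
#' analysis settings: query filter 0.135, species threshold 0.036, scan
#' step 0.0005, 100 rarefaction replicates, 999 PD randomisations, 70%
#' full-length identity for island genes and the >=50% character
#' presence rule. Exactly one input mode applies: `"synthetic"`
#' (simulate a collection), `"files"` (FASTA + GFF3 + protein FASTA) or
#' `"matrix"` (a precomputed distance matrix, optionally with a
#' precomputed OG table).
#'
#' @param input_mode One of `"synthetic"`, `"files"`, `"matrix"`.
#' @param simulation A [simulation_config()] (synthetic mode).
#' @param genome_files Tibble/data frame with columns `fna`, `gff`,
#'   `faa` (files mode).
#' @param distance_matrix_path Path to a square distance TSV (matrix
#'   mode).
#' @param og_table_path Optional path to a precomputed OG count TSV.
#' @param stages Character vector of stages to run, any of
#'   `"distances"`, `"delimit"`, `"tree"`, `"pangenome"`, `"diversity"`,
#'   `"characters"`, `"synteny"`.
#' @param use_planted_distances,use_planted_og_table In synthetic mode,
#'   use the generator's planted channels (default) or recompute from
#'   sequences.
#' @param query_genome Genome id for the query-distance filter, or
#'   `NULL` to skip filtering.
#' @param query_threshold Inclusive query filter threshold.
#' @param formula,k,min_len Distance-kernel parameters.
#' @param step,T_ref Delimitation scan parameters.
#' @param replicates Rarefaction replicates.
#' @param randomisations PD null randomisations.
#' @param min_identity Island gene identity threshold.
#' @param max_gene_gap Island colinearity gap allowance.
#' @param flank_length Flank window for island context (bp).
#' @param seed Master seed; stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_mode = c("synthetic", "files", "matrix"),
                            simulation = simulation_config(),
                            genome_files = NULL,
                            distance_matrix_path = NULL,
                            og_table_path = NULL,
                            stages = c("distances", "delimit", "tree",
                                       "pangenome", "diversity",
                                       "characters", "synteny"),
                            use_planted_distances = TRUE,
                            use_planted_og_table = TRUE,
                            query_genome = NULL,
                            query_threshold = 0.135,
                            formula = "identity", k = 12L, min_len = 50L,
                            step = 0.0005, T_ref = 0.036,
                            replicates = 100, randomisations = 999,
                            min_identity = 0.70, max_gene_gap = 5L,
                            flank_length = 2000, seed = 1) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "files" && is.null(genome_files)) {
    stopf("files mode needs `genome_files`")
  }
  if (input_mode == "matrix" && is.null(distance_matrix_path)) {
    stopf("matrix mode needs `distance_matrix_path`")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order — input acquisition,
#' distances, query filtering, species delimitation, NJ phylogeny,
#' pangenome rarefaction, per-cluster SES of Faith's PD, character
#' scoring and island synteny — writing every stage output under
#' `outdir` (TSV tables, newick trees) plus a summary report. Stages
#' whose inputs are unavailable in the chosen mode (e.g. pangenome from
#' a bare distance matrix) are disabled with a warning. Fully
#' deterministic given the config's seed.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory, or `NULL` for no file output.
#' @return A `pipeline_report` list with the stage results.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    message(sprintf("[phylopan] %s: %s", stage, sprintf(...)))
  }
  report <- list(config = config)
  stages <- config$stages

  # --- inputs ----------------------------------------------------------
  collection <- NULL
  genomes <- NULL
  dm <- NULL
  og <- NULL
  if (config$input_mode == "synthetic") {
    collection <- simulate_collection(config$simulation)
    genomes <- collection$genomes
    log_stage("simulate", "%d genomes, %d planted species, seed %d",
              length(genomes), n_clusters(collection$planted_partition),
              config$simulation$seed)
    report$n_genomes <- length(genomes)
  } else if (config$input_mode == "files") {
    gf <- config$genome_files
    genomes <- map(seq_len(nrow(gf)), function(i) {
      read_genome(gf$fna[i], gf$gff[i], gf$faa[i])
    })
    names(genomes) <- map_chr(genomes, function(g) g$id)
    report$n_genomes <- length(genomes)
  } else {
    dm <- read_distance_matrix(config$distance_matrix_path)
    report$n_genomes <- nrow(dm)
    drop <- intersect(stages, c("synteny", "characters"))
    if (!is.null(config$og_table_path)) {
      og <- read_og_table(config$og_table_path)
      drop <- setdiff(drop, "characters")
    } else {
      drop <- union(drop, c("pangenome", "diversity"))
    }
    if (length(intersect(stages, drop))) {
      warn(sprintf("stage(s) disabled in matrix mode (no proteomes): %s",
                   paste(intersect(stages, drop), collapse = ", ")))
      stages <- setdiff(stages, drop)
    }
  }

  # --- distances -------------------------------------------------------
  if (is.null(dm) && "distances" %in% stages) {
    if (!is.null(collection) && config$use_planted_distances) {
      dm <- collection$planted_distances
      log_stage("distances", "using planted distance channel")
    } else {
      dm <- build_distance_matrix(genomes, formula = config$formula,
                                  k = config$k, min_len = config$min_len)
      log_stage("distances", "computed %dx%d matrix (formula=%s, k=%d, min_len=%d)",
                nrow(dm), ncol(dm), config$formula, config$k, config$min_len)
    }
  }
  if (!is.null(dm)) {
    report$distances <- dm
    if (!is.null(outdir)) {
      write_distance_matrix(dm, file.path(outdir, "distances.tsv"))
    }
  }

  # --- query filter ----------------------------------------------------
  if (!is.null(dm) && !is.null(config$query_genome)) {
    keep <- filter_by_query(dm[config$query_genome, ], config$query_threshold)
    log_stage("filter", "query %s, threshold %g: %d of %d genomes retained",
              config$query_genome, config$query_threshold, length(keep),
              nrow(dm))
    dm <- dm[keep, keep]
    if (!is.null(genomes)) genomes <- genomes[keep]
    report$retained <- keep
  }
  report$n_retained <- if (!is.null(dm)) nrow(dm) else report$n_genomes

  # --- species delimitation -------------------------------------------
  scan <- NULL
  if ("delimit" %in% stages && !is.null(dm)) {
    scan <- delimit_species(dm, step = config$step, T_ref = config$T_ref)
    log_stage("delimit", "best F=%g T=%g -> k=%d, ARI=%.3f",
              scan$best$F, scan$best$T, scan$best$k, scan$best$ari)
    report$scan <- scan
    if (!is.null(outdir)) {
      write_scan_grid(scan, file.path(outdir, "scan_grid.tsv"))
      write_partition(scan$best_partition,
                      file.path(outdir, "best_partition.tsv"))
    }
  }

  # --- NJ tree ---------------------------------------------------------
  tree <- NULL
  if ("tree" %in% stages && !is.null(dm) && nrow(dm) >= 3) {
    tree <- neighbour_joining(dm)
    report$tree <- tree
    if (!is.null(outdir)) {
      ape::write.tree(tree, file.path(outdir, "nj_tree.nwk"))
    }
    log_stage("tree", "neighbour-joining tree over %d genomes", nrow(dm))
  }

  # --- pangenome -------------------------------------------------------
  if ("pangenome" %in% stages) {
    if (is.null(og)) {
      if (!is.null(collection) && config$use_planted_og_table) {
        og <- collection$planted_og_table
        log_stage("pangenome", "using planted OG table (%d OGs)", nrow(og))
      } else if (!is.null(genomes)) {
        proteomes <- map(genomes, function(g) g$proteome)
        og <- build_orthologs(proteomes)
        log_stage("pangenome", "built %d OGs from %d proteomes",
                  nrow(og), length(proteomes))
      }
    }
    if (!is.null(og)) {
      og <- og[, intersect(colnames(og), rownames(dm %||% og)), drop = FALSE]
      rar <- rarefy(og, replicates = config$replicates,
                    seed = child_seed(config$seed, "rarefy"))
      report$og_table <- og
      report$rarefaction <- rar
      report$single_copy_core <- single_copy_core(og)
      log_stage("rarefy", "core(N)=%d, pan(N)=%d over %d replicates",
                as.integer(glance(rar)$core_final),
                as.integer(glance(rar)$pan_final), config$replicates)
      if (!is.null(outdir)) {
        write_og_table(og, file.path(outdir, "og_counts.tsv"))
        write.table(as.data.frame(tidy(rar)),
                    file.path(outdir, "rarefaction.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  # --- diversity -------------------------------------------------------
  if ("diversity" %in% stages && !is.null(tree) && !is.null(scan)) {
    pd <- ses_pd(tree, scan$best_partition,
                 randomisations = config$randomisations,
                 seed = child_seed(config$seed, "sespd"))
    report$pd <- pd
    log_stage("diversity", "SES-PD over %d clusters, %d randomisations",
              nrow(pd), config$randomisations)
    if (!is.null(outdir)) write_tsv_table(pd, file.path(outdir, "ses_pd.tsv"))
  }

  # --- characters ------------------------------------------------------
  if ("characters" %in% stages && !is.null(og) &&
      !is.null(collection) && length(collection$island_og_ids)) {
    calls <- score_characters(og_for_characters(og, collection),
                              island_character_spec(collection))
    report$characters <- calls
    log_stage("characters", "%d genomes scored for the island character",
              length(unique(calls$genome_id)))
    if (!is.null(outdir)) {
      write_tsv_table(calls, file.path(outdir, "character_calls.tsv"))
    }
  }

  # --- synteny ---------------------------------------------------------
  if ("synteny" %in% stages && !is.null(collection) &&
      length(collection$island_og_ids)) {
    query <- island_query_cluster(collection)
    hits <- find_cluster_all(genomes, query,
                             min_identity = config$min_identity,
                             max_gene_gap = config$max_gene_gap)
    report$island_table <- hits$table
    log_stage("synteny", "island located in %d of %d genomes",
              sum(hits$table$present), nrow(hits$table))
    if (length(hits$loci) >= 2) {
      report$island_identity <- cluster_identity_matrix(hits$loci, genomes,
                                                        k = config$k,
                                                        min_len = config$min_len)
    }
    if (length(hits$loci) >= 3) {
      report$island_tree <- cluster_protein_tree(hits$loci, query, genomes)
    }
    if (!is.null(outdir)) {
      write.table(as.data.frame(hits$table),
                  file.path(outdir, "island_loci.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(report$island_tree)) {
        ape::write.tree(report$island_tree,
                        file.path(outdir, "island_tree.nwk"))
      }
    }
  }

  if (!is.null(collection)) report$collection <- collection
  class(report) <- "pipeline_report"
  if (!is.null(outdir)) {
    writeLines(utils::capture.output(print(report)),
               file.path(outdir, "report.txt"))
  }
  report
}

# planted OG tables already key characters by OG id; computed tables need
# no mapping when planted ids are used, so pass through unchanged
og_for_characters <- function(og, collection) og

#' @export
print.pipeline_report <- function(x, ...) {
  cat("phylopan pipeline report\n")
  cat("========================\n")
  cat(sprintf("genomes: %d (retained after query filter: %d)\n",
              x$n_genomes, x$n_retained))
  if (!is.null(x$scan)) {
    cat(sprintf("species delimitation: k=%d at F=%g, T=%g (ARI=%.4f)\n",
                x$scan$best$k, x$scan$best$F, x$scan$best$T, x$scan$best$ari))
  }
  if (!is.null(x$rarefaction)) {
    gl <- glance(x$rarefaction)
    cat(sprintf("pangenome: core(N)=%d, pan(N)=%d, single-copy core=%d\n",
                as.integer(gl$core_final), as.integer(gl$pan_final),
                length(x$single_copy_core)))
  }
  if (!is.null(x$pd)) {
    cat(sprintf("SES-PD: %d clusters, SES range [%.2f, %.2f]\n",
                nrow(x$pd), min(x$pd$ses), max(x$pd$ses)))
  }
  if (!is.null(x$characters)) {
    cat(sprintf("island character present in %d genome(s)\n",
                sum(x$characters$present)))
  }
  if (!is.null(x$island_table)) {
    cat(sprintf("island locus found in %d genome(s)\n",
                sum(x$island_table$present)))
  }
  invisible(x)
}
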