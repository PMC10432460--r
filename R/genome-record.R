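#' Genome records
#'
#' A genome record bundles everything downstream stages need about one
#' assembly: its replicon sequences, its gene models (CDS coordinates,
#' 1-based inclusive, with strand) and its proteome. Gene model
#' `protein_id`s key into the proteome, mirroring the `ID=` attributes of
#' a GFF3 annotation.
#'
#' @param id Unique genome identifier.
#' @param replicons Named character vector of DNA sequences (A/C/G/T).
#' @param genes Data frame with columns `protein_id`, `replicon`, `start`,
#'   `end`, `strand` (`"+"` or `"-"`); coordinates 1-based inclusive.
#' @param proteome Named character vector of amino-acid sequences whose
#'   names match `genes$protein_id`.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, replicons, genes = NULL, proteome = NULL) {
  if (!is.character(id) || length(id) != 1 || !nzchar(id)) {
    stopf("`id` must be a single non-empty string")
  }
  if (is.null(names(replicons)) || anyDuplicated(names(replicons))) {
    stopf("replicons must carry unique names")
  }
  if (is.null(genes)) {
    genes <- tibble(protein_id = character(), replicon = character(),
                    start = integer(), end = integer(), strand = character())
  }
  genes <- tibble::as_tibble(genes)
  if (nrow(genes)) {
    if (anyDuplicated(genes$protein_id)) {
      stopf("protein ids must be unique within genome '%s'", id)
    }
    if (!all(genes$strand %in% c("+", "-"))) {
      stopf("gene strands must be '+' or '-' in genome '%s'", id)
    }
    if (any(genes$start > genes$end) || any(genes$start < 1)) {
      stopf("gene coordinates must satisfy 1 <= start <= end in genome '%s'", id)
    }
    rep_len_of <- nchar(replicons)[genes$replicon]
    if (any(is.na(rep_len_of)) || any(genes$end > rep_len_of)) {
      stopf("gene coordinates exceed replicon bounds in genome '%s'", id)
    }
  }
  if (!is.null(proteome) && nrow(genes) &&
      !all(genes$protein_id %in% names(proteome))) {
    stopf("every gene of genome '%s' must have a protein sequence", id)
  }
  structure(
    list(id = id, replicons = replicons, genes = genes,
         proteome = proteome %||% character()),
    class = "genome_record"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d replicon(s), %d bp, %d genes\n",
              x$id, length(x$replicons), sum(nchar(x$replicons)),
              nrow(x$genes)))
  invisible(x)
}

genome_length <- function(genome) sum(nchar(genome$replicons))

#' Write a genome record to FASTA, GFF3 and protein FASTA
#'
#' Emits `<id>.fna` (replicon DNA), `<id>.gff` (CDS features, 1-based
#' inclusive coordinates, `ID=` attributes) and `<id>.faa` (proteome with
#' ids matching the GFF `ID=` attributes) into `dir`.
#'
#' @param genome A [genome_record()].
#' @param dir Output directory, created if missing.
#' @return Invisibly, the three file paths.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fna <- file.path(dir, paste0(genome$id, ".fna"))
  gff <- file.path(dir, paste0(genome$id, ".gff"))
  faa <- file.path(dir, paste0(genome$id, ".faa"))
  dna <- Biostrings::DNAStringSet(genome$replicons)
  Biostrings::writeXStringSet(dna, fna)
  gr <- GenomicRanges::GRanges(
    seqnames = genome$genes$replicon,
    ranges = IRanges::IRanges(start = genome$genes$start,
                              end = genome$genes$end),
    strand = genome$genes$strand
  )
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$ID <- genome$genes$protein_id
  S4Vectors::mcols(gr)$source <- "phylopan"
  S4Vectors::mcols(gr)$phase <- 0L
  rtracklayer::export(gr, gff, format = "gff3")
  aa <- Biostrings::AAStringSet(genome$proteome)
  Biostrings::writeXStringSet(aa, faa)
  invisible(c(fna = fna, gff = gff, faa = faa))
}

#' Read a genome record from FASTA, GFF3 and protein FASTA
#'
#' @param fna Path to the nucleotide FASTA.
#' @param gff Path to the GFF3 annotation; `CDS` features with `ID=`
#'   attributes become gene models.
#' @param faa Path to the protein FASTA; ids must match the GFF `ID=`s.
#' @param id Genome identifier; defaults to the FASTA basename.
#' @return A [genome_record()].
#' @export
read_genome <- function(fna, gff = NULL, faa = NULL, id = NULL) {
  id <- id %||% sub("\\.(fa|fna|fasta)$", "", basename(fna))
  dna <- Biostrings::readDNAStringSet(fna)
  replicons <- setNames(as.character(dna), sub("\\s.*$", "", names(dna)))
  genes <- NULL
  if (!is.null(gff)) {
    gr <- rtracklayer::import(gff, format = "gff3")
    gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
    genes <- tibble(
      protein_id = as.character(S4Vectors::mcols(gr)$ID),
      replicon = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
  }
  proteome <- NULL
  if (!is.null(faa)) {
    aa <- Biostrings::readAAStringSet(faa)
    proteome <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  }
  genome_record(id, replicons, genes, proteome)
}
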