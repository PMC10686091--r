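#' Read and write the pipeline's tabular formats
#'
#' Thin readr-based readers for the package's TSV dialects. All genomic
#' coordinates in files are 1-based inclusive; BED input (0-based
#' half-open) is converted at this boundary only.
#'
#' @param path File path.
#' @return A tibble.
#' @name marshvar_io
NULL

#' @rdname marshvar_io
#' @export
read_pileup <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_cols(df, c("sample_id", "contig_id", "pos", paste0("count_", DNA_BASES)),
             sprintf("pileup file '%s'", path))
  df
}

#' @rdname marshvar_io
#' @export
read_coverage <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_cols(df, c("sample_id", "contig_id", "mean_coverage"),
             sprintf("coverage file '%s'", path))
  df
}

#' @rdname marshvar_io
#' @export
read_mag_manifest <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_cols(df, c("mag_id", "contig_id", "length", "completeness",
                   "contamination"), sprintf("MAG manifest '%s'", path))
  df
}

#' @rdname marshvar_io
#' @export
read_gene_presence <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_cols(df, c("mag_id", "gene", "copies"),
             sprintf("gene-presence file '%s'", path))
  df
}

#' Read gene/ORF annotation in GFF3 or BED dialect
#'
#' GFF3 is 1-based inclusive; BED is 0-based half-open and converted on
#' read. Returns the unified 1-based inclusive tibble used throughout the
#' package.
#'
#' @param path Annotation file.
#' @param dialect `"gff3"` (default) or `"bed"`.
#' @return A tibble: `gene_id`, `contig_id`, `start`, `end`, `strand`.
#' @export
read_annotation <- function(path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    df <- readr::read_tsv(path, comment = "#", col_names = c(
      "contig_id", "source", "type", "start", "end", "score", "strand",
      "phase", "attributes"), show_col_types = FALSE)
    ids <- stringr::str_match(df$attributes, "ID=([^;]+)")[, 2]
    tibble(gene_id = ids, contig_id = df$contig_id,
           start = df$start, end = df$end,
           strand = ifelse(df$strand %in% c("+", "-"), df$strand, "+"))
  } else {
    df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
    tibble(gene_id = if (ncol(df) >= 4) df[[4]] else
             sprintf("feature%04d", seq_len(nrow(df))),
           contig_id = df[[1]],
           start = df[[2]] + 1, end = df[[3]],
           strand = if (ncol(df) >= 6) df[[6]] else "+")
  }
}

#' @rdname marshvar_io
#' @param genes Annotation tibble (`gene_id`, `contig_id`, `start`, `end`,
#'   `strand`).
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tmarshvar\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$contig_id, as.integer(genes$start),
                     as.integer(genes$end), genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname marshvar_io
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname marshvar_io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits every file format the pipeline consumes — genome FASTA, GFF3
#' gene annotation, MAG manifest, gene-presence table, per-sample pileup
#' TSVs, coverage TSV, sample manifest — plus `truth.json`.
#'
#' @param community A `sim_community`.
#' @param dataset A `sim_dataset` from [simulate_sample_pileups()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sim_bundle <- function(community, dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_fasta(community$genomes, p("genomes.fasta"))
  write_gff3(community$genes, p("genes.gff3"))
  readr::write_tsv(community$mags, p("mags.tsv"))
  readr::write_tsv(community$gene_presence, p("gene_presence.tsv"))
  readr::write_tsv(dataset$coverage, p("coverage.tsv"))
  manifest <- dataset$samples
  manifest$pileup <- paste0("pileup_", manifest$sample_id, ".tsv")
  manifest$coverage <- "coverage.tsv"
  for (sid in manifest$sample_id) {
    readr::write_tsv(dataset$pileups[dataset$pileups$sample_id == sid, ],
                     p(paste0("pileup_", sid, ".tsv")))
  }
  readr::write_tsv(manifest[, c("sample_id", "site", "vegetation",
                                "library_reads", "pileup", "coverage")],
                   p("manifest.tsv"))
  truth <- list(community = community$truth, dataset = dataset$truth)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(dir)
}
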