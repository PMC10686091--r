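#' MAG quality score and screening gates
#'
#' Computes the composite quality score `completeness - 5 * contamination`
#' and applies the screening gates used to retain high-quality
#' metagenome-assembled genomes (MAGs): completeness above 90%,
#' contamination below 5%, and quality score of at least 65.
#'
#' Both completeness gates are strict (`> 90`, `< 5`); the score gate is
#' `>= 65`.
#'
#' @param completeness Numeric vector, percent in \[0, 100\].
#' @param contamination Numeric vector, percent, non-negative.
#' @return A tibble with columns `completeness`, `contamination`,
#'   `score` (points) and `passes` (logical).
#' @examples
#' quality_score(92, 1)
#' quality_score(c(90, 98), c(5, 6))
#' @export
quality_score <- function(completeness, contamination) {
  if (!is.numeric(completeness) || !is.numeric(contamination)) {
    abort("`completeness` and `contamination` must be numeric")
  }
  if (any(!is.finite(completeness)) || any(completeness < 0 | completeness > 100)) {
    abort("`completeness` must lie in [0, 100]")
  }
  if (any(!is.finite(contamination)) || any(contamination < 0)) {
    abort("`contamination` must be >= 0")
  }
  score <- completeness - 5 * contamination
  tibble(
    completeness = completeness,
    contamination = contamination,
    score = score,
    passes = completeness > 90 & contamination < 5 & score >= 65
  )
}

#' Screen a MAG table by quality
#'
#' Data-frame-first wrapper around [quality_score()]: takes a table with one
#' row per MAG (or a MAG manifest with one row per contig, which is first
#' collapsed) and appends `score` and `passes`.
#'
#' @param mags A data frame with columns `mag_id`, `completeness`,
#'   `contamination` (extra columns are preserved; duplicate `mag_id` rows
#'   with identical quality values are collapsed).
#' @return A tibble, one row per MAG, with `score` and `passes` appended.
#' @export
mag_quality <- function(mags) {
  check_cols(mags, c("mag_id", "completeness", "contamination"), "`mags`")
  mags <- distinct(as_tibble(mags), .data$mag_id, .data$completeness,
                   .data$contamination)
  if (anyDuplicated(mags$mag_id)) {
    abort("conflicting completeness/contamination values for the same mag_id")
  }
  qs <- quality_score(mags$completeness, mags$contamination)
  mutate(mags, score = qs$score, passes = qs$passes)
}

SULFUR_GENES_SRB <- c("sat", "aprA", "aprB", "dsrA", "dsrB")
SULFUR_GENES_SOX <- c("soxA", "soxX", "soxY", "soxZ", "soxB")
SULFUR_GENE_VOCAB <- c(
  SULFUR_GENES_SRB, SULFUR_GENES_SOX,
  "soxC", "soxD", "sqr", "soeA", "soeB", "soeC", "fccA", "fccB"
)

#' Classify sulfur-cycling guilds from marker-gene repertoires
#'
#' Sulfate reducers (SRB) are defined by the complete dissimilatory
#' sulfate-reduction pathway (`sat`, `aprA`, `aprB`, `dsrA`, `dsrB`, all
#' present); sulfur oxidizers (SOX) by the truncated thiosulfate oxidation
#' system (`soxA`, `soxX`, `soxY`, `soxZ`, `soxB`, all present). MAGs
#' meeting both criteria are labelled `"SRB+SOX"` and never silently
#' disambiguated (resolving oxidative vs reductive dsrAB types requires
#' dedicated typing outside this package's scope).
#'
#' Gene symbols outside the controlled vocabulary (the marker genes above
#' plus `soxC`, `soxD`, `sqr`, `soeA/B/C`, `fccA/B`, and any `hdr*`
#' subunit) raise a warning and are ignored.
#'
#' @param gene_presence A data frame with columns `gene` (symbol) and
#'   `copies` (count, >= 0), and optionally `mag_id` for multi-MAG tables.
#' @return A tibble with one row per MAG: `guild` (one of `"SRB"`, `"SOX"`,
#'   `"SRB+SOX"`, `"none"`) and list-columns `missing_srb`, `missing_sox`
#'   naming the absent genes of each unmet criterion (empty when met).
#' @export
classify_sulfur_guild <- function(gene_presence) {
  gene_presence <- as_tibble(gene_presence)
  if ("gene_symbol" %in% names(gene_presence) && !"gene" %in% names(gene_presence)) {
    gene_presence <- dplyr::rename(gene_presence, gene = "gene_symbol")
  }
  check_cols(gene_presence, c("gene", "copies"), "`gene_presence`")
  if (!"mag_id" %in% names(gene_presence)) gene_presence$mag_id <- "MAG"
  known <- gene_presence$gene %in% SULFUR_GENE_VOCAB |
    startsWith(gene_presence$gene, "hdr")
  if (any(!known)) {
    warn(sprintf("ignoring unknown gene symbol(s): %s",
                 paste(unique(gene_presence$gene[!known]), collapse = ", ")))
    gene_presence <- gene_presence[known, ]
  }
  mag_ids <- unique(gene_presence$mag_id)
  if (length(mag_ids) == 0) mag_ids <- "MAG"
  classify_one <- function(id) {
    genes <- gene_presence$gene[gene_presence$mag_id == id &
                                  gene_presence$copies >= 1]
    miss_srb <- setdiff(SULFUR_GENES_SRB, genes)
    miss_sox <- setdiff(SULFUR_GENES_SOX, genes)
    guild <- if (length(miss_srb) == 0 && length(miss_sox) == 0) "SRB+SOX"
      else if (length(miss_srb) == 0) "SRB"
      else if (length(miss_sox) == 0) "SOX"
      else "none"
    tibble(mag_id = id, guild = guild,
           missing_srb = list(miss_srb), missing_sox = list(miss_sox))
  }
  purrr::map_dfr(mag_ids, classify_one)
}
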