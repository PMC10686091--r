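#' Genome copies per million reads (GCPM) for one MAG in one sample
#'
#' The abundance of a MAG in a sample is the length-weighted average of its
#' contigs' mean per-base coverage values, standardized by library size per
#' one million metagenomic reads:
#' \deqn{\bar C = \sum_i cov_i \cdot len_i / \sum_i len_i, \quad
#'       GCPM = \bar C \times 10^6 / \mathrm{library\_reads}}
#'
#' @param contig_coverage A data frame with columns `contig_id` and
#'   `mean_coverage` (mean per-base coverage, >= 0).
#' @param mag A data frame describing the MAG's contigs, with columns
#'   `contig_id` and `length` (bp, > 0).
#' @param library_reads Total metagenomic reads in the sample's library
#'   (> 0).
#' @return A single non-negative number (GCPM).
#' @examples
#' mag <- tibble::tibble(contig_id = c("c1", "c2"), length = c(1000, 3000))
#' cov <- tibble::tibble(contig_id = c("c1", "c2"), mean_coverage = c(4, 8))
#' gcpm(cov, mag, library_reads = 2e6) # 3.5
#' @export
gcpm <- function(contig_coverage, mag, library_reads) {
  check_cols(contig_coverage, c("contig_id", "mean_coverage"), "`contig_coverage`")
  check_cols(mag, c("contig_id", "length"), "`mag`")
  if (!is.numeric(library_reads) || length(library_reads) != 1 ||
      !is.finite(library_reads) || library_reads <= 0) {
    abort("`library_reads` must be a single positive count")
  }
  if (any(mag$length <= 0)) abort("every contig length must be > 0")
  idx <- match(mag$contig_id, contig_coverage$contig_id)
  if (anyNA(idx)) {
    abort(sprintf("missing coverage for contig(s): %s",
                  paste(mag$contig_id[is.na(idx)], collapse = ", ")))
  }
  cov <- contig_coverage$mean_coverage[idx]
  if (any(!is.finite(cov)) || any(cov < 0)) {
    abort("coverage values must be finite and >= 0")
  }
  cbar <- sum(cov * mag$length) / sum(mag$length)
  cbar * 1e6 / library_reads
}

#' Build the MAG-by-sample GCPM abundance matrix
#'
#' Computes [gcpm()] for every MAG in every sample and applies the detection
#' threshold (default 2 GCPM; values below it are masked as not detected).
#' Row and column order follow the input order of `mags` and `samples`.
#'
#' @param coverages A data frame with columns `sample_id`, `contig_id`,
#'   `mean_coverage` covering every MAG contig in every sample.
#' @param mags MAG manifest: data frame with columns `mag_id`, `contig_id`,
#'   `length`.
#' @param samples Sample table with columns `sample_id`, `library_reads`
#'   (extra columns such as `site`/`vegetation` are carried through).
#' @param threshold Detection threshold in GCPM units (>= 0, default 2).
#' @return A tibble of class `marshvar_abund`, one row per (MAG, sample),
#'   with columns `mag_id`, `sample_id`, `gcpm`, `detected`, plus any extra
#'   sample columns. The threshold and orderings are stored as attributes.
#' @export
build_abundance_matrix <- function(coverages, mags, samples, threshold = 2) {
  check_cols(coverages, c("sample_id", "contig_id", "mean_coverage"), "`coverages`")
  check_cols(mags, c("mag_id", "contig_id", "length"), "`mags`")
  check_cols(samples, c("sample_id", "library_reads"), "`samples`")
  if (!is.numeric(threshold) || threshold < 0) abort("`threshold` must be >= 0")
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id in `samples`")
  if (anyDuplicated(mags$contig_id)) abort("duplicate contig_id in `mags`")
  mag_ids <- unique(mags$mag_id)
  grid <- tidyr::expand_grid(mag_id = mag_ids, sample_id = samples$sample_id)
  vals <- purrr::pmap_dbl(grid, function(mag_id, sample_id) {
    gcpm(coverages[coverages$sample_id == sample_id, ],
         mags[mags$mag_id == mag_id, c("contig_id", "length")],
         samples$library_reads[samples$sample_id == sample_id])
  })
  out <- grid
  out$gcpm <- vals
  out$detected <- vals >= threshold
  out <- left_join(out, samples, by = "sample_id")
  structure(out,
            class = c("marshvar_abund", class(out)),
            threshold = threshold,
            mag_ids = mag_ids,
            sample_ids = samples$sample_id)
}

#' Widen an abundance result to a MAG-by-sample matrix
#'
#' @param ab A `marshvar_abund` tibble from [build_abundance_matrix()].
#' @param masked If `TRUE`, undetected entries are set to 0.
#' @return A numeric matrix, MAGs as rows, samples as columns.
#' @export
abundance_wide <- function(ab, masked = FALSE) {
  stopifnot(inherits(ab, "marshvar_abund"))
  m <- matrix(0, nrow = length(attr(ab, "mag_ids")),
              ncol = length(attr(ab, "sample_ids")),
              dimnames = list(attr(ab, "mag_ids"), attr(ab, "sample_ids")))
  v <- if (masked) ifelse(ab$detected, ab$gcpm, 0) else ab$gcpm
  m[cbind(ab$mag_id, ab$sample_id)] <- v
  m
}

#' Bray-Curtis dissimilarity between samples
#'
#' Pairwise Bray-Curtis dissimilarities
#' \eqn{d_{jk} = \sum_i |x_{ij} - x_{ik}| / \sum_i (x_{ij} + x_{ik})}
#' over the GCPM abundance profiles of each sample pair. A pair of samples
#' whose profiles are both entirely zero has an undefined dissimilarity;
#' it is reported as 0 with a warning.
#'
#' @param ab A `marshvar_abund` tibble, or a non-negative numeric matrix
#'   with MAGs as rows and samples as columns.
#' @return A symmetric sample-by-sample matrix with zero diagonal, values
#'   in \[0, 1\].
#' @export
bray_curtis <- function(ab) {
  m <- if (inherits(ab, "marshvar_abund")) abundance_wide(ab) else as.matrix(ab)
  if (ncol(m) < 2) abort("Bray-Curtis needs at least 2 samples")
  if (any(m < 0)) abort("abundances must be non-negative")
  ns <- ncol(m)
  d <- matrix(0, ns, ns, dimnames = list(colnames(m), colnames(m)))
  warned <- FALSE
  for (j in seq_len(ns - 1)) {
    for (k in (j + 1):ns) {
      tot <- sum(m[, j] + m[, k])
      if (tot == 0) {
        if (!warned) {
          warn("sample pair(s) with all-zero abundance; dissimilarity set to 0")
          warned <- TRUE
        }
        d[j, k] <- d[k, j] <- 0
      } else {
        d[j, k] <- d[k, j] <- sum(abs(m[, j] - m[, k])) / tot
      }
    }
  }
  d
}
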