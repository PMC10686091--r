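#' Shannon entropy of a pileup column
#'
#' Positional nucleotide diversity in bits: \eqn{H = -\sum_b p_b \log_2 p_b}
#' over the A/C/G/T read-count frequencies at one position. Ranges from 0
#' (single allele) to 2 bits (uniform over four bases). Positions with zero
#' depth have undefined entropy and return `NA`.
#'
#' @param counts A data frame or matrix with columns `count_A`, `count_C`,
#'   `count_G`, `count_T` (one row per position), or a single named vector.
#' @return Numeric vector of entropies in bits (`NA` where depth is 0).
#' @examples
#' position_entropy(c(count_A = 5, count_C = 5)) # 1 bit
#' @export
position_entropy <- function(counts) {
  m <- count_matrix(counts)
  depth <- rowSums(m)
  p <- m / ifelse(depth > 0, depth, 1)
  h <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  ifelse(depth > 0, h, NA_real_)
}

count_matrix <- function(counts) {
  cols <- paste0("count_", DNA_BASES)
  if (is.null(dim(counts))) {
    v <- setNames(numeric(4), cols)
    v[names(counts)] <- counts
    return(matrix(v, nrow = 1, dimnames = list(NULL, cols)))
  }
  counts <- as.data.frame(counts)
  for (cc in setdiff(cols, names(counts))) counts[[cc]] <- 0
  as.matrix(counts[, cols])
}

#' Call single-nucleotide variants from a base-count pileup
#'
#' A position is an SNV iff its depth is at least `min_depth` and its minor
#' allele frequency (one minus the major base's frequency) is at least
#' `min_maf`. Each call carries the positional Shannon entropy.
#'
#' @param pileup A data frame with columns `contig_id`, `pos` (1-based),
#'   `count_A`, `count_C`, `count_G`, `count_T`; an optional `sample_id`
#'   column is honoured and returned.
#' @param min_depth Minimum read depth (>= 1, default 10).
#' @param min_maf Minimum minor allele frequency (in (0, 0.5\], default 0.1).
#' @return A tibble of SNV records sorted by (`contig_id`, `pos`) within
#'   sample: `major_base`, `maf`, `depth`, `entropy`.
#' @export
call_snvs <- function(pileup, min_depth = 10, min_maf = 0.1) {
  if (!is.numeric(min_depth) || min_depth < 1) abort("`min_depth` must be >= 1")
  check_fraction(min_maf, "min_maf", lo = 0, hi = 0.5, lo_open = TRUE)
  pileup <- as_tibble(pileup)
  check_cols(pileup, c("contig_id", "pos", paste0("count_", DNA_BASES)), "`pileup`")
  m <- count_matrix(pileup)
  bad <- which(!stats::complete.cases(m) | rowSums(m < 0) > 0 |
                 is.na(pileup$pos) | pileup$pos < 1)
  if (length(bad) > 0) {
    abort(sprintf("malformed pileup row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  depth <- rowSums(m)
  major_i <- max.col(m, ties.method = "first")
  maf <- 1 - m[cbind(seq_len(nrow(m)), major_i)] / ifelse(depth > 0, depth, 1)
  keep <- depth >= min_depth & maf >= min_maf
  out <- pileup[keep, intersect(c("sample_id", "contig_id", "pos"), names(pileup))]
  out$major_base <- DNA_BASES[major_i[keep]]
  out$maf <- maf[keep]
  out$depth <- depth[keep]
  out$entropy <- position_entropy(m[keep, , drop = FALSE])
  arrange(out, dplyr::pick(intersect(c("sample_id", "contig_id", "pos"), names(out))))
}

#' Per-gene SNV density and mean entropy
#'
#' Counts SNVs falling inside each annotated gene interval, expresses them
#' per kilobase of gene length, and averages positional entropy over the
#' gene's positions with depth of at least `min_depth`. Genes with no such
#' covered position get `mean_entropy = NA` (flagged, never silently 0).
#'
#' @param snvs SNV table from [call_snvs()] (same contig coordinate system).
#' @param pileup The pileup the SNVs were called from.
#' @param genes Gene annotation: data frame with `gene_id`, `contig_id`,
#'   `start`, `end` (1-based inclusive).
#' @param min_depth Depth gate for "covered" positions (default 10).
#' @param contig_lengths Optional named vector of contig lengths; when
#'   given, genes extending outside their contig raise an error.
#' @return A tibble of class `marshvar_genevar`: `gene_id`, `length`,
#'   `n_snvs`, `snv_per_kbp`, `mean_entropy`, `covered_positions`.
#' @export
summarize_gene_variability <- function(snvs, pileup, genes, min_depth = 10,
                                       contig_lengths = NULL) {
  genes <- as_tibble(genes)
  check_cols(genes, c("gene_id", "contig_id", "start", "end"), "`genes`")
  if (any(genes$start < 1 | genes$end < genes$start)) {
    abort("gene intervals must satisfy 1 <= start <= end")
  }
  if (!is.null(contig_lengths)) {
    lim <- contig_lengths[genes$contig_id]
    if (anyNA(lim) || any(genes$end > lim)) {
      abort("gene interval outside contig bounds")
    }
  }
  pileup <- as_tibble(pileup)
  ent <- position_entropy(pileup)
  depth <- rowSums(count_matrix(pileup))
  per_gene <- function(gene_id, contig_id, start, end, ...) {
    len <- end - start + 1
    in_gene_snv <- snvs$contig_id == contig_id & snvs$pos >= start & snvs$pos <= end
    in_gene_cov <- pileup$contig_id == contig_id & pileup$pos >= start &
      pileup$pos <= end & depth >= min_depth
    n <- sum(in_gene_snv)
    tibble(
      gene_id = gene_id, length = len, n_snvs = n,
      snv_per_kbp = n * 1000 / len,
      mean_entropy = if (any(in_gene_cov)) mean(ent[in_gene_cov]) else NA_real_,
      covered_positions = sum(in_gene_cov)
    )
  }
  out <- purrr::pmap_dfr(genes, per_gene)
  structure(out, class = c("marshvar_genevar", class(out)))
}

#' Normalize an SNV count by mapped reads
#'
#' Expresses a sample's SNV count per 100,000 reads mapped to the
#' reference MAG, so divergence can be compared across unequal sequencing
#' effort.
#'
#' @param total_snvs SNV count (>= 0), vectorized.
#' @param mapped_reads Reads mapped to the reference (> 0), vectorized.
#' @return SNVs per 100,000 mapped reads.
#' @examples
#' normalize_snv_rate(646, 100000) # 646
#' @export
normalize_snv_rate <- function(total_snvs, mapped_reads) {
  if (any(!is.finite(mapped_reads)) || any(mapped_reads <= 0)) {
    abort("`mapped_reads` must be > 0")
  }
  if (any(total_snvs < 0)) abort("`total_snvs` must be >= 0")
  total_snvs * 1e5 / mapped_reads
}

#' Flag hypervariable (hotspot) genes
#'
#' Flags genes whose SNV density exceeds the upper Tukey fence
#' (Q3 + 1.5 IQR) of the per-gene `snv_per_kbp` distribution — a
#' concrete, deterministic rule for the "handful of ORFs with outlier
#' values" seen against an otherwise uniform variability background.
#'
#' @param gene_var A `marshvar_genevar` tibble (or any data frame with
#'   `gene_id` and `snv_per_kbp`); at least 4 genes are required.
#' @return The input tibble with a logical `hotspot` column; the fence is
#'   stored in attribute `fence`.
#' @export
flag_hotspot_genes <- function(gene_var) {
  check_cols(gene_var, c("gene_id", "snv_per_kbp"), "`gene_var`")
  if (nrow(gene_var) < 4) abort("need >= 4 genes to estimate the outlier fence")
  q <- quantile(gene_var$snv_per_kbp, c(0.25, 0.75), names = FALSE)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  out <- mutate(as_tibble(gene_var), hotspot = .data$snv_per_kbp > fence)
  structure(out, class = c("marshvar_genevar", class(out)), fence = fence)
}

#' Per-sample SNV totals and normalized rates
#'
#' @param snvs An SNV table with a `sample_id` column.
#' @param mapped A data frame with `sample_id` and `mapped_reads`.
#' @return A tibble: `sample_id`, `mapped_reads`, `total_snvs`,
#'   `snvs_per_100k_reads`.
#' @export
sample_variability <- function(snvs, mapped) {
  check_cols(mapped, c("sample_id", "mapped_reads"), "`mapped`")
  counts <- dplyr::count(as_tibble(snvs), .data$sample_id, name = "total_snvs")
  out <- left_join(as_tibble(mapped), counts, by = "sample_id")
  out$total_snvs[is.na(out$total_snvs)] <- 0L
  mutate(out, snvs_per_100k_reads =
           normalize_snv_rate(.data$total_snvs, .data$mapped_reads))
}
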