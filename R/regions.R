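#' Detect group-specific genomic regions from coverage breadth
#'
#' Scans each contig in fixed windows and scores per-sample breadth of
#' coverage (fraction of window positions with depth >= 1). A window is
#' group-differential when every sample of at least one group covers it at
#' breadth >= `breadth_present` while every sample of at least one other
#' group covers it at breadth <= `breadth_absent`. Adjacent qualifying
#' windows with an identical presence/absence pattern are merged, and
#' merged regions shorter than `min_region` are dropped. This is how, for
#' example, an ~80 kbp island detected only in one site's samples shows up
#' against read recruitment.
#'
#' @param depths Per-position depth table: `sample_id`, `contig_id`, `pos`
#'   (1-based), `depth`. Positions absent from the table count as depth 0.
#' @param groups Data frame mapping `sample_id` to `group`.
#' @param contig_lengths Named numeric vector of contig lengths (bp).
#' @param annotation Optional gene annotation (`gene_id`, `contig_id`,
#'   `start`, `end`) used to count genes overlapping each region by >= 1 bp.
#' @param window Window size in bp (default 1000).
#' @param breadth_present Minimum breadth in every sample of a "present"
#'   group (default 0.5).
#' @param breadth_absent Maximum breadth in every sample of an "absent"
#'   group (default 0.1); must be < `breadth_present`.
#' @param min_region Minimum merged region length in bp (default 5000).
#' @return A tibble: `contig_id`, `start`, `end`, `length`,
#'   `present_groups`, `absent_groups` (comma-joined labels), `n_genes`.
#' @export
detect_differential_regions <- function(depths, groups, contig_lengths,
                                        annotation = NULL,
                                        window = 1000,
                                        breadth_present = 0.5,
                                        breadth_absent = 0.1,
                                        min_region = 5000) {
  if (!is.numeric(window) || window <= 0) abort("`window` must be > 0")
  check_fraction(breadth_present, "breadth_present")
  check_fraction(breadth_absent, "breadth_absent")
  if (breadth_absent >= breadth_present) {
    abort("`breadth_absent` must be < `breadth_present`")
  }
  check_cols(depths, c("sample_id", "contig_id", "pos", "depth"), "`depths`")
  check_cols(groups, c("sample_id", "group"), "`groups`")
  if (length(unique(groups$group)) < 2) abort("need >= 2 sample groups")
  if (is.null(names(contig_lengths))) abort("`contig_lengths` must be named")

  samples <- groups$sample_id
  empty <- tibble(contig_id = character(), start = numeric(), end = numeric(),
                  length = numeric(), present_groups = character(),
                  absent_groups = character(), n_genes = integer())
  regions <- list()
  for (ctg in names(contig_lengths)) {
    len <- contig_lengths[[ctg]]
    n_win <- ceiling(len / window)
    widths <- c(rep(window, n_win - 1), len - (n_win - 1) * window)
    d <- depths[depths$contig_id == ctg & depths$depth >= 1 &
                  depths$sample_id %in% samples, ]
    # breadth matrix: windows x samples
    br <- matrix(0, nrow = n_win, ncol = length(samples),
                 dimnames = list(NULL, samples))
    if (nrow(d) > 0) {
      wi <- (d$pos - 1) %/% window + 1
      tab <- table(factor(wi, levels = seq_len(n_win)),
                   factor(d$sample_id, levels = samples))
      br <- unclass(tab) / widths
    }
    pat <- character(n_win)
    pres <- abs <- vector("list", n_win)
    for (w in seq_len(n_win)) {
      by_group <- split(br[w, ], groups$group[match(samples, groups$sample_id)])
      p <- names(by_group)[vapply(by_group, function(x) all(x >= breadth_present), logical(1))]
      a <- names(by_group)[vapply(by_group, function(x) all(x <= breadth_absent), logical(1))]
      if (length(p) > 0 && length(a) > 0) {
        pres[[w]] <- sort(p); abs[[w]] <- sort(a)
        pat[w] <- paste(paste(sort(p), collapse = ","), "|",
                        paste(sort(a), collapse = ","))
      }
    }
    # merge runs of identical non-empty patterns
    r <- rle(pat)
    ends_w <- cumsum(r$lengths)
    starts_w <- ends_w - r$lengths + 1
    for (i in seq_along(r$values)) {
      if (r$values[i] == "") next
      start <- (starts_w[i] - 1) * window + 1
      end <- min(ends_w[i] * window, len)
      if (end - start + 1 < min_region) next
      regions[[length(regions) + 1]] <- tibble(
        contig_id = ctg, start = start, end = end, length = end - start + 1,
        present_groups = paste(pres[[starts_w[i]]], collapse = ","),
        absent_groups = paste(abs[[starts_w[i]]], collapse = ","),
        n_genes = if (is.null(annotation)) NA_integer_ else {
          sum(annotation$contig_id == ctg &
                annotation$start <= end & annotation$end >= start)
        }
      )
    }
  }
  if (length(regions) == 0) empty else bind_rows(regions)
}

#' Collapse a pileup to per-position depths
#'
#' @param pileup A pileup table with `count_A..count_T` columns.
#' @return The pileup's identifying columns plus a `depth` column.
#' @export
pileup_depth <- function(pileup) {
  pileup <- as_tibble(pileup)
  keep <- intersect(c("sample_id", "contig_id", "pos"), names(pileup))
  out <- pileup[, keep]
  out$depth <- rowSums(count_matrix(pileup))
  out
}
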