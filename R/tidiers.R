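#' Tidy an abundance result
#'
#' @param x A `marshvar_abund` from [build_abundance_matrix()].
#' @param ... Unused.
#' @return A plain tibble (`mag_id`, `sample_id`, `gcpm`, `detected`, ...).
#' @method tidy marshvar_abund
#' @export
tidy.marshvar_abund <- function(x, ...) {
  as_tibble(unclass(x)[seq_along(x)])
}

#' @rdname tidy.marshvar_abund
#' @method glance marshvar_abund
#' @export
glance.marshvar_abund <- function(x, ...) {
  tibble(n_mags = length(attr(x, "mag_ids")),
         n_samples = length(attr(x, "sample_ids")),
         n_detected = sum(x$detected),
         threshold = attr(x, "threshold"))
}

#' Tidy a DGR screen into a cassette table
#'
#' @param x A `dgr_screen` from [detect_dgr()].
#' @param ... Unused.
#' @return A tibble with one row per accepted cassette.
#' @method tidy dgr_screen
#' @export
tidy.dgr_screen <- function(x, ...) {
  if (length(x$cassettes) == 0) {
    return(tibble(contig_id = character(), tr_start = numeric(),
                  tr_end = numeric(), vr_start = numeric(),
                  vr_end = numeric(), target_gene_id = character(),
                  strand = character(), vr_frame = integer(),
                  n_mismatches = integer(), adenine_polarity = numeric()))
  }
  purrr::map_dfr(x$cassettes, function(cas) {
    tibble(contig_id = cas$contig_id, tr_start = cas$tr_start,
           tr_end = cas$tr_end, vr_start = cas$vr_start,
           vr_end = cas$vr_end, target_gene_id = cas$target_gene_id,
           strand = cas$strand, vr_frame = cas$vr_frame,
           n_mismatches = cas$n_mismatches,
           adenine_polarity = cas$adenine_polarity)
  })
}

#' @rdname tidy.dgr_screen
#' @method glance dgr_screen
#' @export
glance.dgr_screen <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs),
         n_cassettes = length(x$cassettes),
         n_rejected = nrow(x$rejections))
}

#' Tidy a theoretical diversity result
#'
#' @param x A `dgr_diversity` from [theoretical_diversity()].
#' @param ... Unused.
#' @return The per-codon accessibility tibble.
#' @method tidy dgr_diversity
#' @export
tidy.dgr_diversity <- function(x, ...) x$codons

#' @rdname tidy.dgr_diversity
#' @method glance dgr_diversity
#' @export
glance.dgr_diversity <- function(x, ...) {
  tibble(n_codons = x$n_codons, n_variable = x$n_variable,
         d_max = x$d_max, d_max_exact = x$d_max_exact,
         d_max_rendered = x$d_max_rendered)
}

#' Tidy an observed recoding result
#'
#' @param x A `dgr_diversity_obs` from [observed_recoding()].
#' @param ... Unused.
#' @return The per-position observation tibble.
#' @method tidy dgr_diversity_obs
#' @export
tidy.dgr_diversity_obs <- function(x, ...) x$positions

#' @rdname tidy.dgr_diversity_obs
#' @method glance dgr_diversity_obs
#' @export
glance.dgr_diversity_obs <- function(x, ...) {
  tibble(n_positions = nrow(x$positions),
         n_flagged = sum(x$positions$flagged),
         d_obs = x$d_obs, d_obs_exact = x$d_obs_exact,
         d_obs_rendered = x$d_obs_rendered)
}
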