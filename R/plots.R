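#' Heatmap of a GCPM abundance matrix
#'
#' Tiles MAGs by samples, filled by log10(GCPM + 1); entries below the
#' detection threshold are greyed out, mirroring the "filtered below two
#' GCPM" convention.
#'
#' @param object A `marshvar_abund` from [build_abundance_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot marshvar_abund
#' @export
autoplot.marshvar_abund <- function(object, ...) {
  df <- tidy(object)
  df$mag_id <- factor(df$mag_id, levels = rev(attr(object, "mag_ids")))
  df$sample_id <- factor(df$sample_id, levels = attr(object, "sample_ids"))
  df$fill <- ifelse(df$detected, log10(df$gcpm + 1), NA_real_)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$mag_id,
                                   fill = .data$fill)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "log10(GCPM+1)",
                                  na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL,
                  caption = sprintf("grey: below %.3g GCPM detection threshold",
                                    attr(object, "threshold"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-gene SNV density with hotspot highlighting
#'
#' @param object A `marshvar_genevar` tibble (ideally after
#'   [flag_hotspot_genes()], so the Tukey fence can be drawn).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot marshvar_genevar
#' @export
autoplot.marshvar_genevar <- function(object, ...) {
  df <- as_tibble(object)
  if (!"hotspot" %in% names(df)) df$hotspot <- FALSE
  p <- ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$gene_id,
                                                           .data$snv_per_kbp),
                                        y = .data$snv_per_kbp,
                                        fill = .data$hotspot)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey30",
                                          `TRUE` = "firebrick"),
                               name = "hotspot") +
    ggplot2::labs(x = NULL, y = "SNVs per kbp") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
  fence <- attr(object, "fence")
  if (!is.null(fence)) {
    p <- p + ggplot2::geom_hline(yintercept = fence, linetype = "dashed")
  }
  p
}

#' Per-codon accessible and observed amino-acid counts of a DGR target
#'
#' @param object A `dgr_diversity` (theoretical counts) or
#'   `dgr_diversity_obs` (observed counts) object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dgr_diversity
#' @export
autoplot.dgr_diversity <- function(object, ...) {
  df <- tidy(object)
  df$variable <- df$n_adenines >= 1
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$count,
                                   fill = .data$variable)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "steelblue"),
                               name = "variable codon") +
    ggplot2::labs(x = "codon position", y = "accessible amino acids",
                  caption = paste("D_max =", object$d_max_rendered)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.dgr_diversity
#' @method autoplot dgr_diversity_obs
#' @export
autoplot.dgr_diversity_obs <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon_index,
                                   y = .data$n_observed,
                                   fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "darkorange",
                                          `TRUE` = "grey70"),
                               name = "no observation") +
    ggplot2::labs(x = "variable codon", y = "observed amino acids",
                  caption = paste("D_obs =", object$d_obs_rendered)) +
    ggplot2::theme_minimal()
}
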