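# ggplot2 views of the main result types.

#' Plot per-window copy number along a chromosome
#'
#' @param windows Window tibble from [estimate_copy_number()].
#' @param regions Optional duplicated regions ([call_duplicated_regions()]).
#' @param cn_min Threshold line to draw.
#' @return A ggplot object.
#' @export
plot_copy_number <- function(windows, regions = NULL, cn_min = 2.5) {
  p <- ggplot2::ggplot(windows,
                       ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = .data$copy_number)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = cn_min, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "estimated copy number") +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "firebrick", alpha = 0.15
    )
  }
  p
}

#' Plot a cleavage-site nucleotide profile
#'
#' Stacked per-position nucleotide frequencies of the 7-mer spanning the
#' inferred endonuclease cut site (5 bases before, 2 after, minus-strand
#' convention).
#'
#' @param profile A `cleavage_profile` from [cleavage_profile()].
#' @return A ggplot object.
#' @export
plot_cleavage_profile <- function(profile) {
  df <- as_tibble(as.table(profile$freq), .name_repair = "minimal")
  names(df) <- c("base", "position", "freq")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$freq,
                                   fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(A = "#33a02c", C = "#1f78b4",
                                          G = "#ff7f00", T = "#e31a1c")) +
    ggplot2::labs(x = "position around inferred cut site",
                  y = "frequency", fill = NULL,
                  title = paste0("cleavage-site composition (n = ",
                                 profile$n, ")")) +
    ggplot2::theme_minimal()
}

#' @rdname plot_cleavage_profile
#' @param object A `cleavage_profile`.
#' @param ... Unused.
#' @export
autoplot.cleavage_profile <- function(object, ...) {
  plot_cleavage_profile(object)
}

#' Plot presence-pattern counts across assemblies
#'
#' Bar chart of the fully resolved presence patterns from
#' [build_presence_matrix()] (a compact stand-in for an upset plot).
#'
#' @param patterns `patterns` tibble from [build_presence_matrix()].
#' @return A ggplot object.
#' @export
plot_presence_patterns <- function(patterns) {
  ggplot2::ggplot(patterns,
                  ggplot2::aes(x = stats::reorder(.data$pattern, -.data$n_loci),
                               y = .data$n_loci)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "presence pattern (1 = shared, assembly order)",
                  y = "loci") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
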