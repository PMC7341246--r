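#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot LD decay
#'
#' Mean r-squared per distance bin against the bin midpoint (Mb).
#'
#' @param object An `ld_decay` table from [bin_ld_decay()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ld_decay
#' @export
autoplot.ld_decay <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$midpoint_bp / 1e6, .data$mean_r2)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "distance (Mb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}

#' Plot an ancestral Ne trajectory
#'
#' Effective population size against generations ago, on log-log axes.
#'
#' @param object A `ne_trajectory` from [estimate_ne_trajectory()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ne_trajectory
#' @export
autoplot.ne_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t, .data$ne)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations ago", y = expression(N[e])) +
    ggplot2::theme_minimal()
}

#' ROH count against total length per individual
#'
#' The classic per-animal diagnostic: individuals with many, long runs sit
#' in the upper right (recent close inbreeding).
#'
#' @param object A `roh_segments` table from [detect_roh()] (any segment
#'   tibble works).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roh_segments
#' @export
autoplot.roh_segments <- function(object, ...) {
  per_ind <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_roh = dplyr::n(),
                     total_length_mb = sum(.data$length_bp) / 1e6,
                     .groups = "drop")
  ggplot2::ggplot(per_ind,
                  ggplot2::aes(.data$total_length_mb, .data$n_roh)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "total ROH length (Mb)", y = "number of ROH") +
    ggplot2::theme_minimal()
}

#' Manhattan plot of an association scan
#'
#' Adjusted p-values by genomic position with the genome-wide and
#' suggestive thresholds drawn as horizontal lines.
#'
#' @param object A `gwas_result` from [genomic_control()].
#' @param opts The [gwas_options()] used (for the threshold lines).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gwas_result
#' @export
autoplot.gwas_result <- function(object, opts = gwas_options(), ...) {
  tab <- object$scan |>
    dplyr::arrange(.data$chrom, .data$bp) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(.offset = .data$bp - min(.data$bp)) |>
    dplyr::ungroup()
  chr_len <- tab |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$.offset) + 1, .groups = "drop") |>
    dplyr::mutate(start = cumsum(dplyr::lag(.data$len, default = 0)))
  tab <- dplyr::left_join(tab, chr_len, by = "chrom")
  ggplot2::ggplot(tab, ggplot2::aes((.data$start + .data$.offset) / 1e6,
                                    -log10(.data$p_adj),
                                    colour = factor(.data$chrom %% 2))) +
    ggplot2::geom_point(size = 0.7, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(opts$threshold_genomewide),
                        colour = "red") +
    ggplot2::geom_hline(yintercept = -log10(opts$threshold_suggestive),
                        colour = "blue") +
    ggplot2::scale_colour_manual(values = c("grey30", "grey60")) +
    ggplot2::labs(x = "genome position (Mb)",
                  y = expression(-log[10](p[adj]))) +
    ggplot2::theme_minimal()
}

#' Q-Q plot of an association scan
#'
#' Observed against expected -log10 p under the null, with the identity
#' line; the deflation/inflation factor lambda is shown in the subtitle.
#'
#' @param result A `gwas_result` from [genomic_control()].
#' @return A ggplot object.
#' @export
plot_qq <- function(result) {
  ggplot2::ggplot(result$qq, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::labs(x = expression(expected ~ -log[10](p)),
                  y = expression(observed ~ -log[10](p)),
                  subtitle = paste("lambda =", signif(result$lambda, 4))) +
    ggplot2::theme_minimal()
}
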