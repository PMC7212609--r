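# ggplot2 views of the main result types.

#' Hockey-stick plot of a super-enhancer catalog
#'
#' Regions ordered by increasing aggregate signal with the tangent cutoff
#' marked; super-enhancers highlighted.
#'
#' @param object An `ls_se` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ls_se <- function(object, ...) {
  df <- arrange(tidy(object), total_signal) |>
    mutate(order = row_number())
  ggplot2::ggplot(df, ggplot2::aes(order, total_signal, colour = is_super)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$cutoff, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red")) +
    ggplot2::labs(x = "regions ranked by signal", y = "aggregate signal",
                  colour = "super-enhancer",
                  title = if (is.na(object$condition)) NULL else object$condition) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a differential-occupancy analysis
#'
#' Depth-normalised control vs treated intensity per site (log10 scale with
#' a 0.5 pseudocount), significantly reduced loci highlighted.
#'
#' @param object An `ls_diffocc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ls_diffocc <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(norm_control + 0.5, norm_treated + 0.5,
                                   colour = reduced)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "red"),
                                 na.value = "grey85") +
    ggplot2::labs(x = "control (tags per million)",
                  y = "treated (tags per million)", colour = "reduced") +
    ggplot2::theme_minimal()
}

#' Domain track plot
#'
#' Draws CCDs and (optionally) factor domains as stacked segments per
#' chromosome, the quickest way to eyeball stitch geometry.
#'
#' @param ccds CCD tibble.
#' @param factor_domains Optional factor-domain or stitch-call tibble; rows
#'   with a `label` column are coloured by it.
#' @return A ggplot.
#' @export
plot_domains <- function(ccds, factor_domains = NULL) {
  ccds <- mutate(as_tibble(ccds), track = "CCD", fill = "CCD")
  df <- ccds
  if (!is.null(factor_domains)) {
    fd <- as_tibble(factor_domains)
    fd$fill <- if ("label" %in% names(fd)) fd$label else "factor domain"
    df <- bind_rows(df, mutate(fd, track = "factor"))
  }
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = start / 1e6, xend = end / 1e6,
                                       y = track, yend = track, colour = fill),
                          linewidth = 4) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
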