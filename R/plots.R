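#' Plot the two-channel droplet amplitude cloud
#'
#' Scatter of FAM (target) against HEX (reference) amplitude, the standard
#' duplex view: four clusters for a transduced sample, two for a
#' non-transduced control, one for a no-template control. When thresholds
#' are given, droplets are coloured by their called cluster and the
#' threshold lines are drawn.
#'
#' @param object A [droplet_well].
#' @param fam_threshold,hex_threshold Optional channel thresholds.
#' @param alpha Point alpha.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot droplet_well
#' @export
autoplot.droplet_well <- function(object, fam_threshold = NULL,
                                  hex_threshold = NULL, alpha = 0.3, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$hex_amplitude,
                                        y = .data$fam_amplitude))
  if (!is.null(fam_threshold) && !is.null(hex_threshold)) {
    df$cluster <- dplyr::case_when(
      df$fam_amplitude > fam_threshold & df$hex_amplitude > hex_threshold ~ "FAM+HEX+",
      df$fam_amplitude > fam_threshold ~ "FAM+HEX-",
      df$hex_amplitude > hex_threshold ~ "FAM-HEX+",
      TRUE ~ "FAM-HEX-"
    )
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$hex_amplitude,
                                          y = .data$fam_amplitude,
                                          colour = .data$cluster)) +
      ggplot2::geom_hline(yintercept = fam_threshold,
                          colour = "deeppink", linewidth = 0.4) +
      ggplot2::geom_vline(xintercept = hex_threshold,
                          colour = "deeppink", linewidth = 0.4)
  }
  p +
    ggplot2::geom_point(alpha = alpha, size = 0.5) +
    ggplot2::labs(
      x = "HEX amplitude (reference, TERT)",
      y = "FAM amplitude (target, WPRE)",
      title = attr(object, "well_id") %||% NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a per-cell VCN distribution
#'
#' Bars for the probability mass at each copy number and a step curve for
#' the cumulative fraction of cells at or below each copy number.
#'
#' @param object A [vcn_distribution()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot vcn_distribution
#' @export
autoplot.vcn_distribution <- function(object, ...) {
  df <- as_tibble(object)
  lab <- sprintf("%s Poisson, rate %.3g",
                 if (attr(object, "truncated")) "zero-truncated" else "all-cells",
                 attr(object, "lam"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$pmf), fill = "steelblue",
                      width = 0.8) +
    ggplot2::geom_step(ggplot2::aes(y = .data$cdf), colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cdf), colour = "firebrick",
                        size = 1) +
    ggplot2::labs(x = "vector copies per cell (k)",
                  y = "fraction of cells",
                  subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Plot a dilution-linearity fit
#'
#' Measured values against expected values with the fitted regression line,
#' on the scale the report was fitted on.
#'
#' @param object A [dilution_linearity()] report.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot linearity_report
#' @export
autoplot.linearity_report <- function(object, ...) {
  df <- attr(object, "data")
  loglog <- object$scale == "log-log"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$expected,
                                        y = .data$measured)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue", linewidth = 0.5) +
    ggplot2::labs(
      x = "expected", y = "measured",
      subtitle = sprintf("slope %.4g, intercept %.4g, R² = %.4f",
                         object$slope, object$intercept, object$r_squared)
    ) +
    ggplot2::theme_minimal()
  if (loglog) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' Plot inter-assay repeatability
#'
#' Per-condition coefficient of variation as bars.
#'
#' @param object An [inter_assay_cv()] report.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot repeatability_report
#' @export
autoplot.repeatability_report <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$cv_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "CV%") +
    ggplot2::theme_minimal()
}
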