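#' Dilution linearity of the assay
#'
#' Fits the measured responses of a dilution series against their expected
#' values by ordinary least squares, on the linear scale or after
#' natural-log transformation of both axes (log-log), and reports the
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot`. A proportional
#' assay yields slope near the true scaling and `R^2` near 1.
#'
#' @param expected Numeric vector of expected values — nominal
#'   concentrations, dilution fractions, or putative transduction
#'   efficiencies (length >= 3).
#' @param measured Numeric vector of measured values, same length.
#' @param scale `"linear"` or `"log-log"`. Log-log requires strictly
#'   positive values on both axes; the base (natural log) only affects
#'   slope and intercept, never `R^2`.
#' @return A one-row tibble of class `linearity_report` with `slope`,
#'   `intercept`, `r_squared`, `scale`, `n_points`; the fitted `lm` object
#'   and the data are kept as attributes for plotting.
#' @export
#' @examples
#' dilution_linearity(c(1, 2, 3), c(2, 4, 6))
dilution_linearity <- function(expected, measured,
                               scale = c("linear", "log-log")) {
  scale <- match.arg(scale)
  if (!is.numeric(expected) || !is.numeric(measured) ||
      length(expected) != length(measured)) {
    stop_dropvcn("`expected` and `measured` must be numeric vectors of equal length.",
                 "invalid_argument")
  }
  if (length(expected) < 3L) {
    stop_dropvcn("at least 3 points are needed for a linearity fit.",
                 "invalid_argument")
  }
  if (any(!is.finite(expected)) || any(!is.finite(measured))) {
    stop_dropvcn("linearity inputs must be finite.", "invalid_argument")
  }
  if (scale == "log-log" && (any(expected <= 0) || any(measured <= 0))) {
    stop_dropvcn("log-log linearity requires strictly positive values.",
                 "invalid_argument")
  }

  x <- if (scale == "log-log") log(expected) else expected
  y <- if (scale == "log-log") log(measured) else measured
  if (var(x) == 0) {
    stop_dropvcn("expected values have zero variance: degenerate regression.",
                 "degenerate_input")
  }

  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)

  out <- new_record(
    tibble(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = 1 - ss_res / ss_tot,
      scale = scale,
      n_points = length(x)
    ),
    "linearity_report"
  )
  attr(out, "model") <- fit
  attr(out, "data") <- tibble(expected = expected, measured = measured)
  out
}

#' Inter-assay repeatability as coefficient of variation
#'
#' Summarises repeated VCN measurements of the same conditions — e.g. each
#' dilution level measured at several time points — by the per-condition
#' coefficient of variation, `CV% = 100 * sample SD / mean`, and its
#' maximum over conditions.
#'
#' @param measurements A data frame with a condition column and a value
#'   column, or a named list of numeric vectors (one element per
#'   condition). Each condition needs >= 2 values with non-zero mean.
#' @param condition,value Column names used when `measurements` is a data
#'   frame.
#' @return A tibble of class `repeatability_report`, one row per condition
#'   with `condition`, `n`, `mean`, `sd`, `cv_pct`; the attribute `max_cv`
#'   holds the largest CV%.
#' @export
#' @examples
#' inter_assay_cv(list(DILN0 = c(2.61, 2.7, 2.58), DILN1 = c(1.3, 1.36, 1.33)))
inter_assay_cv <- function(measurements, condition = "condition",
                           value = "value") {
  if (is.data.frame(measurements)) {
    if (!all(c(condition, value) %in% names(measurements))) {
      stop_dropvcn("`measurements` must contain the condition and value columns.",
                   "invalid_argument")
    }
    groups <- split(measurements[[value]], measurements[[condition]])
  } else if (is.list(measurements) && !is.null(names(measurements))) {
    groups <- measurements
  } else {
    stop_dropvcn("`measurements` must be a data frame or a named list.",
                 "invalid_argument")
  }
  if (length(groups) == 0L) {
    stop_dropvcn("no conditions supplied.", "invalid_argument")
  }

  rows <- purrr::imap(groups, function(v, nm) {
    if (!is.numeric(v) || length(v) < 2L) {
      stop_dropvcn(sprintf("condition '%s' needs at least 2 values.", nm),
                   "invalid_argument")
    }
    m <- mean(v)
    if (m == 0) {
      stop_dropvcn(sprintf("condition '%s' has mean 0: CV undefined.", nm),
                   "undefined_cv")
    }
    tibble(condition = nm, n = length(v), mean = m, sd = sd(v),
           cv_pct = 100 * sd(v) / m)
  })

  out <- new_record(dplyr::bind_rows(rows), "repeatability_report")
  attr(out, "max_cv") <- max(out$cv_pct)
  out
}
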