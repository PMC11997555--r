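#' Adjust bulk VCN to the VCN of transduced cells
#'
#' The bulk VCN averages over all cells, transduced or not, and therefore
#' underestimates the copy load of the cells that actually carry vector —
#' severely so at low transduction efficiency. Under a Poisson model of
#' integration (copies per cell ~ Poisson with rate `VCN_bulk`), the
#' fraction of cells with at least one copy — the putative transduction
#' efficiency — is `1 - exp(-VCN_bulk)`, and the mean copy number among
#' those cells is the zero-truncated Poisson mean
#'
#' \deqn{VCN_{adj} = \frac{VCN_{bulk}}{1 - e^{-VCN_{bulk}}}.}
#'
#' `VCN_adj` always lies at or above both 1 (a transduced cell has at least
#' one copy) and `VCN_bulk`, and converges to `VCN_bulk` as the bulk value
#' grows.
#'
#' @param vcn_bulk Numeric vector of bulk VCN values (copies per cell,
#'   >= 0).
#' @return A tibble with columns `vcn_bulk`, `transduction_putative`
#'   (`1 - exp(-vcn_bulk)`) and `vcn_adj`. For `vcn_bulk = 0` the putative
#'   transduction efficiency is 0 and `vcn_adj` is `NA`: with no detected
#'   vector there is no transduced-cell VCN to report.
#' @export
#' @examples
#' adjust_vcn(c(0.57, 2.23, 9.00))
adjust_vcn <- function(vcn_bulk) {
  if (!is.numeric(vcn_bulk) || any(!is.finite(vcn_bulk))) {
    stop_dropvcn("`vcn_bulk` must be finite numeric.", "invalid_argument")
  }
  if (any(vcn_bulk < 0)) {
    stop_dropvcn("`vcn_bulk` must be non-negative.", "invalid_argument")
  }
  p <- -expm1(-vcn_bulk)
  tibble(
    vcn_bulk = vcn_bulk,
    transduction_putative = p,
    vcn_adj = ifelse(vcn_bulk > 0, vcn_bulk / p, NA_real_)
  )
}

#' Fill the transduced-cell adjustment into a VCN result
#'
#' Applies [adjust_vcn()] to the `vcn_bulk` column of one or more
#' [compute_vcn_bulk()] rows, populating `vcn_adj` and
#' `transduction_putative`.
#'
#' @param results A tibble of `vcn_result` rows.
#' @return The same tibble with `vcn_adj` and `transduction_putative`
#'   filled.
#' @export
refine_vcn <- function(results) {
  if (!is.data.frame(results) || !"vcn_bulk" %in% names(results)) {
    stop_dropvcn("`results` must contain a `vcn_bulk` column.",
                 "invalid_argument")
  }
  adj <- adjust_vcn(results$vcn_bulk)
  results$vcn_adj <- adj$vcn_adj
  results$transduction_putative <- adj$transduction_putative
  results
}

#' Per-cell VCN distribution under the Poisson model
#'
#' Probability mass and cumulative distribution of per-cell vector copy
#' number at rate `lam`. The all-cells variant is a plain Poisson pmf —
#' `pmf[0]` is the theoretical fraction of untransduced cells. The
#' zero-truncated variant conditions on at least one copy and describes the
#' transduced cells; its mean equals `VCN_adj`.
#'
#' @param lam Poisson rate, copies per cell (> 0). For the all-cells
#'   distribution this is the bulk VCN.
#' @param support_max Largest copy number `k` to tabulate. Defaults to the
#'   smallest `k` whose cumulative probability reaches 0.9999. Internally
#'   the support is extended until the cumulative mass is within 1e-9 of 1
#'   so that normalisation is exact regardless of the displayed support.
#' @param truncated Zero-truncated (transduced cells only) instead of
#'   all cells?
#' @return A tibble of class `vcn_distribution` with columns `k`, `pmf`,
#'   `cdf` for `k = 0, ..., support_max`, and attributes `lam`, `truncated`
#'   and `distribution_mean` (the exact mean over the full support).
#' @export
#' @examples
#' vcn_distribution(2.23)
#' vcn_distribution(2.23, truncated = TRUE)
vcn_distribution <- function(lam, support_max = NULL, truncated = FALSE) {
  check_number(lam, "lam", min = 0, strict_min = TRUE)
  check_flag(truncated, "truncated")

  # full support: out to cumulative mass 1 - 1e-9
  k_full <- 0:max(qpois(1 - 1e-10, lam) + 10L, 10L)
  pmf <- dpois(k_full, lam)
  if (truncated) {
    pmf[1] <- 0
    pmf <- pmf / -expm1(-lam)
  }
  cdf <- cumsum(pmf)
  stopifnot(abs(cdf[length(cdf)] - 1) < 1e-9)

  if (is.null(support_max)) {
    support_max <- k_full[match(TRUE, cdf >= 0.9999)]
  } else {
    support_max <- check_count(support_max, "support_max", min = 1L)
  }
  keep <- k_full <= support_max

  out <- new_record(tibble(k = k_full[keep], pmf = pmf[keep], cdf = cdf[keep]),
                    "vcn_distribution")
  attr(out, "lam") <- lam
  attr(out, "truncated") <- truncated
  attr(out, "distribution_mean") <- sum(k_full * pmf)
  out
}

#' Compare theoretical and flow-cytometry untransduced fractions
#'
#' The Poisson model predicts a fraction `exp(-VCN_bulk)` of cells with zero
#' copies. Flow cytometry measures the fraction without detectable
#' transgene surface expression. Because some cells carry vector without
#' expressing it at detectable levels, the theoretical untransduced fraction
#' is expected to fall below the flow-derived one; the reverse direction is
#' flagged as an assay/flow inconsistency.
#'
#' @param vcn_bulk Numeric vector of bulk VCN values (>= 0).
#' @param flow_negative_fraction Fraction(s) in `[0, 1]` of
#'   transgene-negative cells by flow cytometry (1 minus the transduction
#'   efficiency).
#' @return A tibble with `vcn_bulk`, `theoretical_negative`
#'   (`exp(-vcn_bulk)`), `flow_negative`, `difference` (theory minus flow)
#'   and `theory_exceeds_flow`.
#' @export
#' @examples
#' untransduced_fraction_check(0.57, 1 - 0.272)
untransduced_fraction_check <- function(vcn_bulk, flow_negative_fraction) {
  if (!is.numeric(vcn_bulk) || any(!is.finite(vcn_bulk)) || any(vcn_bulk < 0)) {
    stop_dropvcn("`vcn_bulk` must be non-negative finite numeric.",
                 "invalid_argument")
  }
  if (!is.numeric(flow_negative_fraction) ||
      any(flow_negative_fraction < 0) || any(flow_negative_fraction > 1)) {
    stop_dropvcn("`flow_negative_fraction` must lie in [0, 1].",
                 "invalid_argument")
  }
  theo <- exp(-vcn_bulk)
  tibble(
    vcn_bulk = vcn_bulk,
    theoretical_negative = theo,
    flow_negative = flow_negative_fraction,
    difference = theo - flow_negative_fraction,
    theory_exceeds_flow = theo > flow_negative_fraction
  )
}
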