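#' Assay limits from blank replicates and the dilution series
#'
#' Computes the limit of blank (LoB), lower limit of detection (LLoD) and
#' lower limit of quantification (LLoQ) of the assay, in copies/ul of
#' reaction mix, from the measured concentrations of no-template control
#' wells and the lowest concentration actually covered by the dilution
#' series:
#'
#' \deqn{LoB = \bar{x}_{blank} + 1.645\, s_{blank}}
#' \deqn{LLoD = \max(LoB + 3.3\, s_{blank},\ \mathrm{lowest\ dilution\ tested})}
#' \deqn{LLoQ = \max(LoB + 10\, s_{blank},\ \mathrm{lowest\ dilution\ tested})}
#'
#' with the sample (n-1) standard deviation over blanks. The MAX terms keep
#' the limits from falling below concentrations the assay was never
#' challenged at. For non-negative blank SD the ordering
#' `LoB <= LLoD <= LLoQ` always holds.
#'
#' @param blank_measurements Numeric vector (length >= 2) of measured
#'   concentrations in blank (NTC) wells, copies/ul.
#' @param lowest_dilution_tested Lowest concentration of the dilution
#'   series, copies/ul (>= 0).
#' @return A one-row tibble of class `assay_limits` with `lob`, `llod`,
#'   `lloq`, `mean_blank`, `sd_blank`, `lowest_dilution_tested`, `n_blanks`.
#' @export
#' @examples
#' compute_limits(c(0.2, 0.9, 0.4, 0.9), lowest_dilution_tested = 1)
compute_limits <- function(blank_measurements, lowest_dilution_tested = 0) {
  if (!is.numeric(blank_measurements) || length(blank_measurements) < 2L) {
    stop_dropvcn("at least 2 blank measurements are needed (sample SD).",
                 "invalid_argument")
  }
  if (any(!is.finite(blank_measurements)) || any(blank_measurements < 0)) {
    stop_dropvcn("blank measurements must be finite and non-negative.",
                 "invalid_argument")
  }
  check_number(lowest_dilution_tested, "lowest_dilution_tested", min = 0)

  m <- mean(blank_measurements)
  s <- sd(blank_measurements)
  lob <- m + 1.645 * s
  llod <- max(lob + 3.3 * s, lowest_dilution_tested)
  lloq <- max(lob + 10 * s, lowest_dilution_tested)

  new_record(
    tibble(
      lob = lob, llod = llod, lloq = lloq,
      mean_blank = m, sd_blank = s,
      lowest_dilution_tested = lowest_dilution_tested,
      n_blanks = length(blank_measurements)
    ),
    "assay_limits"
  )
}

#' QC flags for a concentration against the assay limits
#'
#' Flags a measured concentration that falls strictly below the limit of
#' blank, detection or quantification. A value equal to a limit is
#' considered quantifiable at that limit and is not flagged.
#'
#' @param estimate A `concentration_estimate` row or a plain concentration
#'   in copies/ul.
#' @param limits An [compute_limits()] result.
#' @return Character vector: subset of `c("below_lob", "below_llod",
#'   "below_lloq")`, empty when the value is at or above the LLoQ.
#' @export
#' @examples
#' lims <- compute_limits(c(0.2, 0.9, 0.4, 0.9))
#' flag_below_limits(7.0, lims)
flag_below_limits <- function(estimate, limits) {
  stopifnot(inherits(limits, "assay_limits"))
  value <- if (inherits(estimate, "concentration_estimate")) {
    estimate$copies_per_ul
  } else {
    check_number(estimate, "estimate", min = 0)
    estimate
  }
  flags <- character()
  if (value < limits$lob) flags <- c(flags, "below_lob")
  if (value < limits$llod) flags <- c(flags, "below_llod")
  if (value < limits$lloq) flags <- c(flags, "below_lloq")
  flags
}
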