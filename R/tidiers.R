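# broom-style accessors: tidy() returns the underlying table as a plain
# tibble, glance() a one-row model-level summary

strip_record <- function(x, keep = NULL) {
  out <- new_tibble(as.list(x), nrow = nrow(x))
  for (a in setdiff(names(attributes(x)),
                    c("names", "row.names", "class", keep))) {
    attr(out, a) <- NULL
  }
  out
}

#' @method tidy droplet_well
#' @export
tidy.droplet_well <- function(x, ...) strip_record(x)

#' @method tidy cluster_counts
#' @export
tidy.cluster_counts <- function(x, ...) {
  strip_record(x) %>%
    tidyr::pivot_longer(dplyr::starts_with("n_fam"),
                        names_to = "cluster", names_prefix = "n_",
                        values_to = "n_droplets")
}

#' @method tidy concentration_estimate
#' @export
tidy.concentration_estimate <- function(x, ...) strip_record(x)

#' @method tidy vcn_result
#' @export
tidy.vcn_result <- function(x, ...) strip_record(x)

#' @method glance vcn_result
#' @export
glance.vcn_result <- function(x, ...) {
  tibble(
    sample_id = x$sample_id,
    vcn_bulk = x$vcn_bulk,
    vcn_adj = x$vcn_adj,
    transduction_putative = x$transduction_putative,
    n_accepted = x$n_accepted,
    n_qc_flags = lengths(x$qc_flags)
  )
}

#' @method tidy vcn_distribution
#' @export
tidy.vcn_distribution <- function(x, ...) strip_record(x)

#' @method glance vcn_distribution
#' @export
glance.vcn_distribution <- function(x, ...) {
  tibble(
    lam = attr(x, "lam"),
    truncated = attr(x, "truncated"),
    mean = attr(x, "distribution_mean"),
    support_max = max(x$k)
  )
}

#' @method tidy assay_limits
#' @export
tidy.assay_limits <- function(x, ...) strip_record(x)

#' @method tidy linearity_report
#' @export
tidy.linearity_report <- function(x, ...) strip_record(x)

#' @method glance linearity_report
#' @export
glance.linearity_report <- function(x, ...) {
  tibble(r_squared = x$r_squared, scale = x$scale, n_points = x$n_points)
}

#' @method tidy repeatability_report
#' @export
tidy.repeatability_report <- function(x, ...) strip_record(x)

#' @method glance repeatability_report
#' @export
glance.repeatability_report <- function(x, ...) {
  tibble(max_cv_pct = attr(x, "max_cv"), n_conditions = nrow(x))
}

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
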