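#' Poisson inversion of droplet counts to an absolute concentration
#'
#' In droplet digital PCR every droplet is an independent Poisson trial:
#' with `lambda` average copies per droplet, a droplet is negative with
#' probability `exp(-lambda)`. The concentration therefore follows from the
#' negative fraction alone, `lambda = -log(n_negative / n_total)`, converted
#' to copies/ul of reaction mix by the droplet volume. The 95% confidence
#' interval is a Wilson score interval on the negative fraction transformed
#' through the same `-log(.) / volume` map (endpoints swap because the map
#' is decreasing).
#'
#' @param counts_negative Number of negative droplets on the channel.
#' @param counts_total Number of accepted droplets.
#' @param droplet_volume_ul Droplet volume in microlitres (default 0.00085,
#'   the usual QX200 value).
#'
#' @return A one-row tibble of class `concentration_estimate` with columns
#'   `copies_per_ul`, `ci_low`, `ci_high` (95%), `lambda` (mean copies per
#'   droplet), `n_accepted`, `n_negative`, `droplet_volume_ul`.
#'
#' @section Errors: `counts_negative = 0` signals a saturation error (every
#'   droplet positive, concentration unbounded); `counts_total = 0` signals
#'   an empty-well error.
#' @export
#' @examples
#' # ~36.8% negative droplets corresponds to 1 copy per droplet
#' estimate_concentration(7358, 20000, 0.00085)
estimate_concentration <- function(counts_negative, counts_total,
                                   droplet_volume_ul = 0.00085) {
  counts_total <- check_count(counts_total, "counts_total")
  if (counts_total == 0L) stop_dropvcn("no accepted droplets.", "empty_well")
  counts_negative <- check_count(counts_negative, "counts_negative")
  if (counts_negative > counts_total) {
    stop_dropvcn("`counts_negative` cannot exceed `counts_total`.",
                 "invalid_argument")
  }
  if (counts_negative == 0L) {
    stop_dropvcn("no negative droplets: reaction saturated, concentration unbounded.",
                 "saturation")
  }
  check_number(droplet_volume_ul, "droplet_volume_ul", min = 0, strict_min = TRUE)

  lambda <- -log(counts_negative / counts_total)
  # Wilson score interval on the negative fraction (no continuity correction)
  ci_p <- stats::prop.test(counts_negative, counts_total,
                           correct = FALSE)$conf.int
  ci <- sort(-log(ci_p) / droplet_volume_ul)

  new_record(
    tibble(
      copies_per_ul = lambda / droplet_volume_ul,
      ci_low = ci[1],
      ci_high = ci[2],
      lambda = lambda,
      n_accepted = counts_total,
      n_negative = counts_negative,
      droplet_volume_ul = droplet_volume_ul
    ),
    "concentration_estimate"
  )
}

#' Per-channel concentrations for one well
#'
#' Applies the Poisson inversion to each channel of a four-cluster count
#' table. On the FAM (WPRE) channel the negatives are the FAM- clusters; on
#' the HEX (TERT) channel the HEX- clusters.
#'
#' @param counts A [cluster_counts] row.
#' @param droplet_volume_ul Droplet volume; defaults to the volume carried
#'   by `counts`.
#' @return A named list with `concentration_estimate` elements `wpre` and
#'   `tert`.
#' @export
quantify_well <- function(counts, droplet_volume_ul = NULL) {
  stopifnot(inherits(counts, "cluster_counts"))
  v <- droplet_volume_ul %||% attr(counts, "droplet_volume_ul") %||% 0.00085
  fam_neg <- counts$n_fam_neg_hex_pos + counts$n_fam_neg_hex_neg
  hex_neg <- counts$n_fam_pos_hex_neg + counts$n_fam_neg_hex_neg
  list(
    wpre = estimate_concentration(fam_neg, counts$n_total, v),
    tert = estimate_concentration(hex_neg, counts$n_total, v)
  )
}

#' Bulk vector copy number from the two channel concentrations
#'
#' Assuming each diploid cell contributes two copies of the reference gene
#' TERT, the average vector copy number over all cells in the sample is
#' `VCN_bulk = 2 * WPRE / TERT`, a ratio of the two channel concentrations.
#' A conservative confidence interval is propagated from the ratio of the
#' channel interval endpoints.
#'
#' @param wpre,tert `concentration_estimate` rows for the target and
#'   reference channels.
#' @param sample_id Sample label.
#' @param lloq Optional lower limit of quantification (copies/ul); a WPRE
#'   concentration strictly below it sets the `below_lloq` QC flag.
#' @param min_accepted Minimum accepted droplets before the `low_droplets`
#'   QC flag is set (default 10000).
#'
#' @return A one-row tibble of class `vcn_result` with `sample_id`,
#'   `vcn_bulk`, `vcn_ci_low`, `vcn_ci_high`, the channel concentrations,
#'   `n_accepted`, placeholders `vcn_adj` and `transduction_putative`
#'   (filled by [refine_vcn()]), and a `qc_flags` list-column.
#'
#' @section Errors: a zero reference concentration signals a
#'   reference-failure error (no quantifiable genome input).
#' @export
#' @examples
#' wpre <- estimate_concentration(15000, 20000)
#' tert <- estimate_concentration(12000, 20000)
#' compute_vcn_bulk(wpre, tert, sample_id = "S1")
compute_vcn_bulk <- function(wpre, tert, sample_id = "sample",
                             lloq = NULL, min_accepted = 10000) {
  stopifnot(inherits(wpre, "concentration_estimate"),
            inherits(tert, "concentration_estimate"))
  if (tert$copies_per_ul <= 0) {
    stop_dropvcn("reference channel measured 0 copies/ul: no quantifiable genome input.",
                 "reference_failure")
  }

  vcn_bulk <- 2 * wpre$copies_per_ul / tert$copies_per_ul
  vcn_ci_low <- 2 * wpre$ci_low / tert$ci_high
  vcn_ci_high <- if (tert$ci_low > 0) 2 * wpre$ci_high / tert$ci_low else Inf

  n_accepted <- min(wpre$n_accepted, tert$n_accepted)
  flags <- character()
  if (!is.null(lloq) && wpre$copies_per_ul < lloq) flags <- c(flags, "below_lloq")
  if (n_accepted < min_accepted) flags <- c(flags, "low_droplets")

  new_record(
    tibble(
      sample_id = sample_id,
      vcn_bulk = vcn_bulk,
      vcn_ci_low = vcn_ci_low,
      vcn_ci_high = vcn_ci_high,
      wpre_copies_per_ul = wpre$copies_per_ul,
      tert_copies_per_ul = tert$copies_per_ul,
      n_accepted = n_accepted,
      vcn_adj = NA_real_,
      transduction_putative = NA_real_,
      qc_flags = list(flags)
    ),
    "vcn_result"
  )
}

#' Full quantification of one well's cluster counts
#'
#' Convenience pipeline step: Poisson-inverts both channels of a
#' [cluster_counts] row and computes the bulk VCN, then fills in the
#' transduced-cell adjustment via [refine_vcn()].
#'
#' @inheritParams quantify_well
#' @inheritParams compute_vcn_bulk
#' @return A one-row `vcn_result` tibble.
#' @export
vcn_from_counts <- function(counts, droplet_volume_ul = NULL,
                            lloq = NULL, min_accepted = 10000) {
  conc <- quantify_well(counts, droplet_volume_ul)
  res <- compute_vcn_bulk(conc$wpre, conc$tert,
                          sample_id = counts$sample_id,
                          lloq = lloq, min_accepted = min_accepted)
  refine_vcn(res)
}

#' Aggregate replicate wells of one sample
#'
#' Combines replicate VCN measurements of the same sample: the point
#' estimate is the accepted-droplet-weighted mean of the replicate
#' `vcn_bulk` values (wells with more droplets carry more information), and
#' dispersion is summarised by the unweighted sample SD and CV%.
#'
#' @param results A tibble of `vcn_result` rows (e.g. from
#'   `dplyr::bind_rows()`), all with the same `sample_id`.
#' @return A one-row tibble of class `vcn_aggregate` with `sample_id`,
#'   `n_replicates`, `vcn_bulk` (weighted mean), `sd`, `cv_pct`,
#'   `n_accepted_total` and a `qc_flags` list-column (`single_replicate`
#'   when the SD is undefined).
#' @export
#' @examples
#' reps <- dplyr::bind_rows(
#'   compute_vcn_bulk(estimate_concentration(14850, 20000),
#'                    estimate_concentration(12000, 20000), "S1"),
#'   compute_vcn_bulk(estimate_concentration(14900, 20000),
#'                    estimate_concentration(12050, 20000), "S1")
#' )
#' aggregate_replicates(reps)
aggregate_replicates <- function(results) {
  if (!is.data.frame(results) || nrow(results) < 1L) {
    stop_dropvcn("`results` must contain at least one vcn_result row.",
                 "invalid_argument")
  }
  ids <- unique(results$sample_id)
  if (length(ids) != 1L) {
    stop_dropvcn("replicates mix sample ids; aggregate one sample at a time.",
                 "mixed_samples")
  }

  w <- results$n_accepted
  mean_vcn <- sum(results$vcn_bulk * w) / sum(w)
  if (nrow(results) >= 2L) {
    sd_vcn <- sd(results$vcn_bulk)
    cv <- 100 * sd_vcn / mean_vcn
    flags <- character()
  } else {
    sd_vcn <- NA_real_
    cv <- NA_real_
    flags <- "single_replicate"
  }

  new_record(
    tibble(
      sample_id = ids,
      n_replicates = nrow(results),
      vcn_bulk = mean_vcn,
      sd = sd_vcn,
      cv_pct = cv,
      n_accepted_total = sum(w),
      qc_flags = list(flags)
    ),
    "vcn_aggregate"
  )
}
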