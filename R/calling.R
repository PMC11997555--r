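#' Per-droplet amplitude records for one well
#'
#' The raw readout of one duplex ddPCR well: one row per droplet with the
#' FAM (target, WPRE) and HEX (reference, TERT) fluorescence amplitudes,
#' plus well metadata stored as attributes. Simulated wells additionally
#' carry the hidden true occupancy counts `k_wpre` and `k_tert`.
#'
#' @param fam_amplitudes,hex_amplitudes Numeric vectors of equal length
#'   (>= 1) of finite fluorescence amplitudes.
#' @param well_id,sample_id Labels.
#' @param dilution_factor Dilution factor in `(0, 1]`.
#' @param is_blank Whether the well is a no-template control.
#' @param droplet_volume_ul Droplet volume in microlitres.
#' @param k_wpre,k_tert Optional hidden true per-droplet copy counts
#'   (simulated wells only).
#'
#' @return A tibble of class `droplet_well`.
#' @export
droplet_well <- function(fam_amplitudes, hex_amplitudes,
                         well_id = "well", sample_id = well_id,
                         dilution_factor = 1, is_blank = FALSE,
                         droplet_volume_ul = 0.00085,
                         k_wpre = NULL, k_tert = NULL) {
  if (length(fam_amplitudes) != length(hex_amplitudes)) {
    stop_dropvcn("FAM and HEX amplitude vectors must have equal length.",
                 "invalid_argument")
  }
  if (length(fam_amplitudes) < 1L) {
    stop_dropvcn("a well must contain at least one droplet.", "empty_well")
  }
  if (any(!is.finite(fam_amplitudes)) || any(!is.finite(hex_amplitudes))) {
    stop_dropvcn("amplitudes must be finite.", "invalid_argument")
  }
  check_number(dilution_factor, "dilution_factor", min = 0, strict_min = TRUE)
  if (dilution_factor > 1) {
    stop_dropvcn("`dilution_factor` must lie in (0, 1].", "invalid_argument")
  }
  check_flag(is_blank, "is_blank")
  check_number(droplet_volume_ul, "droplet_volume_ul", min = 0, strict_min = TRUE)

  data <- tibble(fam_amplitude = as.double(fam_amplitudes),
                 hex_amplitude = as.double(hex_amplitudes))
  if (!is.null(k_wpre)) data$k_wpre <- as.integer(k_wpre)
  if (!is.null(k_tert)) data$k_tert <- as.integer(k_tert)

  out <- new_record(data, c("droplet_well", class(tibble())))
  attr(out, "well_id") <- well_id
  attr(out, "sample_id") <- sample_id
  attr(out, "dilution_factor") <- dilution_factor
  attr(out, "is_blank") <- is_blank
  attr(out, "droplet_volume_ul") <- droplet_volume_ul
  out
}

#' Place a positive/negative threshold on one amplitude channel
#'
#' Separates the negative and positive droplet clusters on a single channel
#' with a scalar threshold, the same model as the single horizontal /
#' vertical threshold line drawn by the instrument software.
#'
#' Methods:
#' \describe{
#'   \item{`"otsu"`}{The cut maximizing between-class variance over a
#'     fixed-bin histogram of the amplitudes (Otsu's criterion).}
#'   \item{`"midpoint"`}{Splits the sorted amplitudes at the boundary
#'     minimizing total within-group sum of squares (exact 1-D two-means)
#'     and returns the mean of the two group centers.}
#'   \item{`"manual"`}{Echoes `manual_value`.}
#' }
#'
#' @param amplitudes Numeric vector of droplet amplitudes (>= 2 droplets for
#'   the automatic methods).
#' @param method One of `"otsu"`, `"midpoint"`, `"manual"`.
#' @param manual_value Threshold to use when `method = "manual"`.
#' @param n_bins Histogram bins for the Otsu scan.
#'
#' @return A single threshold value; for automatic methods it lies within
#'   the amplitude range.
#' @export
#' @examples
#' x <- c(rnorm(500, 1000, 400), rnorm(500, 8000, 400))
#' set_threshold(x, "otsu")
set_threshold <- function(amplitudes, method = c("otsu", "midpoint", "manual"),
                          manual_value = NULL, n_bins = 512) {
  method <- match.arg(method)
  if (method == "manual") {
    if (is.null(manual_value)) {
      stop_dropvcn("`manual_value` is required when method = \"manual\".",
                   "invalid_argument")
    }
    check_number(manual_value, "manual_value")
    return(manual_value)
  }
  if (!is.null(manual_value)) {
    stop_dropvcn("`manual_value` is only accepted with method = \"manual\".",
                 "invalid_argument")
  }
  if (length(amplitudes) < 2L) {
    stop_dropvcn("automatic thresholding needs at least 2 droplets.",
                 "invalid_argument")
  }
  if (any(!is.finite(amplitudes))) {
    stop_dropvcn("amplitudes must be finite.", "invalid_argument")
  }
  rng <- range(amplitudes)
  if (rng[1] == rng[2]) {
    stop_dropvcn("all amplitudes identical: no separable classes.",
                 "degenerate_input")
  }

  switch(method,
         otsu = threshold_otsu(amplitudes, n_bins),
         midpoint = threshold_midpoint(amplitudes))
}

# Otsu on a fixed-bin histogram: pick the cut maximizing between-class
# variance w0 * w1 * (mu0 - mu1)^2
threshold_otsu <- function(x, n_bins) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2

  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  n <- w[n_bins]
  mt <- m[n_bins]

  cuts <- seq_len(n_bins - 1L)
  w0 <- w[cuts]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, n_bins - 1L)
  between[valid] <- (mt * w0[valid] - n * m[cuts][valid])^2 /
    (w0[valid] * w1[valid])
  # the criterion is flat across an empty inter-cluster gap: average all
  # maximizing cuts so the threshold sits mid-gap
  best <- which(between >= max(between) * (1 - 1e-12))
  mean(breaks[best + 1L])
}

# exact 1-D two-means: scan every split of the sorted values, minimize
# within-group SS; threshold is the midpoint of the two group means
threshold_midpoint <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1L)
  ss_left <- cs2[k] - cs[k]^2 / k
  ss_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  best <- which.min(ss_left + ss_right)
  mean_left <- cs[best] / best
  mean_right <- (cs[n] - cs[best]) / (n - best)
  (mean_left + mean_right) / 2
}

#' Droplet counts in the four duplex clusters
#'
#' Container for pre-summarized duplex droplet counts: double-negative,
#' single-positive on each channel, and double-positive, together with the
#' thresholds used. Counts must partition the accepted droplets.
#'
#' @param n_fam_pos_hex_pos,n_fam_pos_hex_neg,n_fam_neg_hex_pos,n_fam_neg_hex_neg
#'   Droplet counts in the four clusters.
#' @param fam_threshold,hex_threshold Thresholds used (may be `NA` for
#'   counts imported without amplitude data).
#' @param well_id,sample_id Labels.
#' @param dilution_factor,is_blank,droplet_volume_ul Well metadata.
#' @return A one-row tibble of class `cluster_counts` with the four counts,
#'   `n_total`, thresholds and labels.
#' @export
cluster_counts <- function(n_fam_pos_hex_pos, n_fam_pos_hex_neg,
                           n_fam_neg_hex_pos, n_fam_neg_hex_neg,
                           fam_threshold = NA_real_, hex_threshold = NA_real_,
                           well_id = "well", sample_id = well_id,
                           dilution_factor = 1, is_blank = FALSE,
                           droplet_volume_ul = 0.00085) {
  counts <- vapply(
    list(n_fam_pos_hex_pos = n_fam_pos_hex_pos,
         n_fam_pos_hex_neg = n_fam_pos_hex_neg,
         n_fam_neg_hex_pos = n_fam_neg_hex_pos,
         n_fam_neg_hex_neg = n_fam_neg_hex_neg),
    function(x) check_count(x, "cluster count"), integer(1))

  out <- new_record(
    tibble(
      well_id = well_id, sample_id = sample_id,
      n_total = sum(counts),
      n_fam_pos_hex_pos = counts[["n_fam_pos_hex_pos"]],
      n_fam_pos_hex_neg = counts[["n_fam_pos_hex_neg"]],
      n_fam_neg_hex_pos = counts[["n_fam_neg_hex_pos"]],
      n_fam_neg_hex_neg = counts[["n_fam_neg_hex_neg"]],
      fam_threshold = as.double(fam_threshold),
      hex_threshold = as.double(hex_threshold)
    ),
    c("cluster_counts", class(tibble()))
  )
  attr(out, "dilution_factor") <- dilution_factor
  attr(out, "is_blank") <- is_blank
  attr(out, "droplet_volume_ul") <- droplet_volume_ul
  out
}

#' Classify droplets into the four duplex clusters
#'
#' Calls each droplet positive or negative on each channel and tallies the
#' four clusters seen in a duplex readout: FAM+HEX+ (droplets carrying both
#' vector and reference templates), FAM+HEX-, FAM-HEX+, and the empty
#' FAM-HEX- cluster. A droplet is positive on a channel iff its amplitude is
#' strictly above the threshold; droplets exactly on the threshold are
#' called negative (conservative with respect to contamination).
#'
#' @param well A [droplet_well].
#' @param fam_threshold,hex_threshold Channel thresholds. When `NULL`, each
#'   is set automatically from the well's amplitudes with [set_threshold()].
#' @param threshold_method Automatic method used when thresholds are `NULL`.
#'
#' @return A one-row [cluster_counts] tibble; the four cluster counts sum to
#'   `n_total`, the number of droplets in the well.
#' @export
#' @examples
#' well <- simulate_well(sim_config(wpre_conc = 400, tert_conc = 1200, seed = 3))
#' classify_droplets(well)
classify_droplets <- function(well, fam_threshold = NULL, hex_threshold = NULL,
                              threshold_method = "otsu") {
  if (!inherits(well, "droplet_well")) {
    stop_dropvcn("`well` must be a droplet_well.", "invalid_argument")
  }
  if (nrow(well) == 0L) stop_dropvcn("empty well.", "empty_well")

  fam_threshold <- fam_threshold %||%
    set_threshold(well$fam_amplitude, threshold_method)
  hex_threshold <- hex_threshold %||%
    set_threshold(well$hex_amplitude, threshold_method)
  check_number(fam_threshold, "fam_threshold")
  check_number(hex_threshold, "hex_threshold")

  fam_pos <- well$fam_amplitude > fam_threshold
  hex_pos <- well$hex_amplitude > hex_threshold

  cluster_counts(
    n_fam_pos_hex_pos = sum(fam_pos & hex_pos),
    n_fam_pos_hex_neg = sum(fam_pos & !hex_pos),
    n_fam_neg_hex_pos = sum(!fam_pos & hex_pos),
    n_fam_neg_hex_neg = sum(!fam_pos & !hex_pos),
    fam_threshold = fam_threshold,
    hex_threshold = hex_threshold,
    well_id = attr(well, "well_id") %||% "well",
    sample_id = attr(well, "sample_id") %||% "well",
    dilution_factor = attr(well, "dilution_factor") %||% 1,
    is_blank = attr(well, "is_blank") %||% FALSE,
    droplet_volume_ul = attr(well, "droplet_volume_ul") %||% 0.00085
  )
}
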