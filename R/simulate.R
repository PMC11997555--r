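#' Simulation settings for a duplex ddPCR well
#'
#' Describes one well of a duplex droplet digital PCR run: droplet number and
#' volume, the true template concentrations of the vector target (WPRE, read
#' on the FAM channel) and of the diploid reference gene (TERT, read on the
#' HEX channel), and the fluorescence amplitude landscape. Each channel is a
#' two-Gaussian mixture (negative and positive clusters) with an optional
#' uniform "rain" band of intermediate droplets.
#'
#' Template molecules partition independently into droplets, so the copy
#' count per droplet is Poisson with rate `concentration * droplet volume`.
#' WPRE and TERT occupancy are independent: the assay digests genomic DNA so
#' that target and reference loci sit on separate fragments before
#' partitioning, and neither amplicon carries the restriction site.
#'
#' @param n_droplets Number of droplets generated for the well.
#' @param droplet_volume_ul Droplet volume in microlitres. The default
#'   0.00085 ul (0.85 nL) is the usual QX200 droplet volume.
#' @param wpre_conc True WPRE concentration, copies/ul of reaction mix.
#' @param tert_conc True TERT concentration, copies/ul of reaction mix.
#' @param fam_neg_mean,fam_pos_mean,fam_sd FAM-channel amplitude model:
#'   means of the negative and positive Gaussians and their common SD
#'   (arbitrary fluorescence units).
#' @param hex_neg_mean,hex_pos_mean,hex_sd Same for the HEX channel.
#' @param rain_fraction Fraction in `[0, 1)` of droplets drawn, on both
#'   channels, uniformly between the negative and positive means instead of
#'   from either Gaussian ("rain").
#' @param seed Integer seed; mandatory so that every simulated well is
#'   reproducible.
#'
#' @return A `sim_config` list.
#' @seealso [simulate_well()], [simulate_dilution_series()]
#' @export
#' @examples
#' cfg <- sim_config(wpre_conc = 500, tert_conc = 1000, seed = 1)
sim_config <- function(n_droplets = 20000,
                       droplet_volume_ul = 0.00085,
                       wpre_conc = 500,
                       tert_conc = 1000,
                       fam_neg_mean = 1000, fam_pos_mean = 8000, fam_sd = 400,
                       hex_neg_mean = 1000, hex_pos_mean = 8000, hex_sd = 400,
                       rain_fraction = 0,
                       seed) {
  n_droplets <- check_count(n_droplets, "n_droplets", min = 1L)
  check_number(droplet_volume_ul, "droplet_volume_ul", min = 0, strict_min = TRUE)
  check_number(wpre_conc, "wpre_conc", min = 0)
  check_number(tert_conc, "tert_conc", min = 0)
  check_number(fam_sd, "fam_sd", min = 0, strict_min = TRUE)
  check_number(hex_sd, "hex_sd", min = 0, strict_min = TRUE)
  if (fam_pos_mean <= fam_neg_mean || hex_pos_mean <= hex_neg_mean) {
    stop_dropvcn("positive cluster mean must exceed negative cluster mean on each channel.",
                 "invalid_argument")
  }
  check_number(rain_fraction, "rain_fraction", min = 0)
  if (rain_fraction >= 1) {
    stop_dropvcn("`rain_fraction` must be in [0, 1).", "invalid_argument")
  }
  if (missing(seed)) stop_dropvcn("`seed` is mandatory.", "invalid_argument")
  seed <- check_count(seed, "seed")

  structure(
    list(
      n_droplets = n_droplets,
      droplet_volume_ul = droplet_volume_ul,
      wpre_conc = wpre_conc,
      tert_conc = tert_conc,
      fam_neg_mean = fam_neg_mean, fam_pos_mean = fam_pos_mean, fam_sd = fam_sd,
      hex_neg_mean = hex_neg_mean, hex_pos_mean = hex_pos_mean, hex_sd = hex_sd,
      rain_fraction = rain_fraction,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' Simulate one duplex ddPCR well
#'
#' Stands in for the droplet generator and reader: partitions WPRE and TERT
#' templates into droplets by independent Poisson draws, then emits a
#' two-channel fluorescence amplitude per droplet. A droplet with at least
#' one template copy on a channel draws its amplitude from the positive
#' Gaussian, otherwise from the negative one; a `rain_fraction` subset draws
#' both amplitudes uniformly between the two cluster means. The hidden
#' per-droplet occupancy counts (`k_wpre`, `k_tert`) are kept alongside the
#' amplitudes so downstream estimates can be checked against ground truth.
#'
#' @param config A [sim_config()].
#' @param well_id,sample_id Labels carried into the result.
#' @param dilution_factor Dilution factor in `(0, 1]` recorded as metadata.
#' @param is_blank Whether the well is a no-template control.
#'
#' @return A [droplet_well] tibble with columns `fam_amplitude`,
#'   `hex_amplitude`, `k_wpre`, `k_tert`, one row per droplet.
#' @export
#' @examples
#' well <- simulate_well(sim_config(wpre_conc = 500, tert_conc = 1000, seed = 7))
#' head(well)
simulate_well <- function(config, well_id = "A01", sample_id = "sim",
                          dilution_factor = 1, is_blank = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_droplets
  v <- config$droplet_volume_ul

  withr::with_seed(config$seed, {
    k_wpre <- rpois(n, config$wpre_conc * v)
    k_tert <- rpois(n, config$tert_conc * v)
    fam <- rnorm(n,
                 mean = ifelse(k_wpre >= 1L, config$fam_pos_mean, config$fam_neg_mean),
                 sd = config$fam_sd)
    hex <- rnorm(n,
                 mean = ifelse(k_tert >= 1L, config$hex_pos_mean, config$hex_neg_mean),
                 sd = config$hex_sd)
    if (config$rain_fraction > 0) {
      rain <- runif(n) < config$rain_fraction
      fam[rain] <- runif(sum(rain), config$fam_neg_mean, config$fam_pos_mean)
      hex[rain] <- runif(sum(rain), config$hex_neg_mean, config$hex_pos_mean)
    }
  })

  droplet_well(
    fam_amplitudes = fam, hex_amplitudes = hex,
    well_id = well_id, sample_id = sample_id,
    dilution_factor = dilution_factor, is_blank = is_blank,
    droplet_volume_ul = v,
    k_wpre = k_wpre, k_tert = k_tert
  )
}

#' Simulate a spike-in dilution series
#'
#' Emulates the linearity experiment in which genomic DNA from a transduced
#' cell product is serially diluted into the same amount of non-transduced
#' genomic DNA from the same donor: the vector target (WPRE) concentration
#' scales with each dilution factor while the reference (TERT) concentration
#' stays constant, because the background DNA contributes reference copies
#' but no vector.
#'
#' @param config A [sim_config()] describing the undiluted well.
#' @param dilution_factors Vector of factors in `(0, 1]`, e.g.
#'   `c(1, 0.5, 0.25, 0.125, 0.0625)` for a twofold series.
#' @param sample_id Sample label shared by the series.
#'
#' @return A named list of [droplet_well] tibbles, one per factor. Each
#'   well's seed is derived from `config$seed` plus its position so wells
#'   are independent but the series is reproducible.
#' @export
simulate_dilution_series <- function(config, dilution_factors,
                                     sample_id = "series") {
  stopifnot(inherits(config, "sim_config"))
  if (length(dilution_factors) == 0) {
    stop_dropvcn("`dilution_factors` must not be empty.", "invalid_argument")
  }
  if (!is.numeric(dilution_factors) || any(!is.finite(dilution_factors)) ||
      any(dilution_factors <= 0) || any(dilution_factors > 1)) {
    stop_dropvcn("each dilution factor must lie in (0, 1].", "invalid_argument")
  }

  purrr::imap(
    setNames(as.list(dilution_factors),
             sprintf("DILN%d", seq_along(dilution_factors) - 1L)),
    function(f, nm) {
      i <- as.integer(sub("DILN", "", nm))
      cfg_i <- config
      cfg_i$wpre_conc <- config$wpre_conc * f
      cfg_i$seed <- config$seed + i
      simulate_well(cfg_i, well_id = nm, sample_id = sample_id,
                    dilution_factor = f)
    }
  )
}

#' Settings for a simulated gene-engineered cell product
#'
#' The per-cell copy model: integrated vector copies per cell are Poisson
#' with rate `lambda_vcn`, the model under which the putative transduction
#' efficiency `1 - exp(-VCN_bulk)` and the zero-truncated adjustment are
#' exact. Transduced cells are those with at least one copy.
#'
#' @param n_cells Number of cells in the product.
#' @param lambda_vcn Mean integrated copies per cell (Poisson rate).
#' @param seed Integer seed (mandatory).
#' @return A `cell_product_config` list.
#' @export
cell_product_config <- function(n_cells, lambda_vcn, seed) {
  n_cells <- check_count(n_cells, "n_cells", min = 1L)
  check_number(lambda_vcn, "lambda_vcn", min = 0)
  if (missing(seed)) stop_dropvcn("`seed` is mandatory.", "invalid_argument")
  seed <- check_count(seed, "seed")
  structure(list(n_cells = n_cells, lambda_vcn = lambda_vcn, seed = seed),
            class = "cell_product_config")
}

#' Simulate per-cell vector copy numbers for a cell product
#'
#' Draws integrated copies per cell from `Poisson(lambda_vcn)` and summarises
#' the product: empirical transduction fraction (cells with >= 1 copy), mean
#' VCN over all cells and over transduced cells only, and the template totals
#' a ddPCR reaction on this product would see — WPRE equals the sum of
#' per-cell copies, TERT equals `2 * n_cells` (two reference copies per
#' diploid genome).
#'
#' @param config A [cell_product_config()].
#' @return A list of class `cell_product` with elements `copies` (integer
#'   vector of per-cell VCN), `n_cells`, `lambda_vcn`, `n_transduced`,
#'   `transduction_fraction`, `mean_vcn_all`, `mean_vcn_transduced`
#'   (`NA` when no cell is transduced), `wpre_total` and `tert_total`.
#' @seealso [product_concentrations()] to convert template totals into
#'   reaction concentrations for an end-to-end simulated assay.
#' @export
#' @examples
#' prod <- simulate_cell_product(cell_product_config(1e4, lambda_vcn = 2, seed = 1))
#' prod$transduction_fraction   # close to 1 - exp(-2)
simulate_cell_product <- function(config) {
  stopifnot(inherits(config, "cell_product_config"))
  copies <- withr::with_seed(config$seed,
                             rpois(config$n_cells, config$lambda_vcn))
  transduced <- copies >= 1L
  structure(
    list(
      copies = copies,
      n_cells = config$n_cells,
      lambda_vcn = config$lambda_vcn,
      n_transduced = sum(transduced),
      transduction_fraction = mean(transduced),
      mean_vcn_all = mean(copies),
      mean_vcn_transduced = if (any(transduced)) mean(copies[transduced]) else NA_real_,
      wpre_total = sum(copies),
      tert_total = 2 * config$n_cells
    ),
    class = "cell_product"
  )
}

#' @export
print.cell_product <- function(x, ...) {
  cat(sprintf("<cell_product> %d cells, lambda = %g\n", x$n_cells, x$lambda_vcn))
  cat(sprintf("  transduced: %d (%.1f%%), mean VCN all/transduced: %.4g / %.4g\n",
              x$n_transduced, 100 * x$transduction_fraction,
              x$mean_vcn_all, x$mean_vcn_transduced))
  cat(sprintf("  template totals: WPRE %d, TERT %d\n", x$wpre_total, x$tert_total))
  invisible(x)
}

#' Reaction concentrations implied by a simulated cell product
#'
#' Maps a product's template totals to copies/ul of reaction mix. Only the
#' WPRE:TERT ratio matters for VCN (a ratio of concentrations), so the
#' reference concentration is pinned to a chosen value — representing how
#' much genomic DNA was loaded into the reaction — and WPRE is scaled by the
#' template ratio.
#'
#' @param product A `cell_product` from [simulate_cell_product()].
#' @param tert_copies_per_ul Reference gene concentration the DNA input
#'   corresponds to, copies/ul of reaction mix.
#' @return A tibble with columns `wpre_conc` and `tert_conc` (copies/ul).
#' @export
product_concentrations <- function(product, tert_copies_per_ul = 1500) {
  stopifnot(inherits(product, "cell_product"))
  check_number(tert_copies_per_ul, "tert_copies_per_ul", min = 0, strict_min = TRUE)
  tibble(
    wpre_conc = tert_copies_per_ul * product$wpre_total / product$tert_total,
    tert_conc = tert_copies_per_ul
  )
}
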