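#' Read a droplet amplitude CSV export
#'
#' Reads one well's per-droplet amplitudes from a CSV in the instrument
#' export dialect: one row per droplet, amplitude columns named
#' `"Ch1 Amplitude"` (FAM) and `"Ch2 Amplitude"` (HEX) by default. Extra
#' columns (e.g. a cluster assignment) are ignored.
#'
#' @param path Path to the CSV file.
#' @param channel_map Named character vector mapping channels to column
#'   names: `c(fam = ..., hex = ...)`.
#' @param well_id,sample_id,dilution_factor,is_blank,droplet_volume_ul Well
#'   metadata attached to the result.
#' @return A [droplet_well] tibble.
#' @export
read_droplet_csv <- function(path,
                             channel_map = c(fam = "Ch1 Amplitude",
                                             hex = "Ch2 Amplitude"),
                             well_id = "well", sample_id = well_id,
                             dilution_factor = 1, is_blank = FALSE,
                             droplet_volume_ul = 0.00085) {
  if (!file.exists(path)) {
    stop_dropvcn(sprintf("file not found: %s", path), "io")
  }
  if (!all(c("fam", "hex") %in% names(channel_map))) {
    stop_dropvcn("`channel_map` must name both 'fam' and 'hex' columns.",
                 "invalid_argument")
  }
  # amplitudes are read as text and converted via strtod so that values
  # written at full precision round-trip bit-identically
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(unname(channel_map[c("fam", "hex")]), names(data))
  if (length(missing_cols) > 0) {
    stop_dropvcn(sprintf("missing amplitude column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 "schema")
  }
  if (nrow(data) == 0L) {
    stop_dropvcn(sprintf("no droplets in file: %s", path), "empty_well")
  }
  fam <- suppressWarnings(as.numeric(data[[channel_map[["fam"]]]]))
  hex <- suppressWarnings(as.numeric(data[[channel_map[["hex"]]]]))
  if (anyNA(fam) || anyNA(hex)) {
    stop_dropvcn("amplitude columns must be numeric.", "schema")
  }

  droplet_well(fam, hex, well_id = well_id, sample_id = sample_id,
               dilution_factor = dilution_factor, is_blank = is_blank,
               droplet_volume_ul = droplet_volume_ul)
}

#' Write a droplet well to the amplitude CSV dialect
#'
#' @param well A [droplet_well].
#' @param path Output path.
#' @param channel_map Column names to use, as in [read_droplet_csv()].
#' @return The path, invisibly.
#' @export
write_droplet_csv <- function(well, path,
                              channel_map = c(fam = "Ch1 Amplitude",
                                              hex = "Ch2 Amplitude")) {
  stopifnot(inherits(well, "droplet_well"))
  out <- tibble(!!channel_map[["fam"]] := well$fam_amplitude,
                !!channel_map[["hex"]] := well$hex_amplitude)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a plate configuration file
#'
#' Loads plate/well metadata — well ids, sample ids, well roles, dilution
#' factors and channel mapping — plus assay settings (droplet volume,
#' minimum accepted droplets, threshold method) from YAML (`.yml`/`.yaml`)
#' or JSON.
#'
#' @param path Path to the config file.
#' @return A list of class `plate_config` with elements `wells` (a tibble)
#'   and `assay` (a list).
#' @export
read_plate_config <- function(path) {
  if (!file.exists(path)) {
    stop_dropvcn(sprintf("file not found: %s", path), "io")
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  if (is.null(raw$wells) || length(raw$wells) == 0L) {
    stop_dropvcn("plate config defines no wells.", "schema")
  }

  wells <- purrr::map_dfr(raw$wells, function(w) {
    tibble(
      well_id = w$well_id %||% stop_dropvcn("well without well_id.", "schema"),
      sample_id = w$sample_id %||% w$well_id,
      role = w$role %||% "sample",
      dilution_factor = as.double(w$dilution_factor %||% 1),
      target_channel = (w$channel_map %||% list())$target %||% "FAM",
      reference_channel = (w$channel_map %||% list())$reference %||% "HEX"
    )
  })
  if (anyDuplicated(wells$well_id)) {
    stop_dropvcn("well ids must be unique.", "schema")
  }
  if (any(wells$dilution_factor <= 0 | wells$dilution_factor > 1)) {
    stop_dropvcn("dilution factors must lie in (0, 1].", "schema")
  }
  if (!all(wells$role %in% c("sample", "ntc", "non_transduced_control"))) {
    stop_dropvcn("well role must be sample, ntc or non_transduced_control.",
                 "schema")
  }

  assay_defaults <- list(droplet_volume_ul = 0.00085,
                         min_accepted_droplets = 10000,
                         threshold_method = "otsu")
  assay <- modifyList(assay_defaults, raw$assay %||% list())

  structure(list(wells = wells, assay = assay), class = "plate_config")
}

# shared per-sample report table: full precision plus the 2-decimal display
# values matching release-report convention
report_table <- function(results) {
  tibble(
    sample_id = results$sample_id,
    vcn_bulk = results$vcn_bulk,
    vcn_bulk_2dp = sprintf("%.2f", results$vcn_bulk),
    vcn_adj = results$vcn_adj,
    vcn_adj_2dp = ifelse(is.na(results$vcn_adj), "NA",
                         sprintf("%.2f", results$vcn_adj)),
    transduction_putative = results$transduction_putative,
    vcn_ci_low = results$vcn_ci_low,
    vcn_ci_high = results$vcn_ci_high,
    wpre_copies_per_ul = results$wpre_copies_per_ul,
    tert_copies_per_ul = results$tert_copies_per_ul,
    n_accepted = results$n_accepted,
    qc_flags = vapply(results$qc_flags, paste, character(1), collapse = ";")
  )
}

#' Write a machine-readable VCN report
#'
#' Writes per-sample results — bulk and adjusted VCN (full precision and
#' 2-decimal display values), putative transduction efficiency, confidence
#' intervals, channel concentrations and QC flags — to JSON or CSV with a
#' deterministic field order. The JSON format additionally embeds, per
#' sample, the per-cell VCN distribution table and, when supplied, the
#' assay limits and validation reports; the CSV holds the per-sample table
#' only, with identical fields and values.
#'
#' @param results A tibble of `vcn_result` rows (see [compute_vcn_bulk()],
#'   [refine_vcn()]).
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @param limits Optional [compute_limits()] result (JSON only).
#' @param linearity Optional [dilution_linearity()] report (JSON only).
#' @param repeatability Optional [inter_assay_cv()] report (JSON only).
#' @param distribution_support Largest VCN tabulated per sample in the JSON
#'   distribution tables (`NULL` for the automatic 0.9999 support).
#' @return The path, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv"),
                         limits = NULL, linearity = NULL,
                         repeatability = NULL, distribution_support = NULL) {
  format <- match.arg(format)
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop_dropvcn("`results` must contain at least one row.", "invalid_argument")
  }
  tab <- report_table(results)

  if (format == "csv") {
    readr::write_csv(tab, path)
    return(invisible(path))
  }

  samples <- purrr::map(seq_len(nrow(tab)), function(i) {
    rec <- as.list(tab[i, ])
    v <- results$vcn_bulk[i]
    if (is.finite(v) && v > 0) {
      d <- vcn_distribution(v, support_max = distribution_support)
      rec$distribution <- as.data.frame(d[, c("k", "pmf", "cdf")])
    }
    rec
  })
  payload <- list(samples = samples)
  if (!is.null(limits)) payload$limits <- as.list(as_tibble(limits))
  if (!is.null(linearity)) {
    payload$linearity <- as.list(as_tibble(linearity))
  }
  if (!is.null(repeatability)) {
    payload$repeatability <- as.data.frame(as_tibble(repeatability))
    payload$max_cv_pct <- attr(repeatability, "max_cv")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
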