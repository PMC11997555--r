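# shared fixture builders; everything is generated in code at test time

default_cfg <- function(wpre = 500, tert = 1500, seed = 1, n = 20000, ...) {
  sim_config(n_droplets = n, wpre_conc = wpre, tert_conc = tert, seed = seed, ...)
}

# hidden-truth negative counts for a simulated well (exact labels, no
# threshold step) -- used where the estimator itself is under test
truth_negatives <- function(well, channel = c("wpre", "tert")) {
  channel <- match.arg(channel)
  k <- if (channel == "wpre") well$k_wpre else well$k_tert
  sum(k == 0L)
}

# minimal vcn_result-shaped rows for aggregation tests
fake_results <- function(vcn, sample_id = "S", n_accepted = 20000) {
  tibble::tibble(
    sample_id = sample_id,
    vcn_bulk = vcn,
    n_accepted = rep_len(n_accepted, length(vcn)),
    qc_flags = replicate(length(vcn), character(), simplify = FALSE)
  )
}

# printed release-table reference values: bulk VCN, adjusted VCN and flow
# transduction % for the six sorted CAR-T products
table1 <- tibble::tibble(
  sample = c("S1", "S2", "S3", "S4", "S5", "S6"),
  vcn_bulk = c(8.47, 2.23, 9.00, 0.57, 1.07, 2.97),
  vcn_adj = c(8.47, 2.50, 9.00, 1.31, 1.63, 3.13),
  flow_transduction_pct = c(78.6, 52.3, 91.5, 27.2, 37.5, 66.2)
)
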