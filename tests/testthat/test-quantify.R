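test_that("all-negative well quantifies to zero with a zero lower bound", {
  est <- estimate_concentration(10000, 10000, 0.00085)
  expect_equal(est$copies_per_ul, 0)
  expect_equal(est$ci_low, 0)
  expect_gt(est$ci_high, 0)
})

test_that("Poisson inversion reproduces direct formula arithmetic", {
  est <- estimate_concentration(7358, 20000, 0.00085)
  expect_equal(est$lambda, -log(7358 / 20000))
  expect_equal(est$lambda, 1.0, tolerance = 1e-4)
  expect_equal(est$copies_per_ul, 1176.5, tolerance = 1e-4)
  expect_lte(est$ci_low, est$copies_per_ul)
  expect_gte(est$ci_high, est$copies_per_ul)
})

test_that("saturated and empty wells are rejected", {
  expect_error(estimate_concentration(0, 20000), class = "dropvcn_saturation")
  expect_error(estimate_concentration(0, 0), class = "dropvcn_empty_well")
  expect_error(estimate_concentration(30, 20), class = "dropvcn_error")
})

test_that("inversion is the exact inverse of the occupancy model", {
  # forward-mapping the estimate through the Poisson model returns the
  # observed negative count to machine precision
  cases <- list(c(7358, 20000), c(19999, 20000), c(3, 15000), c(500, 1000))
  for (case in cases) {
    est <- estimate_concentration(case[1], case[2], 0.00085)
    recovered <- exp(-est$copies_per_ul * est$droplet_volume_ul) * case[2]
    expect_equal(recovered, case[1], tolerance = 1e-12)
  }
})

test_that("bulk VCN is twice the channel concentration ratio", {
  wpre <- estimate_concentration(7358, 20000)   # ~1176.5 copies/ul
  tert <- estimate_concentration(7358, 20000)
  res <- compute_vcn_bulk(wpre, tert)
  expect_equal(res$vcn_bulk, 2.0)

  # wpre 50, tert 200 -> 0.5; build estimates with those concentrations
  wpre$copies_per_ul <- 50
  tert$copies_per_ul <- 200
  expect_equal(compute_vcn_bulk(wpre, tert)$vcn_bulk, 0.5)
})

test_that("bulk VCN is invariant under common rescaling of both channels", {
  wpre <- estimate_concentration(14000, 20000)
  tert <- estimate_concentration(9000, 20000)
  base <- compute_vcn_bulk(wpre, tert)$vcn_bulk
  for (c_scale in c(0.1, 3, 42)) {
    w2 <- wpre; t2 <- tert
    w2$copies_per_ul <- wpre$copies_per_ul * c_scale
    t2$copies_per_ul <- tert$copies_per_ul * c_scale
    expect_equal(compute_vcn_bulk(w2, t2)$vcn_bulk, base)
  }
})

test_that("a dead reference channel raises a reference failure", {
  wpre <- estimate_concentration(15000, 20000)
  tert <- estimate_concentration(20000, 20000)   # zero copies
  expect_error(compute_vcn_bulk(wpre, tert),
               class = "dropvcn_reference_failure")
})

test_that("QC flags mark sub-LLoQ and low-droplet wells", {
  wpre <- estimate_concentration(19990, 20000)   # ~0.6 copies/ul
  tert <- estimate_concentration(9000, 20000)
  res <- compute_vcn_bulk(wpre, tert, lloq = 6.4)
  expect_true("below_lloq" %in% res$qc_flags[[1]])

  small_w <- estimate_concentration(3000, 5000)
  small_t <- estimate_concentration(2000, 5000)
  res2 <- compute_vcn_bulk(small_w, small_t)
  expect_true("low_droplets" %in% res2$qc_flags[[1]])
})

test_that("measured bulk VCN scales with the dilution factor", {
  cfg <- default_cfg(wpre = 700, tert = 1500, seed = 13, n = 20000)
  factors <- c(1, 0.5, 0.25, 0.125, 0.0625)
  series <- simulate_dilution_series(cfg, factors)
  vcn <- vapply(series, function(w) {
    v <- attr(w, "droplet_volume_ul")
    wpre <- estimate_concentration(truth_negatives(w, "wpre"), nrow(w), v)
    tert <- estimate_concentration(truth_negatives(w, "tert"), nrow(w), v)
    compute_vcn_bulk(wpre, tert)$vcn_bulk
  }, numeric(1))
  fit <- lm(vcn ~ 0 + factors)
  expected_slope <- 2 * 700 / 1500
  expect_equal(unname(coef(fit)[1]), expected_slope, tolerance = 0.05)
})

test_that("replicate aggregation weights by accepted droplets", {
  # equal weights: hand arithmetic
  res <- aggregate_replicates(fake_results(c(1.9, 2.0, 2.1)))
  expect_equal(res$vcn_bulk, 2.0)
  expect_equal(res$sd, 0.1)
  expect_equal(res$cv_pct, 5.0)

  # identical replicates: no dispersion
  flat <- aggregate_replicates(fake_results(c(2, 2, 2)))
  expect_equal(flat$vcn_bulk, 2)
  expect_equal(flat$cv_pct, 0)

  # unequal weights pull the mean toward the larger well
  uneven <- dplyr::bind_rows(fake_results(1, n_accepted = 30000),
                             fake_results(4, n_accepted = 10000))
  expect_equal(aggregate_replicates(uneven)$vcn_bulk, 1.75)

  single <- aggregate_replicates(fake_results(2.2))
  expect_true(is.na(single$sd))
  expect_true("single_replicate" %in% single$qc_flags[[1]])

  mixed <- dplyr::bind_rows(fake_results(1, "A"), fake_results(2, "B"))
  expect_error(aggregate_replicates(mixed), class = "dropvcn_mixed_samples")
})

test_that("vcn_from_counts runs the whole well pipeline", {
  well <- simulate_well(default_cfg(wpre = 450, tert = 1500, seed = 21))
  res <- vcn_from_counts(classify_droplets(well))
  expect_s3_class(res, "vcn_result")
  expect_equal(res$vcn_bulk, 2 * 450 / 1500, tolerance = 0.06)
  expect_false(is.na(res$vcn_adj))
  expect_gte(res$vcn_adj, res$vcn_bulk)
})
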