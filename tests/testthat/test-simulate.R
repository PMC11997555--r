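test_that("zero target concentration yields only negative droplets", {
  well <- simulate_well(default_cfg(wpre = 0, tert = 1000, seed = 11))
  expect_true(all(well$k_wpre == 0L))
  # all FAM amplitudes from the negative Gaussian, far below the positive mean
  expect_true(all(well$fam_amplitude < 4500))
  expect_true(any(well$k_tert > 0L))
})

test_that("negative-droplet fraction follows the Poisson occupancy model", {
  v <- 0.00085
  # one average copy per droplet -> negative fraction exp(-1)
  for (seed in c(2, 17, 301)) {
    well <- simulate_well(default_cfg(wpre = 1 / v, tert = 0, seed = seed))
    p <- exp(-1)
    observed <- mean(well$k_wpre == 0L)
    se <- sqrt(p * (1 - p) / nrow(well))
    expect_lt(abs(observed - p), 3 * se)
  }
  # convergence check at larger n, wider band
  big <- simulate_well(default_cfg(wpre = 0.5 / v, tert = 0, seed = 5, n = 1e5))
  p <- exp(-0.5)
  expect_lt(abs(mean(big$k_wpre == 0L) - p), 4 * sqrt(p * (1 - p) / 1e5))
})

test_that("channel occupancies are independent: double-positive fraction is a product", {
  v <- 0.00085
  lam <- 0.8
  well <- simulate_well(default_cfg(wpre = lam / v, tert = lam / v,
                                    seed = 23, n = 1e5))
  p <- (1 - exp(-lam))^2
  observed <- mean(well$k_wpre >= 1L & well$k_tert >= 1L)
  expect_lt(abs(observed - p), 4 * sqrt(p * (1 - p) / 1e5))
})

test_that("same seed reproduces a well bit-identically", {
  cfg <- default_cfg(seed = 99, n = 2000, rain_fraction = 0.02)
  expect_identical(as.data.frame(simulate_well(cfg)),
                   as.data.frame(simulate_well(cfg)))
})

test_that("rain droplets land between the cluster means", {
  cfg <- default_cfg(wpre = 0, tert = 0, seed = 4, n = 5000,
                     rain_fraction = 0.3)
  well <- simulate_well(cfg)
  # negatives only outside rain; rain is uniform on (1000, 8000)
  n_high <- sum(well$fam_amplitude > 3000)
  expect_gt(n_high, 0.3 * 5000 * (5 / 7) * 0.8)
  expect_true(all(well$fam_amplitude < 8000 + 5 * 400))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(seed = 1, rain_fraction = 1), class = "dropvcn_error")
  expect_error(sim_config(seed = 1, wpre_conc = -2), class = "dropvcn_error")
  expect_error(sim_config(seed = 1, fam_pos_mean = 500), class = "dropvcn_error")
  expect_error(sim_config(), class = "dropvcn_error") # seed mandatory
})

test_that("dilution series scales the target and keeps the reference fixed", {
  cfg <- default_cfg(wpre = 800, tert = 1500, seed = 7, n = 5000)
  factors <- c(1, 0.5, 0.25, 0.125, 0.0625)
  series <- simulate_dilution_series(cfg, factors, sample_id = "CAR-1")
  expect_length(series, 5)
  expect_named(series, sprintf("DILN%d", 0:4))

  v <- cfg$droplet_volume_ul
  neg_frac <- vapply(series, function(w) mean(w$k_wpre == 0L), numeric(1))
  lam_hat <- -log(neg_frac)
  # true per-well rates halve stepwise; estimates track within sampling noise
  expect_equal(unname(lam_hat), 800 * factors * v, tolerance = 0.15)
  tert_neg <- vapply(series, function(w) mean(w$k_tert == 0L), numeric(1))
  expect_lt(diff(range(-log(tert_neg))), 0.2)

  # factor 1 is the identical configuration to simulate_well
  expect_identical(as.data.frame(series$DILN0),
                   as.data.frame(simulate_well(cfg, well_id = "DILN0",
                                               sample_id = "CAR-1")))

  expect_error(simulate_dilution_series(cfg, numeric(0)),
               class = "dropvcn_error")
  expect_error(simulate_dilution_series(cfg, c(0.5, 1.5)),
               class = "dropvcn_error")
})

test_that("simulated cell product matches its Poisson ground truth", {
  # degenerate rate: nothing transduced
  none <- simulate_cell_product(cell_product_config(1000, 0, seed = 1))
  expect_identical(none$n_transduced, 0L)
  expect_identical(none$wpre_total, 0L)
  expect_identical(none$tert_total, 2000)
  expect_true(is.na(none$mean_vcn_transduced))

  prod <- simulate_cell_product(cell_product_config(1e5, 2, seed = 42))
  p <- 1 - exp(-2)
  expect_lt(abs(prod$transduction_fraction - p),
            3 * sqrt(p * (1 - p) / 1e5))

  # template conservation
  expect_identical(prod$wpre_total, sum(prod$copies))

  # empirical means: all cells -> lambda, transduced cells -> zero-truncated mean
  expect_lt(abs(prod$mean_vcn_all - 2), 3 * sqrt(2 / 1e5))
  zt_mean <- 2 / (1 - exp(-2))
  zt_var <- (2 + 4) / (1 - exp(-2)) - zt_mean^2
  expect_lt(abs(prod$mean_vcn_transduced - zt_mean),
            3 * sqrt(zt_var / prod$n_transduced))
})

test_that("transduced-cell mean at lambda 0.57 approaches the adjusted VCN", {
  prod <- simulate_cell_product(cell_product_config(1e5, 0.57, seed = 8))
  lam <- 0.57
  zt_mean <- lam / (1 - exp(-lam))        # 1.31 at 2 decimals
  zt_var <- (lam + lam^2) / (1 - exp(-lam)) - zt_mean^2
  expect_lt(abs(prod$mean_vcn_transduced - zt_mean),
            3 * sqrt(zt_var / prod$n_transduced))
  expect_equal(round(zt_mean, 2), 1.31)
})

test_that("product concentrations preserve the template ratio", {
  prod <- simulate_cell_product(cell_product_config(1e4, 1.4, seed = 3))
  conc <- product_concentrations(prod, tert_copies_per_ul = 1200)
  expect_equal(conc$tert_conc, 1200)
  expect_equal(conc$wpre_conc / conc$tert_conc,
               prod$wpre_total / prod$tert_total)
})
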