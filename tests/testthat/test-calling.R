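# droplet-level brute-force oracle for the between-class-variance criterion:
# scan every midpoint between consecutive sorted values
otsu_oracle <- function(x) {
  xs <- sort(unique(x))
  cuts <- (head(xs, -1) + xs[-1]) / 2
  score <- vapply(cuts, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    length(lo) * length(hi) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  cuts[which.max(score)]
}

test_that("automatic thresholds fall between well-separated clusters", {
  set.seed(101)
  x <- c(rnorm(400, 1000, 400), rnorm(400, 8000, 400))
  for (method in c("otsu", "midpoint")) {
    thr <- set_threshold(x, method)
    expect_gt(thr, 2200)
    expect_lt(thr, 6800)
    expect_gte(thr, min(x))
    expect_lte(thr, max(x))
  }
})

test_that("otsu agrees with a droplet-level between-class-variance scan", {
  set.seed(7)
  x <- c(rnorm(150, 1000, 400), rnorm(150, 8000, 400))
  thr <- set_threshold(x, "otsu")
  oracle <- otsu_oracle(x)
  # both cuts must induce the same partition of the droplets
  expect_identical(x > thr, x > oracle)
})

test_that("midpoint threshold is the mean of the two group centers", {
  expect_equal(set_threshold(c(1000, 8000), "midpoint"), 4500)
  # exact two-means on a small asymmetric sample, checked by enumeration
  x <- c(1, 2, 3, 10, 11)
  expect_equal(set_threshold(x, "midpoint"), (2 + 10.5) / 2)
})

test_that("manual thresholding echoes its value and validates its use", {
  expect_equal(set_threshold(c(1, 2), "manual", manual_value = 3000), 3000)
  expect_error(set_threshold(c(1, 2), "manual"), class = "dropvcn_error")
  expect_error(set_threshold(c(1, 2), "otsu", manual_value = 3),
               class = "dropvcn_error")
})

test_that("degenerate amplitude input is rejected", {
  expect_error(set_threshold(rep(5, 10), "otsu"),
               class = "dropvcn_degenerate_input")
  expect_error(set_threshold(rep(5, 10), "midpoint"),
               class = "dropvcn_degenerate_input")
  expect_error(set_threshold(1500, "otsu"), class = "dropvcn_error")
})

test_that("classification partitions droplets into the four duplex clusters", {
  well <- droplet_well(c(5, 15, 25), c(25, 15, 5))
  counts <- classify_droplets(well, fam_threshold = 10, hex_threshold = 10)
  expect_equal(counts$n_fam_pos_hex_pos, 1L)
  expect_equal(counts$n_fam_pos_hex_neg, 1L)
  expect_equal(counts$n_fam_neg_hex_pos, 1L)
  expect_equal(counts$n_fam_neg_hex_neg, 0L)
  expect_equal(counts$n_total, 3L)

  # ties are called negative (strict inequality)
  tie <- classify_droplets(droplet_well(c(10, 10), c(10, 10)),
                           fam_threshold = 10, hex_threshold = 10)
  expect_equal(tie$n_fam_neg_hex_neg, 2L)
})

test_that("a no-template control shows only the double-negative cluster", {
  ntc <- simulate_well(default_cfg(wpre = 0, tert = 0, seed = 31, n = 5000),
                       is_blank = TRUE)
  counts <- classify_droplets(ntc, fam_threshold = 4500, hex_threshold = 4500)
  expect_equal(counts$n_fam_neg_hex_neg, counts$n_total)
})

test_that("a non-transduced sample shows no target-positive droplets", {
  nt <- simulate_well(default_cfg(wpre = 0, tert = 1200, seed = 32, n = 5000))
  counts <- classify_droplets(nt, fam_threshold = 4500, hex_threshold = 4500)
  expect_equal(counts$n_fam_pos_hex_pos + counts$n_fam_pos_hex_neg, 0L)
  expect_gt(counts$n_fam_neg_hex_pos, 0L)
})

test_that("cluster counts always partition the well", {
  for (seed in 1:5) {
    well <- simulate_well(default_cfg(wpre = 300 * seed, tert = 1500,
                                      seed = seed, n = 3000,
                                      rain_fraction = 0.05))
    counts <- classify_droplets(well)
    expect_equal(counts$n_fam_pos_hex_pos + counts$n_fam_pos_hex_neg +
                   counts$n_fam_neg_hex_pos + counts$n_fam_neg_hex_neg,
                 counts$n_total)
    expect_equal(counts$n_total, nrow(well))
  }
})

test_that("raising the FAM threshold never gains positive droplets", {
  well <- simulate_well(default_cfg(seed = 55, n = 3000, rain_fraction = 0.1))
  thresholds <- seq(500, 9000, by = 500)
  n_pos <- vapply(thresholds, function(t) {
    cc <- classify_droplets(well, fam_threshold = t, hex_threshold = 4500)
    cc$n_fam_pos_hex_pos + cc$n_fam_pos_hex_neg
  }, numeric(1))
  expect_true(all(diff(n_pos) <= 0))
})

test_that("calling recovers hidden occupancy labels on separated clusters", {
  well <- simulate_well(default_cfg(wpre = 600, tert = 1200, seed = 77,
                                    n = 20000, rain_fraction = 0))
  counts <- classify_droplets(well)
  fam_pos <- well$fam_amplitude > counts$fam_threshold
  hex_pos <- well$hex_amplitude > counts$hex_threshold
  err <- mean(fam_pos != (well$k_wpre >= 1L) | hex_pos != (well$k_tert >= 1L))
  expect_lt(err, 1e-3)
})

test_that("droplet_well validates its inputs", {
  expect_error(droplet_well(1:3, 1:2), class = "dropvcn_error")
  expect_error(droplet_well(numeric(0), numeric(0)), class = "dropvcn_empty_well")
  expect_error(droplet_well(c(1, NA), c(1, 2)), class = "dropvcn_error")
  expect_error(droplet_well(1:2, 1:2, dilution_factor = 1.5),
               class = "dropvcn_error")
})
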