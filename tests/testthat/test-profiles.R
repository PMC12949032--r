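# Profile analysis: extraction, peak/valley location, PVDR, 1-D gamma
# (with brute-force oracle) and profile scaling.

test_that("lateral extraction averages the central-x window on the grid spacing", {
  g <- analysis_grid(2)
  arr <- array(1, c(length(g$x), length(g$y), 1))
  m <- dose_map(arr, g)
  p <- extract_lateral(m, 2)
  expect_true(all(p$value == 1))                     # flat map, flat profile
  expect_equal(diff(p$position)[1], 0.1)             # grid y-spacing
  expect_equal(p$depth_cm, 2)
  expect_error(extract_lateral(m, 30), "depth")
})

test_that("PDD extraction normalizes to 100% and behaves at peak vs valley", {
  sf <- small_flash10()
  tot <- sf$sim$total
  pdd_pk <- extract_pdd(tot, "peak")
  pdd_vl <- extract_pdd(tot, "valley")
  expect_equal(max(pdd_pk$value), 100)
  expect_equal(pdd_pk$axis, "depth")
  # raw (unnormalized) dose: peak line dominates the valley line at
  # shallow depth, and the two converge by 12 cm
  raw_pk <- extract_pdd(tot, "peak", percent = FALSE)
  raw_vl <- extract_pdd(tot, "valley", percent = FALSE)
  i2 <- which.min(abs(raw_pk$position - 2))
  i12 <- which.min(abs(raw_pk$position - 12))
  expect_gt(raw_pk$value[i2], raw_vl$value[i2])
  expect_lt(raw_pk$value[i12] / raw_vl$value[i12], 1.3)
})

test_that("peak/valley location finds the comb structure and rejects flat profiles", {
  comb <- comb_profile()
  pos <- locate_peaks_valleys(comb)
  expect_equal(length(pos$peaks), 5)
  expect_equal(length(pos$valleys), 4)
  expect_true(all(abs(pos$peaks - c(-5.6, -2.8, 0, 2.8, 5.6)) <= 0.5 + 1e-9))
  # 1% multiplicative noise moves positions by < 0.2 mm
  set.seed(3)
  noisy <- comb
  noisy$value <- comb$value * (1 + stats::rnorm(length(comb$value), 0, 0.01))
  pos_n <- locate_peaks_valleys(noisy)
  expect_equal(length(pos_n$peaks), 5)
  expect_true(all(abs(sort(pos_n$peaks) - sort(pos$peaks)) <= 0.2 + 1e-9))
  # flat profile: no modulation
  flat <- mb_profile(seq(-10, 10, 0.1), rep(2, 201))
  expect_error(locate_peaks_valleys(flat), "modulation")
  # profile must span two pitches
  short <- mb_profile(seq(-2, 2, 0.1), stats::runif(41, 1, 2))
  expect_error(locate_peaks_valleys(short), "span")
})

test_that("PVDR of a comb is exact and invariant under scaling", {
  comb <- comb_profile(peak = 4, valley = 1)
  pos <- locate_peaks_valleys(comb)
  r <- compute_pvdr(comb, pos)
  expect_equal(r$pvdr, 4.0)
  expect_equal(r$uncertainty, 0)
  expect_equal(length(r$peaks), 3)                   # central-3 estimator
  # uniform profile through forced positions gives 1
  flat <- mb_profile(seq(-10, 10, 0.05), rep(2, 401))
  r_flat <- compute_pvdr(flat, list(peaks = c(-2.8, 0, 2.8),
                                    valleys = c(-1.4, 1.4)))
  expect_equal(r_flat$pvdr, 1.0)
  # scale invariance
  sc <- scale_profile(comb, factor = 7.3)$profile
  r_sc <- compute_pvdr(sc, locate_peaks_valleys(sc))
  expect_equal(r_sc$pvdr, r$pvdr)
  # zero valley: infinite-PVDR sentinel
  comb0 <- comb_profile(valley = 0)
  r0 <- compute_pvdr(comb0, list(peaks = c(-2.8, 0, 2.8),
                                 valleys = c(-1.4, 1.4)))
  expect_true(is.infinite(r0$pvdr))
})

test_that("gamma is zero for identical profiles and one at the dose criterion", {
  sf <- small_flash10()
  p <- extract_lateral(sf$sim$total, 2)
  g <- gamma_1d(p, p)
  expect_equal(g$pass_fraction, 1)
  expect_true(all(g$gamma == 0))
  # uniform profiles differing by exactly the 3% criterion
  x <- seq(-10, 10, 0.1)
  ref <- mb_profile(x, rep(100, length(x)))
  ev <- mb_profile(x, rep(97, length(x)))
  g2 <- gamma_1d(ref, ev, dose_crit_pct = 3, dta_mm = 0.3)
  expect_equal(max(abs(g2$gamma - 1)), 0, tolerance = 1e-9)
  # no overlap errors
  far <- mb_profile(x + 100, rep(1, length(x)))
  expect_error(gamma_1d(ref, far), "overlap")
})

test_that("gamma passes for shifts within DTA and matches the brute-force oracle", {
  x <- seq(-10, 10, 0.05)
  v <- 50 + 40 * sin(x) + 10 * cos(2.3 * x)
  ref <- mb_profile(x, v)
  shifted <- mb_profile(x, approx(x + 0.3, v, xout = x, rule = 2)$y)
  g <- gamma_1d(ref, shifted, dose_crit_pct = 3, dta_mm = 0.3)
  expect_true(all(g$gamma <= 1 + 1e-6))
  # oracle agreement on random smooth profile pairs
  set.seed(17)
  for (i in 1:20) {
    a <- 30 + 20 * stats::runif(1) * sin(stats::runif(1, 0.5, 2) * x) + 50
    b <- a * stats::runif(1, 0.95, 1.05) +
      5 * sin(stats::runif(1, 0.5, 3) * x + stats::runif(1, 0, 3))
    pa <- mb_profile(x, pmax(a, 0))
    pb <- mb_profile(x, pmax(b, 0))
    g1 <- gamma_1d(pa, pb)
    g2 <- gamma_oracle(pa, pb)
    expect_equal(g1$pass_fraction, g2$pass_fraction, tolerance = 0.02)
    expect_lt(max(abs(g1$gamma - g2$gamma)), 0.05)
  }
})

test_that("gamma restricts evaluation to the central overlap fraction", {
  x <- seq(0, 100, 0.5)
  ref <- mb_profile(x, rep(10, length(x)))
  ev <- mb_profile(x, rep(10, length(x)))
  g <- gamma_1d(ref, ev, central_fraction = 0.95)
  expect_equal(g$region[1], 2.5)
  expect_equal(g$region[2], 97.5)
  expect_lt(diff(range(g$position)), 95.1)
})

test_that("least-squares profile scaling recovers a known factor", {
  x <- seq(-5, 5, 0.1)
  base <- mb_profile(x, 10 + 5 * cos(x))
  target <- scale_profile(base, factor = 2.4)$profile
  fit <- scale_profile(base, reference = target)
  expect_equal(fit$factor, 2.4, tolerance = 1e-10)
  expect_equal(scale_profile(base, factor = 2)$profile$value,
               2 * base$value)
  expect_error(scale_profile(base), "factor")
})

test_that("profile CSVs round-trip", {
  p <- comb_profile()
  path <- tempfile(fileext = ".csv")
  write_profile_csv(p, path)
  q <- read_profile_csv(path)
  expect_equal(q$position, p$position)
  expect_equal(q$value, p$value)
  expect_equal(q$axis, "lateral")
})
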