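# Dose-rate metrics: cumulative curves, average rate, the PBS
# (Folkerts) rate against hand calculations and the brute-force oracle,
# masking, and threshold behavior.

test_that("cumulative curves conserve the total and build breakpoints", {
  tl <- toy_stack_log(doses = 10, starts = 0, ends = 2)
  cur <- build_cumulative_curves(tl$stack, tl$log)
  expect_equal(cur$t0, 0)
  expect_equal(cur$t1, 2)
  expect_equal(as.numeric(colSums(cur$M)), 10)
  # final cumulative equals the accumulated total at machine precision
  sf <- small_flash10()
  stack <- sf$sim$stack
  log <- schedule_delivery(stack$plan, scenario_beam(sf$cfg))
  nxy <- length(stack$grid$x) * length(stack$grid$y)
  vox <- seq_len(nxy)                      # 2 cm plane
  cur2 <- build_cumulative_curves(stack, log, voxels = vox)
  tot <- accumulate_total(stack)
  expect_equal(as.numeric(colSums(cur2$M)), as.numeric(tot$dose[vox]),
               tolerance = 1e-12)
  # mismatched plans are rejected
  log_bad <- log
  log_bad$records <- log$records[1:10, ]
  expect_error(build_cumulative_curves(stack, log_bad), "plan")
})

test_that("average dose rate is elementwise D / t_total", {
  g <- dose_grid(0, c(0, 1), 10)
  m <- dose_map(array(c(20, 0), c(1, 2, 1)), g)
  r <- average_dose_rate(m, 2.5)
  expect_equal(as.numeric(r$dose), c(8, 0))
  expect_equal(average_dose_rate(m, 1.25)$dose, 2 * r$dose)
  expect_error(average_dose_rate(m, 0), "t_total")
})

test_that("PBS rate matches hand calculations", {
  # constant rate: 10 Gy over 2 s, threshold 0.5 -> exactly D/T
  cur <- toy_curves(0, 2, matrix(10))
  r <- pbs_dose_rate(cur)
  expect_equal(r$rate, 5)
  expect_equal(r$t_cross0, 0.1)
  expect_equal(r$t_cross1, 1.9)
  # two bursts: 5 Gy on [0,1], 5 Gy on [9,10]
  cur2 <- toy_curves(c(0, 9), c(1, 10), matrix(c(5, 5), 2))
  r2 <- pbs_dose_rate(cur2)
  expect_equal(r2$rate, 9 / 9.8)
  expect_equal(r2$t_cross0, 0.1)
  expect_equal(r2$t_cross1, 9.9)
  # low-dose voxel masked, not zeroed
  cur3 <- toy_curves(0, 2, matrix(0.8))
  r3 <- pbs_dose_rate(cur3)
  expect_false(r3$valid)
  expect_true(is.na(r3$rate))
})

test_that("on the simulated field the PBS rate dominates the average rate", {
  sf <- small_flash10()
  stack <- sf$sim$stack
  log <- schedule_delivery(stack$plan, scenario_beam(sf$cfg))
  tot <- accumulate_total(stack)
  iz <- 1                                  # 2 cm plane
  nxy <- length(stack$grid$x) * length(stack$grid$y)
  k <- sf$cfg$cal_peak_dose / max(tot$dose[, , iz])
  cur <- build_cumulative_curves(stack, log, voxels = seq_len(nxy),
                                 scale = k)
  pbs <- pbs_dose_rate(cur)
  D <- pbs$total
  avg <- k * tot$dose[seq_len(nxy)] / log$t_total
  # high-dose voxels accumulate their dose in a window much shorter than
  # the whole field delivery, so their PBS rate exceeds the average rate
  idx <- pbs$valid & is.finite(pbs$rate) & D >= 0.5 * max(D)
  expect_gt(sum(idx), 500)
  expect_true(all(pbs$rate[idx] >= avg[idx]))
})

test_that("PBS rate agrees with the dense-resampling oracle on random cases", {
  set.seed(42)
  for (case in 1:20) {
    ns <- sample(2:10, 1)
    nv <- sample(5:40, 1)
    dur <- stats::runif(ns, 0.3, 1)
    gap <- stats::runif(ns, 0, 0.5)
    t1 <- cumsum(dur + gap)
    t0 <- t1 - dur
    M <- matrix(stats::rexp(ns * nv) * (stats::runif(ns * nv) < 0.6),
                ns, nv)
    # guarantee a healthy mix of valid and masked voxels
    M[, 1] <- 2
    cur <- toy_curves(t0, t1, M)
    cfg <- pbs_config(threshold = 0.5)
    a <- pbs_dose_rate(cur, cfg)
    b <- pbs_dose_rate_oracle(cur, cfg, dt = 1e-3)
    expect_identical(a$valid, b$valid)
    idx <- a$valid & is.finite(a$rate)
    expect_lt(max(abs(a$rate[idx] - b$rate[idx]) / b$rate[idx]), 1e-3)
  }
})

test_that("pulse-resolved curves refine spot-uniform curves with equal endpoints", {
  tl <- toy_stack_log(doses = c(4, 6), starts = c(0, 1), ends = c(0.5, 1.8))
  su <- build_cumulative_curves(tl$stack, tl$log,
                                pbs_config(fidelity = "spot-uniform"))
  pr <- build_cumulative_curves(tl$stack, tl$log,
                                pbs_config(fidelity = "pulse-resolved"))
  expect_gt(length(pr$t0), length(su$t0))
  expect_equal(sum(pr$M), sum(su$M), tolerance = 1e-12)
  expect_equal(min(pr$t0), min(su$t0))
  # constant-rate case: both fidelities give D/T
  r_su <- pbs_dose_rate(su)$rate
  r_pr <- pbs_dose_rate(pr)$rate
  expect_equal(r_su, r_pr, tolerance = 0.05)
})

test_that("threshold sweep: constant-rate voxels are threshold-independent", {
  cur <- toy_curves(0, 2, matrix(10))
  rates <- vapply(c(0.1, 0.25, 0.5, 1), function(th)
    pbs_dose_rate(cur, pbs_config(threshold = th))$rate, numeric(1))
  expect_equal(rates, rep(5, 4))
  # threshold 0: window spans first-to-last nonzero accrual
  cur2 <- toy_curves(c(0, 5, 9), c(1, 6, 10),
                     matrix(c(0, 5, 0, 0, 5, 0), 3, 2))
  r0 <- pbs_dose_rate(cur2, pbs_config(threshold = 0))
  expect_equal(r0$t_cross0, c(5, 5))
  expect_equal(r0$t_cross1, c(6, 6))
})

test_that("rate summaries obey max dominance and uniform-field equality", {
  g <- dose_grid(0, seq(-2, 2, 0.1), 20)
  n <- length(g$y)
  avg <- array(3, c(1, n, 1))
  pbs <- structure(list(rate = stats::runif(n, 5, 9),
                        valid = rep(TRUE, n),
                        voxels = seq_len(n), grid = g),
                   class = "pbs_rate_field")
  s <- summarize_rates(avg, pbs, g, 2, peaks = c(-1, 0, 1),
                       valleys = c(-0.5, 0.5), x_window_mm = 10)
  expect_equal(s$PDR, s$VDR)               # uniform average field
  expect_gte(s$MDR_PBS, s$PDR_PBS)
  expect_gte(s$MDR_PBS, s$VDR_PBS)
})
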