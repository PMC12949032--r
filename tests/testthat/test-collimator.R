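# Collimator transport: phase-space sampling, MC slit/septum transport,
# perfect-absorber limit and the analytic Gaussian-slit oracle.

uhdr_beam <- function() beam_spec(228, 5.6, 5.6, 298, 970, 125)

test_that("sampled spot phase space matches the projection geometry", {
  spec <- uhdr_beam()
  d <- 15
  b <- sample_spot_phase_space(spec, c(0, 0), 1e5, seed = 11,
                               distance_upstream_of_iso = d)
  expect_equal(stats::sd(b$y), spot_sigma_at_plane(spec, "y", d),
               tolerance = 0.01)
  expect_equal(stats::sd(b$x), spot_sigma_at_plane(spec, "x", d),
               tolerance = 0.01)
  # off-axis spot center projects by (SAD - d)/SAD
  b2 <- sample_spot_phase_space(spec, c(15, 0), 2e4, seed = 12,
                                distance_upstream_of_iso = d)
  expect_equal(mean(b2$x), 15 * (298 - d) / 298, tolerance = 0.02)
  # determinism under fixed seed
  b3 <- sample_spot_phase_space(spec, c(0, 0), 1000, seed = 5,
                                distance_upstream_of_iso = d)
  b4 <- sample_spot_phase_space(spec, c(0, 0), 1000, seed = 5,
                                distance_upstream_of_iso = d)
  expect_identical(b3$y, b4$y)
  expect_error(sample_spot_phase_space(spec, c(0, 0), 10, 1,
                                       distance_upstream_of_iso = 400),
               "SAD")
})

test_that("axial protons pass slit centers untouched and stop in septa", {
  col <- collimator_spec(thickness = 6.5)
  mk <- function(y) phase_space_batch(0, y, 0, 0, 1, 228,
                                      plane = -(6.5 + 5) * 10)
  # slit center: unchanged direction and energy
  thru <- transport_msc(mk(0), col, seed = 1)
  expect_equal(n_particles(thru), 1)
  expect_equal(thru$energy, 228)
  expect_equal(thru$uy, 0)
  # septum center: terminated (brass range << 6.5 cm)
  blocked <- transport_msc(mk(1.4), col, seed = 1)
  expect_equal(n_particles(blocked), 0)
  expect_error(transport_msc(mk(0), col, step = 0), "step")
  expect_error(transport_msc(mk(0), col, step = 10), "step")
})

test_that("transport conserves counts/weights and never gains energy", {
  spec <- uhdr_beam()
  col <- collimator_spec(thickness = 10)
  b <- sample_spot_phase_space(spec, c(0, 0), 2e4, seed = 3,
                               distance_upstream_of_iso = 15)
  ex <- transport_msc(b, col, seed = 4)
  expect_lte(n_particles(ex), n_particles(b))
  expect_true(all(ex$weight == 1))
  expect_true(all(ex$energy <= 228 + 1e-9))
  expect_identical(attr(ex, "n_incident"), n_particles(b))
  # determinism
  ex2 <- transport_msc(b, col, seed = 4)
  expect_identical(ex$y, ex2$y)
})

test_that("perfect-absorber transmission matches the ray-trace open fraction", {
  col <- collimator_spec(thickness = 10)
  set.seed(99)
  n <- 2e5
  # broad parallel beam covering exactly one central period
  y <- stats::runif(n, -1.4, 1.4)
  b <- phase_space_batch(rep(0, n), y, rep(0, n), rep(0, n), rep(1, n),
                         rep(228, n), plane = -150)
  ex <- transport_msc(b, col, seed = 1, perfect_absorber = TRUE)
  p_hat <- n_particles(ex) / n
  p <- 1.0 / 2.8
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("exit fluence is modulated at the slit pitch, more deeply for the thicker collimator", {
  spec <- uhdr_beam()
  run <- function(thickness) {
    col <- collimator_spec(thickness = thickness)
    b <- sample_spot_phase_space(spec, c(0, 0), 6e4, seed = 21,
                                 distance_upstream_of_iso =
                                   col$exit_to_surface_gap + col$thickness)
    transport_msc(b, col, seed = 22)
  }
  prof <- function(ex) {
    h <- hist(ex$y[abs(ex$y) < 7], breaks = seq(-7, 7, 0.1), plot = FALSE)
    h
  }
  ex10 <- run(10); ex65 <- run(6.5)
  h10 <- prof(ex10)
  # peaks of the exit fluence sit at the slit positions (pitch 2.8 mm)
  pk_bins <- h10$mids[h10$counts > 0.5 * max(h10$counts)]
  centers <- c(-5.6, -2.8, 0, 2.8, 5.6)
  expect_true(all(vapply(pk_bins, function(p) min(abs(p - centers)) < 0.6,
                         logical(1))))
  # valley-to-peak fluence ratio: 10 cm collimator is cleaner
  vp <- function(h) {
    pk <- mean(h$counts[abs(h$mids) < 0.3])
    vl <- mean(h$counts[abs(abs(h$mids) - 1.4) < 0.3])
    vl / pk
  }
  expect_lt(vp(prof(ex10)), vp(prof(ex65)))
})

test_that("analytic Gaussian-slit transmission matches the error-function form", {
  r <- analytic_slit_fluence(5.6, c(-0.5, 0.5))
  expect_equal(r$fraction, stats::pnorm(0.5 / 5.6) - stats::pnorm(-0.5 / 5.6))
  expect_equal(r$fraction, 0.0712, tolerance = 1e-3)
  expect_equal(analytic_slit_fluence(3, c(-Inf, Inf))$fraction, 1)
  # symmetric slit gives a symmetric profile
  y <- seq(-0.45, 0.45, by = 0.05)
  expect_equal(r$profile(y), rev(r$profile(-y)))
  expect_equal(r$profile(0.8), 0)  # outside the slit
})
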