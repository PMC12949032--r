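# Shared fixtures, memoized per test run so expensive simulations are
# built once and reused across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# reduced-scale flash-10 simulation for unit tests (not acceptance)
small_flash10 <- function() {
  memo("small_flash10", {
    cfg <- make_scenario("flash-10",
                         list(n_histories = 8000,
                              grid = list(depths_cm = c(2, 4, 6, 12))))
    sim <- run_simulate(cfg)
    list(cfg = cfg, sim = sim)
  })
}

# hand-built cumulative-curves object from explicit intervals and doses;
# M is (intervals x voxels)
toy_curves <- function(t0, t1, M, t_total = max(t1)) {
  structure(list(t0 = t0, t1 = t1, M = M, voxels = seq_len(ncol(M)),
                 grid = NULL, t_total = t_total),
            class = "cumulative_curves")
}

# single-spot stack + matching log for simple dose-rate cases
toy_stack_log <- function(doses, starts, ends) {
  ns <- length(doses)
  grid <- dose_grid(0, 0, 10)
  plan <- structure(list(spots = data.frame(spot = seq_len(ns),
                                            x = seq_len(ns), y = 0, mu = 1),
                         pattern = "A",
                         field = list(n_side = ns)),
                    class = "spot_plan")
  maps <- lapply(doses, function(d) array(d, c(1, 1, 1)))
  stack <- spot_dose_stack(maps, grid, plan)
  log <- structure(
    list(records = data.frame(spot_index = seq_len(ns), x_mm = seq_len(ns),
                              y_mm = 0, mu = 1, t_start_s = starts,
                              t_end_s = ends, charge_nC = 1),
         t_total = max(ends) - min(starts),
         pulse_rate = 1000, pulse_width = 10e-6),
    class = "delivery_log")
  list(stack = stack, log = log)
}

# brute-force 1-D gamma oracle: dense resampling of the evaluated curve
# and direct minimum search
gamma_oracle <- function(reference, evaluated, dose_crit_pct = 3,
                         dta_mm = 0.3, central_fraction = 0.95,
                         step = 0.005) {
  lo <- max(min(reference$position), min(evaluated$position))
  hi <- min(max(reference$position), max(evaluated$position))
  trim <- (hi - lo) * (1 - central_fraction) / 2
  keep <- reference$position >= lo + trim & reference$position <= hi - trim
  rp <- reference$position[keep]; rv <- reference$value[keep]
  dcrit <- dose_crit_pct / 100 * max(reference$value)
  xs <- seq(min(evaluated$position), max(evaluated$position), by = step)
  vs <- approx(evaluated$position, evaluated$value, xout = xs)$y
  g <- vapply(seq_along(rp), function(i) {
    sqrt(min(((xs - rp[i]) / dta_mm)^2 + ((vs - rv[i]) / dcrit)^2))
  }, numeric(1))
  list(gamma = g, pass_fraction = mean(g <= 1))
}

# synthetic minibeam comb profile: n_teeth rectangular teeth of the given
# width/period, peak value `peak`, baseline `valley`
comb_profile <- function(period = 2.8, width = 1, n_teeth = 5,
                         peak = 4, valley = 1, spacing = 0.05,
                         half_extent = 10) {
  y <- seq(-half_extent, half_extent, by = spacing)
  centers <- (seq_len(n_teeth) - (n_teeth + 1) / 2) * period
  v <- rep(valley, length(y))
  for (ct in centers) v[abs(y - ct) <= width / 2] <- peak
  mb_profile(y, v, axis = "lateral", depth_cm = 2)
}
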