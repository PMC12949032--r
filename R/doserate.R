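# Dose-rate metrics: field-average dose rate (total dose over total
# irradiation time) and the Folkerts PBS dose rate
# (D - 2*Dth) / (t1 - t0), with t0/t1 the threshold-crossing times of the
# per-voxel cumulative dose curve, plus a dense-resampling brute-force
# oracle and per-depth summary tables.

#' PBS dose-rate configuration
#'
#' @param threshold threshold dose D^th, Gy (>= 0; default 0.5).
#' @param fidelity temporal fidelity of the cumulative curves:
#'   `"spot-uniform"` (dose accrues linearly across each spot interval) or
#'   `"pulse-resolved"` (per-pulse steps).
#' @return An object of class `pbs_config`.
#' @export
pbs_config <- function(threshold = 0.5,
                       fidelity = c("spot-uniform", "pulse-resolved")) {
  if (threshold < 0) stop("threshold must be >= 0")
  structure(list(threshold = threshold, fidelity = match.arg(fidelity)),
            class = "pbs_config")
}

#' Build per-voxel cumulative dose curves
#'
#' Pairs the per-spot dose maps with the delivery-log intervals. Within
#' each interval dose accrues linearly; with pulse-resolved fidelity each
#' spot is subdivided into its pulse intervals (equal endpoints, refined
#' interior). The final cumulative dose equals the accumulated total at
#' every voxel exactly.
#'
#' @param stack a [spot_dose_stack()].
#' @param log the matching [schedule_delivery()] log (same plan order).
#' @param cfg a [pbs_config()].
#' @param voxels optional integer subset of voxel indices (column-major
#'   over the grid) to restrict the curves to.
#' @param scale multiplicative dose calibration factor applied to the
#'   per-spot maps (e.g. from [calibrate_dose()]).
#' @return An object of class `cumulative_curves`: interval times `t0`,
#'   `t1`, per-interval dose matrix `M` (intervals x voxels), voxel
#'   indices and grid.
#' @export
build_cumulative_curves <- function(stack, log, cfg = pbs_config(),
                                    voxels = NULL, scale = 1) {
  rec <- log$records
  if (nrow(rec) != length(stack$maps))
    stop("delivery log and stack refer to different plans")
  if (!all(rec$spot_index == stack$plan$spots$spot))
    stop("delivery log and stack refer to different plans")
  nvox_all <- length(stack$maps[[1]])
  if (is.null(voxels)) voxels <- seq_len(nvox_all)
  ns <- nrow(rec)
  mu <- stack$plan$spots$mu
  if (cfg$fidelity == "spot-uniform") {
    t0 <- rec$t_start_s; t1 <- rec$t_end_s
    M <- matrix(0, ns, length(voxels))
    for (k in seq_len(ns)) M[k, ] <- scale * mu[k] * stack$maps[[k]][voxels]
  } else {
    pul <- expand_pulses(log)
    if (as.double(nrow(pul)) * length(voxels) > 5e7)
      stop("pulse-resolved curves too large; restrict `voxels`")
    t0 <- pul$t_start_s
    t1 <- pul$t_start_s + pul$width_s
    M <- matrix(0, nrow(pul), length(voxels))
    for (k in seq_len(ns)) {
      rows <- which(pul$spot_index == rec$spot_index[k])
      frac <- pul$charge_nC[rows] / sum(pul$charge_nC[rows])
      M[rows, ] <- frac %o% (scale * mu[k] * stack$maps[[k]][voxels])
    }
  }
  structure(list(t0 = t0, t1 = t1, M = M, voxels = voxels,
                 grid = stack$grid, t_total = log$t_total),
            class = "cumulative_curves")
}

#' @export
print.cumulative_curves <- function(x, ...) {
  cat(sprintf("<cumulative_curves> %d intervals x %d voxels, t_total %.4g s\n",
              length(x$t0), ncol(x$M), x$t_total))
  invisible(x)
}

#' Field-average dose rate
#'
#' Elementwise `D(x) / t_total`: the ratio of the total dose at a point
#' to the total irradiation time.
#'
#' @param total a [dose_map()] (or numeric array) of total dose.
#' @param t_total total irradiation time, s (> 0).
#' @return object of the same shape with dose-rate values.
#' @export
average_dose_rate <- function(total, t_total) {
  if (t_total <= 0) stop("t_total must be > 0")
  if (inherits(total, "dose_map"))
    dose_map(total$dose / t_total, total$grid)
  else total / t_total
}

# first time each voxel's cumulative curve reaches `target` (vector per
# voxel), by linear interpolation within the crossing interval.
crossing_times <- function(curves, target) {
  cum <- apply(curves$M, 2, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
  n_int <- nrow(cum)
  tgt <- matrix(target, n_int, length(target), byrow = TRUE)
  k <- 1L + colSums(cum < tgt)
  k <- pmin(k, n_int)
  j <- seq_along(target)
  # zero (or negative) target: crossing is the start of the first
  # interval with nonzero accrual
  zt <- target <= 0
  if (any(zt)) {
    kpos <- max.col(t(curves$M > 0), ties.method = "first")
    k[zt] <- kpos[zt]
  }
  prev <- numeric(length(k))
  gt1 <- k > 1
  prev[gt1] <- cum[cbind(k[gt1] - 1, j[gt1])]
  dk <- curves$M[cbind(k, j)]
  f <- ifelse(dk > 0, (target - prev) / dk, 0)
  f <- pmin(pmax(f, 0), 1)
  curves$t0[k] + f * (curves$t1[k] - curves$t0[k])
}

#' PBS (Folkerts) dose rate
#'
#' Per voxel i with total dose `D_i`: `t0` is the first time the
#' cumulative dose reaches `D^th`, `t1` the first time it reaches
#' `D_i - D^th`, and the PBS rate is `(D_i - 2 D^th) / (t1 - t0)`.
#' Voxels with `D_i <= 2 D^th` are masked invalid rather than given a
#' rate. A zero-length window with positive numerator yields `Inf` (an
#' explicit infinite-rate sentinel).
#'
#' @param curves a [build_cumulative_curves()] object.
#' @param cfg a [pbs_config()].
#' @return An object of class `pbs_rate_field`: `rate` (NA where
#'   invalid), `valid` mask, `t_cross0`, `t_cross1`, `total`, `voxels`,
#'   `grid`.
#' @export
pbs_dose_rate <- function(curves, cfg = pbs_config()) {
  D <- colSums(curves$M)
  th <- cfg$threshold
  valid <- D > 2 * th
  rate <- rep(NA_real_, length(D))
  t0x <- rep(NA_real_, length(D)); t1x <- t0x
  if (any(valid)) {
    sub <- curves
    sub$M <- curves$M[, valid, drop = FALSE]
    ta <- crossing_times(sub, pmin(rep(th, sum(valid)), D[valid]))
    tb <- crossing_times(sub, D[valid] - th)
    num <- D[valid] - 2 * th
    den <- tb - ta
    r <- ifelse(den > 0, num / den, Inf)
    rate[valid] <- r
    t0x[valid] <- ta; t1x[valid] <- tb
  }
  structure(list(rate = rate, valid = valid, t_cross0 = t0x, t_cross1 = t1x,
                 total = D, voxels = curves$voxels, grid = curves$grid),
            class = "pbs_rate_field")
}

#' @export
print.pbs_rate_field <- function(x, ...) {
  cat(sprintf("<pbs_rate_field> %d voxels, %d valid (%.1f%%), max %.4g Gy/s\n",
              length(x$rate), sum(x$valid), 100 * mean(x$valid),
              suppressWarnings(max(x$rate[x$valid], 0))))
  invisible(x)
}

#' Brute-force PBS dose-rate oracle
#'
#' Independent check of [pbs_dose_rate()]: resamples every voxel's
#' cumulative curve on a dense uniform time grid and finds the threshold
#' crossings by direct search (no interpolation logic shared with the
#' main implementation).
#'
#' @param curves a [build_cumulative_curves()] object.
#' @param cfg a [pbs_config()].
#' @param dt resampling step, s.
#' @return list with `rate` and `valid`, aligned with [pbs_dose_rate()].
#' @export
pbs_dose_rate_oracle <- function(curves, cfg = pbs_config(), dt = 1e-3) {
  D <- colSums(curves$M)
  th <- cfg$threshold
  valid <- D > 2 * th
  tg <- seq(min(curves$t0), max(curves$t1) + dt, by = dt)
  rate <- rep(NA_real_, length(D))
  for (v in which(valid)) {
    # cumulative value at each grid time, built segment by segment
    cumv <- numeric(length(tg))
    base <- 0
    for (k in seq_along(curves$t0)) {
      a <- curves$t0[k]; b <- curves$t1[k]; d <- curves$M[k, v]
      if (b > a) {
        seg <- pmin(pmax((tg - a) / (b - a), 0), 1)
        cumv <- cumv + d * seg
      } else {
        cumv <- cumv + d * (tg >= a)
      }
      base <- base + d
    }
    cross <- function(target) {
      i <- which(cumv >= target)[1]
      if (is.na(i) || i == 1) return(tg[1])
      # local linear interpolation between the bracketing samples
      tg[i - 1] + (target - cumv[i - 1]) / (cumv[i] - cumv[i - 1]) * dt
    }
    den <- cross(D[v] - th) - cross(th)
    rate[v] <- if (den > 0) (D[v] - 2 * th) / den else Inf
  }
  list(rate = rate, valid = valid)
}

#' Summarize dose-rate fields at peak/valley positions
#'
#' Samples the average-rate and PBS-rate fields at the minibeam peak and
#' valley positions of a depth plane: PDR/VDR from the average-rate
#' field, PDR_PBS/VDR_PBS from the PBS field, and MDR_PBS as the maximum
#' of the valid PBS field on that plane.
#'
#' @param avg_rate a [dose_map()]-shaped array of average dose rate.
#' @param pbs a [pbs_rate_field()] covering the plane.
#' @param grid the [dose_grid()].
#' @param depth_cm depth of the plane, cm.
#' @param peaks,valleys peak and valley y-positions, mm (from
#'   [locate_peaks_valleys()]).
#' @param window_mm half-window around each position, mm.
#' @param x_window_mm central-x averaging window (full width), mm.
#' @return named list: `PDR`, `VDR`, `PDR_PBS`, `VDR_PBS`, `MDR_PBS`.
#' @export
summarize_rates <- function(avg_rate, pbs, grid, depth_cm, peaks, valleys,
                            window_mm = 0.2, x_window_mm = 20) {
  if (inherits(avg_rate, "dose_map")) avg_rate <- avg_rate$dose
  iz <- which.min(abs(grid$z - depth_cm * 10))
  xs <- abs(grid$x) <= x_window_mm / 2
  nx <- length(grid$x); ny <- length(grid$y)
  sample_mean <- function(field_plane, pos) {
    mean(vapply(pos, function(p) {
      ys <- abs(grid$y - p) <= window_mm
      mean(field_plane[xs, ys, drop = FALSE], na.rm = TRUE)
    }, numeric(1)))
  }
  avg_plane <- matrix(avg_rate[, , iz], nx, ny)
  # PBS field reshaped onto the grid (NA outside the valid mask)
  pbs_full <- rep(NA_real_, nx * ny * length(grid$z))
  pbs_full[pbs$voxels] <- pbs$rate
  pbs_plane <- matrix(array(pbs_full, c(nx, ny, length(grid$z)))[, , iz],
                      nx, ny)
  if (all(is.na(pbs_plane))) stop("no valid PBS voxels at this depth")
  list(PDR = sample_mean(avg_plane, peaks),
       VDR = sample_mean(avg_plane, valleys),
       PDR_PBS = sample_mean(pbs_plane, peaks),
       VDR_PBS = sample_mean(pbs_plane, valleys),
       MDR_PBS = max(pbs_plane[is.finite(pbs_plane)], na.rm = TRUE))
}

#' PBS dose-rate sensitivity to the threshold dose
#'
#' Recomputes the PBS field for each threshold and summarizes it at the
#' given peak/valley positions; used to verify that the metric is not
#' strongly threshold-dependent.
#'
#' @param curves a [build_cumulative_curves()] object.
#' @param thresholds numeric vector of D^th values, Gy.
#' @inheritParams summarize_rates
#' @return data.frame with one row per threshold: `threshold`,
#'   `PDR_PBS`, `VDR_PBS`, `MDR_PBS`.
#' @export
threshold_sweep <- function(curves, thresholds, grid, depth_cm,
                            peaks, valleys, window_mm = 0.2,
                            x_window_mm = 20) {
  rows <- lapply(thresholds, function(th) {
    pbs <- pbs_dose_rate(curves, pbs_config(threshold = th))
    avg_dummy <- array(0, c(length(grid$x), length(grid$y), length(grid$z)))
    s <- summarize_rates(avg_dummy, pbs, grid, depth_cm, peaks, valleys,
                         window_mm, x_window_mm)
    data.frame(threshold = th, PDR_PBS = s$PDR_PBS, VDR_PBS = s$VDR_PBS,
               MDR_PBS = s$MDR_PBS)
  })
  do.call(rbind, rows)
}
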