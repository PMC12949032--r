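# Profile analysis: lateral and depth-dose extraction, minibeam
# peak/valley location, PVDR with uncertainty, 1-D gamma comparison on
# the central overlap, and cross-beam profile scaling.

#' 1-D dose profile
#'
#' @param position strictly increasing positions: mm (lateral) or cm
#'   (depth).
#' @param value nonnegative dose values.
#' @param axis `"lateral"` or `"depth"`.
#' @param depth_cm extraction depth for lateral profiles, cm.
#' @param provenance `"simulated"` or `"synthetic-film"`.
#' @return An object of class `mb_profile`.
#' @export
mb_profile <- function(position, value, axis = c("lateral", "depth"),
                       depth_cm = NA_real_, provenance = "simulated") {
  axis <- match.arg(axis)
  if (length(position) != length(value)) stop("position/value length mismatch")
  if (any(diff(position) <= 0)) stop("positions must be strictly increasing")
  if (any(value < 0)) stop("dose values must be >= 0")
  structure(list(position = position, value = value, axis = axis,
                 depth_cm = depth_cm, provenance = provenance),
            class = "mb_profile")
}

#' @export
print.mb_profile <- function(x, ...) {
  cat(sprintf("<mb_profile> %s, %d points on [%g, %g]%s (%s)\n",
              x$axis, length(x$position), min(x$position), max(x$position),
              if (x$axis == "lateral") sprintf(", depth %g cm", x$depth_cm)
              else "", x$provenance))
  invisible(x)
}

#' Extract a lateral (y) profile at depth
#'
#' Dose versus y at the grid plane nearest the requested depth, averaged
#' over a central window in x.
#'
#' @param map a [dose_map()].
#' @param depth_cm extraction depth, cm (within the grid).
#' @param x_window_mm full width of the central-x averaging window, mm.
#' @return an [mb_profile()] with 0.1 mm spacing inherited from the grid.
#' @export
extract_lateral <- function(map, depth_cm, x_window_mm = 20) {
  g <- map$grid
  if (depth_cm * 10 < min(g$z) - 5 || depth_cm * 10 > max(g$z) + 5)
    stop("depth outside the scored grid")
  iz <- which.min(abs(g$z - depth_cm * 10))
  xs <- abs(g$x) <= x_window_mm / 2
  vals <- colMeans(map$dose[xs, , iz, drop = FALSE][, , 1, drop = TRUE])
  mb_profile(g$y, vals, axis = "lateral", depth_cm = g$z[iz] / 10)
}

#' Extract a depth-dose (PDD) profile
#'
#' Dose versus depth along a fixed y-line (a named peak/valley position
#' or an explicit y in mm), averaged over a central window in x;
#' optionally normalized to its own maximum (percent depth dose).
#'
#' @param map a [dose_map()] (needs more than one z plane).
#' @param at `"peak"`, `"valley"`, or an explicit y position, mm. The
#'   named positions are the central slit center (y = 0) and the first
#'   mid-septum line (y = pitch/2).
#' @param pitch_mm slit pitch used for the named positions, mm.
#' @param x_window_mm central-x averaging window, mm.
#' @param percent normalize so the maximum is 100.
#' @param y_window_mm half-window around the y-line, mm.
#' @return an [mb_profile()] along depth (cm).
#' @export
extract_pdd <- function(map, at = "peak", pitch_mm = 2.8, x_window_mm = 20,
                        percent = TRUE, y_window_mm = 0.2) {
  g <- map$grid
  y0 <- if (is.character(at)) {
    switch(match.arg(at, c("peak", "valley")), peak = 0, valley = pitch_mm / 2)
  } else as.numeric(at)
  xs <- abs(g$x) <= x_window_mm / 2
  ys <- abs(g$y - y0) <= y_window_mm
  vals <- vapply(seq_along(g$z),
                 function(iz) mean(map$dose[xs, ys, iz]), numeric(1))
  if (percent && max(vals) > 0) vals <- 100 * vals / max(vals)
  mb_profile(g$z / 10, vals, axis = "depth")
}

#' Locate minibeam peaks and valleys in a lateral profile
#'
#' Peaks are local maxima within half a (projected) pitch of the
#' projected slit centers; valleys are the minima between adjacent
#' peaks. A profile with modulation below 5% (max/min < 1.05) raises a
#' "no modulation" error.
#'
#' @param profile a lateral [mb_profile()].
#' @param pitch_mm slit center-to-center pitch, mm.
#' @param n_slits number of slits.
#' @param magnification projected-pitch magnification at the extraction
#'   plane (virtual-source geometry); 1 = unprojected.
#' @return list with `peaks` and `valleys` (positions, mm) and the
#'   corresponding `peak_values`, `valley_values`.
#' @export
locate_peaks_valleys <- function(profile, pitch_mm = 2.8, n_slits = 5,
                                 magnification = 1) {
  p <- profile$position; v <- profile$value
  span <- 2 * pitch_mm * magnification
  if (max(p) - min(p) < span) stop("profile must span at least 2 pitches")
  core <- v[p >= -span & p <= span]
  if (max(core) / max(min(core), .Machine$double.eps) < 1.05)
    stop("no modulation: profile is flat (max/min < 1.05)")
  centers <- (seq_len(n_slits) - (n_slits + 1) / 2) * pitch_mm * magnification
  # dose-weighted centroid of the upper (peaks) / lower (valleys) 20% band
  # of the window: robust against flat tops and sampling noise
  centroid <- function(w, top = TRUE) {
    vmax <- max(v[w]); vmin <- min(v[w])
    sel <- if (top) w[v[w] >= vmin + 0.8 * (vmax - vmin)]
           else w[v[w] <= vmin + 0.2 * (vmax - vmin)]
    pos <- sum(p[sel] * v[sel]) / sum(v[sel])
    if (!is.finite(pos)) pos <- mean(p[sel])
    i <- sel[which.min(abs(p[sel] - pos))]
    c(pos = pos, val = v[i])
  }
  peaks <- numeric(0); pv <- numeric(0)
  for (ct in centers) {
    w <- which(abs(p - ct) <= 0.5 * pitch_mm * magnification)
    if (length(w) == 0) next
    r <- centroid(w, top = TRUE)
    peaks <- c(peaks, r["pos"]); pv <- c(pv, r["val"])
  }
  valleys <- numeric(0); vv <- numeric(0)
  if (length(peaks) >= 2) {
    for (i in seq_len(length(peaks) - 1)) {
      w <- which(p > peaks[i] & p < peaks[i + 1])
      r <- centroid(w, top = FALSE)
      valleys <- c(valleys, r["pos"]); vv <- c(vv, r["val"])
    }
  }
  list(peaks = unname(peaks), peak_values = unname(pv),
       valleys = unname(valleys), valley_values = unname(vv))
}

#' Peak-to-valley dose ratio
#'
#' PVDR = mean dose in windows around the central peaks divided by the
#' mean dose in the windows around their adjacent valleys. By default
#' the central 3 peaks and their adjacent valleys are used, each with a
#' +/- 0.2 mm averaging window; the uncertainty is propagated from the
#' per-window standard deviations of the window samples.
#'
#' @param profile a lateral [mb_profile()].
#' @param positions output of [locate_peaks_valleys()].
#' @param window_mm half-width of the averaging window, mm.
#' @param n_central_peaks number of central peaks to use.
#' @return An object of class `pvdr_result`: `pvdr`, `uncertainty`,
#'   `peaks`, `peak_doses`, `valleys`, `valley_doses`, `depth_cm`.
#' @export
compute_pvdr <- function(profile, positions, window_mm = 0.2,
                         n_central_peaks = 3) {
  pk <- positions$peaks; vl <- positions$valleys
  if (length(pk) < 1 || length(vl) < 1)
    stop("need at least one peak and one valley")
  use_pk <- pk[order(abs(pk))][seq_len(min(n_central_peaks, length(pk)))]
  use_pk <- sort(use_pk)
  # valleys adjacent to any used peak (within one inter-peak spacing)
  spacing <- if (length(pk) >= 2) stats::median(diff(sort(pk))) else Inf
  use_vl <- vl[vapply(vl, function(y) min(abs(y - use_pk)) <= spacing,
                      logical(1))]
  if (length(use_vl) == 0) use_vl <- vl
  win <- function(pos) {
    i <- abs(profile$position - pos) <= window_mm
    profile$value[i]
  }
  pk_s <- lapply(use_pk, win); vl_s <- lapply(use_vl, win)
  mp <- mean(vapply(pk_s, mean, numeric(1)))
  mv <- mean(vapply(vl_s, mean, numeric(1)))
  if (mv == 0) {
    pvdr <- Inf; unc <- NA_real_
  } else {
    pvdr <- mp / mv
    rel2 <- function(s) {
      allv <- unlist(s)
      (stats::sd(allv) / sqrt(length(allv)))^2
    }
    unc <- pvdr * sqrt(rel2(pk_s) / mp^2 + rel2(vl_s) / mv^2)
  }
  structure(list(pvdr = pvdr, uncertainty = unc,
                 peaks = use_pk, peak_doses = vapply(pk_s, mean, numeric(1)),
                 valleys = use_vl,
                 valley_doses = vapply(vl_s, mean, numeric(1)),
                 depth_cm = profile$depth_cm),
            class = "pvdr_result")
}

#' @export
print.pvdr_result <- function(x, ...) {
  cat(sprintf("<pvdr_result> PVDR = %.3f +/- %.3f at %g cm (%d peaks, %d valleys)\n",
              x$pvdr, x$uncertainty, x$depth_cm, length(x$peaks),
              length(x$valleys)))
  invisible(x)
}

# squared distance from point (px, pv) to segment (x1,v1)-(x2,v2) in
# already-normalized gamma coordinates; vectorized over segments
.seg_dist2 <- function(px, pv, x1, v1, x2, v2) {
  dx <- x2 - x1; dv <- v2 - v1
  len2 <- dx^2 + dv^2
  t <- ifelse(len2 > 0, ((px - x1) * dx + (pv - v1) * dv) / len2, 0)
  t <- pmin(pmax(t, 0), 1)
  (x1 + t * dx - px)^2 + (v1 + t * dv - pv)^2
}

#' 1-D gamma comparison of two profiles
#'
#' Standard gamma index: for each reference point,
#' `gamma = min sqrt((dx/dta)^2 + (dD/dose_crit)^2)` over the evaluated
#' curve (treated as piecewise linear, minimized exactly per segment).
#' The dose criterion is global: a percentage of the reference maximum.
#' Evaluation is restricted to the central fraction (default 95%) of
#' the overlapping position range.
#'
#' @param reference,evaluated lateral or depth [mb_profile()]s on a
#'   common axis.
#' @param dose_crit_pct dose-difference criterion, % of the reference
#'   maximum.
#' @param dta_mm distance-to-agreement criterion, in position units.
#' @param central_fraction central share of the overlap to evaluate.
#' @return An object of class `gamma_result`: `position`, `gamma`,
#'   `pass_fraction` (share with gamma <= 1), `criteria`, `region`.
#' @export
gamma_1d <- function(reference, evaluated, dose_crit_pct = 3, dta_mm = 0.3,
                     central_fraction = 0.95) {
  lo <- max(min(reference$position), min(evaluated$position))
  hi <- min(max(reference$position), max(evaluated$position))
  if (!(lo < hi)) stop("profiles have no overlapping support")
  trim <- (hi - lo) * (1 - central_fraction) / 2
  lo <- lo + trim; hi <- hi - trim
  keep <- reference$position >= lo & reference$position <= hi
  rp <- reference$position[keep]; rv <- reference$value[keep]
  dcrit <- dose_crit_pct / 100 * max(reference$value)
  ex <- evaluated$position / dta_mm
  ev <- evaluated$value / dcrit
  n_seg <- length(ex) - 1
  g <- vapply(seq_along(rp), function(i) {
    d2 <- .seg_dist2(rp[i] / dta_mm, rv[i] / dcrit,
                     ex[-length(ex)], ev[-length(ev)], ex[-1], ev[-1])
    sqrt(min(d2))
  }, numeric(1))
  structure(list(position = rp, gamma = g, pass_fraction = mean(g <= 1),
                 criteria = list(dose_crit_pct = dose_crit_pct,
                                 dta_mm = dta_mm),
                 region = c(lo, hi)),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> %.1f%% pass (gamma <= 1) on [%g, %g]; %g%%/%g mm\n",
    100 * x$pass_fraction, x$region[1], x$region[2],
    x$criteria$dose_crit_pct, x$criteria$dta_mm))
  invisible(x)
}

#' Scale a profile
#'
#' Multiplicative scaling, either by an explicit factor or by the
#' least-squares factor matching a reference profile (the film
#' cross-beam normalization step). PVDR is invariant under scaling.
#'
#' @param profile an [mb_profile()].
#' @param factor explicit scale factor.
#' @param reference an [mb_profile()] on the same positions; the
#'   least-squares factor `sum(ref*v)/sum(v^2)` is used.
#' @return list with `profile` (scaled) and `factor`.
#' @export
scale_profile <- function(profile, factor = NULL, reference = NULL) {
  if (is.null(factor)) {
    if (is.null(reference)) stop("provide either factor or reference")
    rv <- stats::approx(reference$position, reference$value,
                        xout = profile$position, rule = 2)$y
    factor <- sum(rv * profile$value) / sum(profile$value^2)
  }
  out <- profile
  out$value <- profile$value * factor
  list(profile = out, factor = factor)
}

#' Write a profile as two-column CSV
#'
#' @param profile an [mb_profile()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  col1 <- if (profile$axis == "lateral") "position_mm" else "depth_cm"
  df <- data.frame(profile$position, profile$value)
  names(df) <- c(col1, "dose")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a profile written by [write_profile_csv()]
#'
#' @param path file path.
#' @param provenance provenance label for the restored profile.
#' @return an [mb_profile()].
#' @export
read_profile_csv <- function(path, provenance = "simulated") {
  df <- utils::read.csv(path)
  axis <- if (names(df)[1] == "depth_cm") "depth" else "lateral"
  mb_profile(df[[1]], df[[2]], axis = axis, provenance = provenance)
}
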