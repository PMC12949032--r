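# Dose scoring on the phantom grid: hybrid engine that carries the Monte
# Carlo collimator-exit phase space into water analytically — each
# surviving particle deposits a Bortfeld-style depth-dose along its ray,
# widened by the Fermi-Eyges lateral spread at depth and attenuated for
# nuclear interactions.

#' Phantom dose grid
#'
#' Voxel-center coordinate vectors in mm. x and y are transverse (y is the
#' minibeam modulation axis), z is depth below the phantom surface.
#'
#' @param x,y,z voxel-center coordinates, mm, strictly increasing and
#'   uniformly spaced per axis.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(x, y, z) {
  for (v in list(x, y, z)) {
    if (length(v) < 1 || any(diff(v) <= 0))
      stop("grid axes must be strictly increasing")
  }
  if (any(z < 0)) stop("depth axis must be >= 0")
  structure(list(x = x, y = y, z = z), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  fmt <- function(v) sprintf("[%g, %g] mm x %d", min(v), max(v), length(v))
  cat("<dose_grid>\n  x:", fmt(x$x), "\n  y:", fmt(x$y),
      "\n  z:", fmt(x$z), "\n")
  invisible(x)
}

#' Analysis grid at selected depths
#'
#' Transverse extent 51 x 501 voxels (1 mm in x, 0.1 mm in y, matching the
#' phantom scoring resolution) with z planes at the requested depths.
#'
#' @param depths_cm depth planes, cm.
#' @param half_extent_mm transverse half-extent, mm.
#' @return a [dose_grid()].
#' @export
analysis_grid <- function(depths_cm = c(2, 4, 6), half_extent_mm = 25) {
  dose_grid(x = seq(-half_extent_mm, half_extent_mm, by = 1),
            y = seq(-half_extent_mm, half_extent_mm, by = 0.1),
            z = depths_cm * 10)
}

#' Dose map on a grid
#'
#' @param dose numeric array with dim `(nx, ny, nz)`, all values >= 0.
#' @param grid the [dose_grid()] the array lives on.
#' @return An object of class `dose_map`.
#' @export
dose_map <- function(dose, grid) {
  stopifnot(inherits(grid, "dose_grid"))
  dm <- c(length(grid$x), length(grid$y), length(grid$z))
  if (!identical(dim(dose), as.integer(dm)))
    stop("dose array dimensions do not match the grid")
  if (any(dose < 0)) stop("dose values must be >= 0")
  structure(list(dose = dose, grid = grid), class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> %d x %d x %d voxels, max %.4g\n",
              dim(x$dose)[1], dim(x$dose)[2], dim(x$dose)[3], max(x$dose)))
  invisible(x)
}

# Bragg curve as a function of residual range r0 (cm) at the surface;
# shared by bragg_depth_dose and the scoring engine.
bragg_curve_r <- function(r0, depth, straggling_frac = 0.012) {
  if (r0 <= 0) return(numeric(length(depth)))
  e <- energy_from_range(r0)
  bragg_depth_dose(e, depth, straggling_frac = straggling_frac)
}

#' Score a per-spot dose map from collimator-exit phase space
#'
#' Particles are grouped into residual-range bins; for each grid depth
#' plane the ray positions are histogrammed, weighted by the Bragg curve
#' value at that depth (with nuclear fluence attenuation
#' `exp(-weq/lambda)` over the total water-equivalent path), and blurred
#' with the Fermi-Eyges lateral sigma for the bin energy. The result is
#' normalized per incident particle.
#'
#' @param exit_batch a [phase_space_batch()] drifted to the phantom
#'   surface (plane z = 0).
#' @param grid a [dose_grid()].
#' @param energy nominal beam energy, MeV, used for the upstream
#'   water-equivalent path bookkeeping; defaults to the batch maximum.
#' @param nuclear_lambda nuclear attenuation length, cm water-equivalent.
#' @param range_bin_cm residual-range bin width, cm.
#' @return a [dose_map()]; dose in relative units per incident particle.
#' @export
score_spot_dose <- function(exit_batch, grid, energy = NULL,
                            nuclear_lambda = 110, range_bin_cm = 2) {
  if (abs(exit_batch$plane) > 1e-6)
    stop("batch must be at the phantom surface (plane z = 0); drift it first")
  nx <- length(grid$x); ny <- length(grid$y); nz <- length(grid$z)
  out <- array(0, c(nx, ny, nz))
  n_inc <- attr(exit_batch, "n_incident")
  if (is.null(n_inc)) n_inc <- n_particles(exit_batch)
  if (n_particles(exit_batch) == 0) return(dose_map(out, grid))
  dx <- grid$x[2] - grid$x[1]; dy <- grid$y[2] - grid$y[1]
  xe <- c(grid$x - dx / 2, max(grid$x) + dx / 2)
  ye <- c(grid$y - dy / 2, max(grid$y) + dy / 2)
  r <- exit_batch$r_res
  sx <- exit_batch$ux / exit_batch$uz
  sy <- exit_batch$uy / exit_batch$uz
  # upstream water-equivalent path already consumed (brass), for the
  # nuclear attenuation bookkeeping
  if (is.null(energy)) energy <- max(exit_batch$energy)
  consumed <- pmax(range_from_energy(energy) - r, 0)
  bin <- floor(r / range_bin_cm)
  for (bi in sort(unique(bin))) {
    sel <- which(bin == bi)
    r_rep <- stats::median(r[sel])
    if (r_rep <= 0) next
    e_rep <- energy_from_range(r_rep)
    cons_rep <- stats::median(consumed[sel])
    for (iz in seq_len(nz)) {
      z_mm <- grid$z[iz]; z_cm <- z_mm / 10
      if (z_cm >= 1.05 * r_rep) next
      b <- bragg_curve_r(r_rep, z_cm) * exp(-(cons_rep + z_cm) / nuclear_lambda)
      if (b <= 0) next
      px <- exit_batch$x[sel] + sx[sel] * z_mm
      py <- exit_batch$y[sel] + sy[sel] * z_mm
      ix <- findInterval(px, xe, all.inside = FALSE)
      iy <- findInterval(py, ye, all.inside = FALSE)
      ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
      if (!any(ok)) next
      h <- tabulate(ix[ok] + (iy[ok] - 1L) * nx, nbins = nx * ny)
      plane <- matrix(h * b, nx, ny)
      sig_mm <- lateral_sigma_growth(e_rep, min(z_cm, 0.99 * r_rep))
      out[, , iz] <- out[, , iz] + blur_xy(plane, sig_mm / dx, sig_mm / dy)
    }
  }
  out[out < 0] <- 0                       # clip FFT ringing at zero
  dose_map(out / n_inc, grid)
}

#' Per-spot dose stack
#'
#' Ordered per-spot dose maps sharing one grid, with per-spot monitor
#' units, aligned with the rows of a [spot_plan()].
#'
#' @param maps list of dose arrays (or [dose_map()]s) sharing one grid.
#' @param grid the shared [dose_grid()].
#' @param plan the [build_plan()] spot plan the stack is aligned with.
#' @return An object of class `spot_dose_stack`.
#' @export
spot_dose_stack <- function(maps, grid, plan) {
  maps <- lapply(maps, function(m) if (inherits(m, "dose_map")) m$dose else m)
  dm <- c(length(grid$x), length(grid$y), length(grid$z))
  for (m in maps)
    if (!identical(dim(m), as.integer(dm)))
      stop("all stack maps must share the grid")
  if (length(maps) != nrow(plan$spots))
    stop("stack length must match the plan")
  structure(list(maps = maps, grid = grid, plan = plan),
            class = "spot_dose_stack")
}

#' @export
print.spot_dose_stack <- function(x, ...) {
  cat(sprintf("<spot_dose_stack> %d spots on %d x %d x %d grid (pattern %s)\n",
              length(x$maps), length(x$grid$x), length(x$grid$y),
              length(x$grid$z), x$plan$pattern))
  invisible(x)
}

#' Accumulate the MU-weighted total dose
#'
#' The weighted sum is computed in a canonical spot order (sorted by spot
#' coordinates), so the total is exactly invariant under any permutation
#' of the delivery order.
#'
#' @param stack a [spot_dose_stack()].
#' @param mu_weights per-spot weights; default the plan's MU values.
#' @return a [dose_map()] of the total.
#' @export
accumulate_total <- function(stack, mu_weights = NULL) {
  if (is.null(mu_weights)) mu_weights <- stack$plan$spots$mu
  if (length(mu_weights) != length(stack$maps))
    stop("weights length must equal stack length")
  ord <- order(stack$plan$spots$x, stack$plan$spots$y)
  tot <- array(0, dim(stack$maps[[1]]))
  for (i in ord) tot <- tot + mu_weights[i] * stack$maps[[i]]
  dose_map(tot, stack$grid)
}

#' Reorder a spot stack to another plan's delivery order
#'
#' Matches spots by their (x, y) grid position. Because per-spot
#' simulations are seeded by spot position (not delivery order), the
#' reordered stack is exactly the stack that simulating the other
#' pattern would produce.
#'
#' @param stack a [spot_dose_stack()].
#' @param plan a [build_plan()] plan over the identical spot set.
#' @return a [spot_dose_stack()] in the new plan's order.
#' @export
reorder_stack <- function(stack, plan) {
  key <- function(s) paste(round(s$x, 6), round(s$y, 6))
  idx <- match(key(plan$spots), key(stack$plan$spots))
  if (any(is.na(idx))) stop("plans do not share the same spot set")
  spot_dose_stack(stack$maps[idx], stack$grid, plan)
}

#' Calibrate a dose map to a reference value
#'
#' Multiplies the map by the factor `k` that makes the designated
#' statistic equal the reference. This is a normalization convention (the
#' absolute Gy-per-MU calibration of the machine is not modelled):
#' `"match-peak"` matches the map maximum to a reference dose,
#' `"match-peak-average-rate"` matches `max(map)/t_total` to a reference
#' dose rate, and `"match-open-field"` matches the mean over a region.
#'
#' @param map a [dose_map()] (nonzero).
#' @param mode calibration statistic, see above.
#' @param reference reference value (> 0): Gy, or Gy/s for
#'   `"match-peak-average-rate"`.
#' @param t_total total delivery time, s (rate mode only).
#' @param region logical array selecting the open-field region (mean
#'   mode only; default all voxels with positive dose).
#' @return list with `map` (scaled [dose_map()]) and `scale` (k).
#' @export
calibrate_dose <- function(map, mode = c("match-peak",
                                         "match-peak-average-rate",
                                         "match-open-field"),
                           reference, t_total = NULL, region = NULL) {
  mode <- match.arg(mode)
  if (reference <= 0) stop("reference must be > 0")
  if (max(map$dose) == 0) stop("cannot calibrate an all-zero map")
  stat <- switch(mode,
    "match-peak" = max(map$dose),
    "match-peak-average-rate" = {
      if (is.null(t_total) || t_total <= 0)
        stop("t_total required for match-peak-average-rate")
      max(map$dose) / t_total
    },
    "match-open-field" = {
      if (is.null(region)) region <- map$dose > 0
      mean(map$dose[region])
    })
  k <- reference / stat
  list(map = dose_map(map$dose * k, map$grid), scale = k)
}

#' Save / load a dose map or stack
#'
#' Self-describing container: a list with the dose array(s), explicit axis
#' vectors (mm, axis order x, y, z) and a metadata block, written with
#' `saveRDS`.
#'
#' @param obj a [dose_map()] or [spot_dose_stack()].
#' @param path file path.
#' @param meta optional metadata list.
#' @return `path`, invisibly (for `save_dose_map`); the restored object
#'   (for `load_dose_map`).
#' @export
save_dose_map <- function(obj, path, meta = list()) {
  payload <- list(
    format = "pmbflash-dose-v1",
    class = class(obj)[1],
    axes = if (inherits(obj, "dose_map")) obj$grid else obj$grid,
    axis_order = c("x", "y", "z"), units = "mm",
    data = obj, meta = meta)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_dose_map
#' @export
load_dose_map <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "pmbflash-dose-v1"))
    stop("not a pmbflash dose container: ", path)
  payload$data
}
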