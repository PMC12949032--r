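# Monte Carlo transport of spot phase space through a brass multi-slit
# collimator: straight-line advance in the air slits, Highland angular
# kicks and residual-range bookkeeping in the septa, with edge crossing
# handled by the stepping. A perfect-absorber mode provides the analytic
# ray-trace limit used as an oracle.

#' Multi-slit collimator specification
#'
#' Parallel slit array; slits run along x, so the dose modulation is along
#' y. Slit centers are symmetric about y = 0.
#'
#' @param n_slits number of slits (>= 1).
#' @param slit_width slit opening, mm (must be < pitch).
#' @param pitch center-to-center slit spacing, mm.
#' @param thickness collimator thickness along the beam, cm.
#' @param material septum material; default [brass_material()].
#' @param exit_to_surface_gap air gap between collimator exit face and the
#'   phantom surface, cm.
#' @return An object of class `collimator_spec`.
#' @export
collimator_spec <- function(n_slits = 5, slit_width = 1.0, pitch = 2.8,
                            thickness = 10, material = brass_material(),
                            exit_to_surface_gap = 5) {
  if (n_slits < 1) stop("n_slits must be >= 1")
  if (slit_width >= pitch) stop("slit_width must be < pitch")
  if (thickness <= 0) stop("thickness must be > 0")
  if (exit_to_surface_gap < 0) stop("gap must be >= 0")
  structure(
    list(n_slits = as.integer(n_slits), slit_width = slit_width,
         pitch = pitch, thickness = thickness, material = material,
         exit_to_surface_gap = exit_to_surface_gap, slit_long_axis = "x"),
    class = "collimator_spec")
}

#' @export
print.collimator_spec <- function(x, ...) {
  cat(sprintf(
    "<collimator_spec> %d slits x %.1f mm, pitch %.1f mm, %.1f cm %s, gap %.1f cm\n",
    x$n_slits, x$slit_width, x$pitch, x$thickness, x$material$name,
    x$exit_to_surface_gap))
  invisible(x)
}

#' Slit center positions
#'
#' @param col a [collimator_spec()].
#' @return numeric vector of slit center y-positions, mm.
#' @export
slit_centers <- function(col) {
  (seq_len(col$n_slits) - (col$n_slits + 1) / 2) * col$pitch
}

#' Phase-space batch
#'
#' Column-vector container for a particle batch at a single transverse
#' plane: positions (mm), unit direction cosines, energy (MeV), residual
#' water-equivalent range (cm) and statistical weight.
#'
#' @param x,y transverse positions, mm.
#' @param ux,uy,uz direction cosines (normalized, uz > 0).
#' @param energy kinetic energies, MeV.
#' @param weight statistical weights (>= 0); default 1.
#' @param plane z position of the plane in mm (phantom surface = 0,
#'   upstream negative).
#' @param label plane label string.
#' @return An object of class `phase_space_batch`.
#' @export
phase_space_batch <- function(x, y, ux, uy, uz, energy,
                              weight = rep(1, length(x)),
                              plane = 0, label = "plane") {
  n <- length(x)
  stopifnot(length(y) == n, length(ux) == n, length(uy) == n,
            length(uz) == n, length(energy) == n, length(weight) == n)
  if (any(weight < 0)) stop("weights must be >= 0")
  norm <- ux^2 + uy^2 + uz^2
  if (n > 0 && any(abs(norm - 1) > 1e-9))
    stop("direction cosines must be normalized")
  structure(
    list(x = x, y = y, ux = ux, uy = uy, uz = uz,
         energy = energy, r_res = range_from_energy(energy),
         weight = weight, plane = plane, label = label),
    class = "phase_space_batch")
}

#' @export
print.phase_space_batch <- function(x, ...) {
  cat(sprintf("<phase_space_batch> %d particles at plane z = %.1f mm (%s)\n",
              length(x$x), x$plane, x$label))
  if (length(x$x) > 0)
    cat(sprintf("  energy %.1f-%.1f MeV, total weight %g\n",
                min(x$energy), max(x$energy), sum(x$weight)))
  invisible(x)
}

#' Number of particles in a batch
#' @param batch a [phase_space_batch()].
#' @return integer count.
#' @export
n_particles <- function(batch) length(batch$x)

#' Sample spot phase space at the collimator entrance plane
#'
#' Positions are Gaussian per axis with sigma projected from the isocenter
#' values by the per-axis virtual-source geometry; each particle's
#' direction points from the per-axis virtual point source through its
#' sampled position.
#'
#' @param spec a [beam_spec()].
#' @param spot_center_iso spot center at isocenter, `c(x, y)` in mm.
#' @param n number of particles.
#' @param seed RNG seed (integer); fixed seed gives identical batches.
#' @param distance_upstream_of_iso entrance plane position, cm upstream of
#'   isocenter.
#' @return a [phase_space_batch()] at the entrance plane.
#' @export
sample_spot_phase_space <- function(spec, spot_center_iso, n, seed,
                                    distance_upstream_of_iso) {
  if (n < 1) stop("n must be >= 1")
  d <- distance_upstream_of_iso
  if (d >= min(spec$sad_x, spec$sad_y))
    stop("entrance plane beyond SAD")
  set.seed(as.integer(seed))
  # sample at isocenter, then project back to the entrance plane
  x_iso <- stats::rnorm(n, spot_center_iso[1], spec$sigma_iso_x)
  y_iso <- stats::rnorm(n, spot_center_iso[2], spec$sigma_iso_y)
  mx <- (spec$sad_x - d) / spec$sad_x
  my <- (spec$sad_y - d) / spec$sad_y
  sx <- x_iso / (spec$sad_x * 10)         # slope: mm lateral per mm axial
  sy <- y_iso / (spec$sad_y * 10)
  nrm <- sqrt(1 + sx^2 + sy^2)
  phase_space_batch(
    x = x_iso * mx, y = y_iso * my,
    ux = sx / nrm, uy = sy / nrm, uz = 1 / nrm,
    energy = rep(spec$energy, n),
    plane = -d * 10, label = "collimator-entrance")
}

#' Transport a batch through the multi-slit collimator
#'
#' Stepwise transport along the beam axis. Inside an air slit the particle
#' advances in a straight line; inside a brass septum it receives Gaussian
#' angular kicks with per-step variance accumulated from the Highland
#' formula (so the whole-path angle is reproduced), and its residual
#' water-equivalent range is consumed at `1/range_scale` cm per cm of
#' brass; the particle terminates when the residual range is exhausted.
#' Particles cross slit/septum boundaries between steps, which is how edge
#' scattering arises.
#'
#' @param batch a [phase_space_batch()] at the collimator entrance plane.
#' @param col a [collimator_spec()].
#' @param step step length along z, mm (<= 5).
#' @param seed RNG seed for the scattering kicks.
#' @param perfect_absorber if TRUE, any particle touching a septum is
#'   terminated and no scattering occurs (ray-trace oracle mode).
#' @return a [phase_space_batch()] of survivors at the collimator exit
#'   plane, with attribute `n_incident` (incident particle count).
#' @export
transport_msc <- function(batch, col, step = 1, seed = 1,
                          perfect_absorber = FALSE) {
  if (step <= 0) stop("step must be > 0")
  if (step > 5) stop("step must be <= 5 mm")
  set.seed(as.integer(seed))
  n0 <- n_particles(batch)
  x <- batch$x; y <- batch$y
  sx <- batch$ux / batch$uz; sy <- batch$uy / batch$uz
  r_res <- batch$r_res
  w <- batch$weight
  mat <- col$material
  x0_cm <- mat$radiation_length
  inv_scale <- 1 / mat$range_scale
  half_w <- col$slit_width / 2
  half_span <- (col$n_slits - 1) / 2
  thick_mm <- col$thickness * 10
  n_steps <- ceiling(thick_mm / step)
  ds_mm <- thick_mm / n_steps
  ds_cm <- ds_mm / 10
  brass_path <- numeric(length(x))       # cm traversed in brass
  alive <- rep(TRUE, length(x))
  for (i in seq_len(n_steps)) {
    idx <- which(alive)
    if (length(idx) == 0) break
    yk <- y[idx]
    k <- round(yk / col$pitch)
    in_slit <- abs(k) <= half_span & abs(yk - k * col$pitch) <= half_w
    ib <- idx[!in_slit]
    if (length(ib) > 0) {
      if (perfect_absorber) {
        alive[ib] <- FALSE
      } else {
        r_res[ib] <- r_res[ib] - ds_cm * inv_scale
        dead <- ib[r_res[ib] <= 0]
        alive[dead] <- FALSE
        ib <- ib[r_res[ib] > 0]
        if (length(ib) > 0) {
          pv <- proton_pv(energy_from_range(r_res[ib]))
          l0 <- brass_path[ib] / x0_cm
          l1 <- (brass_path[ib] + ds_cm) / x0_cm
          dvar <- (14.1 / pv)^2 * pmax(highland_f(l1) - highland_f(l0), 0)
          kick <- sqrt(dvar)
          sx[ib] <- sx[ib] + stats::rnorm(length(ib)) * kick
          sy[ib] <- sy[ib] + stats::rnorm(length(ib)) * kick
          brass_path[ib] <- brass_path[ib] + ds_cm
        }
      }
    }
    mv <- which(alive)
    x[mv] <- x[mv] + sx[mv] * ds_mm
    y[mv] <- y[mv] + sy[mv] * ds_mm
  }
  keep <- which(alive)
  nrm <- sqrt(1 + sx[keep]^2 + sy[keep]^2)
  out <- phase_space_batch(
    x = x[keep], y = y[keep],
    ux = sx[keep] / nrm, uy = sy[keep] / nrm, uz = 1 / nrm,
    energy = energy_from_range(pmax(r_res[keep], 0)),
    weight = w[keep],
    plane = batch$plane + thick_mm, label = "collimator-exit")
  attr(out, "n_incident") <- n0
  out
}

#' Drift a batch in air to a downstream plane
#'
#' Straight-line advance (air scattering and energy loss neglected).
#'
#' @param batch a [phase_space_batch()].
#' @param dz_mm drift distance along z, mm (>= 0).
#' @param label new plane label.
#' @return drifted [phase_space_batch()].
#' @export
drift_batch <- function(batch, dz_mm, label = "drifted") {
  if (dz_mm < 0) stop("drift distance must be >= 0")
  out <- batch
  out$x <- batch$x + batch$ux / batch$uz * dz_mm
  out$y <- batch$y + batch$uy / batch$uz * dz_mm
  out$plane <- batch$plane + dz_mm
  out$label <- label
  attr(out, "n_incident") <- attr(batch, "n_incident")
  out
}

#' Analytic slit transmission of a centered Gaussian beam
#'
#' Perfect-absorber, zero-divergence closed form: the transmitted fraction
#' of a Gaussian fluence through the interval `[a, b]` is
#' `Phi(b/sigma) - Phi(a/sigma)`, and the transmitted profile is the
#' Gaussian times the slit indicator.
#'
#' @param sigma Gaussian sigma, mm (> 0).
#' @param slit `c(a, b)` slit interval, mm (a < b; may be infinite).
#' @return list with `fraction` and `profile` (a function of y, mm).
#' @export
analytic_slit_fluence <- function(sigma, slit) {
  if (sigma <= 0) stop("sigma must be > 0")
  a <- slit[1]; b <- slit[2]
  if (!(a < b)) stop("slit interval must satisfy a < b")
  frac <- stats::pnorm(b / sigma) - stats::pnorm(a / sigma)
  prof <- function(y) stats::dnorm(y, sd = sigma) * (y >= a & y <= b)
  list(fraction = frac, profile = prof)
}
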