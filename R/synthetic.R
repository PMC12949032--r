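# Synthetic inputs: named scenario presets bundling the study's printed
# parameters, film-scan emulation (0.085 mm pixel pitch, multiplicative
# noise), and the day-to-day output factor of the UHDR beam.

scenario_preset_table <- function() {
  flash_beam <- list(energy = 228, sigma_iso_x = 5.6, sigma_iso_y = 5.6,
                     current = 125)
  conv_beam <- list(energy = 226, sigma_iso_x = 3.4, sigma_iso_y = 3.4,
                    current = 1.88)
  mk <- function(beam, thickness, cal_peak_dose) {
    list(beam = beam, thickness = thickness, cal_peak_dose = cal_peak_dose)
  }
  # calibration convention: peak dose (Gy) = printed peak average dose
  # rate at 2 cm times the delivery time for that mode
  list(
    "flash-10"  = mk(flash_beam, 10,  8.4 * 2.5),
    "flash-6.5" = mk(flash_beam, 6.5, 9.8 * 2.5),
    "conv-10"   = mk(conv_beam, 10,   0.1 * 166),
    "conv-6.5"  = mk(conv_beam, 6.5,  0.2 * 166))
}

#' Scenario presets
#'
#' @return character vector of available preset names.
#' @export
scenario_presets <- function() names(scenario_preset_table())

#' Build a named scenario configuration
#'
#' Bundles beam, collimator, spot plan, PBS configuration, grid, seeds
#' and run sizes for one of the study arms: `"flash-10"`, `"flash-6.5"`
#' (228 MeV, sigma 5.6 mm, 125 nA) or `"conv-10"`, `"conv-6.5"` (226
#' MeV, sigma 3.4 mm, 1.88 nA), through the 10 cm or 6.5 cm brass
#' multi-slit collimator. Overrides are applied last as a nested list
#' (e.g. `list(n_histories = 1e4, beam = list(current = 60))`).
#'
#' @param preset preset name; see [scenario_presets()].
#' @param overrides nested named list of overrides.
#' @return An object of class `scenario_config`.
#' @export
make_scenario <- function(preset, overrides = list()) {
  tab <- scenario_preset_table()
  if (!preset %in% names(tab))
    stop("unknown preset '", preset, "'; available: ",
         paste(names(tab), collapse = ", "))
  p <- tab[[preset]]
  cfg <- list(
    id = preset,
    beam = c(p$beam, list(sad_x = 298, sad_y = 970, pulse_rate = 1000,
                          pulse_width = 10e-6, charge_per_mu = 0.1276)),
    collimator = list(n_slits = 5, slit_width = 1.0, pitch = 2.8,
                      thickness = p$thickness, exit_to_surface_gap = 5),
    plan = list(field_size_cm = 3, spacing_mm = 5, mu_per_spot = 50,
                pattern = "A"),
    pbs = list(threshold = 0.5, fidelity = "spot-uniform"),
    grid = list(depths_cm = c(2, 4, 6, 8, 12), half_extent_mm = 25),
    cal_peak_dose = p$cal_peak_dose,
    dead_time = 0,
    n_histories = 1e5,
    seed = 1)
  cfg <- utils::modifyList(cfg, overrides)
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %s: %g MeV, sigma %g mm, %g nA, %g cm MSC, %g histories/spot\n",
    x$id, x$beam$energy, x$beam$sigma_iso_y, x$beam$current,
    x$collimator$thickness, x$n_histories))
  invisible(x)
}

# projected slit-pitch magnification at depth: the slit pattern at the
# collimator mid-plane, projected from the y-axis virtual source to the
# extraction plane (a fraction of a percent at these SADs)
pitch_magnification <- function(cfg, depth_cm) {
  sad <- cfg$beam$sad_y
  d_mid <- cfg$collimator$exit_to_surface_gap + cfg$collimator$thickness / 2
  (sad + depth_cm) / (sad - d_mid)
}

# materialize the domain objects from a scenario
scenario_beam <- function(cfg) do.call(beam_spec, cfg$beam)
scenario_collimator <- function(cfg) do.call(collimator_spec, cfg$collimator)
scenario_plan <- function(cfg) do.call(build_plan, cfg$plan)
scenario_grid <- function(cfg) do.call(analysis_grid, cfg$grid)
scenario_pbs <- function(cfg) do.call(pbs_config, cfg$pbs)

#' Film image
#'
#' 2-D pixel array in dose units on a uniform pixel grid (film-scan
#' emulation; the optical-density conversion step is not modelled).
#'
#' @param pixels matrix of nonnegative values (rows = x, cols = y).
#' @param pitch_mm pixel pitch, mm (default 0.085, i.e. 300 dpi).
#' @param x0_mm,y0_mm position of the first pixel center, mm.
#' @param noise_cv noise descriptor (coefficient of variation).
#' @return An object of class `film_image`.
#' @export
film_image <- function(pixels, pitch_mm = 0.085, x0_mm = 0, y0_mm = 0,
                       noise_cv = 0) {
  if (any(pixels < 0)) stop("film pixel values must be >= 0")
  if (pitch_mm <= 0) stop("pixel pitch must be > 0")
  structure(list(pixels = pixels, pitch_mm = pitch_mm,
                 x = x0_mm + (seq_len(nrow(pixels)) - 1) * pitch_mm,
                 y = y0_mm + (seq_len(ncol(pixels)) - 1) * pitch_mm,
                 noise_cv = noise_cv),
            class = "film_image")
}

#' @export
print.film_image <- function(x, ...) {
  cat(sprintf("<film_image> %d x %d px at %.3f mm pitch, noise cv %.3f\n",
              nrow(x$pixels), ncol(x$pixels), x$pitch_mm, x$noise_cv))
  invisible(x)
}

#' Synthesize a film scan from simulated dose
#'
#' Resamples a dose-map slice (or a 1-D profile, replicated across a
#' narrow strip) onto the film pixel grid by linear interpolation and
#' applies multiplicative Gaussian noise with the given coefficient of
#' variation. Reproducible under a fixed seed.
#'
#' @param src a [dose_map()] (its plane at `depth_cm` is used) or an
#'   [mb_profile()].
#' @param depth_cm depth plane for a dose-map source, cm.
#' @param pixel_pitch_mm film pixel pitch, mm.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param seed RNG seed.
#' @param strip_px number of replicated rows for a profile source.
#' @return a [film_image()].
#' @export
synth_film <- function(src, depth_cm = NULL, pixel_pitch_mm = 0.085,
                       noise_cv = 0.02, seed = 1, strip_px = 8) {
  set.seed(as.integer(seed))
  if (inherits(src, "dose_map")) {
    if (is.null(depth_cm)) stop("depth_cm required for a dose-map source")
    iz <- which.min(abs(src$grid$z - depth_cm * 10))
    gx <- src$grid$x; gy <- src$grid$y
    fx <- seq(min(gx), max(gx), by = pixel_pitch_mm)
    fy <- seq(min(gy), max(gy), by = pixel_pitch_mm)
    # bilinear resample: interpolate along x, then along y
    sl <- src$dose[, , iz]
    mx <- apply(sl, 2, function(col)
      stats::approx(gx, col, xout = fx, rule = 2)$y)
    px <- t(apply(mx, 1, function(row)
      stats::approx(gy, row, xout = fy, rule = 2)$y))
    x0 <- fx[1]; y0 <- fy[1]
  } else if (inherits(src, "mb_profile")) {
    fy <- seq(min(src$position), max(src$position), by = pixel_pitch_mm)
    v <- stats::approx(src$position, src$value, xout = fy, rule = 2)$y
    px <- matrix(v, nrow = strip_px, ncol = length(fy), byrow = TRUE)
    x0 <- 0; y0 <- fy[1]
  } else stop("src must be a dose_map or mb_profile")
  if (noise_cv > 0)
    px <- px * (1 + stats::rnorm(length(px), 0, noise_cv))
  px[px < 0] <- 0
  film_image(px, pitch_mm = pixel_pitch_mm, x0_mm = x0, y0_mm = y0,
             noise_cv = noise_cv)
}

#' Lateral profile from a film image
#'
#' Averages the film rows (x direction) into a 1-D dose-vs-y profile at
#' the film pixel pitch.
#'
#' @param film a [film_image()].
#' @param depth_cm depth label carried on the profile, cm.
#' @return an [mb_profile()] with provenance `"synthetic-film"`.
#' @export
film_to_profile <- function(film, depth_cm = NA_real_) {
  mb_profile(film$y, colMeans(film$pixels), axis = "lateral",
             depth_cm = depth_cm, provenance = "synthetic-film")
}

#' Daily output factor of the UHDR beam
#'
#' Draws a multiplicative output factor (lognormal, unit mean) emulating
#' day-to-day fluctuation of the beam output; the film normalization
#' step ([scale_profile()]) recovers it.
#'
#' @param seed RNG seed.
#' @param cv coefficient of variation (default 0.05); 0 returns exactly 1.
#' @return scalar factor.
#' @export
daily_output_factor <- function(seed, cv = 0.05) {
  if (cv < 0) stop("cv must be >= 0")
  if (cv == 0) return(1)
  set.seed(as.integer(seed))
  sl <- sqrt(log(1 + cv^2))
  stats::rlnorm(1, meanlog = -sl^2 / 2, sdlog = sl)
}

#' Write a film image as 16-bit TIFF with a sidecar metadata file
#'
#' The pixel array is scaled to the 16-bit range; the scale, pixel pitch
#' and units are recorded in a YAML sidecar next to the TIFF.
#'
#' @param film a [film_image()].
#' @param path output TIFF path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_film_tiff <- function(film, path) {
  mx <- max(film$pixels)
  scale <- if (mx > 0) mx else 1
  tiff::writeTIFF(film$pixels / scale, path, bits.per.sample = 16)
  side <- sub("\\.tiff?$", ".yaml", path)
  if (identical(side, path)) side <- paste0(path, ".yaml")
  yaml::write_yaml(list(pixel_pitch_mm = film$pitch_mm,
                        units = "dose (relative)",
                        dose_per_level = scale / 65535,
                        noise_cv = film$noise_cv), side)
  invisible(path)
}
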