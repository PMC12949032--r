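# End-to-end orchestration: simulate (beam -> collimator -> dose),
# doserate (delivery log -> dose-rate fields -> study-style
# summary), analyze (profiles -> PVDR -> gamma), with manifests and a
# YAML config round trip.

#' Simulate all spots of a scenario
#'
#' Runs sample -> collimator transport -> air-gap drift -> dose scoring
#' for every spot of the plan, with one deterministic RNG stream per
#' (spot, stage) keyed by the spot's grid position, so per-spot results
#' do not depend on delivery order. Returns the per-spot stack and the
#' MU-weighted total.
#'
#' @param cfg a [make_scenario()] configuration.
#' @param n_histories histories per spot; default from `cfg`.
#' @param seed base seed; default from `cfg`.
#' @param out_dir optional output directory; stack, total and manifest
#'   are persisted there.
#' @return list with `stack` ([spot_dose_stack()]), `total`
#'   ([dose_map()]), `manifest`.
#' @export
run_simulate <- function(cfg, n_histories = NULL, seed = NULL,
                         out_dir = NULL) {
  t_start <- Sys.time()
  if (is.null(n_histories)) n_histories <- cfg$n_histories
  if (is.null(seed)) seed <- cfg$seed
  beam <- scenario_beam(cfg)
  col <- scenario_collimator(cfg)
  plan <- scenario_plan(cfg)
  grid <- scenario_grid(cfg)
  d_ent <- col$exit_to_surface_gap + col$thickness
  maps <- vector("list", nrow(plan$spots))
  for (i in seq_len(nrow(plan$spots))) {
    sp <- plan$spots[i, ]
    key <- round(sp$x * 10) * 4096 + round(sp$y * 10) + 2^21
    b <- sample_spot_phase_space(beam, c(sp$x, sp$y), n_histories,
                                 seed = derive_seed(seed, key, "sample"),
                                 distance_upstream_of_iso = d_ent)
    ex <- transport_msc(b, col, step = 1,
                        seed = derive_seed(seed, key, "transport"))
    surf <- drift_batch(ex, col$exit_to_surface_gap * 10, "phantom-surface")
    maps[[i]] <- score_spot_dose(surf, grid, energy = beam$energy)$dose
  }
  stack <- spot_dose_stack(maps, grid, plan)
  total <- accumulate_total(stack)
  manifest <- list(
    scenario = cfg$id, seed = seed, n_histories = n_histories,
    package_version = tryCatch(
      as.character(utils::packageVersion("pmbflash")), error = function(e) NA),
    config_hash = config_hash(unclass(cfg)),
    output_hash = config_hash(total$dose),
    wall_time_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    outputs = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, c("stack.rds", "total.rds", "manifest.yaml"))
    save_dose_map(stack, paths[1], meta = manifest["scenario"])
    save_dose_map(total, paths[2], meta = manifest["scenario"])
    manifest$outputs <- paths
    yaml::write_yaml(manifest, paths[3])
  }
  list(stack = stack, total = total, manifest = manifest)
}

#' Dose-rate maps and summary table for a simulated scenario
#'
#' Schedules the pulsed delivery, calibrates the total dose with the
#' documented peak-dose convention, builds per-voxel cumulative curves
#' and emits the field-average and PBS dose-rate summaries
#' (PDR/VDR/PDR_PBS/VDR_PBS/MDR_PBS) at the requested depths.
#'
#' @param sim result of [run_simulate()] (or a [spot_dose_stack()]).
#' @param cfg the [make_scenario()] configuration.
#' @param log optional [schedule_delivery()] log; built from the
#'   scenario beam/plan when omitted.
#' @param depths_cm summary depths, cm.
#' @param out_dir optional directory for the summary CSV.
#' @return list with `summary` (data.frame, one row per depth),
#'   `avg_rate` ([dose_map()]), `pbs` (per-depth [pbs_dose_rate()]
#'   fields), `log`, `scale`.
#' @export
run_doserate <- function(sim, cfg, log = NULL, depths_cm = c(2, 4, 6),
                         out_dir = NULL) {
  stack <- if (inherits(sim, "spot_dose_stack")) sim else sim$stack
  total <- accumulate_total(stack)
  beam <- scenario_beam(cfg)
  if (is.null(log))
    log <- schedule_delivery(stack$plan, beam, dead_time = cfg$dead_time)
  grid <- stack$grid
  # calibration convention: peak dose on the shallowest summary plane
  iz2 <- which.min(abs(grid$z - depths_cm[1] * 10))
  k <- cfg$cal_peak_dose / max(total$dose[, , iz2])
  cal_total <- dose_map(total$dose * k, grid)
  avg <- average_dose_rate(cal_total, log$t_total)
  pbs_cfg <- scenario_pbs(cfg)
  nxy <- length(grid$x) * length(grid$y)
  rows <- list(); pbs_fields <- list()
  for (d in depths_cm) {
    iz <- which.min(abs(grid$z - d * 10))
    vox <- (iz - 1L) * nxy + seq_len(nxy)
    curves <- build_cumulative_curves(stack, log, pbs_cfg, voxels = vox,
                                      scale = k)
    pbs <- pbs_dose_rate(curves, pbs_cfg)
    prof <- extract_lateral(cal_total, d)
    col <- scenario_collimator(cfg)
    pos <- locate_peaks_valleys(prof, pitch_mm = col$pitch,
                                magnification = pitch_magnification(cfg, d))
    pvdr <- compute_pvdr(prof, pos)
    # the plane-restricted pbs field indexes voxels 1..nxy on a 1-plane grid
    pbs$voxels <- seq_len(nxy)
    pbs$grid <- dose_grid(grid$x, grid$y, grid$z[iz])
    s <- summarize_rates(array(avg$dose[, , iz], c(length(grid$x),
                                                   length(grid$y), 1L)),
                         pbs, pbs$grid, d, pos$peaks, pos$valleys)
    rows[[length(rows) + 1]] <- data.frame(
      collimator_cm = cfg$collimator$thickness, depth_cm = d,
      PVDR = pvdr$pvdr, PVDR_unc = pvdr$uncertainty,
      PDR = s$PDR, VDR = s$VDR, PDR_PBS = s$PDR_PBS, VDR_PBS = s$VDR_PBS,
      MDR_PBS = s$MDR_PBS, t_total_s = log$t_total)
    pbs_fields[[as.character(d)]] <- pbs
  }
  summary <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(out_dir, "doserate_summary.csv"),
                     row.names = FALSE)
  }
  list(summary = summary, avg_rate = avg, pbs = pbs_fields, log = log,
       scale = k)
}

#' Profile / PVDR / gamma analysis of a total dose map
#'
#' Extracts lateral profiles at the requested depths, locates peaks and
#' valleys, computes PVDR per depth, and (optionally) compares against a
#' second profile source with the 1-D gamma index.
#'
#' @param total a [dose_map()] (e.g. `run_simulate()$total`) or a
#'   [film_image()].
#' @param cfg the [make_scenario()] configuration.
#' @param depths_cm analysis depths, cm.
#' @param reference optional [mb_profile()] (or list of, keyed by depth)
#'   to gamma-compare each extracted profile against.
#' @param out_dir optional directory for the PVDR CSV.
#' @return list with `profiles`, `pvdr_table` (data.frame), `gamma`.
#' @export
run_analyze <- function(total, cfg, depths_cm = c(2, 4, 6),
                        reference = NULL, out_dir = NULL) {
  pitch <- cfg$collimator$pitch
  profiles <- list(); gam <- list(); rows <- list()
  for (d in depths_cm) {
    prof <- if (inherits(total, "film_image"))
      film_to_profile(total, depth_cm = d)
    else extract_lateral(total, d)
    pos <- locate_peaks_valleys(prof, pitch_mm = pitch,
                                magnification = pitch_magnification(cfg, d))
    pvdr <- compute_pvdr(prof, pos)
    profiles[[as.character(d)]] <- prof
    rows[[length(rows) + 1]] <- data.frame(
      depth_cm = d, PVDR = pvdr$pvdr, PVDR_unc = pvdr$uncertainty,
      n_peaks = length(pos$peaks), n_valleys = length(pos$valleys))
    if (!is.null(reference)) {
      ref <- if (inherits(reference, "mb_profile")) reference
      else reference[[as.character(d)]]
      if (!is.null(ref))
        gam[[as.character(d)]] <- gamma_1d(ref, prof)
    }
  }
  pvdr_table <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(pvdr_table, file.path(out_dir, "pvdr.csv"),
                     row.names = FALSE)
  }
  list(profiles = profiles, pvdr_table = pvdr_table, gamma = gam)
}

#' Write / read a scenario configuration as YAML
#'
#' @param cfg a [make_scenario()] configuration.
#' @param path YAML file path.
#' @return `path` invisibly; `read_config()` returns the validated
#'   `scenario_config` (missing keys raise an error naming the key).
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("id", "beam", "collimator", "plan", "pbs", "grid",
                "cal_peak_dose", "dead_time", "n_histories", "seed")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0)
    stop("config validation error: missing key(s): ",
         paste(missing, collapse = ", "))
  structure(cfg, class = "scenario_config")
}
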