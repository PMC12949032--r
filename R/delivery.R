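# Scan plans (raster patterns A/B), pulsed delivery scheduling from beam
# current and synchrocyclotron pulse structure, and the delivery-log CSV
# dialect.

#' Build a raster spot plan
#'
#' Pattern A is row-serpentine (rows of constant y, x direction
#' alternating row to row); Pattern B is column-serpentine. Both patterns
#' contain the identical spot set; only the delivery order differs. The
#' default field is the 3 x 3 cm^2, 5 mm spacing, 7 x 7 = 49-spot raster.
#'
#' @param field_size_cm square field side, cm.
#' @param spacing_mm spot center-to-center spacing, mm; must divide the
#'   field extent into an integer spot count.
#' @param mu_per_spot monitor units per spot (> 0).
#' @param pattern `"A"` (row-serpentine) or `"B"` (column-serpentine).
#' @return An object of class `spot_plan`: `$spots` is a data.frame with
#'   columns `spot`, `x`, `y` (mm at isocenter), `mu`, plus `$pattern` and
#'   a `$field` descriptor.
#' @export
build_plan <- function(field_size_cm = 3, spacing_mm = 5, mu_per_spot = 50,
                       pattern = c("A", "B")) {
  pattern <- match.arg(pattern)
  if (mu_per_spot <= 0) stop("mu_per_spot must be > 0")
  ext_mm <- field_size_cm * 10
  if (abs(ext_mm / spacing_mm - round(ext_mm / spacing_mm)) > 1e-9)
    stop("spacing must divide the field extent into an integer spot count")
  n_side <- as.integer(round(ext_mm / spacing_mm)) + 1L
  pos <- (seq_len(n_side) - (n_side + 1) / 2) * spacing_mm
  if (pattern == "A") {
    rows <- lapply(seq_len(n_side), function(i) {
      xs <- if (i %% 2 == 1) pos else rev(pos)
      data.frame(x = xs, y = pos[i])
    })
    spots <- do.call(rbind, rows)
  } else {
    cols <- lapply(seq_len(n_side), function(i) {
      ys <- if (i %% 2 == 1) pos else rev(pos)
      data.frame(x = pos[i], y = ys)
    })
    spots <- do.call(rbind, cols)
  }
  spots$spot <- seq_len(nrow(spots))
  spots$mu <- mu_per_spot
  spots <- spots[, c("spot", "x", "y", "mu")]
  structure(
    list(spots = spots, pattern = pattern,
         field = list(field_size_cm = field_size_cm,
                      spacing_mm = spacing_mm, n_side = n_side)),
    class = "spot_plan")
}

#' @export
print.spot_plan <- function(x, ...) {
  cat(sprintf("<spot_plan> pattern %s: %d spots (%d x %d), %g MU/spot\n",
              x$pattern, nrow(x$spots), x$field$n_side, x$field$n_side,
              x$spots$mu[1]))
  invisible(x)
}

#' Schedule pulsed delivery of a spot plan
#'
#' Each spot delivers charge `mu * charge_per_mu` at the beam's
#' time-averaged current, so its duration is `charge / current`
#' (continuous in time; the 1 kHz pulse quantization is available through
#' [expand_pulses()]). Spots are delivered sequentially in plan order,
#' separated by `dead_time`. Total time at fixed charge scales exactly as
#' 1/current.
#'
#' @param plan a [build_plan()] spot plan.
#' @param spec a [beam_spec()] (current, pulse structure, charge_per_mu).
#' @param dead_time inter-spot dead time, s.
#' @return An object of class `delivery_log`: `$records` data.frame with
#'   columns `spot_index`, `x_mm`, `y_mm`, `mu`, `t_start_s`, `t_end_s`,
#'   `charge_nC`; plus `$t_total`, `$pulse_rate`, `$pulse_width`.
#' @export
schedule_delivery <- function(plan, spec, dead_time = 0) {
  if (spec$current <= 0) stop("current must be > 0")
  if (spec$charge_per_mu <= 0) stop("charge_per_mu must be > 0")
  if (dead_time < 0) stop("dead_time must be >= 0")
  s <- plan$spots
  charge <- s$mu * spec$charge_per_mu            # nC
  dur <- charge / spec$current                   # nC / nA = s
  t_end <- cumsum(dur) + dead_time * (seq_along(dur) - 1)
  t_start <- t_end - dur
  rec <- data.frame(spot_index = s$spot, x_mm = s$x, y_mm = s$y, mu = s$mu,
                    t_start_s = t_start, t_end_s = t_end, charge_nC = charge)
  structure(
    list(records = rec,
         t_total = if (nrow(rec)) max(t_end) - min(t_start) else 0,
         pulse_rate = spec$pulse_rate, pulse_width = spec$pulse_width),
    class = "delivery_log")
}

#' @export
print.delivery_log <- function(x, ...) {
  cat(sprintf("<delivery_log> %d spots, t_total = %.4g s, %g nC total\n",
              nrow(x$records), x$t_total, sum(x$records$charge_nC)))
  invisible(x)
}

#' Expand a delivery log to per-pulse records
#'
#' Splits each spot into 1 kHz (or `pulse_rate`) pulse records of width
#' `pulse_width`. Full pulses carry `charge / (duration * rate)` each;
#' the final partial pulse carries the remainder, so total charge is
#' conserved exactly.
#'
#' @param log a [schedule_delivery()] log.
#' @return data.frame with columns `spot_index`, `pulse`, `t_start_s`,
#'   `width_s`, `charge_nC`.
#' @export
expand_pulses <- function(log) {
  rate <- log$pulse_rate
  out <- lapply(seq_len(nrow(log$records)), function(i) {
    r <- log$records[i, ]
    dur <- r$t_end_s - r$t_start_s
    if (dur <= 0) return(NULL)
    n_full <- floor(dur * rate)
    cpp <- r$charge_nC / (dur * rate)
    frac <- dur * rate - n_full
    n <- n_full + (frac > 1e-12)
    ch <- rep(cpp, n)
    if (frac > 1e-12) ch[n] <- r$charge_nC - n_full * cpp
    data.frame(spot_index = r$spot_index, pulse = seq_len(n),
               t_start_s = r$t_start_s + (seq_len(n) - 1) / rate,
               width_s = pmin(log$pulse_width, dur - (seq_len(n) - 1) / rate),
               charge_nC = ch)
  })
  do.call(rbind, out)
}

#' Write / read a delivery log CSV
#'
#' Plain CSV dialect: header row, SI-unit column names
#' (`spot_index,x_mm,y_mm,mu,t_start_s,t_end_s,charge_nC`), `.` decimal
#' separator. `read_delivery_log()` enforces the log invariants
#' (nondecreasing times, end >= start) and reports parse failures with
#' the offending line number.
#'
#' @param log a [schedule_delivery()] log.
#' @param path file path.
#' @param pulse_rate,pulse_width pulse structure restored on read.
#' @return `path` invisibly; `read_delivery_log()` returns the
#'   `delivery_log`.
#' @export
write_delivery_log <- function(log, path) {
  utils::write.csv(log$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_delivery_log
#' @export
read_delivery_log <- function(path, pulse_rate = 1000, pulse_width = 10e-6) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty delivery log: ", path)
  want <- c("spot_index", "x_mm", "y_mm", "mu", "t_start_s", "t_end_s",
            "charge_nC")
  hdr <- strsplit(lines[1], ",")[[1]]
  if (!identical(hdr, want))
    stop("line 1: malformed header, expected ", paste(want, collapse = ","))
  rows <- lapply(seq_along(lines)[-1], function(i) {
    f <- strsplit(lines[i], ",")[[1]]
    if (length(f) != length(want))
      stop("line ", i, ": expected ", length(want), " fields")
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v))) stop("line ", i, ": non-numeric field")
    v
  })
  rec <- as.data.frame(do.call(rbind, rows))
  names(rec) <- want
  if (any(rec$t_end_s < rec$t_start_s))
    stop("invalid log: t_end < t_start at line ",
         which(rec$t_end_s < rec$t_start_s)[1] + 1)
  if (any(diff(rec$t_start_s) < 0))
    stop("invalid log: decreasing start times at line ",
         which(diff(rec$t_start_s) < 0)[1] + 2)
  structure(
    list(records = rec, t_total = max(rec$t_end_s) - min(rec$t_start_s),
         pulse_rate = pulse_rate, pulse_width = pulse_width),
    class = "delivery_log")
}
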