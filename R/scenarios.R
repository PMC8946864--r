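.preset_table <- list(
  implant_A = list(diffusivity = 2e-6,
                   label = "implant A (moderate conductor)"),
  implant_B = list(diffusivity = 5e-6,
                   label = "implant B (good conductor)"),
  # Titanium and ceramic diffusivities are chosen so that a 1.3 cm implant
  # has intrinsic times of 1.9 s and 27.4 s respectively, the values quoted
  # for those materials; the diffusivities themselves are back-derived from
  # tau = L^2/(alpha pi^2), not tabulated material constants.
  titanium = list(diffusivity = 9.0e-6,
                  label = "titanium (diffusivity derived from tau = 1.9 s)"),
  ceramic = list(diffusivity = 6.25e-7,
                 label = "ceramic (diffusivity derived from tau = 27.4 s)")
)

.preset_length <- 0.013  # m; standard fixture length used throughout

#' Implant material presets
#'
#' Standard implant models, all with length `L = 1.3 cm`:
#' \describe{
#'   \item{`implant_A`}{alpha = 2e-6 m^2/s, moderate conductor, tau ~ 8.6 s}
#'   \item{`implant_B`}{alpha = 5e-6 m^2/s, good conductor, tau ~ 3.4 s}
#'   \item{`titanium`}{alpha = 9.0e-6 m^2/s (derived from tau = 1.9 s)}
#'   \item{`ceramic`}{alpha = 6.25e-7 m^2/s (derived from tau = 27.4 s)}
#' }
#'
#' @param name one of `"implant_A"`, `"implant_B"`, `"titanium"`,
#'   `"ceramic"`.
#' @return An [implant_model()].
#' @examples
#' intrinsic_time(preset_model("implant_A"))  # 8.56 s, prints as 8.6
#' @export
preset_model <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.preset_table))
    stop(sprintf("unknown preset %s; available presets: %s",
                 deparse(substitute(name)),
                 paste(names(.preset_table), collapse = ", ")))
  p <- .preset_table[[name]]
  implant_model(.preset_length, p$diffusivity, p$label)
}

.location_fractions <- c(B1 = 3 / 4, B2 = 1 / 2, B3 = 1 / 4)

#' Named locations along the implant
#'
#' The conventional observation points: B1 at `3L/4` (superficial, near the
#' oral cavity), B2 at `L/2` (middle), B3 at `L/4` (deep, near the bone).
#'
#' @param point `"B1"`, `"B2"` or `"B3"`, or directly a numeric position in
#'   metres (returned unchanged after validation).
#' @param model an [implant_model()].
#' @return Position in metres.
#' @export
location_y <- function(point, model) {
  stopifnot(inherits(model, "implant_model"))
  if (is.numeric(point)) {
    .check_positions(point, model$length)
    return(as.numeric(point))
  }
  if (!is.character(point) || length(point) != 1L ||
      !point %in% names(.location_fractions))
    stop("'point' must be one of \"B1\", \"B2\", \"B3\" or a numeric position")
  unname(.location_fractions[point]) * model$length
}

#' Parameter-study datasets behind the standard figures
#'
#' Regenerates, as long-format data frames, the parameter combinations of
#' the package's standard illustrations:
#' \describe{
#'   \item{2}{the thermal load itself for `t0 = 0.2 s` and `t0 = 2 s`}
#'   \item{3}{spatial profiles for implant A, `t0 = 2 s`, at
#'     `t = 9, 12, 15, 18 s`}
#'   \item{4}{histories at B1/B2/B3 for implant A, `t0 = 2 s`}
#'   \item{5}{histories at B2 for implants A and B, `t0 = 2 s`}
#'   \item{6}{histories at B2 for implant A, `t0 = 2, 5, 8, 11, 14 s`}
#'   \item{7}{histories at B2 for implant B, `t0 = 1, 2, 3, 5, 6 s`}
#' }
#'
#' @param fig_id integer in `2:7`.
#' @param cfg a [series_config()].
#' @return A data frame with columns `figure`, `series`, `t0_s`, `t_s`,
#'   `y_m`, `temperature_C`.
#' @export
figure_dataset <- function(fig_id, cfg = series_config()) {
  if (!is.numeric(fig_id) || length(fig_id) != 1L || !fig_id %in% 2:7)
    stop("'fig_id' must be one of 2, 3, 4, 5, 6, 7")
  fig_id <- as.integer(fig_id)
  A <- preset_model("implant_A")
  B <- preset_model("implant_B")
  row <- function(series, t0, t, y, temp)
    data.frame(figure = fig_id, series = series, t0_s = t0, t_s = t,
               y_m = y, temperature_C = temp)
  out <- switch(
    as.character(fig_id),
    "2" = {
      ts <- seq(0, 10, length.out = 201L)
      do.call(rbind, lapply(c(0.2, 2), function(t0) {
        ld <- thermal_load(exposure_time = t0)
        row(sprintf("t0 = %g s", t0), t0, ts, A$length,
            load_temperature(ld, ts))
      }))
    },
    "3" = {
      ld <- thermal_load(exposure_time = 2)
      ys <- seq(0, A$length, length.out = 101L)
      do.call(rbind, lapply(c(9, 12, 15, 18), function(tt)
        row(sprintf("t = %g s", tt), 2, tt, ys,
            implant_temperature(A, ld, tt, ys, cfg))))
    },
    "4" = {
      ld <- thermal_load(exposure_time = 2)
      ts <- seq(0, 30, length.out = 301L)
      do.call(rbind, lapply(c("B1", "B2", "B3"), function(p) {
        y <- location_y(p, A)
        row(p, 2, ts, y, implant_temperature(A, ld, ts, y, cfg))
      }))
    },
    "5" = {
      ld <- thermal_load(exposure_time = 2)
      ts <- seq(0, 30, length.out = 301L)
      do.call(rbind, lapply(list(A, B), function(m) {
        y <- location_y("B2", m)
        row(m$label, 2, ts, y, implant_temperature(m, ld, ts, y, cfg))
      }))
    },
    "6" = {
      ts <- seq(0, 70, length.out = 351L)
      y <- location_y("B2", A)
      do.call(rbind, lapply(c(2, 5, 8, 11, 14), function(t0) {
        ld <- thermal_load(exposure_time = t0)
        row(sprintf("t0 = %g s", t0), t0, ts, y,
            implant_temperature(A, ld, ts, y, cfg))
      }))
    },
    "7" = {
      ts <- seq(0, 30, length.out = 301L)
      y <- location_y("B2", B)
      do.call(rbind, lapply(c(1, 2, 3, 5, 6), function(t0) {
        ld <- thermal_load(exposure_time = t0)
        row(sprintf("t0 = %g s", t0), t0, ts, y,
            implant_temperature(B, ld, ts, y, cfg))
      }))
    })
  rownames(out) <- NULL
  out
}

#' Sweep the exposure time and record the peak
#'
#' Runs [peak_temperature()] at a named location for a sequence of exposure
#' times, holding the load endpoint temperatures fixed.  The search horizon
#' is `max(10 * t0, 10 * tau)` per exposure time so late peaks are never
#' clipped.
#'
#' @param model an [implant_model()].
#' @param base_load a [thermal_load()] supplying `t_hot` and `t_body`.
#' @param t0_values positive exposure times in seconds.
#' @param point location name (`"B1"`, `"B2"`, `"B3"`) or numeric position.
#' @param cfg a [series_config()].
#' @return Data frame with columns `t0_s`, `t_peak_s`, `T_peak_C`, ordered
#'   by `t0_s`.
#' @export
exposure_sweep <- function(model, base_load, t0_values, point = "B2",
                           cfg = series_config()) {
  stopifnot(inherits(model, "implant_model"), inherits(base_load, "thermal_load"))
  if (!is.numeric(t0_values) || length(t0_values) < 1L || any(t0_values <= 0))
    stop("'t0_values' must be a non-empty vector of positive exposure times")
  y <- location_y(point, model)
  t0_values <- sort(as.numeric(t0_values))
  rows <- lapply(t0_values, function(t0) {
    ld <- thermal_load(base_load$t_hot, base_load$t_body, t0)
    pk <- peak_temperature(model, ld, y, cfg = cfg)
    data.frame(t0_s = t0, t_peak_s = pk$t_peak, T_peak_C = pk$T_peak)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# dense temperature history at a location over [0, horizon]
.history <- function(model, load, y, horizon, cfg, n = 2001L) {
  ts <- seq(0, horizon, length.out = n)
  list(times = ts, temps = implant_temperature(model, load, ts, y, cfg))
}

#' Time spent above a temperature threshold
#'
#' Measure of `{t : T(t, y) > threshold}` over `[0, horizon]`, computed
#' from a 2001-point history with the crossing times refined by root
#' bracketing ([stats::uniroot()]) inside each sub-interval where the
#' history crosses the threshold.
#'
#' @param model an [implant_model()].
#' @param load a [thermal_load()].
#' @param point location name or numeric position (metres).
#' @param threshold temperature in degC.
#' @param cfg a [series_config()].
#' @param horizon search horizon in seconds; default
#'   `max(10 * t0, 10 * tau)`.
#' @return Duration in seconds (0 when the history never exceeds the
#'   threshold).
#' @export
time_above_threshold <- function(model, load, point, threshold,
                                 cfg = series_config(), horizon = NULL) {
  stopifnot(inherits(model, "implant_model"), inherits(load, "thermal_load"))
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("'threshold' must be a single finite temperature in degC")
  y <- location_y(point, model)
  if (is.null(horizon))
    horizon <- max(10 * load$exposure_time, 10 * intrinsic_time(model))
  h <- .history(model, load, y, horizon, cfg)
  f <- function(t) implant_temperature(model, load, t, y, cfg) - threshold
  above <- h$temps > threshold
  if (!any(above)) return(0)
  total <- 0
  ts <- h$times
  n <- length(ts)
  # walk the sampled history; refine each crossing with uniroot
  entry <- NULL
  for (i in seq_len(n)) {
    if (above[i] && is.null(entry)) {
      entry <- if (i == 1L) ts[1L] else
        stats::uniroot(f, c(ts[i - 1L], ts[i]), tol = 1e-9)$root
    } else if (!above[i] && !is.null(entry)) {
      exit <- stats::uniroot(f, c(ts[i - 1L], ts[i]), tol = 1e-9)$root
      total <- total + (exit - entry)
      entry <- NULL
    }
  }
  if (!is.null(entry)) total <- total + (ts[n] - entry)
  total
}

#' Cumulative thermal dose of a temperature history
#'
#' CEM43 (cumulative equivalent minutes at 43 degC) for a sampled
#' temperature history: `integral R^(43 - T(t)) dt / 60`, with `R = 0.5` at
#' or above 43 degC (time-to-effect halves per degree: 120 min worth of
#' effect per hour at 44 degC) and `R = 0.25` between the 39 degC lower
#' cutoff and 43 degC; temperatures below the cutoff contribute nothing.
#' Trapezoidal accumulation.
#'
#' @param times sample times in seconds, non-decreasing.
#' @param temps temperatures in degC, same length as `times`.
#' @param breakpoint reference temperature, default 43 degC.
#' @param r_above,r_below per-degree factors above/below the breakpoint
#'   (defaults 0.5 and 0.25).
#' @param cutoff temperature below which the dose rate is taken as zero
#'   (default 39 degC).
#' @return Equivalent minutes at 43 degC.
#' @examples
#' cem43_history(c(0, 3600), c(44, 44))  # one hour at 44 degC -> 120 min
#' @export
cem43_history <- function(times, temps, breakpoint = 43, r_above = 0.5,
                          r_below = 0.25, cutoff = 39) {
  if (!is.numeric(times) || !is.numeric(temps) ||
      length(times) != length(temps) || length(times) < 2L ||
      is.unsorted(times))
    stop("'times' and 'temps' must be equal-length vectors, times non-decreasing")
  R <- ifelse(temps >= breakpoint, r_above, r_below)
  rate <- R^(breakpoint - temps)
  rate[temps < cutoff] <- 0
  sum(diff(times) * (rate[-1L] + rate[-length(rate)]) / 2) / 60
}

#' CEM43 thermal dose at an implant location
#'
#' Evaluates the closed-form history at the location on a dense grid (4001
#' points over the horizon) and accumulates [cem43_history()].
#'
#' @inheritParams time_above_threshold
#' @param ... passed on to [cem43_history()] (breakpoint, factors, cutoff).
#' @return Equivalent minutes at 43 degC.
#' @export
cem43 <- function(model, load, point, cfg = series_config(), horizon = NULL,
                  ...) {
  stopifnot(inherits(model, "implant_model"), inherits(load, "thermal_load"))
  y <- location_y(point, model)
  if (is.null(horizon))
    horizon <- max(10 * load$exposure_time, 10 * intrinsic_time(model))
  h <- .history(model, load, y, horizon, cfg, n = 4001L)
  cem43_history(h$times, h$temps, ...)
}

#' Peak and threshold report for one location
#'
#' Bundles the clinically relevant summaries of one location's temperature
#' history: the peak, the time spent above a threshold, and the CEM43 dose.
#'
#' @inheritParams time_above_threshold
#' @param threshold threshold in degC for the time-above metric (default
#'   47, the cortical-bone necrosis threshold; 42 is the osteoblast injury
#'   threshold).
#' @return An object of class `"threshold_report"`: list with `location`,
#'   `y_m`, `t_peak`, `T_peak`, `threshold`, `time_above`, `cem43_minutes`.
#' @export
threshold_report <- function(model, load, point, threshold = 47,
                             cfg = series_config(), horizon = NULL) {
  y <- location_y(point, model)
  if (is.null(horizon))
    horizon <- max(10 * load$exposure_time, 10 * intrinsic_time(model))
  pk <- peak_temperature(model, load, y, horizon, cfg)
  structure(
    list(location = if (is.character(point)) point else sprintf("y=%g m", y),
         y_m = y, t_peak = pk$t_peak, T_peak = pk$T_peak,
         threshold = threshold,
         time_above = time_above_threshold(model, load, point, threshold,
                                           cfg, horizon),
         cem43_minutes = cem43(model, load, point, cfg, horizon)),
    class = "threshold_report"
  )
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf(
    "Location %s (y = %.4g m): peak %.2f degC at t = %.2f s; %.3g s above %g degC; CEM43 = %.3g min\n",
    x$location, x$y_m, x$T_peak, x$t_peak, x$time_above, x$threshold,
    x$cem43_minutes))
  invisible(x)
}
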