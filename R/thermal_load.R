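#' Exponentially decaying oral thermal load
#'
#' Describes the boundary temperature imposed at the oral-cavity end of the
#' implant when a hot (or cold) substance is consumed: the surface starts at
#' \code{t_hot} and relaxes exponentially towards body temperature
#' \code{t_body} with decay constant \code{exposure_time}.  The temperature
#' excess is \code{delta_t(load) = t_hot - t_body} (23 degC for the default
#' hot-beverage scenario, 60 degC down to 37 degC).
#'
#' @param t_hot initial surface temperature in degC (default 60).
#' @param t_body body temperature in degC, the asymptotic value (default 37).
#' @param exposure_time decay constant t0 of the load in seconds; strictly
#'   positive.  The effective duration of the load is roughly `5 * t0`
#'   (see [load_duration()]).
#'
#' @return An object of class `"thermal_load"`.
#' @seealso [load_temperature()], [load_duration()]
#' @examples
#' ld <- thermal_load(exposure_time = 2)
#' load_temperature(ld, c(0, 2, 10))
#' @export
thermal_load <- function(t_hot = 60, t_body = 37, exposure_time) {
  if (!is.numeric(exposure_time) || length(exposure_time) != 1L ||
      !is.finite(exposure_time) || exposure_time <= 0)
    stop("'exposure_time' must be a single finite positive number (seconds)")
  for (nm in c("t_hot", "t_body")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite temperature in degC", nm))
  }
  structure(
    list(t_hot = as.numeric(t_hot), t_body = as.numeric(t_body),
         exposure_time = as.numeric(exposure_time)),
    class = "thermal_load"
  )
}

#' Temperature excess of a thermal load
#'
#' The driving temperature difference `t_hot - t_body`, always recomputed
#' from the stored endpoint temperatures.
#'
#' @param load a [thermal_load()].
#' @return Temperature difference in degC.
#' @export
delta_t <- function(load) {
  stopifnot(inherits(load, "thermal_load"))
  load$t_hot - load$t_body
}

#' Boundary temperature of the oral cavity at time t
#'
#' Evaluates the load `(t_hot - t_body) * exp(-t / t0) + t_body`.  For a hot
#' load this decreases strictly monotonically from `t_hot` at `t = 0` to
#' `t_body` as `t -> Inf`.
#'
#' @param load a [thermal_load()].
#' @param t time(s) in seconds, each `>= 0`; vectorised.
#' @return Temperature(s) in degC, same length as `t`.
#' @export
load_temperature <- function(load, t) {
  stopifnot(inherits(load, "thermal_load"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and >= 0 (seconds)")
  delta_t(load) * exp(-t / load$exposure_time) + load$t_body
}

#' Effective duration of a thermal load
#'
#' The load has decayed to under 1 percent of its initial excess after about
#' five decay constants, so its effective duration is taken as `5 * t0`:
#' 10 s for t0 = 2 s, about 1 s for t0 = 0.2 s.
#'
#' @param load a [thermal_load()].
#' @return Duration in seconds.
#' @export
load_duration <- function(load) {
  stopifnot(inherits(load, "thermal_load"))
  5 * load$exposure_time
}

#' @export
print.thermal_load <- function(x, ...) {
  cat(sprintf(
    "Thermal load: %.6g degC -> %.6g degC, t0 = %.6g s (duration ~ %.6g s, dT = %.6g degC)\n",
    x$t_hot, x$t_body, x$exposure_time, load_duration(x), delta_t(x)))
  invisible(x)
}
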