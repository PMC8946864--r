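#' One-dimensional implant model
#'
#' Geometry and material of the implant, modelled as a homogeneous rod of
#' length `L` (bone end at `y = 0`, oral-cavity end at `y = L`) with a single
#' constant thermal diffusivity `alpha`.  The characteristic diffusion
#' timescale is the intrinsic time `tau = L^2 / (alpha * pi^2)`, the decay
#' time of the slowest spatial mode; see [intrinsic_time()].
#'
#' @param length implant length `L` in metres, strictly positive.
#' @param diffusivity thermal diffusivity `alpha` in m^2/s, strictly positive.
#' @param label optional free-text description.
#'
#' @return An object of class `"implant_model"`.
#' @seealso [preset_model()] for the standard presets.
#' @examples
#' m <- implant_model(length = 0.013, diffusivity = 2e-6)
#' intrinsic_time(m)  # ~ 8.56 s
#' @export
implant_model <- function(length, diffusivity, label = "") {
  for (nm in c("length", "diffusivity")) {
    v <- get(nm)
    if (!is.numeric(v) || base::length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single finite positive number", nm))
  }
  structure(
    list(length = as.numeric(length), diffusivity = as.numeric(diffusivity),
         label = as.character(label)[1L]),
    class = "implant_model"
  )
}

#' Intrinsic time of an implant
#'
#' `tau = L^2 / (alpha * pi^2)`, the diffusive timescale of the implant:
#' the e-folding time of the slowest sine mode of the rod.  The transient
#' solution depends on `L` and `alpha` only through `tau` (together with the
#' fractional position `y / L`).  `tau` is invariant under the rescaling
#' `L -> c L`, `alpha -> c^2 alpha`.
#'
#' @param model an [implant_model()].
#' @return Intrinsic time in seconds.
#' @examples
#' intrinsic_time(implant_model(0.013, 2e-6))  # prints as 8.6 s
#' intrinsic_time(implant_model(0.013, 5e-6))  # prints as 3.4 s
#' @export
intrinsic_time <- function(model) {
  stopifnot(inherits(model, "implant_model"))
  model$length^2 / (model$diffusivity * pi^2)
}

#' @export
print.implant_model <- function(x, ...) {
  cat(sprintf("Implant model%s: L = %.6g m, alpha = %.6g m^2/s, tau = %.4g s\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$length, x$diffusivity, intrinsic_time(x)))
  invisible(x)
}

#' Series truncation and resonance controls
#'
#' Controls evaluation of the Fourier sine series: the number of retained
#' modes and the tolerance under which the resonance-limit formula replaces
#' the general mode-amplitude expression (whose denominator
#' `n^2 t0 / tau - 1` vanishes when `n^2 t0 = tau`).
#'
#' @param n_terms number of series terms, integer `>= 1` (default 200).
#' @param resonance_tol relative tolerance on `|n^2 t0 / tau - 1|` below
#'   which the exact limit formula is used; must lie in `(0, 1e-2)`.
#'   Default `1e-8`.
#'
#' @return An object of class `"series_config"`.
#' @export
series_config <- function(n_terms = 200L, resonance_tol = 1e-8) {
  if (!is.numeric(n_terms) || length(n_terms) != 1L || !is.finite(n_terms) ||
      n_terms < 1 || n_terms != round(n_terms))
    stop("'n_terms' must be a single integer >= 1")
  if (!is.numeric(resonance_tol) || length(resonance_tol) != 1L ||
      !is.finite(resonance_tol) || resonance_tol <= 0 || resonance_tol >= 1e-2)
    stop("'resonance_tol' must lie in (0, 1e-2)")
  structure(list(n_terms = as.integer(n_terms),
                 resonance_tol = as.numeric(resonance_tol)),
            class = "series_config")
}

#' Time/position evaluation grid
#'
#' @param times non-decreasing vector of times in seconds, each `>= 0`.
#' @param positions non-decreasing vector of positions in metres; each must
#'   lie within `[0, L]` of the implant the grid is evaluated on (checked at
#'   evaluation time).
#' @return An object of class `"evaluation_grid"`.
#' @seealso [evaluate_field()]
#' @export
evaluation_grid <- function(times, positions) {
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times)) ||
      any(times < 0) || is.unsorted(times))
    stop("'times' must be a non-empty non-decreasing vector of times >= 0")
  if (!is.numeric(positions) || length(positions) < 1L ||
      any(!is.finite(positions)) || any(positions < 0) ||
      is.unsorted(positions))
    stop("'positions' must be a non-empty non-decreasing vector of positions >= 0")
  structure(list(times = as.numeric(times), positions = as.numeric(positions)),
            class = "evaluation_grid")
}
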