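#' Finite-difference grid specification
#'
#' Grid controls for the Crank-Nicolson oracle [fd_solve()].
#'
#' @param n_space number of interior spatial nodes (default 200; minimum 10).
#' @param dt time step in seconds, or `NULL` (default) to use
#'   `min(tau / 2000, t0 / 50)`: the diffusive timescale resolved with 2000
#'   steps per intrinsic time, capped so the boundary forcing gets at least
#'   50 steps per decay constant when `t0` is short.
#' @param t_end final time in seconds, strictly positive.
#' @return An object of class `"fd_grid_spec"`.
#' @export
fd_grid_spec <- function(n_space = 200L, dt = NULL, t_end) {
  if (!is.numeric(n_space) || length(n_space) != 1L || n_space < 10 ||
      n_space != round(n_space))
    stop("'n_space' must be a single integer >= 10")
  if (!is.null(dt) && (!is.numeric(dt) || length(dt) != 1L || dt <= 0))
    stop("'dt' must be NULL or a single positive time step (seconds)")
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0)
    stop("'t_end' must be a single positive duration (seconds)")
  structure(list(n_space = as.integer(n_space),
                 dt = if (is.null(dt)) NULL else as.numeric(dt),
                 t_end = as.numeric(t_end)),
            class = "fd_grid_spec")
}

#' Crank-Nicolson finite-difference oracle
#'
#' Solves `dT/dt = alpha d^2T/dy^2` on `[0, L]` with the bone end pinned at
#' `t_body`, the oral end following [load_temperature()], and initial
#' condition `t_body` throughout, independently of the closed-form series.
#' The scheme is Crank-Nicolson (second order in space and time,
#' unconditionally stable); the time-dependent Dirichlet value at `y = L`
#' enters each step at the half-step `t + dt/2` (as the mean of the two
#' endpoint values), preserving second-order accuracy.  The first time
#' step is replaced by two implicit-Euler half-steps (Rannacher start-up)
#' to damp the non-smooth `t = 0, y = L` corner, which keeps the discrete
#' solution within the bounds of the boundary data.
#'
#' @param model an [implant_model()].
#' @param load a [thermal_load()].
#' @param spec an [fd_grid_spec()].
#' @return A `"temperature_field"` with `method = "finite_difference"` on
#'   the uniform grid, including both boundary columns.
#' @export
fd_solve <- function(model, load, spec) {
  stopifnot(inherits(model, "implant_model"), inherits(load, "thermal_load"),
            inherits(spec, "fd_grid_spec"))
  L <- model$length
  alpha <- model$diffusivity
  N <- spec$n_space
  dt <- spec$dt
  if (is.null(dt))
    dt <- min(intrinsic_time(model) / 2000, load$exposure_time / 50)
  nsteps <- ceiling(spec$t_end / dt)
  times <- dt * (0:nsteps)
  dy <- L / (N + 1)
  y <- dy * (0:(N + 1))
  lam <- alpha * dt / dy^2

  # interior second-difference operator
  A <- diag(-2, N)
  idx <- seq_len(N - 1)
  A[cbind(idx, idx + 1)] <- 1
  A[cbind(idx + 1, idx)] <- 1

  I <- diag(N)
  Minv_cn <- solve(I - (lam / 2) * A)   # Crank-Nicolson implicit operator
  Mexp_cn <- I + (lam / 2) * A
  Minv_be <- Minv_cn  # implicit Euler over dt/2 has the same implicit operator

  T2 <- load$t_body
  gL <- function(t) load_temperature(load, t)

  V <- matrix(NA_real_, nrow = nsteps + 1L, ncol = N + 2L)
  V[1L, ] <- T2
  V[1L, N + 2L] <- gL(0)
  u <- rep(T2, N)

  step_cn <- function(u, t) {
    # boundary contribution averaged over the step: lam * g(t + dt/2) to
    # second order, written as the mean of the endpoint values
    b <- numeric(N)
    b[1L] <- lam * T2          # bone end, constant on both sides
    b[N] <- (lam / 2) * (gL(t) + gL(t + dt))
    Minv_cn %*% (Mexp_cn %*% u + b)
  }
  step_be_half <- function(u, tnew) {
    # implicit Euler over dt/2: (I - (lam/2) A) u_new = u + (lam/2) bc(tnew)
    b <- numeric(N)
    b[1L] <- (lam / 2) * T2
    b[N] <- (lam / 2) * gL(tnew)
    Minv_be %*% (u + b)
  }

  for (m in seq_len(nsteps)) {
    if (m == 1L) {
      u <- step_be_half(u, times[1L] + dt / 2)
      u <- step_be_half(u, times[2L])
    } else {
      u <- step_cn(u, times[m])
    }
    V[m + 1L, ] <- c(T2, u, gL(times[m + 1L]))
  }
  temperature_field(times, y, V, "finite_difference", model, load, spec)
}

#' Integrate the mode-amplitude ODE numerically
#'
#' Independent verification of the closed-form mode amplitudes: integrates
#' \deqn{C_n'(t) + \alpha (n\pi/L)^2 C_n(t) =
#'   \frac{\Delta T A_n}{L t_0} e^{-t/t_0}, \qquad
#'   C_n(0) = -\Delta T A_n / L,}
#' with classical fixed-step fourth-order Runge-Kutta (via
#' [deSolve::rk4()]); the step is `tau / (1000 n^2)` so it shrinks with the
#' mode's decay rate.  The closed form satisfies
#' `C_n(t) = (2 dT / pi) * D_n(t)` (see [mode_amplitude()]).
#'
#' @param n mode index, single integer `>= 1`.
#' @param model an [implant_model()].
#' @param load a [thermal_load()].
#' @param times non-decreasing output times in seconds starting at 0.
#' @return Numeric vector of `C_n` values at `times`.
#' @export
integrate_mode_ode <- function(n, model, load, times) {
  stopifnot(inherits(model, "implant_model"), inherits(load, "thermal_load"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a single integer >= 1")
  if (!is.numeric(times) || length(times) < 1L || any(times < 0) ||
      is.unsorted(times) || times[1L] != 0)
    stop("'times' must be non-decreasing and start at 0")
  tau <- intrinsic_time(model)
  t0 <- load$exposure_time
  L <- model$length
  lambda <- n^2 / tau                      # = alpha (n pi / L)^2
  An <- fourier_coefficient(n, L)
  amp <- delta_t(load) * An / (L * t0)
  C0 <- -delta_t(load) * An / L
  h <- tau / (1000 * n^2)
  grid <- sort(unique(c(seq(0, max(times), by = h), max(times), times)))
  deriv <- function(t, y, parms) list(-lambda * y + amp * exp(-t / t0))
  out <- deSolve::rk4(y = c(C = C0), times = grid, func = deriv, parms = NULL)
  idx <- findInterval(times, out[, 1L])
  # grid contains every requested time exactly
  out[idx, 2L]
}

#' Compare two temperature fields
#'
#' Reports the maximum-absolute and root-mean-square discrepancy between two
#' fields of the same model and load, together with the grid point where the
#' maximum occurs.  When the grids differ, `b` is interpolated onto `a`'s
#' grid bilinearly (linear in time, then linear in position); extrapolation
#' is refused.
#'
#' @param a,b `"temperature_field"` objects with matching model and load.
#' @return An object of class `"field_error_report"` with `max_abs`, `rms`
#'   (degC), `location_of_max` (named `t`, `y`), and `interpolated`.
#' @export
field_error <- function(a, b) {
  stopifnot(inherits(a, "temperature_field"), inherits(b, "temperature_field"))
  ma <- a$model; mb <- b$model
  la <- a$load; lb <- b$load
  if (!isTRUE(all.equal(c(ma$length, ma$diffusivity), c(mb$length, mb$diffusivity))) ||
      !isTRUE(all.equal(unlist(la[c("t_hot", "t_body", "exposure_time")]),
                        unlist(lb[c("t_hot", "t_body", "exposure_time")]))))
    stop("fields have incompatible provenance (different model or load)")
  same <- length(a$times) == length(b$times) &&
    length(a$positions) == length(b$positions) &&
    all(a$times == b$times) && all(a$positions == b$positions)
  if (same) {
    Vb <- b$values
  } else {
    if (min(a$times) < min(b$times) || max(a$times) > max(b$times) ||
        min(a$positions) < min(b$positions) || max(a$positions) > max(b$positions))
      stop("grid of 'a' extends beyond 'b'; refusing to extrapolate")
    # interpolate b onto a's grid: time first, then position
    Vt <- apply(b$values, 2L, function(col)
      stats::approx(b$times, col, xout = a$times)$y)
    Vt <- matrix(Vt, nrow = length(a$times))
    Vb <- t(apply(Vt, 1L, function(row)
      stats::approx(b$positions, row, xout = a$positions)$y))
    Vb <- matrix(Vb, nrow = length(a$times))
  }
  d <- abs(a$values - Vb)
  i <- arrayInd(which.max(d), dim(d))
  structure(
    list(max_abs = max(d), rms = sqrt(mean(d^2)),
         location_of_max = c(t = a$times[i[1L]], y = a$positions[i[2L]]),
         interpolated = !same),
    class = "field_error_report"
  )
}

#' @export
print.field_error_report <- function(x, ...) {
  cat(sprintf("Field error: max |dT| = %.3g degC at (t = %.4g s, y = %.4g m), rms = %.3g degC%s\n",
              x$max_abs, x$location_of_max[["t"]], x$location_of_max[["y"]],
              x$rms, if (x$interpolated) " [b interpolated onto a's grid]" else ""))
  invisible(x)
}
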