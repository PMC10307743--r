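#' Right-hand side of the dimensionless growth/radiotherapy system
#'
#' Evaluates the four time-derivatives of the model state
#' `(T, TS, TR, c)`: undamaged viable volume, sub-lethally damaged volume,
#' lethally damaged (dead) volume and oxygen concentration. `T` and `TS`
#' proliferate into free space `1 - Sigma` (with `Sigma = T + TS + TR + V0`),
#' die from nutrient starvation when `c <= c_min`, and during irradiation
#' (dose rate `R > 0`) are damaged at rates proportional to `c * R`.
#' Sub-lethal damage is repaired at rate `mu`, accumulates into lethal damage
#' at rate `lamS * c * R`, or leads to death by mitotic catastrophe at rate
#' `xi`; dead material is cleared at rate `etaR`. Oxygen is supplied by the
#' vasculature at rate `g * (1 - c) * V0` and consumed for maintenance by
#' `T + theta1 * TS` and for proliferation by `T + theta2 * TS`.
#'
#' This R implementation is the readable reference; the integrator uses an
#' identical compiled version.
#'
#' @param state Numeric vector `c(T, TS, TR, c)` (names optional). Must be
#'   non-negative with `0 <= c <= 1`.
#' @param t Time (minutes). Unused by the autonomous right-hand side itself
#'   (time dependence enters through `R`), kept for the integrator signature.
#' @param params An [rt_params] object.
#' @param R Dimensionless dose rate (non-negative scalar); 0 outside
#'   irradiation windows.
#' @return Named numeric vector `c(dT, dTS, dTR, dc)`.
#' @examples
#' p <- rt_params(0.5, 5, 0.003)
#' rt_rhs(c(T = 0.1, TS = 0, TR = 0, c = 0.5), params = p, R = 0.2)
#' @export
rt_rhs <- function(state, t = 0, params, R = 0) {
  stopifnot(inherits(params, "rt_params"))
  validate_state(state, params)
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R < 0) {
    abort("`R` must be a single non-negative dose rate.")
  }
  T <- state[[1]]; TS <- state[[2]]; TR <- state[[3]]; cc <- state[[4]]
  p <- params
  Sigma <- T + TS + TR + p$V0
  starv <- (p$c_min - cc) * heaviside(p$c_min - cc)
  dT  <- p$q2 * cc * T * (1 - Sigma) -
    (p$delta1 * starv + p$lam * cc * R + p$nu * cc * R) * T + p$mu * TS
  dTS <- p$theta2 * p$q2 * cc * TS * (1 - Sigma) -
    (p$delta1S * starv + p$lamS * cc * R + p$mu + p$xi) * TS + p$nu * cc * R * T
  dTR <- p$lam * cc * R * T + (p$xi + p$lamS * cc * R) * TS - p$etaR * TR
  dc  <- p$g * (1 - cc) * p$V0 - p$q1 * (T + p$theta1 * TS) * cc -
    p$q3 * (T + p$theta2 * TS) * cc * (1 - Sigma)
  c(dT = dT, dTS = dTS, dTR = dTR, dc = dc)
}

validate_state <- function(state, params = NULL, check_sigma = FALSE) {
  if (!is.numeric(state) || length(state) != 4L || any(!is.finite(state))) {
    abort("`state` must be a finite numeric vector (T, TS, TR, c).")
  }
  if (any(state[1:3] < 0)) abort("Volumes T, TS, TR must be non-negative.")
  if (state[[4]] < 0 || state[[4]] > 1) abort("Oxygen c must lie in [0, 1].")
  if (check_sigma && !is.null(params) &&
      sum(state[1:3]) + params$V0 > 1 + 1e-9) {
    abort("Initial state violates T + TS + TR + V0 <= 1.")
  }
  invisible(state)
}

# Parameter vector layout shared with src/rt_derivs.c (order matters).
pack_parms <- function(params, R = 0) {
  c(params$q1, params$q3, params$V0, params$c_min, params$g,
    params$q2, params$delta1, params$delta1S, params$theta1, params$theta2,
    params$nu, params$lam, params$lamS, params$mu, params$xi, params$etaR, R)
}
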