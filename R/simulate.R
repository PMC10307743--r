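#' Pre-treatment equilibrium state
#'
#' The initial condition for treatment simulations is the treatment-free
#' equilibrium `(T*, 0, 0, c*)`. Monostable tumours start at their unique
#' admissible equilibrium; bistable tumours start at the NL equilibrium,
#' the attractor of physically realistic small initial tumours.
#'
#' @param params An [rt_params] object.
#' @return A list with `T` and `c`.
#' @export
pretreatment_state <- function(params) {
  regime <- classify_regime(params)
  ss <- if (regime == "SL") sl_steady_state(params) else nl_steady_state(params)
  list(T = ss$T, c = ss$c)
}

# Output grid for one integration segment [t0, t1]: segment endpoints, a
# coarse interior grid, and a fine grid where t overlaps [dense_from, dense_to].
segment_times <- function(t0, t1, coarse, dense_from, dense_to, dense_by = 1) {
  tt <- seq(t0, t1, by = coarse)
  if (dense_from < t1 && dense_to > t0) {
    lo <- max(t0, dense_from); hi <- min(t1, dense_to)
    tt <- c(tt, seq(lo, hi, by = dense_by))
  }
  sort(unique(c(tt, t1)))
}

# Piecewise integration of the model between dose-rate breakpoints. The dose
# rate is constant on each segment, so the integrator is restarted at every
# irradiation window boundary where R(t) jumps. Within a segment the only
# non-smoothness is the C0 starvation switch at c = c_min, which the
# adaptive error control resolves without event handling.
integrate_model <- function(params, schedule, t_end, y0,
                            rtol = 1e-8, atol = 1e-10, method = "ode45",
                            dense_from = Inf, dense_to = Inf) {
  w <- schedule$windows
  w <- w[w$start < t_end, , drop = FALSE]
  breaks <- sort(unique(c(0, w$start, pmin(w$end, t_end), t_end)))
  coarse <- max(10, min(60, ceiling(t_end / 3000)))
  in_window <- function(tm) any(w$start <= tm & tm < w$end)

  y <- y0
  pieces <- vector("list", length(breaks) - 1)
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1]
    R <- if (nrow(w) > 0 && in_window((t0 + t1) / 2)) schedule$R_value else 0
    seg_coarse <- if (R > 0) min(coarse, schedule$delta_R / 4) else coarse
    tt <- segment_times(t0, t1, seg_coarse, dense_from, dense_to)
    sol <- deSolve::ode(y = y, times = tt, func = "rt_derivs",
                        parms = pack_parms(params, R),
                        dllname = "rtresponse", initfunc = "rt_initmod",
                        method = method, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      abort(paste0("Integrator failed on segment [", t0, ", ", t1,
                   "]; istate = ", attr(sol, "istate")[1]))
    }
    y <- sol[nrow(sol), 2:5]
    keep <- if (i == 1) seq_len(nrow(sol)) else seq(2, nrow(sol))
    pieces[[i]] <- cbind(sol[keep, , drop = FALSE], R = R)
  }
  out <- do.call(rbind, pieces)
  colnames(out) <- c("t_min", "T", "TS", "TR", "c", "R")
  out
}

new_trajectory <- function(mat, params, schedule, solver) {
  traj <- as_tibble(as.data.frame(mat))
  traj$Sigma <- traj$T + traj$TS + traj$TR + params$V0
  traj <- traj[, c("t_min", "T", "TS", "TR", "c", "Sigma", "R")]
  # event log: fraction window boundaries and c_min crossings (sign changes
  # of c - c_min located by linear interpolation on the dense output)
  w <- schedule$windows[schedule$windows$start <= max(traj$t_min), , drop = FALSE]
  ev <- dplyr::bind_rows(
    tibble(time = w$start, event = "fraction_start"),
    tibble(time = w$end, event = "fraction_end"))
  s <- traj$c - params$c_min
  idx <- which(s[-1] * s[-length(s)] < 0)
  if (length(idx) > 0) {
    tcross <- traj$t_min[idx] - s[idx] *
      (traj$t_min[idx + 1] - traj$t_min[idx]) / (s[idx + 1] - s[idx])
    ev <- dplyr::bind_rows(ev, tibble(time = tcross, event = "c_min_crossing"))
  }
  structure(traj,
            params = params, schedule = schedule, solver = solver,
            events = dplyr::arrange(ev, .data$time),
            class = c("rt_trajectory", class(traj)))
}

#' Simulate treatment-free tumour growth
#'
#' Integrates the model with `R == 0` from a small initial tumour
#' (by default `(T, TS, TR, c) = (0.05, 0, 0, 1)`). Over a long horizon the
#' trajectory converges to the admissible equilibrium of the tumour's
#' regime (the NL state for bistable tumours started small).
#'
#' @param params An [rt_params] object.
#' @param initial_state Numeric `(T, TS, TR, c)` satisfying the state
#'   invariants (non-negative volumes, `c` in `[0, 1]`, total `<= 1`).
#' @param t_end Horizon in minutes (dimensionless time units).
#' @param rtol,atol Integrator tolerances.
#' @param method `deSolve` method; the default is the Dormand-Prince
#'   Runge-Kutta 4(5) pair.
#' @return An `rt_trajectory`: a tibble with columns `t_min`, `T`, `TS`,
#'   `TR`, `c`, `Sigma`, `R` and attributes `params`, `schedule`, `solver`
#'   and `events`.
#' @examples
#' \donttest{
#' traj <- simulate_growth(rt_params(0.5, 5, 0.0005), t_end = 2e5)
#' tail(traj, 1)  # near the NL equilibrium
#' }
#' @export
simulate_growth <- function(params, initial_state = c(T = 0.05, TS = 0, TR = 0, c = 1),
                            t_end = 2e5, rtol = 1e-8, atol = 1e-10,
                            method = "ode45") {
  stopifnot(inherits(params, "rt_params"), t_end > 0)
  validate_state(initial_state, params, check_sigma = TRUE)
  schedule <- rt_null_schedule()
  mat <- integrate_model(params, schedule, t_end, initial_state,
                         rtol = rtol, atol = atol, method = method)
  new_trajectory(mat, params, schedule,
                 list(method = method, rtol = rtol, atol = atol))
}

#' Simulate tumour response to a fractionation schedule
#'
#' Integrates the model under the piecewise-constant dose rate of
#' `schedule`, restarting the integrator at every irradiation window
#' boundary where `R(t)` is discontinuous. Output is sampled at least every
#' minute across the final treatment week so last-week time averages are
#' quadrature-accurate, and at least once inside every fraction window.
#' By default the initial condition is the pre-treatment equilibrium
#' `(T*, 0, 0, c*)` from [pretreatment_state()].
#'
#' @param params An [rt_params] object.
#' @param schedule An [rt_schedule]; the untreated control
#'   [rt_null_schedule()] reproduces [simulate_growth()] exactly.
#' @param t_end Horizon in minutes; defaults to the end of the final
#'   treatment week. Must not end before the last fraction window.
#' @param initial_state Optional `(T, TS, TR, c)` override.
#' @param rtol,atol,method As in [simulate_growth()].
#' @return An `rt_trajectory` (see [simulate_growth()]).
#' @examples
#' \donttest{
#' p <- rt_params(1.08, 8.83, 0.005)  # space-limited tumour
#' traj <- simulate_treatment(p, rt_schedule(2, 5))
#' response_summary(p, rt_schedule(2, 5), traj)
#' }
#' @export
simulate_treatment <- function(params, schedule, t_end = NULL,
                               initial_state = NULL,
                               rtol = 1e-8, atol = 1e-10, method = "ode45") {
  stopifnot(inherits(params, "rt_params"), inherits(schedule, "rt_schedule"))
  t_end <- t_end %||% max(schedule$t_end_week, 1)
  if (schedule$n_fractions > 0 && t_end < max(schedule$windows$end)) {
    abort("`t_end` must reach at least the end of the last fraction window.")
  }
  if (is.null(initial_state)) {
    ss <- pretreatment_state(params)
    initial_state <- c(T = ss$T, TS = 0, TR = 0, c = ss$c)
  }
  validate_state(initial_state, params, check_sigma = TRUE)
  dense_from <- if (schedule$n_fractions > 0) schedule$t_end_week - 10080 else Inf
  dense_to <- if (schedule$n_fractions > 0) schedule$t_end_week else Inf
  mat <- integrate_model(params, schedule, t_end, initial_state,
                         rtol = rtol, atol = atol, method = method,
                         dense_from = dense_from, dense_to = dense_to)
  new_trajectory(mat, params, schedule,
                 list(method = method, rtol = rtol, atol = atol))
}

#' @export
print.rt_trajectory <- function(x, ...) {
  p <- attr(x, "params"); s <- attr(x, "schedule")
  cat(sprintf("<rt_trajectory> %d samples over [0, %g] min (q1 = %g, q3 = %g, V0 = %g; %s)\n",
              nrow(x), max(x$t_min), p$q1, p$q3, p$V0,
              if (s$n_fractions == 0) "untreated"
              else sprintf("%g Gy x %d", s$D, s$n_fractions)))
  NextMethod()
}

#' @rdname simulate_growth
#' @param x An `rt_trajectory`.
#' @param ... Unused.
#' @export
glance.rt_trajectory <- function(x, ...) {
  last <- x[nrow(x), ]
  tibble(t_end = last$t_min, T_end = last$T, TS_end = last$TS,
         TR_end = last$TR, c_end = last$c, Sigma_end = last$Sigma,
         max_Sigma = max(x$Sigma), min_state = min(last$T, last$TS, last$TR),
         n_samples = nrow(x))
}

#' Post-treatment attractor of a treated tumour
#'
#' Continues the treated trajectory well beyond the end of the protocol
#' (with `R == 0` after the last fraction) and labels the terminal state by
#' its nearest admissible equilibrium. Monostable tumours always return to
#' their pre-treatment state; bistable tumours either return to the NL
#' state or switch to the larger SL state when treatment pushes them out of
#' the NL basin of attraction.
#'
#' @param params An [rt_params] object.
#' @param schedule An [rt_schedule].
#' @param t_end Long horizon in minutes (default 2.5e5).
#' @param match_tol Matching tolerance (default 1e-4) on
#'   `|T + TS + TR - T*|`: the total cell volume is compared because the
#'   dead compartment clears on the slowest timescale (`1/etaR`) and its
#'   residual transiently occupies space at the equilibrium it converges
#'   to. The oxygen level must also fall on the equilibrium's side of
#'   `c_min`. The equilibria are separated by order 0.1-0.9 in `T`, so the
#'   tolerance is conservative.
#' @param damage_tol Residual `TS`, `TR` allowed at the terminal state
#'   (default 1e-3; the residual is still decaying exponentially).
#' @param ... Passed to [simulate_treatment()].
#' @return `"NL"` or `"SL"`; `"unresolved"` (with a warning advising a
#'   longer horizon) when the terminal state matches neither equilibrium.
#' @export
post_treatment_attractor <- function(params, schedule, t_end = 2.5e5,
                                     match_tol = 1e-4, damage_tol = 1e-3, ...) {
  traj <- simulate_treatment(params, schedule, t_end = t_end, ...)
  classify_terminal_state(params, unlist(traj[nrow(traj), c("T", "TS", "TR", "c")]),
                          match_tol = match_tol, damage_tol = damage_tol)
}

classify_terminal_state <- function(params, state, match_tol = 1e-4,
                                    damage_tol = 1e-3) {
  if (state[[2]] > damage_tol || state[[3]] > damage_tol) {
    warn("Damaged compartments have not decayed; attractor unresolved (integrate longer).")
    return("unresolved")
  }
  total <- state[[1]] + state[[2]] + state[[3]]
  nl <- nl_steady_state(params); sl <- sl_steady_state(params)
  if (nl$admissible && abs(total - nl$T) < match_tol && state[[4]] < params$c_min) {
    return("NL")
  }
  if (sl$admissible && abs(total - sl$T) < match_tol && state[[4]] >= params$c_min) {
    return("SL")
  }
  warn(sprintf(
    "Terminal state (T = %.6g, c = %.6g) matches no admissible equilibrium; unresolved (integrate longer).",
    state[[1]], state[[4]]))
  "unresolved"
}
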