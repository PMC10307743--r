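#' Space-limited (SL) equilibrium
#'
#' The SL steady state is reached when proliferation ceases for lack of
#' space, with no cell death: `T* = 1 - V0` and the oxygen balance gives the
#' closed form `c* = g V0 / (g V0 + q1 (1 - V0))`. The state is admissible
#' (physically attainable in the SL regime) iff `c* >= c_min`.
#'
#' @param params An [rt_params] object.
#' @return A list with `T`, `c` and logical `admissible`.
#' @examples
#' sl_steady_state(rt_params(0.5, 5, 0.003))  # admissible, c* ~ 0.0292
#' @export
sl_steady_state <- function(params) {
  stopifnot(inherits(params, "rt_params"))
  T_star <- 1 - params$V0
  c_star <- params$g * params$V0 / (params$g * params$V0 + params$q1 * T_star)
  list(T = T_star, c = c_star, admissible = c_star >= params$c_min)
}

# NL equilibrium core. With TS = TR = 0 and the starvation switch active,
# the two stationarity relations reduce to
#   c = r * c_min / ((1 - Sigma) + r),  r = delta1 / q2,
# and a quadratic in T:
#   r*c_min*q3 * T^2 - T*(g*V0 + r*c_min*(q1 + q3*(1 - V0)))
#                    + g*V0*(1 - V0 + r*(1 - c_min)) = 0.
# `p` needs fields q1, q3, V0, g, c_min, q2, delta1 only.
nl_roots <- function(p) {
  r <- p$delta1 / p$q2
  a <- r * p$c_min * p$q3
  b <- -(p$g * p$V0 + r * p$c_min * (p$q1 + p$q3 * (1 - p$V0)))
  d <- p$g * p$V0 * (1 - p$V0 + r * (1 - p$c_min))
  disc <- b^2 - 4 * a * d
  if (disc < 0) return(numeric(0))
  sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
}

nl_c_of_T <- function(p, T) {
  r <- p$delta1 / p$q2
  r * p$c_min / ((1 - T - p$V0) + r)
}

# Jacobian (central differences) of the reduced 2-variable treatment-free
# system at (T, c) with the starvation term active; stable iff all
# eigenvalue real parts < -1e-12.
nl_stable <- function(p, T, cc, h = 1e-7) {
  f <- function(T, cc) {
    starv <- (p$c_min - cc) * (p$c_min - cc >= 0)
    u <- 1 - T - p$V0
    c(p$q2 * cc * T * u - p$delta1 * starv * T,
      p$g * (1 - cc) * p$V0 - p$q1 * T * cc - p$q3 * T * cc * u)
  }
  J <- cbind((f(T + h, cc) - f(T - h, cc)) / (2 * h),
             (f(T, cc + h) - f(T, cc - h)) / (2 * h))
  all(Re(eigen(J, only.values = TRUE)$values) < -1e-12)
}

nl_solve <- function(p) {
  roots <- nl_roots(p)
  roots <- roots[roots > 0 & roots <= 1 - p$V0]
  for (T_star in roots) {       # smaller root first; at most one is stable
    c_star <- nl_c_of_T(p, T_star)
    if (c_star >= 0 && c_star < p$c_min && nl_stable(p, T_star, c_star)) {
      return(list(T = T_star, c = c_star, admissible = TRUE))
    }
  }
  list(T = NA_real_, c = NA_real_, admissible = FALSE)
}

#' Nutrient-limited (NL) equilibrium
#'
#' The NL steady state balances proliferation against starvation-driven
#' death, with oxygen below the anoxic threshold `c_min`. With the default
#' coupling `delta1 = q2` the stationarity relations give
#' `c* = c_min / (2 - Sigma*)` and a quadratic for `T*`; the stable root
#' (negative-real-part eigenvalues of the reduced Jacobian) is returned.
#' Admissibility requires `0 <= T* <= 1 - V0` and `c* < c_min` (the latter
#' holds automatically whenever `Sigma* < 1`).
#'
#' @param params An [rt_params] object.
#' @return A list with `T`, `c` and logical `admissible` (`T` and `c` are
#'   `NA` when no admissible stable NL state exists).
#' @examples
#' nl_steady_state(rt_params(0.5, 5, 0.0005))  # admissible
#' nl_steady_state(rt_params(0.5, 5, 0.003))   # inadmissible: SL-only point
#' @export
nl_steady_state <- function(params) {
  stopifnot(inherits(params, "rt_params"))
  nl_solve(params)
}

#' Vascular threshold below which only the NL state exists
#'
#' `V_N` is the vascular volume at which the SL oxygen level equals the
#' anoxic threshold: `V_N = c_min q1 / (g (1 - c_min) + c_min q1)`. For
#' `V0 <= V_N` only the NL equilibrium is admissible. `V_N` is independent
#' of `q3` and strictly increasing in `q1`.
#'
#' @param q1 Maintenance oxygen consumption rate.
#' @param g Oxygen exchange rate (default 5).
#' @param c_min Anoxic threshold (default 1e-2).
#' @return The threshold vascular volume fraction.
#' @examples
#' vn_threshold(0.5)  # ~1.009e-3
#' @export
vn_threshold <- function(q1, g = 5, c_min = 1e-2) {
  stopifnot(q1 > 0, g > 0, c_min > 0)
  c_min * q1 / (g * (1 - c_min) + c_min * q1)
}

#' Vascular threshold above which only the SL state exists
#'
#' `V_S` is the supremum of vascular volumes for which an admissible NL
#' state exists; for `V_N < V0 < V_S` the NL and SL equilibria coexist
#' (bistable window). It is located by bisection on the NL-admissibility
#' predicate, which is monotone in `V0` by the fold structure of the
#' bifurcation diagram. When `q3` is not sufficiently large relative to
#' `q1` no bistable window exists and `NA` is returned.
#'
#' @param q1,q3 Oxygen consumption rates.
#' @param g,c_min,k Environment parameters (defaults as in [rt_params]).
#' @param tol Absolute bisection tolerance in `V0` (default 1e-9).
#' @return The threshold `V_S`, or `NA` when undefined.
#' @examples
#' vs_threshold(0.5, 5)    # bistable window exists
#' vs_threshold(0.5, 0.5)  # NA: no bistable window
#' @export
vs_threshold <- function(q1, q3, g = 5, c_min = 1e-2, k = 1e-2, tol = 1e-9) {
  stopifnot(q1 > 0, q3 > 0, g > 0, c_min > 0)
  p0 <- list(q1 = q1, q3 = q3, g = g, c_min = c_min, q2 = k * q3, delta1 = k * q3)
  adm <- function(V0) nl_solve(modifyList(p0, list(V0 = V0)))$admissible
  vn <- vn_threshold(q1, g, c_min)
  lo <- vn * (1 + 1e-9)
  if (!adm(lo)) return(NA_real_)       # NL admissibility ends at V_N: no window
  hi <- 2 * lo
  while (adm(hi)) {
    hi <- 2 * hi
    if (hi > 1) return(NA_real_)       # no fold found in the physical range
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (adm(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Classify the growth regime of a parameter set
#'
#' Labels a tumour NL (only the nutrient-limited equilibrium is admissible),
#' SL (only the space-limited equilibrium) or BS (both coexist; small
#' tumours then grow to the NL state).
#'
#' @param params An [rt_params] object.
#' @return One of `"NL"`, `"SL"`, `"BS"`.
#' @examples
#' classify_regime(rt_params(0.5, 5, 0.0005))  # "NL"
#' classify_regime(rt_params(0.5, 5, 0.0015))  # "BS"
#' classify_regime(rt_params(0.5, 5, 0.003))   # "SL"
#' @export
classify_regime <- function(params) {
  stopifnot(inherits(params, "rt_params"))
  nl <- nl_solve(params)$admissible
  sl <- sl_steady_state(params)$admissible
  if (nl && sl) return("BS")
  if (nl) return("NL")
  if (sl) return("SL")
  abort("No admissible equilibrium: model violation for these parameters.")
}

#' Proximity index of a bistable tumour
#'
#' For a tumour in the bistable window, `V_d = (V0 - V_N) / (V_S - V_N)`
#' measures where it sits: `V_d -> 0` approaching the NL-only regime and
#' `V_d -> 1` approaching the SL-only regime.
#'
#' @param params An [rt_params] object in the BS regime.
#' @return `V_d` in (0, 1). Calling outside the BS regime is an error that
#'   names the actual regime.
#' @examples
#' vd_index(rt_params(4.55e-2, 7.94, 0.00275))  # ~0.993
#' @export
vd_index <- function(params) {
  regime <- classify_regime(params)
  if (regime != "BS") {
    abort(paste0("`vd_index()` requires the BS regime; these parameters are ", regime, "."))
  }
  vn <- vn_threshold(params$q1, params$g, params$c_min)
  vs <- vs_threshold(params$q1, params$q3, params$g, params$c_min, params$k)
  (params$V0 - vn) / (vs - vn)
}

#' Full steady-state report for a parameter set
#'
#' Collects the admissible equilibria, the regime label, the vascular
#' thresholds `V_N` and `V_S`, and (in the bistable regime) the proximity
#' index `V_d`.
#'
#' @param params An [rt_params] object.
#' @return An object of class `rt_steady_state_report`; `tidy()` turns it
#'   into a one-row tibble.
#' @examples
#' tidy(steady_state_report(rt_params(0.5, 5, 0.0015)))
#' @export
steady_state_report <- function(params) {
  stopifnot(inherits(params, "rt_params"))
  nl <- nl_solve(params)
  sl <- sl_steady_state(params)
  regime <- classify_regime(params)
  vn <- vn_threshold(params$q1, params$g, params$c_min)
  vs <- vs_threshold(params$q1, params$q3, params$g, params$c_min, params$k)
  vd <- if (regime == "BS") (params$V0 - vn) / (vs - vn) else NA_real_
  structure(list(params = params, regime = regime,
                 nl = nl, sl = sl, V_N = vn, V_S = vs, V_d = vd),
            class = "rt_steady_state_report")
}

#' @export
print.rt_steady_state_report <- function(x, ...) {
  cat(sprintf("<rt_steady_state_report> regime %s (q1 = %g, q3 = %g, V0 = %g)\n",
              x$regime, x$params$q1, x$params$q3, x$params$V0))
  if (x$nl$admissible) cat(sprintf("  NL: T* = %.6g, c* = %.6g\n", x$nl$T, x$nl$c))
  if (x$sl$admissible) cat(sprintf("  SL: T* = %.6g, c* = %.6g\n", x$sl$T, x$sl$c))
  cat(sprintf("  V_N = %.6g, V_S = %s%s\n", x$V_N,
              ifelse(is.na(x$V_S), "undefined", format(x$V_S, digits = 6)),
              ifelse(is.na(x$V_d), "", sprintf(", V_d = %.4g", x$V_d))))
  invisible(x)
}

#' @rdname steady_state_report
#' @param x An `rt_steady_state_report`.
#' @param ... Unused.
#' @export
tidy.rt_steady_state_report <- function(x, ...) {
  tibble(q1 = x$params$q1, q3 = x$params$q3, V0 = x$params$V0,
         regime = x$regime,
         T_star_NL = if (x$nl$admissible) x$nl$T else NA_real_,
         c_star_NL = if (x$nl$admissible) x$nl$c else NA_real_,
         T_star_SL = if (x$sl$admissible) x$sl$T else NA_real_,
         c_star_SL = if (x$sl$admissible) x$sl$c else NA_real_,
         V_N = x$V_N, V_S = x$V_S, V_d = x$V_d)
}

#' Regime map over a (q3, V0) grid
#'
#' Classifies every point of a rectangular `(q3, V0)` grid at fixed `q1`,
#' reproducing the regime-diagram content as a tidy table.
#'
#' @param q1 Fixed maintenance consumption rate.
#' @param q3 Numeric vector of proliferation consumption rates.
#' @param V0 Numeric vector of vascular volume fractions.
#' @param ... Extra parameters passed to [rt_params()].
#' @return A tibble with columns `q1`, `q3`, `V0`, `regime`, `V_N`, `V_S`,
#'   `V_d`.
#' @export
regime_map <- function(q1, q3, V0, ...) {
  grid <- tidyr::expand_grid(q3 = q3, V0 = V0)
  purrr::pmap_dfr(grid, function(q3, V0) {
    tidy(steady_state_report(rt_params(q1 = q1, q3 = q3, V0 = V0, ...)))
  })
}

#' Check that a converged state carries no radiation damage
#'
#' The model admits no equilibrium with damaged material: every NL or SL
#' steady state has `TS* = TR* = 0`, so any long-run post-treatment state
#' must shed all sub-lethal and lethal damage. This verifies that property
#' on a numerically converged state (a regression check of the result, not
#' a proof).
#'
#' @param params An [rt_params] object.
#' @param state Numeric state `(T, TS, TR, c)` at the end of a long
#'   treatment-free integration.
#' @param tol Tolerance on `TS` and `TR` (default 1e-8).
#' @param rhs_tol Convergence requirement: all components of the
#'   treatment-free right-hand side must be below this (default 1e-9),
#'   otherwise the state is rejected as non-converged.
#' @return `TRUE` iff `TS` and `TR` are below `tol` at the converged state.
#' @export
verify_no_damaged_steady_state <- function(params, state, tol = 1e-8,
                                           rhs_tol = 1e-9) {
  derivs <- rt_rhs(pmax(state, 0), params = params, R = 0)
  if (any(abs(derivs) > rhs_tol)) {
    abort("`state` has not converged (right-hand side is not ~0); integrate longer.")
  }
  state[[2]] < tol && state[[3]] < tol
}
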