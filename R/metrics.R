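trapezoid_mean <- function(t, y) {
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2) / (max(t) - min(t))
}

#' Last-week time averages of a treated trajectory
#'
#' Time-averages (trapezoidal quadrature over the dense solver output) of
#' `T`, `TS`, `TR` and `c` over the final treatment week: the 10080 minutes
#' ending at the end of the last week that contains a fraction (including
#' that week's trailing weekend). For protocols whose final week is partial
#' the window still spans the full 10080 minutes ending that week's Sunday
#' midnight, keeping the window length fixed across dosing frequencies.
#'
#' @param traj An `rt_trajectory` (or any tibble with `t_min`, `T`, `TS`,
#'   `TR`, `c`) covering the final treatment week.
#' @param schedule The [rt_schedule] that produced it.
#' @return A one-row tibble with `tbar`, `tsbar`, `trbar`, `cbar`.
#' @export
last_week_means <- function(traj, schedule) {
  stopifnot(inherits(schedule, "rt_schedule"))
  if (schedule$n_fractions == 0) abort("Schedule has no fractions: no treatment week.")
  w1 <- schedule$t_end_week
  w0 <- w1 - 10080
  m <- traj[traj$t_min >= w0 - 1e-9 & traj$t_min <= w1 + 1e-9, , drop = FALSE]
  if (nrow(m) < 2 || min(m$t_min) > w0 + 1e-6 || max(m$t_min) < w1 - 1e-6) {
    abort("Trajectory does not cover the final treatment week.")
  }
  tibble(tbar = trapezoid_mean(m$t_min, m$T),
         tsbar = trapezoid_mean(m$t_min, m$TS),
         trbar = trapezoid_mean(m$t_min, m$TR),
         cbar = trapezoid_mean(m$t_min, m$c))
}

#' Treatment response summary of one tumour
#'
#' Assembles the response record from a treated trajectory: the last-week
#' time averages; the percent changes
#' `Delta_viable = 100 * ((Tbar + TSbar) - T0) / T0` and
#' `Delta_total = 100 * (Sigmabar - Sigma0) / Sigma0` between the start of
#' treatment and the final treatment week; and the end-of-treatment
#' composition percentages `%T`, `%TS`, `%TR`, `%V0`, all relative to the
#' pre-treatment total volume `Sigma0 = T0 + V0`. These satisfy the exact
#' identity `Delta_total = (%T + %TS + %TR + %V0) - 100`.
#'
#' @param params An [rt_params] object.
#' @param schedule The [rt_schedule] used.
#' @param traj Trajectory from [simulate_treatment()] started at the
#'   pre-treatment equilibrium (`t = 0`, no damaged material).
#' @param traj_long Optional longer trajectory (well past treatment) used
#'   to label the post-treatment attractor.
#' @return A one-row tibble with columns `t0`, `sigma0`, `tbar`, `tsbar`,
#'   `trbar`, `cbar`, `delta_viable`, `delta_total`, `pct_t`, `pct_ts`,
#'   `pct_tr`, `pct_v0`, `attractor`.
#' @export
response_summary <- function(params, schedule, traj, traj_long = NULL) {
  stopifnot(inherits(params, "rt_params"))
  if (abs(traj$t_min[1]) > 1e-9 || traj$TS[1] > 1e-12 || traj$TR[1] > 1e-12) {
    abort("`traj` must start at the pre-treatment state (t = 0, TS = TR = 0).")
  }
  T0 <- traj$T[1]
  sigma0 <- T0 + params$V0
  m <- last_week_means(traj, schedule)
  sigbar <- m$tbar + m$tsbar + m$trbar + params$V0
  attractor <- if (is.null(traj_long)) NA_character_ else {
    classify_terminal_state(params,
                            unlist(traj_long[nrow(traj_long), c("T", "TS", "TR", "c")]))
  }
  tibble(t0 = T0, sigma0 = sigma0,
         tbar = m$tbar, tsbar = m$tsbar, trbar = m$trbar, cbar = m$cbar,
         delta_viable = 100 * ((m$tbar + m$tsbar) - T0) / T0,
         delta_total = 100 * (sigbar - sigma0) / sigma0,
         pct_t = 100 * m$tbar / sigma0,
         pct_ts = 100 * m$tsbar / sigma0,
         pct_tr = 100 * m$trbar / sigma0,
         pct_v0 = 100 * params$V0 / sigma0,
         attractor = attractor)
}
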