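#' Construct a fractionated radiotherapy schedule
#'
#' Builds the ordered set of irradiation windows for a Monday-to-Friday
#' fractionation protocol. Time is measured in minutes with `t = 0` at
#' Monday 00:00 of week 1; the first fraction starts at `t = 0` and every
#' fraction is delivered at the same time of day over `delta_R` minutes at
#' the constant dimensionless dose rate `R_value = D / (delta_R * R_max)`.
#' The number of fractions is `floor(total_dose_cap / D)`, so the realised
#' total dose is the largest multiple of `D` not exceeding the cap: the
#' conventional protocol (`D = 2`, five fractions per week) gives 40
#' fractions over 8 weeks (80 Gy); `D = 3` gives 26 fractions (78 Gy) over
#' 5.2 weeks at five per week or 8.67 weeks at three per week.
#'
#' @param D Dose per fraction in Gy (> 0). For the untreated control use
#'   [rt_null_schedule()].
#' @param n_per_week Fractions per week: 5 (Mon-Fri), 3 (Mon/Wed/Fri) or
#'   1 (Mon).
#' @param delta_R Fraction duration in minutes (default 10).
#' @param R_max Maximum dose rate in Gy/min used in the nondimensionalisation
#'   (default 1).
#' @param total_dose_cap Total dose cap in Gy (default 80).
#' @return An object of class `rt_schedule` with fields `D`, `n_per_week`,
#'   `delta_R`, `R_max`, `R_value`, `total_dose_cap`, `n_fractions`,
#'   `duration_weeks`, `t_end_week` (end of the final treatment week,
#'   minutes) and `windows` (a tibble of `start`/`end` minutes).
#' @examples
#' conventional <- rt_schedule(D = 2, n_per_week = 5)
#' conventional$n_fractions      # 40
#' dose_rate(5, conventional)    # 0.2 inside the first window
#' @export
rt_schedule <- function(D, n_per_week, delta_R = 10, R_max = 1,
                        total_dose_cap = 80) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D < 0) {
    abort("`D` must be a single non-negative dose in Gy.")
  }
  if (D == 0) {
    abort("D = 0 means no treatment: use `rt_null_schedule()`.")
  }
  if (!n_per_week %in% c(1, 3, 5)) {
    abort("`n_per_week` must be 1, 3 or 5 (Mon / Mon-Wed-Fri / Mon-Fri).")
  }
  if (delta_R <= 0) abort("`delta_R` must be a positive duration in minutes.")
  if (total_dose_cap < D) abort("`total_dose_cap` must allow at least one fraction.")

  n_fractions <- floor(total_dose_cap / D)
  day <- 1440; week <- 10080
  days <- switch(as.character(n_per_week), "5" = 0:4, "3" = c(0, 2, 4), "1" = 0)
  n_weeks_spanned <- ceiling(n_fractions / n_per_week)
  starts <- as.vector(outer(days * day, (seq_len(n_weeks_spanned) - 1) * week, "+"))
  starts <- sort(starts)[seq_len(n_fractions)]

  structure(list(
    D = D, n_per_week = n_per_week, delta_R = delta_R, R_max = R_max,
    R_value = D / (delta_R * R_max), total_dose_cap = total_dose_cap,
    n_fractions = n_fractions,
    duration_weeks = n_fractions / n_per_week,
    t_end_week = n_weeks_spanned * week,
    windows = tibble(start = starts, end = starts + delta_R)
  ), class = "rt_schedule")
}

#' Untreated control schedule
#'
#' A schedule with no irradiation windows (`R == 0` for all `t`), so that
#' treatment simulations reduce exactly to treatment-free growth.
#'
#' @return An `rt_schedule` with zero fractions.
#' @export
rt_null_schedule <- function() {
  structure(list(
    D = 0, n_per_week = 0, delta_R = 0, R_max = 1, R_value = 0,
    total_dose_cap = 0, n_fractions = 0, duration_weeks = 0, t_end_week = 0,
    windows = tibble(start = numeric(0), end = numeric(0))
  ), class = "rt_schedule")
}

#' @export
print.rt_schedule <- function(x, ...) {
  if (x$n_fractions == 0) {
    cat("<rt_schedule> untreated control (R == 0)\n")
  } else {
    cat(sprintf(
      "<rt_schedule> %g Gy x %d fractions (%g Gy total), %d/week, %.3g weeks\n",
      x$D, x$n_fractions, x$D * x$n_fractions, x$n_per_week, x$duration_weeks))
    cat(sprintf("  delta_R = %g min, R_value = %g, first fraction at t = %g min\n",
                x$delta_R, x$R_value, x$windows$start[1]))
  }
  invisible(x)
}

#' Piecewise-constant dose rate of a schedule
#'
#' Returns the dimensionless dose rate at time `t`: the schedule's `R_value`
#' when `t` lies in an irradiation window (closed interval), 0 otherwise.
#'
#' @param t Numeric vector of times in minutes (non-negative).
#' @param schedule An [rt_schedule] object.
#' @return Numeric vector of dose rates.
#' @export
dose_rate <- function(t, schedule) {
  stopifnot(inherits(schedule, "rt_schedule"))
  if (any(t < 0)) abort("`t` must be non-negative.")
  if (schedule$n_fractions == 0) return(rep(0, length(t)))
  w <- schedule$windows
  inside <- vapply(t, function(ti) any(w$start <= ti & ti <= w$end), logical(1))
  ifelse(inside, schedule$R_value, 0)
}

#' @rdname rt_schedule
#' @param x An `rt_schedule` object.
#' @param ... Unused.
#' @export
tidy.rt_schedule <- function(x, ...) {
  dplyr::mutate(x$windows,
                fraction = dplyr::row_number(),
                week = floor(.data$start / 10080) + 1,
                R_value = x$R_value,
                .before = 1)
}

#' @rdname rt_schedule
#' @export
glance.rt_schedule <- function(x, ...) {
  tibble(D = x$D, n_per_week = x$n_per_week, delta_R = x$delta_R,
         R_value = x$R_value, n_fractions = x$n_fractions,
         total_dose = x$D * x$n_fractions, duration_weeks = x$duration_weeks)
}

#' Read or write a schedule as JSON
#'
#' @param schedule An `rt_schedule` object.
#' @param path File path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   reconstructs the `rt_schedule` (windows are rebuilt from the scalar
#'   fields and must round-trip exactly).
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "rt_schedule"))
  jsonlite::write_json(
    schedule[c("D", "n_per_week", "delta_R", "R_max", "total_dose_cap")],
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (v$D == 0) return(rt_null_schedule())
  rt_schedule(D = v$D, n_per_week = v$n_per_week, delta_R = v$delta_R,
              R_max = v$R_max, total_dose_cap = v$total_dose_cap)
}
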