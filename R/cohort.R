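.regime_v0 <- c(NL = 0.0005, SL = 0.005, BS = 0.00275)

with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# q1 at which the NL-only threshold V_N(q1) equals V0 (inverse of
# vn_threshold in q1): NL regime iff q1 >= this, SL admissible iff q1 <= it.
q1_at_vn <- function(V0, g = 5, c_min = 1e-2) {
  g * (1 - c_min) * V0 / (c_min * (1 - V0))
}

.classify_q <- function(q1, q3, V0) classify_regime(rt_params(q1, q3, V0))

# Boundary in q3 of a regime's slice at fixed q1, assuming the slice is
# contiguous and anchored at `anchor` ("lower": [lo, b]; "upper": [b, hi]).
q3_boundary <- function(q1, V0, regime, lo, hi, anchor, iter = 40) {
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    inside <- .classify_q(q1, mid, V0) == regime
    if (anchor == "lower") { if (inside) lo <- mid else hi <- mid }
    else                   { if (inside) hi <- mid else lo <- mid }
  }
  (lo + hi) / 2
}

#' Sample a virtual tumour cohort
#'
#' Draws `n` tumours with `(q1, q3)` pairs from the requested growth regime
#' at that regime's fixed vascular volume (`V0 = 0.0005`, `0.005` and
#' `0.00275` for NL, SL and BS).
#'
#' The default `"conditional"` sampler draws `q1` uniformly over the
#' regime's feasible `q1` interval and then `q3` uniformly over the
#' regime's `q3` slice at that `q1` (the slice bounds are located by
#' bisection on the regime classifier). Every `q1` slice therefore carries
#' equal weight. The `"rejection"` sampler instead draws uniformly over the
#' full box `[1e-2, 10]^2` and keeps in-regime points, i.e. it is uniform
#' over the two-dimensional regime region; wider slices then carry more
#' weight. The two coincide for the NL regime, whose region is a rectangle
#' (NL membership does not depend on `q3`).
#'
#' Draws are deterministic given `seed` and the caller's RNG state is left
#' untouched.
#'
#' @param regime `"NL"`, `"SL"` or `"BS"`.
#' @param n Cohort size (default 250).
#' @param seed Integer seed.
#' @param v0 Vascular volume override (defaults to the regime's value).
#' @param method `"conditional"` (default) or `"rejection"`.
#' @return An `rt_cohort`: a tibble with columns `id`, `q1`, `q3` and
#'   attributes `regime`, `v0`, `seed`, `method`, `acceptance_rate`
#'   (rejection sampler only, `NA` otherwise).
#' @examples
#' cohort <- sample_cohort("SL", n = 20, seed = 1)
#' table(vapply(seq_len(20), function(i)
#'   classify_regime(rt_params(cohort$q1[i], cohort$q3[i], 0.005)),
#'   character(1)))
#' @export
sample_cohort <- function(regime = c("NL", "SL", "BS"), n = 250, seed = 1,
                          v0 = NULL, method = c("conditional", "rejection")) {
  regime <- match.arg(regime)
  method <- match.arg(method)
  stopifnot(n >= 1)
  v0 <- v0 %||% .regime_v0[[regime]]
  box <- .rt_ranges$q1
  res <- with_preserved_seed(seed, {
    if (method == "conditional") {
      list(pairs = sample_conditional(regime, n, v0, box), rate = NA_real_)
    } else {
      sample_rejection(regime, n, v0, box)
    }
  })
  structure(
    tibble(id = seq_len(n), q1 = res$pairs[, 1], q3 = res$pairs[, 2]),
    regime = regime, v0 = v0, seed = seed, method = method,
    acceptance_rate = res$rate,
    class = c("rt_cohort", class(tibble())))
}

sample_conditional <- function(regime, n, v0, box) {
  out <- matrix(NA_real_, n, 2)
  qvn <- q1_at_vn(v0)
  if (regime == "NL") {
    # NL iff V0 <= V_N(q1), independent of q3: a rectangle
    q1lo <- max(box[1], qvn)
    if (q1lo >= box[2]) abort("No NL tumours exist in the box at this V0.")
    out[, 1] <- runif(n, q1lo, box[2])
    out[, 2] <- runif(n, box[1], box[2])
  } else if (regime == "SL") {
    q1hi <- min(box[2], qvn)
    if (q1hi <= box[1]) abort("No SL tumours exist in the box at this V0.")
    for (i in seq_len(n)) {
      q1 <- runif(1, box[1], q1hi)
      if (.classify_q(q1, box[1], v0) != "SL") {
        abort("SL slice not anchored at the low-q3 edge; unexpected region shape.")
      }
      q3hi <- if (.classify_q(q1, box[2], v0) == "SL") box[2] else {
        q3_boundary(q1, v0, "SL", box[1], box[2], anchor = "lower")
      }
      out[i, ] <- c(q1, runif(1, box[1], q3hi))
    }
  } else {
    # BS slices sit at the high-q3 edge; feasible q1 range found by
    # bisection of the classifier at q3 = 10
    q1cap <- min(box[2], qvn)
    if (.classify_q(box[1], box[2], v0) != "BS") {
      abort("No bistable window at the low-q1 edge of the box for this V0.")
    }
    lo <- box[1]; hi <- q1cap
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (.classify_q(mid, box[2], v0) == "BS") lo <- mid else hi <- mid
    }
    q1hi <- lo
    for (i in seq_len(n)) {
      q1 <- runif(1, box[1], q1hi)
      q3lo <- q3_boundary(q1, v0, "BS", box[1], box[2], anchor = "upper")
      out[i, ] <- c(q1, runif(1, q3lo, box[2]))
    }
  }
  out
}

sample_rejection <- function(regime, n, v0, box) {
  acc <- matrix(numeric(0), ncol = 2)
  attempts <- 0L
  while (nrow(acc) < n) {
    m <- max(1000L, 4L * n)
    q1 <- runif(m, box[1], box[2])
    q3 <- runif(m, box[1], box[2])
    keep <- vapply(seq_len(m), function(i) {
      .classify_q(q1[i], q3[i], v0) == regime
    }, logical(1))
    attempts <- attempts + m
    acc <- rbind(acc, cbind(q1[keep], q3[keep]))
    if (attempts >= 20000L && nrow(acc) / attempts < 1e-3) {
      abort(sprintf(
        "Acceptance rate %.2g for regime %s at V0 = %g is below 1e-3; the regime region is (near-)empty in the sampling box.",
        nrow(acc) / attempts, regime, v0))
    }
  }
  list(pairs = acc[seq_len(n), , drop = FALSE], rate = nrow(acc) / attempts)
}

#' @export
print.rt_cohort <- function(x, ...) {
  cat(sprintf("<rt_cohort> %d %s tumours (V0 = %g, seed = %s, %s sampler)\n",
              nrow(x), attr(x, "regime"), attr(x, "v0"),
              format(attr(x, "seed")), attr(x, "method")))
  NextMethod()
}

#' Run a fractionation protocol over a cohort
#'
#' Simulates every cohort member under `schedule` from its pre-treatment
#' equilibrium and collects one [response_summary()] row per member.
#' Individual member failures are recorded in the `error` column and do not
#' abort the batch.
#'
#' @param cohort An [sample_cohort()] result (or any tibble with `id`,
#'   `q1`, `q3` plus a `v0` attribute or column).
#' @param schedule An [rt_schedule].
#' @param attractor If `TRUE`, also continue each simulation to
#'   `t_end_long` and label the post-treatment attractor.
#' @param t_end_long Long horizon for attractor labelling (default 2.5e5).
#' @param rtol,atol,method Integrator settings, as in [simulate_treatment()].
#' @return An `rt_cohort_result` tibble: `id`, `q1`, `q3`, the
#'   response-summary columns and `error`. Use [cohort_summary()] or
#'   `glance()` for the cohort-level summary.
#' @export
run_cohort <- function(cohort, schedule, attractor = FALSE, t_end_long = 2.5e5,
                       rtol = 1e-8, atol = 1e-10, method = "ode45") {
  stopifnot(inherits(schedule, "rt_schedule"))
  v0 <- attr(cohort, "v0") %||% cohort$v0
  if (is.null(v0)) abort("`cohort` must carry a vascular volume (v0).")

  rows <- purrr::pmap(list(cohort$id, cohort$q1, cohort$q3),
                      function(id, q1, q3) {
    tryCatch({
      p <- rt_params(q1, q3, v0[[1]])
      traj <- simulate_treatment(p, schedule, rtol = rtol, atol = atol,
                                 method = method)
      traj_long <- if (attractor) {
        simulate_treatment(p, schedule, t_end = t_end_long,
                           rtol = rtol, atol = atol, method = method)
      } else NULL
      dplyr::bind_cols(tibble(id = id, q1 = q1, q3 = q3),
                       response_summary(p, schedule, traj, traj_long),
                       tibble(error = NA_character_))
    }, error = function(e) {
      tibble(id = id, q1 = q1, q3 = q3, error = conditionMessage(e))
    })
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
            regime = attr(cohort, "regime"), v0 = v0, schedule = schedule,
            class = c("rt_cohort_result", class(tibble())))
}

#' Cohort-level response summary
#'
#' Median and quartiles of `Delta_viable` and `Delta_total` over the cohort
#' and the shares of members whose viable / total volume grew during
#' treatment.
#'
#' @param results An [run_cohort()] result.
#' @return A one-row tibble (all-`NA` for an empty cohort).
#' @export
cohort_summary <- function(results) {
  has_cols <- "delta_viable" %in% names(results)
  ok <- if (has_cols) {
    results[is.na(results$error) & !is.na(results$delta_viable), , drop = FALSE]
  } else results[0, , drop = FALSE]
  if (nrow(ok) == 0) {
    return(tibble(n = nrow(results), n_failed = nrow(results),
                  median_delta_viable = NA_real_, q1_delta_viable = NA_real_,
                  q3_delta_viable = NA_real_, median_delta_total = NA_real_,
                  q1_delta_total = NA_real_, q3_delta_total = NA_real_,
                  frac_delta_viable_pos = NA_real_, frac_delta_total_pos = NA_real_))
  }
  qs <- function(x) unname(quantile(x, c(0.25, 0.5, 0.75)))
  qv <- qs(ok$delta_viable); qt <- qs(ok$delta_total)
  tibble(n = nrow(results), n_failed = nrow(results) - nrow(ok),
         median_delta_viable = qv[2], q1_delta_viable = qv[1], q3_delta_viable = qv[3],
         median_delta_total = qt[2], q1_delta_total = qt[1], q3_delta_total = qt[3],
         frac_delta_viable_pos = mean(ok$delta_viable > 0),
         frac_delta_total_pos = mean(ok$delta_total > 0))
}

#' @rdname cohort_summary
#' @param x An `rt_cohort_result`.
#' @param ... Unused.
#' @export
glance.rt_cohort_result <- function(x, ...) cohort_summary(x)
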