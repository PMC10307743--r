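#' Heaviside step function
#'
#' Unit step with the right-continuous convention `H(0) = 1`, as used in the
#' starvation death switch of the growth model: cells die from nutrient
#' insufficiency exactly when the oxygen concentration satisfies
#' `c <= c_min`, i.e. when `H(c_min - c) = 1`.
#'
#' @param x Numeric vector. Must be finite.
#' @return Integer vector of 0/1, same length as `x`.
#' @examples
#' heaviside(c(-1, 0, 2))
#' @export
heaviside <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort("`x` must be a finite numeric vector.")
  }
  as.integer(x >= 0)
}

# Table of default rates; q1, q3 and V0 are tumour-specific and have no default
.rt_defaults <- list(
  c_min = 1e-2,  # anoxic oxygen threshold (fraction of vascular concentration)
  g     = 5,     # oxygen exchange rate per unit vascular volume
  k     = 1e-2,  # conversion factor linking proliferation and consumption
  theta1 = 10,   # q1S = theta1 * q1 (damaged cells consume more for maintenance)
  theta2 = 0.1,  # q2S = theta2 * q2, q3S = theta2 * q3 (and slower proliferation)
  nu    = 10,    # sub-lethal damage rate
  lam   = 1,     # lethal damage rate
  lamS  = 1,     # sub-lethal -> lethal accumulation rate
  mu    = 5e-3,  # repair rate
  xi    = 5e-4,  # mitotic-catastrophe death rate
  etaR  = 5e-5   # dead-cell clearance rate
)

# Recommended sampling box for the oxygen consumption rates and the
# admissible vascular volume range.
.rt_ranges <- list(q1 = c(1e-2, 10), q3 = c(1e-2, 10), V0 = c(0, 5e-3))

.derived_names <- c("q2", "delta1", "delta1S", "q1S", "q2S", "q3S")

#' Construct a dimensionless tumour parameter set
#'
#' Builds the full parameter set of the radiotherapy growth model from the
#' three tumour-specific rates -- `q1` (oxygen consumption for maintenance),
#' `q3` (oxygen consumption for proliferation) and `V0` (vascular volume
#' fraction) -- and the default radiobiological rates. The derived couplings
#' `q2 = k * q3`, `delta1 = q2`, `delta1S = theta2 * q2`, `q1S = theta1 * q1`,
#' `q2S = theta2 * q2` and `q3S = theta2 * q3` are recomputed from their
#' parents unless explicitly overridden (an override is reported via a
#' message so a broken coupling is never silent).
#'
#' All quantities are dimensionless; the time unit of the model is one
#' minute, volumes are fractions of the total available space, and oxygen is
#' a fraction of the vascular concentration.
#'
#' @param q1,q3 Oxygen consumption rates for maintenance and proliferation.
#'   Recommended range `[1e-2, 10]` (values outside trigger a warning).
#' @param V0 Vascular volume fraction, in `(0, 1)`; realistic tumours use
#'   `(0, 5e-3]`.
#' @param ... Named overrides for any default or derived parameter
#'   (`c_min`, `g`, `k`, `theta1`, `theta2`, `nu`, `lam`, `lamS`, `mu`,
#'   `xi`, `etaR`, `q2`, `delta1`, `delta1S`, `q1S`, `q2S`, `q3S`).
#'   Unknown names are rejected.
#' @return An object of class `rt_params`: a named list of all rates.
#' @examples
#' p <- rt_params(q1 = 0.5, q3 = 5, V0 = 0.003)
#' p$q2      # = k * q3 = 0.05
#' tidy(p)
#' @export
rt_params <- function(q1, q3, V0, ...) {
  overrides <- list(...)
  base_names <- names(.rt_defaults)
  unknown <- setdiff(names(overrides), c(base_names, .derived_names))
  if (length(unknown) > 0 || (length(overrides) > 0 && is.null(names(overrides)))) {
    abort(paste0("Unknown parameter(s): ", paste(unknown, collapse = ", ")))
  }

  p <- modifyList(.rt_defaults, overrides[intersect(names(overrides), base_names)])
  p$q1 <- q1; p$q3 <- q3; p$V0 <- V0

  for (nm in c("q1", "q3", "V0", base_names)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(paste0("Parameter `", nm, "` must be a single finite number."))
    }
  }
  if (q1 <= 0 || q3 <= 0) abort("`q1` and `q3` must be strictly positive.")
  if (V0 <= 0 || V0 >= 1) {
    abort("`V0` is a vascular volume fraction and must lie in (0, 1).")
  }
  if (p$c_min <= 0 || p$c_min >= 1) abort("`c_min` must lie in (0, 1).")
  if (!(p$theta2 < 1 && 1 < p$theta1) || p$theta2 <= 0) {
    abort("Multipliers must satisfy 0 < theta2 < 1 < theta1.")
  }
  for (nm in c("g", "k", "nu", "lam", "lamS", "mu", "xi", "etaR")) {
    if (p[[nm]] <= 0) abort(paste0("Rate `", nm, "` must be strictly positive."))
  }
  if (q1 < .rt_ranges$q1[1] || q1 > .rt_ranges$q1[2] ||
      q3 < .rt_ranges$q3[1] || q3 > .rt_ranges$q3[2]) {
    warn("q1/q3 outside the recommended sampling range [1e-2, 10].")
  }
  if (V0 > .rt_ranges$V0[2]) {
    warn("V0 above the realistic vascular range (0, 5e-3].")
  }

  derived <- list(
    q2     = p$k * p$q3,
    q1S    = p$theta1 * p$q1,
    q3S    = p$theta2 * p$q3
  )
  derived$q2S     <- p$theta2 * derived$q2
  derived$delta1  <- derived$q2
  derived$delta1S <- derived$q2S
  for (nm in .derived_names) {
    if (nm %in% names(overrides)) {
      message("Derived parameter `", nm, "` overridden; its coupling no longer holds.")
      derived[[nm]] <- overrides[[nm]]
      if (derived[[nm]] <= 0) abort(paste0("Rate `", nm, "` must be strictly positive."))
    }
  }
  structure(c(p, derived[.derived_names]), class = "rt_params")
}

#' @export
print.rt_params <- function(x, ...) {
  cat("<rt_params> dimensionless tumour parameter set\n")
  cat(sprintf("  q1 = %g, q3 = %g, V0 = %g\n", x$q1, x$q3, x$V0))
  cat(sprintf("  derived: q2 = %g, delta1 = %g, q1S = %g, q2S = %g, q3S = %g, delta1S = %g\n",
              x$q2, x$delta1, x$q1S, x$q2S, x$q3S, x$delta1S))
  cat(sprintf("  RT rates: nu = %g, lam = %g, lamS = %g, mu = %g, xi = %g, etaR = %g\n",
              x$nu, x$lam, x$lamS, x$mu, x$xi, x$etaR))
  cat(sprintf("  environment: c_min = %g, g = %g, k = %g, theta1 = %g, theta2 = %g\n",
              x$c_min, x$g, x$k, x$theta1, x$theta2))
  invisible(x)
}

#' @rdname rt_params
#' @param x An `rt_params` object.
#' @export
tidy.rt_params <- function(x, ...) {
  tibble(parameter = names(unclass(x)), value = unlist(unclass(x), use.names = FALSE))
}

#' Read or write a parameter set as a flat key-value config
#'
#' Parameter sets serialize to a flat JSON (or YAML, if the `yaml` package is
#' installed) object mapping parameter names to numbers. On reading, unknown
#' keys are rejected and the derived couplings are re-validated: a stored
#' derived value that disagrees with its parents is treated as an explicit
#' override.
#'
#' @param params An `rt_params` object.
#' @param path File path; format chosen by extension (`.json`, `.yaml`, `.yml`).
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   an `rt_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "rt_params"))
  vals <- unclass(params)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("The `yaml` package is required to write YAML configs.")
    }
    yaml::write_yaml(vals, path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("The `yaml` package is required to read YAML configs.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("q1", "q3", "V0", names(.rt_defaults), .derived_names)
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown key(s) in parameter config: ", paste(unknown, collapse = ", ")))
  }
  if (!all(c("q1", "q3", "V0") %in% names(vals))) {
    abort("Parameter config must provide q1, q3 and V0.")
  }
  vals <- lapply(vals, as.numeric)
  args <- vals[setdiff(names(vals), c("q1", "q3", "V0", .derived_names))]
  # only pass stored derived values through as overrides when they disagree
  # with the recomputed couplings (i.e. they were genuine overrides)
  probe <- do.call(rt_params, c(list(q1 = vals$q1, q3 = vals$q3, V0 = vals$V0), args))
  for (nm in intersect(.derived_names, names(vals))) {
    if (abs(vals[[nm]] - probe[[nm]]) > 1e-12 * max(1, abs(probe[[nm]]))) {
      args[[nm]] <- vals[[nm]]
    }
  }
  do.call(rt_params, c(list(q1 = vals$q1, q3 = vals$q3, V0 = vals$V0), args))
}
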