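# Independent term-by-term oracle for the four derivatives, written directly
# from the model's interaction terms (kept separate from the production RHS).
oracle_rhs <- function(s, p, R) {
  T <- s[1]; TS <- s[2]; TR <- s[3]; cc <- s[4]
  free <- 1 - (T + TS + TR + p$V0)
  H <- if (p$c_min - cc >= 0) 1 else 0
  death  <- p$delta1  * (p$c_min - cc) * H * T
  deathS <- p$delta1S * (p$c_min - cc) * H * TS
  prolif  <- p$q2 * cc * T * free
  prolifS <- p$theta2 * p$q2 * cc * TS * free
  lethal  <- p$lam * cc * R * T
  subleth <- p$nu * cc * R * T
  repair  <- p$mu * TS
  accum   <- p$lamS * cc * R * TS
  mc      <- p$xi * TS
  c(prolif - death - lethal - subleth + repair,
    prolifS - deathS + subleth - repair - mc - accum,
    lethal + accum + mc - p$etaR * TR,
    p$g * (1 - cc) * p$V0 - p$q1 * cc * (T + p$theta1 * TS) -
      p$q3 * cc * (T + p$theta2 * TS) * free)
}

test_that("an empty tumour only receives oxygen", {
  p <- rt_params(0.5, 5, 0.003)
  d <- rt_rhs(c(0, 0, 0, 0.5), params = p, R = 0)
  expect_equal(unname(d), c(0, 0, 0, p$g * 0.5 * p$V0))
})

test_that("the RHS matches an independent arithmetic oracle (R and compiled paths)", {
  set.seed(42)
  for (i in 1:25) {
    p <- rt_params(runif(1, 1e-2, 10), runif(1, 1e-2, 10), runif(1, 1e-4, 5e-3))
    s <- random_state(p)
    R <- sample(c(0, 0.1, 0.2, 0.5), 1)
    expect_equal(unname(rt_rhs(s, params = p, R = R)), oracle_rhs(s, p, R),
                 tolerance = 1e-13)
    # compiled derivatives used by the integrator agree with the R reference
    compiled <- deSolve::DLLfunc(
      y = s, times = 0, func = "rt_derivs", dllname = "rtresponse",
      initfunc = "rt_initmod", parms = rtresponse:::pack_parms(p, R))$dy
    expect_equal(unname(compiled), unname(rt_rhs(s, params = p, R = R)),
                 tolerance = 1e-14)
  }
  # the fixed spot-check state
  p <- rt_params(1, 1, 0.003)
  s <- c(0.1, 0.05, 0.02, 0.5)
  expect_equal(unname(rt_rhs(s, params = p, R = 0.2)), oracle_rhs(s, p, 0.2))
})

test_that("with no treatment and no damage the system reduces to the two-variable growth model", {
  set.seed(7)
  for (i in 1:10) {
    p <- rt_params(runif(1, 0.1, 5), runif(1, 0.1, 5), runif(1, 1e-4, 5e-3))
    T <- runif(1, 0, 0.9); cc <- runif(1)
    d <- rt_rhs(c(T, 0, 0, cc), params = p, R = 0)
    expect_identical(unname(d[2]), 0)
    expect_identical(unname(d[3]), 0)
    u <- 1 - T - p$V0
    H <- as.numeric(p$c_min >= cc)
    expect_equal(unname(d[1]),
                 p$q2 * cc * T * u - p$delta1 * (p$c_min - cc) * H * T)
    expect_equal(unname(d[4]),
                 p$g * (1 - cc) * p$V0 - p$q1 * cc * T - p$q3 * cc * T * u)
  }
})

test_that("radiation transfer and repair terms cancel in the total cell balance", {
  set.seed(8)
  for (i in 1:15) {
    p <- rt_params(runif(1, 1e-2, 10), runif(1, 1e-2, 10), runif(1, 1e-4, 5e-3))
    s <- random_state(p)
    R <- runif(1, 0, 0.5)
    d <- rt_rhs(s, params = p, R = R)
    free <- 1 - sum(s[1:3]) - p$V0
    H <- as.numeric(p$c_min >= s[4])
    expected <- p$q2 * s[4] * s[1] * free + p$theta2 * p$q2 * s[4] * s[2] * free -
      p$delta1 * (p$c_min - s[4]) * H * s[1] -
      p$delta1S * (p$c_min - s[4]) * H * s[2] -
      p$etaR * s[3]
    expect_equal(sum(d[1:3]), expected, tolerance = 1e-12)
  }
})

test_that("the state space is forward-invariant at its boundaries", {
  set.seed(9)
  for (i in 1:10) {
    p <- rt_params(runif(1, 1e-2, 10), runif(1, 1e-2, 10), runif(1, 1e-4, 5e-3))
    # at Sigma = 1 the total cell volume cannot grow
    x <- runif(3); x <- x / sum(x) * (1 - p$V0)
    d <- rt_rhs(c(x, runif(1)), params = p, R = runif(1, 0, 0.5))
    expect_lte(sum(d[1:3]), 1e-14)
    s <- random_state(p)
    # oxygen stays within [0, 1]
    expect_lte(rt_rhs(c(s[1:3], 1), params = p, R = 0)[["dc"]], 1e-14)
    expect_gte(rt_rhs(c(s[1:3], 0), params = p, R = 0)[["dc"]], -1e-14)
  }
})

test_that("the starvation switch is continuous at c = c_min", {
  p <- rt_params(0.5, 5, 0.003)
  s <- c(0.2, 0.1, 0.05, 0)
  eps <- 1e-9
  lo <- rt_rhs(c(s[1:3], p$c_min - eps), params = p, R = 0)
  hi <- rt_rhs(c(s[1:3], p$c_min + eps), params = p, R = 0)
  expect_equal(unname(lo), unname(hi), tolerance = 1e-6)
})

test_that("invalid states and dose rates are rejected", {
  p <- rt_params(0.5, 5, 0.003)
  expect_error(rt_rhs(c(-0.1, 0, 0, 0.5), params = p), "non-negative")
  expect_error(rt_rhs(c(0.1, 0, 0, 1.5), params = p), "0, 1")
  expect_error(rt_rhs(c(0.1, 0, 0, 0.5), params = p, R = -1), "dose rate")
  expect_error(rt_rhs(c(0.1, 0, 0, NA), params = p), "finite")
})
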