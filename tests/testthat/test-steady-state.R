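test_that("the SL equilibrium closed form and admissibility boundary are exact", {
  p <- rt_params(0.5, 5, 0.003)
  s <- sl_steady_state(p)
  expect_equal(s$T, 0.997)
  expect_equal(s$c, 0.015 / 0.5135)
  expect_true(s$admissible)

  s2 <- sl_steady_state(rt_params(0.5, 5, 0.0005))
  expect_false(s2$admissible)   # c* < c_min: NL-only vascular volume

  # at V0 = V_N the SL oxygen level sits exactly on the threshold
  vn <- vn_threshold(0.5)
  s3 <- sl_steady_state(rt_params(0.5, 5, vn))
  expect_equal(s3$c, 0.01, tolerance = 1e-12)
})

test_that("the NL equilibrium solves both stationarity relations and is stable", {
  p <- rt_params(0.5, 5, 0.0005)
  n <- nl_steady_state(p)
  expect_true(n$admissible)
  expect_gt(n$c, p$c_min / 2)         # c* = c_min / (2 - Sigma*), Sigma* < 1
  expect_lt(n$c, p$c_min)
  d <- rt_rhs(c(n$T, 0, 0, n$c), params = p, R = 0)
  expect_lt(max(abs(d)), 1e-10)

  expect_false(nl_steady_state(rt_params(0.5, 5, 0.003))$admissible)

  # forward integration from a small tumour lands on the same equilibrium
  traj <- simulate_growth(p, t_end = 2e5)
  expect_equal(traj$T[nrow(traj)], n$T, tolerance = 1e-5)
  expect_equal(traj$c[nrow(traj)], n$c, tolerance = 1e-5)
})

test_that("V_N is the q3-independent NL/bistable vascular threshold", {
  expect_equal(vn_threshold(0.5), 0.005 / 4.955)
  # strictly increasing in q1
  q1s <- c(0.05, 0.2, 0.5, 1, 3, 8)
  expect_true(all(diff(vapply(q1s, vn_threshold, numeric(1))) > 0))
  # below V_N only NL is admissible, just above it SL becomes admissible,
  # for any q3
  for (q3 in c(0.05, 1, 9)) {
    expect_false(sl_steady_state(rt_params(0.5, q3, 0.9e-3))$admissible)
    expect_true(sl_steady_state(rt_params(0.5, q3, 1.1e-3))$admissible)
  }
  expect_lt(vn_threshold(0.5, c_min = 1e-6), 1e-6)  # V_N -> 0 with c_min
})

test_that("V_S bounds the bistable window and is undefined without one", {
  vs <- vs_threshold(0.5, 5)
  vn <- vn_threshold(0.5)
  expect_gt(vs, vn)
  expect_true(vn < 0.0015 && 0.0015 < vs)  # B1 sits inside the window
  expect_true(is.na(vs_threshold(0.5, 0.5)))  # q3 ~ q1: unique SL state
  # NL admissibility flips exactly at V_S
  expect_true(nl_steady_state(rt_params(0.5, 5, vs - 1e-6))$admissible)
  expect_false(nl_steady_state(rt_params(0.5, 5, vs + 1e-6))$admissible)
})

test_that("regimes classify as on the example points of the phase diagram", {
  for (i in seq_len(nrow(regime_points))) {
    r <- regime_points[i, ]
    expect_equal(classify_regime(rt_params(0.5, r$q3, r$V0)), r$regime,
                 label = r$label)
  }
})

test_that("the V_d proximity index matches the bistable representatives", {
  expect_equal(vd_index(rt_params(4.55e-2, 7.94, 0.00275)), 0.993,
               tolerance = 0.01)
  expect_equal(vd_index(rt_params(3.92e-2, 9.96, 0.00275)), 0.791,
               tolerance = 0.01)
  # D3: printed 0.00376; recomputation from the 3-s.f. parameters gives
  # ~0.005 (V_N is q1-sensitive in the 4th digit here)
  expect_lt(abs(vd_index(rt_params(1.36, 9.93, 0.00275)) - 0.00376), 2e-3)
  # V_d -> 0 as V0 -> V_N
  vn <- vn_threshold(0.5)
  expect_lt(vd_index(rt_params(0.5, 5, vn * 1.001)), 0.01)
  expect_error(vd_index(rt_params(0.5, 5, 0.003)), "SL")
})

test_that("admissible equilibria zero the full RHS and are correctly ordered", {
  set.seed(21)
  for (i in 1:20) {
    p <- rt_params(runif(1, 1e-2, 10), runif(1, 1e-2, 10), runif(1, 1e-4, 5e-3))
    nl <- nl_steady_state(p); sl <- sl_steady_state(p)
    if (nl$admissible) {
      expect_lt(max(abs(rt_rhs(c(nl$T, 0, 0, nl$c), params = p, R = 0))), 1e-10)
    }
    if (sl$admissible) {
      expect_lt(max(abs(rt_rhs(c(sl$T, 0, 0, sl$c), params = p, R = 0))), 1e-10)
    }
    if (nl$admissible && sl$admissible) {  # NL state is the smaller one
      expect_lt(nl$T, sl$T)
      expect_lt(nl$c, sl$c)
    }
  }
})

test_that("equilibria vary monotonically with vascular volume", {
  v0s <- seq(2e-4, 3e-3, length.out = 8)
  nlT <- nlc <- slT <- slc <- rep(NA_real_, length(v0s))
  for (i in seq_along(v0s)) {
    p <- rt_params(0.5, 5, v0s[i])
    nl <- nl_steady_state(p); sl <- sl_steady_state(p)
    if (nl$admissible) { nlT[i] <- nl$T; nlc[i] <- nl$c }
    if (sl$admissible) { slT[i] <- sl$T; slc[i] <- sl$c }
  }
  expect_true(all(diff(nlT[!is.na(nlT)]) > 0))
  expect_true(all(diff(nlc[!is.na(nlc)]) > 0))
  expect_true(all(diff(slT[!is.na(slT)]) < 0))
  expect_true(all(diff(slc[!is.na(slc)]) > 0))
})

test_that("steady_state_report and regime_map assemble consistent tables", {
  rep <- steady_state_report(rt_params(0.5, 5, 0.0015))
  td <- tidy(rep)
  expect_equal(td$regime, "BS")
  expect_equal(td$V_d, (0.0015 - td$V_N) / (td$V_S - td$V_N))
  expect_true(td$T_star_NL < td$T_star_SL)

  m <- regime_map(0.5, q3 = c(0.5, 5), V0 = c(0.0005, 0.003))
  expect_equal(nrow(m), 4)
  expect_setequal(m$regime[m$V0 == 0.0005], "NL")
})

test_that("no steady state carries damaged material", {
  p <- rt_params(0.5, 5, 0.0005)
  n <- nl_steady_state(p)
  expect_true(verify_no_damaged_steady_state(p, c(n$T, 0, 0, n$c)))
  # a fabricated damaged state is not an equilibrium at all
  expect_error(
    verify_no_damaged_steady_state(p, c(n$T, 0, 0.1, n$c)), "not converged")
  expect_false(
    verify_no_damaged_steady_state(p, c(n$T, 0, 0.1, n$c), rhs_tol = Inf))
  # the dead-cell balance dTR/dt = 0 holds exactly when xi*TS = etaR*TR
  TS <- 0.01; TR <- p$xi * TS / p$etaR   # = 0.1
  d <- rt_rhs(c(0.1, TS, TR, 0.5), params = p, R = 0)
  expect_equal(unname(d[3]), 0)
})
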