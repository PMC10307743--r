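classify_terminal_state_of <- function(traj, p) {
  rtresponse:::classify_terminal_state(
    p, unlist(traj[nrow(traj), c("T", "TS", "TR", "c")]))
}

test_that("untreated growth converges to the regime's equilibrium", {
  # NL tumour (A1 point) and bistable tumour (B1 point): both grow from a
  # small initial volume to the NL equilibrium
  for (v0 in c(0.0005, 0.0015)) {
    p <- rt_params(0.5, 5, v0)
    n <- nl_steady_state(p)
    traj <- simulate_growth(p, t_end = 2e5)
    expect_equal(traj$T[nrow(traj)], n$T, tolerance = 1e-4)
    expect_lt(traj$c[nrow(traj)], p$c_min)
    expect_equal(classify_terminal_state_of(traj, p), "NL")
  }
  # SL tumour fills the space
  p <- rt_params(0.5, 5, 0.003)
  traj <- simulate_growth(p, t_end = 2e5)
  expect_equal(traj$T[nrow(traj)], 1 - p$V0, tolerance = 1e-4)
})

test_that("the empty tumour is absorbing and oxygen saturates", {
  p <- rt_params(0.5, 5, 0.003)
  traj <- simulate_growth(p, initial_state = c(0, 0, 0, 0.2), t_end = 5e4)
  expect_true(all(abs(traj$T) < 1e-12))
  expect_equal(traj$c[nrow(traj)], 1, tolerance = 1e-6)
})

test_that("a null schedule reproduces treatment-free growth exactly", {
  p <- rt_params(0.5, 5, 0.0015)
  ic <- c(T = 0.05, TS = 0, TR = 0, c = 1)
  a <- simulate_growth(p, ic, t_end = 2e4)
  b <- simulate_treatment(p, rt_null_schedule(), t_end = 2e4, initial_state = ic)
  expect_equal(a$t_min, b$t_min)
  expect_equal(a$T, b$T)
  expect_equal(a$c, b$c)
})

test_that("pretreatment state picks the physically reached equilibrium", {
  # SL tumour starts full
  s <- pretreatment_state(rt_params(1.08, 8.83, 0.005))
  expect_equal(s$T, 1 - 0.005)
  # bistable tumour starts at its NL state, not the larger SL state
  p <- rt_params(0.787, 8.38, 0.00275)
  expect_equal(classify_regime(p), "BS")
  s <- pretreatment_state(p)
  expect_equal(s$T, nl_steady_state(p)$T)
  expect_lt(s$c, p$c_min)
  # NL tumour: hypoxic equilibrium
  s <- pretreatment_state(p_nl_rep)
  expect_lt(s$c, 0.01)
})

test_that("treated trajectories respect the state invariants and sampling contract", {
  traj <- simulate_treatment(p_sl_rep, conventional)
  expect_true(all(traj$T > -1e-9 & traj$TS > -1e-9 & traj$TR > -1e-9))
  expect_true(all(traj$Sigma <= 1 + 1e-9))
  expect_true(all(traj$c >= -1e-9 & traj$c <= 1 + 1e-9))
  expect_true(all(diff(traj$t_min) > 0))
  # at least one sample strictly inside every fraction window
  w <- conventional$windows
  inside <- vapply(seq_len(nrow(w)), function(i) {
    any(traj$t_min > w$start[i] & traj$t_min < w$end[i])
  }, logical(1))
  expect_true(all(inside))
  # dense (<= 1 min) sampling across the final treatment week
  lastwk <- traj$t_min[traj$t_min >= conventional$t_end_week - 10080]
  expect_lte(max(diff(lastwk)), 1)
  # the dose-rate column matches the schedule definition away from boundaries
  mid <- traj$t_min %% 1440 > 30
  expect_equal(traj$R[mid], dose_rate(traj$t_min[mid], conventional))
})

test_that("viable volume falls under treatment for monostable tumours and rises for the typical bistable one", {
  trajSL <- simulate_treatment(p_sl_rep, conventional)
  viable <- trajSL$T + trajSL$TS
  expect_lt(viable[nrow(trajSL)], viable[1])
  pBS <- rt_params(0.787, 8.38, 0.00275)
  trajBS <- simulate_treatment(pBS, conventional)
  expect_gt(trajBS$T[nrow(trajBS)] + trajBS$TS[nrow(trajBS)], trajBS$T[1])
  expect_gt(trajBS$Sigma[nrow(trajBS)], trajBS$Sigma[1])
})

test_that("monostable tumours return to their pre-treatment state after RT", {
  expect_equal(post_treatment_attractor(p_nl_rep, conventional), "NL")
  expect_equal(post_treatment_attractor(p_sl_rep, conventional), "SL")
})

test_that("the event log records fractions and threshold crossings", {
  traj <- simulate_treatment(p_sl_rep, conventional)
  ev <- attr(traj, "events")
  expect_equal(sum(ev$event == "fraction_start"), 40)
  expect_equal(sum(ev$event == "fraction_end"), 40)
  # the SL tumour is driven below c_min by irradiation spikes
  expect_gt(sum(ev$event == "c_min_crossing"), 0)
})

test_that("bad horizons and states are rejected", {
  expect_error(simulate_treatment(p_sl_rep, conventional, t_end = 1000),
               "last fraction")
  expect_error(simulate_growth(p_sl_rep, initial_state = c(0.9, 0.2, 0, 1),
                               t_end = 100), "<= 1")
})
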