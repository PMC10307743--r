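# Shared fixtures: representative tumours and the conventional protocol.

conventional <- rt_schedule(D = 2, n_per_week = 5)

# Fig-2-style example points at q1 = 0.5 (V0, q3) and their regimes
regime_points <- tibble::tribble(
  ~label, ~q3, ~V0, ~regime,
  "A1", 5,   0.0005, "NL",
  "B1", 5,   0.0015, "BS",
  "C1", 5,   0.003,  "SL",
  "A2", 0.5, 0.0005, "NL",
  "B2", 0.5, 0.0015, "SL",
  "C2", 0.5, 0.003,  "SL"
)

# representative monostable tumours (conventional-schedule benchmarks)
p_sl_rep <- rt_params(1.08, 8.83, 0.005)    # space limited
p_nl_rep <- rt_params(0.832, 2.98, 0.0005)  # nutrient limited

# nutrient-limited composition benchmarks (q1, q3) at V0 = 0.0005
nl_reps <- tibble::tribble(
  ~label, ~q1, ~q3,
  "A1", 8.91e-1, 1.14e-1,
  "B1", 7.78,    4.01e-2,
  "C1", 8.91e-1, 9.75,
  "D1", 7.60,    9.94
)

# bistable representatives (q1, q3) at V0 = 0.00275 and their
# post-treatment attractors under the conventional schedule
bs_reps <- tibble::tribble(
  ~label, ~q1, ~q3, ~attractor,
  "A3", 4.55e-2, 7.94, "SL",
  "B3", 1.06,    4.92, "SL",
  "C3", 3.92e-2, 9.96, "NL",
  "D3", 1.36,    9.93, "NL"
)

random_state <- function(p) {
  repeat {
    s <- c(runif(3, 0, 0.5), runif(1))
    if (sum(s[1:3]) + p$V0 <= 1) return(s)
  }
}
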