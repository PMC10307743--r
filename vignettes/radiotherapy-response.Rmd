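---
title: "Modelling tumour response to fractionated radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tumour response to fractionated radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtresponse)
```

## The model

`rtresponse` simulates a well-mixed solid tumour whose growth can be arrested
by two distinct mechanisms — oxygen insufficiency or competition for space —
and tracks how radiotherapy (RT) damage interacts with each. The state has
four dimensionless variables: the undamaged viable volume $T$, the
sub-lethally damaged volume $T_S$, the lethally damaged (dead) volume $T_R$
(all fractions of the total available space) and the oxygen concentration $c$
(fraction of the vascular concentration). With
$\Sigma = T + T_S + T_R + V_0$, where $V_0$ is the (constant) vascular
volume fraction, the dynamics are

$$
\begin{aligned}
\dot T   &= q_2\, c\, T (1-\Sigma)
           - \big(\delta_1 (c_{min}-c) H(c_{min}-c) + \lambda c R + \nu c R\big) T
           + \mu T_S,\\
\dot T_S &= \theta_2 q_2\, c\, T_S (1-\Sigma)
           - \big(\delta_{1,S} (c_{min}-c) H(c_{min}-c) + \lambda_S c R + \mu + \xi\big) T_S
           + \nu c R\, T,\\
\dot T_R &= \lambda c R\, T + (\xi + \lambda_S c R)\, T_S - \eta_R T_R,\\
\dot c   &= g (1-c) V_0 - q_1 (T + \theta_1 T_S)\, c
           - q_3 (T + \theta_2 T_S)\, c\, (1-\Sigma).
\end{aligned}
$$

$H$ is the Heaviside step with $H(0)=1$: starvation-driven death acts
exactly when $c \le c_{min}$, and the death term
$(c_{min}-c)H(c_{min}-c)$ is continuous (it vanishes at the threshold).
$R(t)$ is the piecewise-constant dimensionless dose rate: $D/(\delta_R
R_{max})$ inside each irradiation window, 0 otherwise. Irradiation damages
viable cells at rates proportional to $cR$ — poorly oxygenated tumours are
radio-resistant — splitting into direct lethal damage (rate $\lambda$) and
sub-lethal damage (rate $\nu$). Sub-lethal damage is repaired (rate $\mu$),
accumulates into lethal damage ($\lambda_S c R$), or kills the cell through
mitotic catastrophe (rate $\xi$); dead material is cleared at rate
$\eta_R$. This time-resolved description of damage and repair replaces the
instantaneous cell-kill of linear-quadratic survival models and lets the
package follow the tumour's composition through a protocol.

The time unit is one minute (the natural scale of a fraction); all schedule
arithmetic is done in minutes, with $t = 0$ at Monday 00:00 of treatment
week 1.

### Parameters

Three rates characterise an individual tumour: `q1` (oxygen consumption for
maintenance), `q3` (oxygen consumption for proliferation) and `V0`, each
dimensionless. The remaining rates default to literature-motivated values
and are rarely changed:

```{r}
tidy(rt_params(q1 = 0.5, q3 = 5, V0 = 0.003))
```

Derived couplings are enforced at construction: $q_2 = k\,q_3$,
$\delta_1 = q_2$, $q_{1,S} = \theta_1 q_1$,
$q_{2,S} = \theta_2 q_2 = \delta_{1,S}$, $q_{3,S} = \theta_2 q_3$, with
$\theta_1 = 10$ and $\theta_2 = 0.1$ encoding that damaged cells spend more
oxygen on repair and less on proliferation. Overriding a derived value is
possible but always announced, so a silently broken coupling cannot occur.
The recommended ranges are $q_1, q_3 \in [10^{-2}, 10]$ and
$V_0 \in (0, 5\times 10^{-3}]$; `xi = 5e-4` gives mitotic-catastrophe
casualties a half-life of roughly one day, and `etaR = 5e-5` makes dead
material the slowest-clearing compartment (half-life $\approx$ 9.6 days),
which matters for several numerical choices below.

## Growth regimes without treatment

With $R \equiv 0$ and no damaged material the system reduces to a
two-variable growth model with two kinds of stable equilibria:

* **NL (nutrient limited)** — proliferation balances starvation death,
  $c^* < c_{min}$. The two stationarity relations collapse (using
  $\delta_1 = q_2$) to $c^* = c_{min}/(2-\Sigma^*)$ and a *quadratic* in
  $T^*$, which `nl_steady_state()` solves in closed form; candidate roots
  are admissibility-filtered ($0 \le T^* \le 1-V_0$) and
  stability-filtered through the numerically differenced Jacobian of the
  reduced system (central differences, step $10^{-7}$; stable means all
  eigenvalue real parts $< -10^{-12}$).
* **SL (space limited)** — proliferation stops when the space fills:
  $T^* = 1 - V_0$ and $c^* = gV_0 / (gV_0 + q_1(1-V_0)) \ge c_{min}$.

`vn_threshold()` gives the closed-form vascular volume $V_N$ at which the
SL oxygen level touches $c_{min}$ (below it only NL states exist; $V_N$ is
independent of $q_3$). Above $V_N$, an NL state may coexist with the SL
state up to a fold at $V_S$, located by `vs_threshold()` through bisection
on the NL-admissibility predicate (absolute tolerance $10^{-9}$ in $V_0$;
the predicate is monotone in $V_0$ because the quadratic's two roots merge
at the fold). Between the thresholds the tumour is bistable (**BS**) and
`vd_index()` reports the proximity index
$V_d = (V_0 - V_N)/(V_S - V_N) \in (0,1)$. Small tumours in the BS window
grow to the *NL* state, which is therefore used as the pre-treatment
state.

```{r}
tidy(steady_state_report(rt_params(0.5, 5, 0.0015)))
```

## Fractionation schedules

`rt_schedule(D, n_per_week)` builds Monday-anchored protocols: five
fractions per week on Mon–Fri, three on Mon/Wed/Fri, one on Monday, each
delivered over $\delta_R = 10$ min starting at the top of the simulated
day (the model only requires "same time of day"; the offset within the day
is immaterial because the inter-fraction dynamics depend on elapsed time).
The fraction count is $\lfloor 80/D \rfloor$ for the default 80 Gy cap.
The floor convention — rather than rounding to the nearest multiple of
$D$ — is what reproduces the benchmark durations of 8 weeks at
$2\,$Gy$\times 5$/week, 5.2 weeks at $3\,$Gy$\times 5$/week (26 fractions,
78 Gy) and 8.67 weeks at $3\,$Gy$\times 3$/week.

## Numerical integration

Treatment simulations integrate the system piecewise with the
Dormand–Prince RK4(5) pair (`deSolve`, compiled right-hand side), with
`rtol = 1e-8` and `atol = 1e-10` — tighter than solver defaults because
benchmark values are quoted to four significant figures. The integrator is
restarted at every irradiation window boundary, where $R(t)$ jumps; within
a segment the only non-smoothness is the starvation switch at
$c = c_{min}$, which is $C^0$ (the term vanishes at the crossing), so the
adaptive error control resolves it without event-located restarts. The
crossing times are still recorded in the trajectory's event log. Two
property tests back this choice: tightening both tolerances tenfold moves
last-week means by less than 0.1%, and equilibria reached by forward
integration agree with the closed-form states.

Output is sampled coarsely (10–60 min, scaled to the horizon) outside the
region of interest, at least every 2.5 min inside irradiation windows, and
every minute across the final treatment week so that time averages are
quadrature-accurate.

Degenerate inputs are handled explicitly: the empty tumour is absorbing;
a null schedule reproduces treatment-free growth exactly; initial states
violating $\Sigma \le 1$ or $c \in [0,1]$ are rejected before integration.

## Response metrics

For a protocol ending in week $w$, the averaging window is the final
10080 minutes ending at that week's Sunday midnight — including any
trailing weekend, and spanning a full week even when the last week of
dosing is partial, so the window length is identical across dosing
frequencies. Time averages $\bar T, \bar T_S, \bar T_R, \bar c$ use
trapezoidal quadrature on the minute-resolution output, and

$$
\Delta_{viable} = 100\,\frac{(\bar T + \bar T_S) - T_0}{T_0},\qquad
\Delta_{total} = 100\,\frac{\bar\Sigma - \Sigma_0}{\Sigma_0},
$$

with composition percentages $\%T, \%T_S, \%T_R, \%V_0$ relative to
$\Sigma_0 = T_0 + V_0$. These satisfy
$\Delta_{total} = (\%T + \%T_S + \%T_R + \%V_0) - 100$ exactly, which the
test suite asserts to $10^{-10}$ as a bookkeeping check. The continuous
time-average was chosen over a mean of raw solver points deliberately:
solver output density varies with step size and would bias a point mean
toward the fast transients inside fraction windows.

`post_treatment_attractor()` continues the integration well past the
protocol (default $2.5\times 10^5$ min) and labels the terminal state by
its nearest equilibrium. Matching compares the *total* cell volume
$T + T_S + T_R$ against $T^*$ (tolerance $10^{-4}$) and requires the
oxygen level on the equilibrium's side of $c_{min}$: the dead compartment
clears at the slowest timescale in the model, and its residual transiently
occupies space that $T$ has not yet refilled, so matching $T$ alone would
mislabel recently treated tumours. A terminal state matching neither
equilibrium returns `"unresolved"` with advice to lengthen the horizon.

## Virtual cohorts

A cohort fixes $V_0$ per regime ($5\times 10^{-4}$ NL, $5\times 10^{-3}$
SL, $2.75\times 10^{-3}$ BS) and draws $N = 250$ pairs $(q_1, q_3)$ from
the regime's region of the box $[10^{-2}, 10]^2$. Two samplers are
provided:

* **conditional** (default): $q_1$ uniform over the regime's feasible
  $q_1$ interval (closed form via the inverse of $V_N$), then $q_3$
  uniform over the regime's $q_3$ slice at that $q_1$ (slice endpoints by
  bisection on the classifier). Each $q_1$ slice carries equal weight.
* **rejection**: uniform over the two-dimensional region itself, so wider
  slices carry more weight.

The two coincide for NL cohorts, whose region is a rectangle (regime
membership is independent of $q_3$ there). They differ materially for SL
and BS cohorts because the bistable wedge carves the high-$q_1$,
high-$q_3$ corner out of the SL region: the conditional sampler's SL
cohort has median $\Delta_{viable} \approx -38$ with quartiles near
$(-54, -31)$ under the conventional protocol, whereas region-uniform
sampling over-weights strongly responding low-$q_1$ tumours (median
$\approx -49$). The conditional scheme is the default because slice-wise
uniform bounds are the natural reading of regime-dependent,
$q_1$-conditional sampling intervals, and because its population
statistics match the benchmark values; the rejection sampler is retained
for uniform-on-region designs and carries a chi-square uniformity test.

Cohorts are deterministic given a seed, restore the caller's RNG state,
and re-classify every member as a purity check. What the generator does
*not* emulate: real tumours are spatially structured, vascularised
dynamically (here $V_0$ is frozen, which is also why monostable tumours
always return to their pre-treatment volume), and heterogeneous within a
lesion. Passing cohort benchmarks therefore demonstrates reproduction of
the model's population behaviour, not clinical response rates.

## Problem sizes and known limitations

The test suite simulates the two representative monostable tumours, the
four NL composition benchmarks, the four BS switching tumours (horizon
$2.5\times 10^5$ min) and three cohorts of $N = 100$; the acceptance
script runs the full $N = 250$ cohorts. These sizes keep a complete run in
the one-to-two-minute range on a single core.

Known limitations:

* Near-periodicity of treated solutions is asymptotic. The viable and
  oxygen variables repeat week-over-week to a few parts in a thousand by
  week 7–8 of the conventional protocol, but the dead compartment's
  weekly drift contracts only by $e^{-\eta_R \cdot 10080} \approx 0.6$
  per week and is still 1–2% in week 8. A pointwise 0.5% periodicity
  check across all four variables is therefore not attainable at the end
  of an 8-week protocol and the corresponding assertions document this.
* The proximity index is sensitive to $q_1$ near the NL boundary:
  three-significant-figure parameter inputs can move $V_d$ by $\sim
  10^{-3}$ when $V_0 - V_N$ is itself of that order.
* Dimensional inputs are out of scope: the package works entirely in the
  dimensionless groupings; users with SI rates must nondimensionalise
  before constructing parameter sets.
* No normal-tissue toxicity constraint is modelled; the 80 Gy cap is a
  protocol input, not a toxicity model.
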