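---
title: "Cell-cycle criticality: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-cycle criticality: model, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclecrit)
```

This vignette is the package's account of the science it implements:
the single-cell model and its assumptions, the parameters that matter,
the population-level machinery, the numerical choices, and — equally
important — what the simulations do and do not demonstrate.

## 1. The Rb/E2F switch as a fold bifurcation

The G1–S transition is gated by a bistable switch built from mutual
antagonism between active Rb and the E2F/CycE axis, with CycD as the
mitogen-controlled input. The package uses a deliberately minimal
one-variable reduction: active Rb `r` obeys

$$dr = \big(1 - (\gamma_D + \gamma_P(r, C))\,r\big)\,dt + \sigma r\,dW,
\qquad
\gamma_P(r, C) = V\,\frac{C}{1 + C/k_1}\,\frac{1}{1 + (r/k_2)^2}.$$

The Hill-2 feedback term stands in phenomenologically for the
cooperative E2F/CycE cascade; any switch with a fold behaves the same
way near the fold, which is the regime everything else depends on. The
reference parameters are
`gamma_D = 1` h⁻¹, `V = 100` h⁻¹, `k1 = 1`, `k2 = 0.1`, `sigma = 0.3`
h^(-1/2), birth state `r0 = 4`, S-entry threshold `r_thresh = 0.05`
(concentrations in units of the production rate over `gamma_D`).
`find_fixed_points()` brackets sign changes of the drift on
`(0, 1/gamma_D]` and polishes them with `uniroot()`; the test suite
checks it against a generic polynomial solve of the equivalent cubic.
`find_bifurcation()` bisection-brackets the change in root count and
polishes the fold with a damped Newton solve of
`drift = 0, d(drift)/dr = 0` (tolerance 1e-4 on `C`; the Newton polish
is much tighter). With the reference parameters the bistable window is
`C` in (0.2176, 0.3521); the upper fold — the critical mitogen level —
is `C_crit = 0.352`, with the G1 state annihilating at `r* = 0.478`.

Integration is Euler–Maruyama in the Itô convention with post-step
clipping `r <- max(r, 0)`: the exact dynamics keep `r > 0` but a
discrete step can undershoot, and clipping is the simplest consistent
treatment. S entry is the first *sample* strictly below `r_thresh`, with
no sub-step interpolation; the induced O(dt) bias is covered by a
step-halving convergence test. Default steps are 0.1 h for population
runs and 0.05 h for single-cell ensembles.

## 2. Normal form and the Airy delay formula

Near the fold the dynamics collapse onto
$dx = (x^2 + \mu)\,dt + \xi\,dW$ with $\mu \propto C - C_\mathrm{crit}$.
The mean transition delay is the closed form

$$T(\mu, \xi) = 2^{1/3}\pi^2 \xi^{-2/3}
\left(\mathrm{Ai}^2\!\big[-2^{2/3}\xi^{-4/3}\mu\big] +
      \mathrm{Bi}^2\!\big[-2^{2/3}\xi^{-4/3}\mu\big]\right),$$

implemented in `mfpt_exact()`. Base R has no Airy pair, so the package
evaluates Ai and Bi through Bessel identities: modified Bessel `K` and
`I` for positive arguments (with `expon.scaled` so the whole formula is
available on the log scale far past double-precision overflow),
ordinary `J` for negative arguments, a Maclaurin series within |x| < 1
where the identities become 0/0, and the oscillation envelope
`Ai² + Bi² -> 1/(pi sqrt(z))` beyond `-2000`, where the Bessel argument
would exceed `besselJ`'s range. The switch-overs are covered by
continuity tests and the values by frozen 40-digit references.

`mfpt_kramers()` is the double-well escape approximation
$(\pi/\sqrt{|\mu|})\exp\!\big(\tfrac{8}{3}|\mu|^{3/2}/\xi^2\big)$, valid
for $\mu < 0$ deep in the barrier regime $|\mu|^{3/2}/\xi^2 \gg 1$; the
prefactor is the standard curvature one. `scaling_exponent()` recovers
the super-exponential law $\log T \sim |\mu|^{3/2}$ as the slope of
`log(log T)` against `log|mu|` (1.486 at `xi = 0.05` over `mu` in
[-0.6, -0.2], approaching 3/2 as `xi` shrinks).

`mfpt_empirical()` checks the theory by brute force: Euler–Maruyama
paths from $-\max(3, 3\sqrt{|\mu|})$ to absorption at
$+\max(3, 3\sqrt{|\mu|})$ — boundaries wide enough that the truncation
error sits below Monte-Carlo noise — with a hard time cap of 50 times
the exact prediction; capped paths are reported as a censored count,
never dropped silently. The central oracle test holds the ensemble mean
within three standard errors of the Airy value on a 3×3 grid of
$(\mu, \xi)$ chosen so every mean delay is under ~65 rescaled time units
(deeply sub-critical points have astronomically long delays and are
checked through the closed form instead).

`reduce_to_normal_form()` maps the switch onto the normal form by local
expansion at the fold: with $a = \partial_C \mathrm{drift}$ and
$b = \tfrac12 \partial_r^2 \mathrm{drift}$ at $(r^*, C_\mathrm{crit})$,
the substitution $x = b\,(r - r^*)$ (time unchanged, so one rescaled
unit is one hour) gives $\mu = ab\,(C - C_\mathrm{crit})$ and
$\xi = |b|\,\sigma r^*$. At the reference parameters
$\mu = 2.0\,(C - C_\mathrm{crit})$ and $\xi = 0.26$. Two regimes of
validity matter:

* at low molecular noise (`sigma = 0.05`, so `xi ≈ 0.044`) the mapped
  Airy delay predicts the full switch's mean G1 within 5% — the
  asymptotic regime, asserted in the tests;
* at the reference `sigma = 0.3` the reduction is qualitative only
  (`xi = 0.26` is outside the smallness assumptions and the quadratic
  approximation is exceeded during escape); the package still reports
  the mapped coefficients but no quantitative claim is tested there.

## 3. G1-length ensembles across mitogen conditions

`simulate_condition()` draws each cell's `C` from
$\mathcal N(C_m, C_s^2)$ (clipped at 0, constant through G1; `C_s =
0.05` throughout), integrates the switch, and records the first passage
below `r_thresh`; cells not out by 100 h are censored and excluded from
moments but counted. The four reference conditions are mTeSR1
(`C_m = 0.5`, n = 114), E8+IWP2 (0.6, n = 105), E8 (0.7, n = 112) and
mTeSR1+Wnt (1.5, n = 104). Where only a relative Wnt activity is
available, `wnt_to_C()` maps it linearly with the critical level
anchored at 3/4 of the minimal observed activity; explicit per-condition
`C_m` values override the mapping. With these inputs the simulated E8
ensemble averages ≈ 4.5 h and mTeSR1 ≈ 6.2 h, with the mTeSR1 CV about
1.4× the E8 CV and a visibly heavier upper tail (skewness test). The
CV contrast in the underlying experimental data is stronger (roughly a
factor 2.5); the forward model at these parameters reproduces the
direction and the variance amplification (variance ratio ≈ 3.8) but not
the full CV ratio — a known gap, stated here rather than hidden in a
tuned parameter.

Box summaries use type-7 quantiles (linear interpolation between order
statistics) and whiskers at the farthest points within 1.5 IQR —
whisker placement depends on the quantile convention, so it is fixed
and documented. `fit_r2()` scores model condition means and variances
against observed ones with plain $1 - SS_{res}/SS_{tot}$, and compares
against ordinary least-squares regressions on Wnt activity. Because
only four conditions enter, these R² values are noisy; the robust,
testable property (asserted over ten seeds) is that the forward model's
predictions outscore the linear baselines for both means and variances
on data the model itself generated.

`generate_dataset()` wraps the forward model into the standard per-cell
schema (condition, Wnt activity, G1 hours, censoring flag) with
optional additive measurement noise (default 0: the model itself has
none). What it emulates: condition-dependent means with heavy-tailed,
condition-dependent variance and exact per-condition sample sizes. What
it does not: correlated sister-cell fates, measurement frame
quantisation, reporter-intensity features, or any mismatch between the
fitted model family and reality — so passing recovery tests shows the
inverse machinery works on model-true data, not that the model is true.
`recover_parameters()` inverts by grid search, matching (mean,
log-variance) pairs; identifiability is sharp near the fold (median
absolute error ≤ 0.05 at n = 150 per condition) and degrades far above
it, where the objective profile flattens and is flagged.

## 4. Ghost transients and reversibility

Just above the fold, trajectories crawl through the remnant of the
annihilated fixed points. `simulate_ghost_ensemble()` (defaults: 50,000
cells, 100 h, dt = 0.05 h, `C ~ N(C_crit + 0.008, 0.004²)`) tracks
switch activity `1 - tanh(r)` against three thresholds — active (0.4),
high (0.7), S entry (`1 - tanh(r_thresh)`) — recording first crossings
online so full trajectories need only be kept for a subset. The
decomposition shows the signature multi-phasic G1: a long, highly
variable intermediate phase (active→high) followed by a short,
stereotyped final rise (high→S). `align_and_bin()` aligns trajectories
at S entry (t = 0), interpolates linearly on the activity scale, and
averages within total-G1 bins (quartile edges by default — the
published bin edges are not stated, so quartiles are the documented
choice).

`perturbation_experiment()` drops `C` by 0.1 at 15 h from a constant
`C_crit` start (100 cells, 80 h) and classifies each cell: *proceeds*
if it crosses the S-entry threshold after the drop; *reverts* if it
never enters S, was above activity 0.5 just before the drop, and
averages below 0.4 over the final 5 h (the averaging window is a
documented choice; the classification phrase "low on average" does not
fix one). Cells matching neither rule are labelled *other* — with these
settings many cells are still below the intermediate band at the drop
and simply stay quiescent. Both named classes are non-empty at the
defaults, and the probability of proceeding increases with activity at
the moment of inhibition — position along the trajectory, not elapsed
time, is what commits a cell.

## 5. Population control: fate topologies and feedback

Fate is coupled to cycle length by a competing-risks rule: each cell
draws a commitment time (exponential, mean `tau_d = 20` h — the
minimal memoryless choice; deterministic and gamma timers are available
analytically through `theta_of_T()`). Under **RD** the commitment clock
firing is itself the differentiation event: a cell that reaches its
commitment age leaves the population at that moment, so any division —
Rb-triggered or the slow baseline process (probability `dt/720` per
step) — is a self-renewal. Under **DR** fate is resolved at division:
dividing before the commitment age differentiates, after it renews.
Both rules give the same net bias
$\theta(T) = 2e^{-T/\tau_d} - 1$ (sign-flipped for DR) for a cell of
cycle length $T$; the distinction matters dynamically. An alternative
reading — RD cells differentiating only *at* their next division —
makes recovery of the set point from above structurally impossible:
during a sub-critical decline every cell's age exceeds its commitment
draw, no division can ever renew, and the population goes extinct
deterministically. The event-at-expiry semantics is the one under which
the RD circuit behaves as a population controller at all, and is what
the engine implements.

With feedback `C = C_crit N_st / N` (RD pairing, `df/dN < 0`) or
`C = C_crit N / N_st` (DR pairing, `df/dN > 0`), both topologies hold
the population at the set point — RD settles at ≈ 105 and DR at ≈ 94.5
for `N_st = 100` — and the time-averaged `C` experienced by cells sits
within ±0.05 of the fold: the feedback self-tunes the network to
criticality. The two topologies differ exactly as the stability chain
predicts (`stability_check()`): RD recovers from a 10-cell bottleneck
in tens of hours (bang-bang-like: far below the set point `C` is high
and every fast division renews), DR over thousands of hours (only the
slow baseline divisions, at ages beyond commitment, renew). At a
ten-cell niche both persist without extinction for 5000 h; RD holds
≈ 10.6 and DR ≈ 7.9 — at this size one cell is 10% of the feedback
signal and DR's slow recovery from downward excursions skews its time
average low; the pooled occupancy is within 10% of the set point.

Mis-sensing mutants perceive `alpha_i * N` with `alpha_i` mutated at
birth (probability 0.001 per division, log-normal factor with log-sd
0.5, floor 0.03; daughter only — the parent keeps its value). Both
topologies drift toward under-sensing clones (`alpha < 1`) and a higher
population fixed point `N_st/alpha`; RD is taken over within ~1–2
thousand hours while DR resists an order of magnitude longer because
its invading mutants carry long cycle times. Default horizons (8000 h
for the drift comparisons) were chosen from these convergence
diagnostics.

## 6. The two-compartment variant: an instability worth knowing about

Feeding the signal from the differentiated pool `D` (renewals keep `N`,
differentiation events add to `D`, `D` decays at `gamma`) and letting a
`D`-derived mitogen set `C` requires the DR fate rule by the sign
chain. The package's analysis goes one step further: with a *linear*
mapping `C ∝ D` anchored at the operating point, the `D`-compartment's
own response is destabilising — more `D` means more mitogen, shorter
cycles, and *more* differentiation flux into `D` — and the magnitude of
that loop, set by the critical sensitivity `|d log T / dC| ≈ 13` near
the fold, exceeds the stabilising decay `gamma` by roughly an order of
magnitude *for any* `gamma` (the anchoring scale cancels it).
Simulations confirm: every linear configuration tested collapses to an
absorbing depleted-pool state. The `differentiated_pool` variant
therefore includes a basal niche-derived mitogen under the `D`-derived
one, `C = C_basal + (C_crit - C_basal) D/D_st` with `C_basal = 0.3`
(just below the fold): the floor keeps slow cycling alive when the pool
is depleted so the flux can refill it. The system then settles into a
bounded stochastic oscillation around the set point, the RD pairing
still destabilises (runaway growth, as the sign chain demands), and the
steady-state balance `N_s/T_s = gamma D_s` holds within a few percent
when `T_s` is the *measured* mean age at fate events. The sharp-timer
value `tau_d log 2 = 13.86` h under-estimates the operational cycle
length by ~15% here: with dispersed cycle lengths the zero of the
*expected* bias sits at a longer mean (Jensen's inequality on
`exp(-T/tau)`), so both values are reported. Runs start from a fate
frozen warm-up (40 h with the pool clamped) because a cold,
synchronised cohort produces no differentiation flux for a full G1 —
an initialisation artefact, not dynamics.

## 7. Reproducibility mechanics

Every stochastic routine takes a seed and uses R's global RNG (the
compiled population engine draws through R's RNG as well, so
`set.seed()` governs everything); one seeded stream per run rather than
per cell keeps results exactly reproducible from the run seed, which is
the contract the manifests rely on. `run_stage()` executes any analysis
stage from a flat YAML/JSON configuration and writes a manifest
(resolved parameters, seed, package version, MD5 checksums), and
re-running a manifest reproduces its outputs bit-identically. Problem
sizes in the test suite are scaled-down versions of the reference
configurations (ensembles of 1–3 thousand cells, horizons of 3–8
thousand hours, 2–10 seeds per property), chosen so the full suite
exercises every claim at Monte-Carlo tolerances appropriate to those
sizes.

## 8. Known limitations

* One-variable switch: no explicit CycE/E2F species, no parameter
  inference for the switch itself.
* The normal-form reduction is quantitative only at low noise (§2).
* The CV amplification across culture conditions is weaker in the
  forward model than in the experimental data it emulates (§3).
* No spatial structure, asymmetric divisions, or biphasic short-G1
  removal; ligands are at quasi-steady state (the timescale-separation
  argument), so no explicit ligand ODE.
* The two-compartment circuit is stable only with the basal-mitogen
  floor (§6); the strictly linear pool feedback is genuinely unstable
  under critical sensitivity at these parameters.
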