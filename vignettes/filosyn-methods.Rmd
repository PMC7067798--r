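---
title: "Modelling filopodial kinetics and synaptogenesis with filosyn"
author: "filosyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling filopodial kinetics and synaptogenesis with filosyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filosyn)
```

## The biological system and the two models

An R7 photoreceptor axon terminal forms its 20–25 synapses serially
over roughly 50 h of pupal development. The terminal continuously
extends and retracts thin filopodia; occasionally a filopodium acquires
a bulbous tip, and a bulb that persists beyond 40 min (a *synaptogenic*
filopodium) can mature into a synapse. Only one to two synaptogenic
filopodia exist at any instant in the wild type, because they compete
for a limited supply of synaptic seeding factors; autophagy degrades
those factors, so autophagy loss raises, and autophagy upregulation
lowers, the number and stability of synaptogenic filopodia.

`filosyn` implements this picture at two timescales.

**The developmental model** tracks integer copy numbers of short-lived
filopodia (`sF`), long-lived filopodia (`lF`), transient bulbous tips
(`sB`), stabilized synaptogenic bulbs (`synB`) and synapses (`S`) from
P40 onwards (time in minutes after P40; 60 min per percent pupal
development, so P60 = 1200 min). Filopodia are generated at zero order
and retract at first order; bulbs form from any filopodium, retract,
stabilize, and mature. Three modulation functions shape the rates:

- `f_F(t)`: a fifth-order polynomial drive on filopodium generation,
  clamped at zero.
- `f_FB(t) = (1 + tanh[(3/t½)(t − t½)])/2` with `t½ = 1000` min: the
  late-developmental switch that turns bulb formation on.
- `f1(synB, B50)`: feedback of existing synaptogenic bulbs on new bulb
  formation.

**The mechanistic (winner-takes-all) model** resolves the competition
itself on the fast timescale: each filopodium holds `i` of `n = 120`
seed states, gains seeds from a free pool at `S·c_in` (c_in = 0.07),
releases them at `c_out = 1.5`, and retracts at hazard `1/i` — so the
filopodium that happens to accumulate most seeds lives longest and
accumulates still more. Genotypes differ *only* in the initial pool
`‖n·B̄(P60)‖` (round half up), where `B̄` is the genotype's mean
bulbous-tip count. Autophagy upregulation is modelled as loss of the
competitive advantage: a constant retraction hazard equal to
`c4 = 1/120`, which reproduces destabilized, short-lived bulbs without
changing the accumulation dynamics.

## Design choices where the published description is ambiguous

Several entries of the published formulation do not compose consistently;
the package makes the following choices and keeps the literal variants
available behind flags.

**Direction of the bulb feedback `f1`.** The typeset formula
`(synB + B50)/B50` *increases* with `synB`, which contradicts its
stated role (auto-inhibition through limited resources) and would make
the bulb count explode. The default is the saturating inhibition
`B50/(synB + B50)` ∈ (0, 1], equal to 1 with no bulbs and ½ at
`synB = B50`; the literal form remains available as
`f1_mode = "as_printed"`.

**Stabilization entry of the generator matrix.** The typeset transition
`[i, j] → [i, j + 1]` at rate `j·c5` neither consumes a transient bulb
nor scales with their number, conflicting with the reaction
`R5: sB → synB`. The default (`generator_mode = "reaction_consistent"`)
uses `[i, j] → [i − 1, j + 1]` at `i·c5`; the literal variant is kept
for comparison, and the two coincide when `c5 = 0` (a property the test
suite checks).

**The drive polynomial's printed coefficients.** Evaluated with `t` in
minutes, the printed `p5 = −2.97·10⁻¹⁴` term reaches −74 at P60, so the
clamped polynomial is identically zero from about 460 min onwards —
which would make the generation-constant estimate `c1 = λ·c2/f_F(P60)`
undefined. The exponents have most likely drifted in typesetting; since
the original coefficient source is not available, the package stores
the coefficients exactly as printed, raises an explicit error whenever
an operation would divide by a non-positive `f_F`, and lets simulations
replace the polynomial with a piecewise-linear drive interpolated from
per-stage filopodia counts (`filopodial_drive()`), normalized to 1 at
P60 so that `c1 = λ(P60)·c2` there. The built-in presets use such drive
tables.

**R3/R4 and the filopodium pool.** The published model explicitly neglects
the return flux of retracting bulbs into the filopodium compartment
because bulb numbers are small. The package applies the same
simplification to the outward flux: `R3` increments `sB` without
decrementing `sF`/`lF`. This keeps the filopodium compartment an exact
immigration–death process — whose Poisson stationary law is precisely
what the λ estimators assume — and makes the `(sB, synB)` subsystem
exactly the 2-D chain used for the stationary fit. The approximation is
good in the regime the data occupy (≈15 filopodia vs ≈2 bulbs).

**"Time step" of the mechanistic model.** The run length "100,000 time
steps" is interpreted as 100,000 Gillespie events; exponential waiting
times are tracked throughout so bulb lifetimes are reported in model
time, not event counts. Retraction returns all held seeds to the pool
(`G3`), which is required for the pool to be a conserved resource
rather than draining irreversibly; a no-return variant exists behind
`seed_return = FALSE` for sensitivity analysis. At `i = 0` the
competitive hazard `1/i` is undefined; empty filopodia retract at rate
1 (`1/max(i, 1)`). Seed accumulation is blocked at the state cap
`i = n`.

**c6 arithmetic.** The steepest synapse-accumulation slope for the
control data is 5 synapses per 600 min at 1.1 synaptogenic bulbs;
`estimate_c6()` reports the exact value 5/660 = 1/132 min⁻¹ (the published account
rounds the same expression to 1/133).

## Simulation scheme

The generation rates (through `f_F`) and the bulb-formation rate
(through `f_FB`) depend on time, so naive SSA would be biased. The
default sampler is a thinning (rejection) scheme: over a lookahead
window (default 10 min) each time-dependent factor is bounded above —
`f_FB` is increasing, so its bound is its value at the window end; the
drive is bounded on a 1-min grid with a small safety inflation — and
candidate event times drawn at the bounding rate are accepted with
probability true/bound. Between events the state is constant, so the
state-dependent factors are exact. This is statistically exact for any
bounded drive. A 1-min piecewise-constant-rate variant
(`method = "piecewise"`) is retained for cross-validation; the test
suite confirms the two agree on a time-dependent benchmark within
Monte-Carlo error.

The stationary distribution of the truncated `(sB, synB)` generator is
obtained from the dense eigendecomposition of `Gᵀ`, taking the
eigenvalue of smallest magnitude (analytically zero), clamping
round-off negatives and renormalizing; the residual `max |Gᵀv|` is
reported. A reducible generator (e.g. `c5 = c6 = 0`, which freezes
`synB`) is detected by counting near-zero eigenvalues and reported with
its communicating classes rather than returning an arbitrary
eigenvector. The truncation defaults to `N = 15` and is enlarged until
the stationary mass within one count of the reflecting boundary is
below 10⁻⁶ (`choose_truncation()`).

## Fitting (c5, B50, r3)

`fit_bulbs()` minimizes the equally weighted sum of the two
Kullback–Leibler divergences `KL(observed ‖ model)` for the `sB` and
`synB` marginals, with `c4` and `c6` fixed, a pseudocount of 10⁻⁶ per
bin, positivity enforced by log-parameterization, and a deterministic
optimizer: a 5×5×5 log-spaced grid centred on moment-matched initial
values, refined by Nelder–Mead from the three best grid points. Whether
the two KL terms should be weighted is not specified in the published
workflow; equal weights are used and recorded in the fit object.
`B50` has the flattest likelihood of the three parameters — recovery
tests bound it at ±25% where `c5` and `r3` recover within ±15% — which
is expected, since `f1` enters only through its values at the handful
of `synB` counts that carry mass.

## The synthetic-data generators and what they do (not) show

No imaging data are deposited with the published study, so the package
generates the observation layer itself, from known ground truth:

- `gen_track_table()` emulates the live-imaging design: 60-min windows
  (default), 8 terminals per genotype, snapshots at a 1-min cadence
  (the live cadence at P60 is not stated in the published account; it is a
  parameter, never hard-coded). Because the filopodium classes are
  *defined* by the 8-min lifetime cutoff, each class is generated as a
  stationary M/G/∞ immigration–death process whose class-conditional
  lifetime law lives on its side of the cutoff with mean exactly
  `1/c2` — truncated exponential below, `cutoff +` exponential above
  (memoryless beyond the cutoff, i.e. first-order retraction once
  established). Concurrent counts are then exactly Poisson(λ) and the
  inverse-mean estimators are consistent, so parameter recovery tests
  measure estimator noise, not definitional bias. Objects alive at a
  window boundary are emitted censored rather than with truncated
  lifetimes, and the estimators exclude them.
- `gen_bulb_observations()` simulates the exact 2-D bulb chain and
  tabulates empirical marginals after discarding a relaxation prefix —
  this doubles as the brute-force oracle against which the eigen-solve
  is verified (total-variation distance < 0.02 in the tests).
- `gen_fixed_timepoints()` emulates the fixed-preparation counts
  (default 40 terminals per stage, stages every 10 percent).

Every generator takes a single seed and emits a manifest sufficient to
regenerate its output exactly.

What passing these tests shows is *internal* consistency: the
estimators recover the parameters of data generated under the model's
own assumptions at the study's sample sizes. Real imaging data violate
those assumptions in known ways — lifetimes are measured on a frame
grid, tracing errors truncate tracks, filopodia counts drift within a
window — none of which the generators emulate, so recovery tolerances
here are lower bounds on real-data uncertainty.

## Genotype presets and calibration

The genotype-specific parameter values of the published study's
supplementary tables are not reproduced in its text, so the built-in
presets (`genotype_presets()`: `control`, `atg_mutant`, `upregulated`)
are synthetic stand-ins assembled as follows and frozen. Shared,
published constants: `c4 = 1/120` min⁻¹, `c6 = 5/660` min⁻¹,
`t½ = 1000` min, the printed drive-polynomial coefficients (stored but
overridden by drive tables, as above). Filopodium statistics
(λ ≈ 6 + 9 at P60, mean lifetimes 3 and 15–20 min) are plausible values
on the measured scale. The bulb triple `(c3, c5, B50)` of each genotype
was calibrated once, by fixed-point iteration on the stationary
eigen-solve, so that the P60 stationary bulb means sit mid-band for the
reported phenotypes — control ≈ 0.35 transient + 1.45 stabilized
(one-to-two band, and a control full course that accumulates 20–25
synapses by P90), `atg_mutant` ≈ 0.5 + 3.0 (three-to-four band),
`upregulated` ≈ 0.3 + 0.5 (reduced and destabilized) — with feedback
strength `B50` increasing (inhibition weakening) in the mutants, as the
resource interpretation implies. The calibrated values are defaults of
the data structures, not measurements, and every function accepts
user-supplied parameter files instead.

Problem sizes used by the test suite were chosen to keep Monte-Carlo
error well inside the asserted tolerances while remaining quick on one
CPU: 40 terminals for the full-course synapse check, ≥10⁴ events for
lifetime recovery, 10⁴ snapshots for dispersion checks, and ≥10⁵ min of
simulated time for stationary-distribution comparisons.

## Known limitations

- No spatial structure: medulla layers and target selection are outside
  the model; synapse counts are per-terminal totals.
- The two models are run separately, as in the published workflow; the
  seed-pool dynamics do not feed back into the developmental rates.
- Censoring is handled by exclusion, not by survival analysis; only
  basic bootstrap intervals are provided for `c2` and λ.
- The stationary fit freezes `t = P60`; no time-resolved fitting of
  `(c5, B50, r3)` is attempted.
- The dense eigen-solve is comfortable to `N ≈ 60` (3721 states); far
  larger truncations would need sparse methods, which the biology does
  not require.
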