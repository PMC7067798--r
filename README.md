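# filosyn

Stochastic models of filopodial kinetics and synapse formation in
developing *Drosophila* R7 photoreceptor axon terminals.

During the second half of pupal development (P40–P100, modelled as
minutes after P40 with 60 min per percent), an R7 axon terminal extends
many short-lived exploratory filopodia, a few of which acquire bulbous
tips; bulbs that stabilize for more than 40 min are synaptogenic and can
mature, one by one, into synapses. Autophagy tunes this process by
degrading the synaptic seeding factors (Syd-1, Liprin-α) that stabilize
bulbous tips. `filosyn` implements the two stochastic models that make
this quantitative, and the estimation machinery that connects them to
live-imaging observables:

- **Developmental model** — a time-inhomogeneous Markov jump process
  over copy numbers (sF, ℓF, sB, synB, S) with reactions

  ```
  R1,sF: ∅ → sF        r1,sF = f_F(t)·c1,sF
  R2,sF: sF → ∅        r2,sF = sF·c2,sF          (ℓF analogous)
  R3:    F  → sB       r3 = c3·(sF+ℓF)·f1(synB, B50)·f_FB(t, t½)
  R4:    sB → ∅        r4 = c4·sB
  R5:    sB → synB     r5 = c5·sB
  R6:    synB → S      r6 = c6·synB
  ```

  where `f_F` is a fifth-order polynomial drive on filopodium
  generation, `f_FB(t) = (1 + tanh[(3/t½)(t − t½)])/2` switches
  bulb formation on late in development (t½ = 1000 min), and
  `f1 = B50/(synB + B50)` is the saturating auto-inhibition by existing
  synaptogenic bulbs. Simulation is exact (thinning SSA;
  `simulate_developmental()`).

- **Bulbous-tip stationary inference** — on the fast timescale the
  (sB, synB) pair is a 2-D continuous-time Markov chain; the package
  builds its truncated generator matrix (`build_generator()`), solves
  `Gᵀv = λv` at λ₀ = 0 for the stationary law
  (`stationary_distribution()`), and fits (c5, B50, r3) to observed
  count distributions by Kullback–Leibler minimization (`fit_bulbs()`).

- **Parameter estimation** — retraction constants as inverse mean
  lifetimes split at the 8-min cutoff, generation constants from the
  Poisson stationary relation c1 = λ·c2/f_F, c4 fixed at 1/120 min⁻¹,
  c6 from the steepest synapse-accumulation slope (5/(1.1·600) = 1/132
  min⁻¹), and c3 = r3/((sF+ℓF)·f_FB); assembled per genotype by
  `estimate_genotype()`.

- **Winner-takes-all mechanistic model** — filopodia compete for a
  conserved pool of seeding factors (gain S·c_in, release c_out,
  retract at hazard 1/i where i is the seeds held); genotypes differ
  only in pool size ‖n·B̄(P60)‖, and autophagy upregulation is modelled
  as loss of the competitive advantage (constant retraction hazard
  c4). `simulate_mechanistic()`, `analyze_bulbs()`.

- **Synthetic data** — seeded generators for track tables, count
  snapshots and bulb count distributions (`gen_track_table()`,
  `gen_bulb_observations()`, `gen_fixed_timepoints()`) so every
  estimator is testable by parameter recovery.

## Worked example

```r
library(filosyn)

# stationary bulb statistics of the built-in control genotype at P60
params <- genotype_presets()$control
m <- stationary_bulb_summary(params)
print(stationary_distribution(attr(m, "generator")))
#> Stationary distribution on [0, 15]^2 (eigenvalue 5.24e-16, residual 5.91e-17)
#>   E[sB] = 0.350, E[synB] = 1.450, E[total] = 1.800
```

The eigenvalue is numerically zero, as it must be for a proper
generator; the control terminal holds 1–2 concurrent bulbous tips at
P60, most of them stabilized (synB).

```r
# recover (c5, B50, r3) from synthetic count distributions
obs <- gen_bulb_observations(r3 = 0.0218, c4 = 1/120, c5 = 0.0314,
                             c6 = 5/660, B50 = 2, total_time = 120000,
                             sample_dt = 20, N = 8, seed = 42)
fit <- fit_bulbs(obs$sB, obs$synB, c4 = 1/120, c6 = 5/660, N = 8)
print(fit)
#> Bulbous-tip stationary KL fit
#>   c5 = 0.03026, B50 = 3.405, r3 = 0.01852   (KL objective 0.0009024)
#>   fixed: c4 = 0.008333, c6 = 0.007576; N = 8; reaction_consistent / inhibition
```

The stabilization constant and birth rate come back within ~5–15% of
the generating values (c5 = 0.0314, r3 = 0.0218); `B50` has a flat
likelihood around the optimum and is the least identifiable of the
three, which the recovery tests bound at ±25% for long observation
times.

```r
# full estimation chain on a synthetic live-imaging experiment
tracks <- gen_track_table(6, 9, 1/3, 1/15, duration = 600,
                          n_terminals = 8, seed = 42)
gf <- estimate_genotype(tracks$tracks, tracks$snapshots,
                        bulb_obs = list(sB = obs$sB, synB = obs$synB),
                        genotype_label = "synthetic control")
print(gf)
#> Genotype parameter estimation — synthetic control
#>   c1_sF      2.0118
#>   c1_lF      0.58824
#>   c2_sF      0.33235
#>   c2_lF      0.067265
#>   lambda_sF  6.0532
#>   lambda_lF  8.7452
#>   c3         0.0016283
#>   c4         0.0083333
#>   c5         0.030261
#>   c6         0.0075758
#>   B50        3.4048
#>   r3         0.018518
```

Retraction constants (true 1/3 and 1/15) and Poisson means (true 6 and
9) are recovered to within a few percent; `c4` is fixed at the
published 1/120 and `c6` at the published slope value, as the
estimation workflow prescribes.

A command-line pipeline over the same functions is available via
`inst/cli/filosyn.R` (subcommands `synth`, `simulate-dev`,
`simulate-mech`, `estimate`, `fit-bulbs`, `summarize`), e.g.

```sh
Rscript inst/cli/filosyn.R synth --preset control --seed 7 --out out/
Rscript inst/cli/filosyn.R estimate --tracks out/tracks.csv \
  --snapshots out/snapshots.csv --sb out/dist_sB.csv \
  --synb out/dist_synB.csv --out fit/
```

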