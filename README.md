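# loopkit

Cyclization ("looping") and decyclization ("unlooping") of short DNA with
complementary single-stranded overhangs is the workhorse assay for measuring
DNA bendability, but the two rates respond very differently to where the
sticky ends sit around the helical axis.  `loopkit` implements the models
that explain this for ~100-bp DNA, and a fully synthetic single-molecule
FRET pipeline to validate the rate estimators that connect those models to
experiment.

**For whom:** biophysicists and quantitative biologists analyzing
single-molecule looping kinetics, and anyone modeling the bending mechanics
of DNA shorter than one persistence length.

## What it computes

* **Rigid base-pair elastic model** — per-step (tilt, roll, twist) angles
  with quadratic energy `E/kT = Σ αᵢ (xᵢ − x₀ᵢ)²`, finite helix width
  (backbone strands at the corners of the base-pair rectangle), optional
  phased intrinsic curvature, 3-D reconstruction, XYZ/PDB-trace export.
* **Constrained loop minimization** — teardrop loops under a stiff harmonic
  sticky-end distance constraint; registered energy landscapes
  `E_bend(Θ, L)` over bending directions Θ and lengths L; nicked-circle
  loops with end excluded volume.  Transition-state looping rates
  `k_loop(L) ∝ Σ_Θ exp(−E_bend(Θ, L)/kT)`; oscillation-period analysis.
  The straight finite-width model oscillates with a ~10.5-bp period (maxima
  at half-integer helical turns); adding central intrinsic curvature of one
  helix-width deflection makes the loop energy oscillate with a ~21-bp
  (two-turn) period.
* **J factors** — Monte Carlo capture-ball J for a discrete wormlike
  chain; semi-analytic aligned J with a helical twist-mismatch factor;
  alignment free energy `ΔG_θφ = −kT ln(J_θφ/J)` versus nick stacking;
  constrained (looped) end-angle distributions via a Metropolis sampler;
  experimental `J_exp = k_loop / k_on`.
* **Three-state kinetics** — unlooped ⇄ teardrop ⇄ smooth (nick-closed)
  loop: exact stochastic simulation, equilibrium occupancies, and the
  effective decyclization rate `k_unloop = k₂k₄/(k₃+k₄)` of the
  equilibrated looped pair.
* **Synthetic smFRET** — salt-jump trace generation (two FRET levels,
  Gaussian noise, photobleaching), two-point smoothing, transition
  detection, censoring-aware exponential rate fitting with
  profile-likelihood intervals, and the photobleaching bias of
  censoring-naive estimates.

## Worked example

Minimize a 105-bp loop (10 helical turns) at a 1-nm sticky-end contact:

```r
library(loopkit)

p <- dna_params(105, persistence_length = 50)
fit <- minimize_loop(p, register_angle = 0)
fit
#> <loop_fit> 105 bp: E_bend = 18.684 kT, end distance 1 nm (target 1),
#>   converged in 2177 iterations
```

18.7 kT is the elastic price of closing ten helical turns of DNA into a
teardrop — a few kT above the zero-width elastica value because at an
integer number of turns the sticky ends sit on opposite helix faces.

Run a synthetic looping experiment (250 molecules, salt jump at 20 s,
true k_loop = 0.05 s⁻¹) and recover the rate and the experimental J factor:

```r
rates <- three_state_rates(k1 = 0.05, k2 = 0)
cfg <- trace_config(rates, n_traces = 250, seed = 42)
res <- recover_rates(cfg, k_on = 1.196e6)
res
#> <recovery_result> loop experiment: k = 0.0496 s^-1
#>   (95% CI 0.04371-0.056), 250 usable traces, 0% censored,
#>   J_exp = 41.47 nM
tidy(res$fit)
#> # A tibble: 1 × 5
#>   term  estimate std.error conf.low conf.high
#>   <chr>    <dbl>     <dbl>    <dbl>     <dbl>
#> 1 rate    0.0496   0.00314   0.0437    0.0560
```

The pipeline recovers the true 0.05 s⁻¹ within its confidence interval and
converts it to an effective molar concentration with the measured annealing
rate constant.  `autoplot()` methods show traces, landscapes, rate
profiles, periodograms and survival curves; see the methods vignette
(`vignettes/loop-mechanics.Rmd`) for the models, assumptions, and numerical
choices.

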