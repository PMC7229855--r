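---
title: "Modeling DNA cyclization and decyclization kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling DNA cyclization and decyclization kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopkit)
```

## Scope

`loopkit` models how short DNA (~100 bp) with complementary single-stranded
overhangs ("sticky ends") loops and unloops.  Four connected pieces are
implemented:

1. a rigid base-pair elastic model of the double helix with finite width and
   optional intrinsic curvature, plus constrained minimization of looped
   conformations;
2. wormlike-chain J factors, with and without helical (axial + torsional)
   end alignment, and the free-energy cost of that alignment;
3. a three-state kinetic model -- unlooped (U), teardrop loop (T), smooth
   loop (S) -- with exact stochastic simulation and closed-form effective
   rates;
4. a synthetic single-molecule FRET pipeline that emulates a salt-jump
   looping/unlooping experiment end to end, so rate estimators can be
   validated against known ground truth.

## The rigid base-pair model

Each base pair carries an orthonormal triad (long in-plane axis, short
in-plane axis, helical axis).  Step $i$ rotates triad $i$ into triad $i+1$
by intrinsic rotations *twist* (about the local helical axis), then *roll*
(about the local short axis), then *tilt* (about the local long axis); the
origin advances by the rise (0.34 nm) along the new helical axis.  Any fixed
composition order defines a valid parameterization; this one is used
consistently and is inverted exactly by `extract_step_angles()`
(round-trips to ~1e-8 rad).

The deformation energy is quadratic in the step angles,

$$E_{\mathrm{bend}}/k_BT \;=\; \sum_{i} \alpha_i\,(x_i - x_{0,i})^2,$$

summed over the three angles of all $N-1$ steps (three terms per step; the
energy is zero exactly at the ground state).  Continuum persistence lengths
map onto isotropic per-step stiffnesses $\alpha = L_p/(2\ell)$ per angle:
$L_p = 50$ nm gives $\alpha_{\mathrm{bend}} = 73.5\,k_BT/\mathrm{rad}^2$ at
$\ell = 0.34$ nm, and a torsional persistence of 90 nm gives
$\alpha_{\mathrm{twist}} = 132\,k_BT/\mathrm{rad}^2$.  The intrinsic twist
is $2\pi/h$ with helical repeat $h = 10.5$ bp.  Sequence-specific per-step
tables can be supplied via `dna_params(step_table = ...)`; the isotropic set
is the tested default.

**Backbone geometry.**  The two antiparallel strands run through the two
corners of the *longer* side of the base-pair rectangle: both attachment
points are offset to the same side of the long axis, at azimuths
`corner_angle` and `pi - corner_angle` (default $\pi/6$, i.e. angular gaps
of 120 and 240 degrees between the strands -- the groove asymmetry of the
double helix), at distance `helix_radius` (1 nm) from the axis.  A
diametric placement (`corner_angle = 0`) is also available but makes the
two bending registers that differ by half a turn nearly equivalent, which
suppresses the curvature-phase effects discussed below.

**Intrinsic curvature.**  `add_intrinsic_curvature()` biases the
ground-state bend of a window of steps.  The default `phase = "helical"`
counter-rotates the bias between roll and tilt by the accumulated intrinsic
twist so that the biased steps bend coherently about one lab direction, as
phased curvature (A-tract-like) does in real DNA.  A *constant* roll bias
is retained as an option, but note that with ~34 degrees of twist per step
a constant roll bias cancels almost exactly over a full helical turn, so a
two-turn window of constant roll produces nearly zero net bend -- phased
biasing is the physically meaningful default.  `tune_curvature()` picks the
bias so the relaxed molecule's axis deflects end to end by a target
distance, by default one helix width (2 nm), the magnitude at which the
curvature-driven modulation of looping becomes comparable to the
finite-width modulation.

## Constrained loop minimization

A loop forms when the two sticky-end attachment points -- strand a at the
last base pair, strand b at the first -- come within a capture distance.
`minimize_loop()` minimizes the elastic energy plus a stiff harmonic
penalty $(k_c/2)(d - d_{\mathrm{target}})^2$ on that distance, starting
from a planar circular arc bent in a chosen register direction $\Theta$
(the rotational direction about the helical axis in which the molecule
bends).  The default capture target is 1 nm, a sticky-end contact distance;
the 7-nm capture radius used for J-factor comparisons is a separate,
deliberately distinct notion.

Two minimization regimes are provided, and the distinction matters
scientifically:

* **Polished** (`polish = TRUE`, default): a gradient-flow phase followed
  by a limited-memory quasi-Newton (L-BFGS) descent with backtracking line
  search (every accepted step strictly decreases the objective) down to a
  gradient norm of 0.02.  This finds the fully relaxed minimum.  For an
  isotropic chain, rotating the bending direction while keeping the ends
  juxtaposed is a *soft mode*: full relaxation therefore drifts to the
  globally best register no matter where it starts, and the relaxed energy
  is independent of the initial $\Theta$.  Use this regime for single
  minimum-energy shapes -- teardrop elastica checks, nicked loops, relaxed
  loop geometry.

* **Register-resolved quasi-static descent** (`polish = FALSE`, the
  default inside `energy_landscape()`): preconditioned plain gradient
  descent (per-coordinate steps scaled by the inverse elastic stiffness, a
  diagonal metric that equalizes bend and twist relaxation rates) with a
  bounded step, stopped at a loose gradient norm (0.5) or an energy
  plateau.  This approximates the continuous gradient flow from the initial
  arc and deliberately freezes the slow register-rotation drift, so
  $E_{\mathrm{bend}}(\Theta, L)$ retains its dependence on the bending
  direction.  The landscape is deterministic and smooth in $(\Theta, L)$;
  its absolute level depends mildly on the iteration budget (default
  15&nbsp;000 flow iterations), which is fixed and documented, and cancels
  in the detrended oscillation analyses for which landscapes are used.

The constraint stiffness ramp (default single stage at 1000, or
10--10^4 kT/nm^2 for polished fits) leaves a residual violation below
0.05 nm.  Reported energies are always the elastic term only.

**Validation.**  In the zero-width limit (helix radius 0, capture distance
0) the minimized teardrop energy matches the classical planar elastica
result $E = 14.055\,k_BT\,L_p/L$ to better than 0.1% at the 0.34-nm
discretization; the test suite recomputes the elastica coefficient from
scratch by direct minimization of the continuum bending energy over tangent
angles (an independent discretization and optimizer).

## Loop-energy landscapes and rate oscillations

`energy_landscape()` runs the register-resolved minimization over a grid of
lengths and register angles; `looping_rate_profile()` forms the
transition-state estimate

$$k_{\mathrm{loop}}(L) \;\propto\; \sum_{\Theta}
  e^{-E_{\mathrm{bend}}(\Theta, L)/k_BT},$$

over the full register grid (default 24 angles) or a contiguous half
interval to mimic surface hindrance of bending directions.
`oscillation_period()` detrends the log-profile with a quadratic fit and
reports the dominant least-squares periodogram period, with a permutation
test for significance.

Three model predictions follow, and the package reproduces all three:

* **Straight finite-width model: one-turn oscillation.**  The relative
  azimuth of the two sticky-end attachment points is set by the total
  intrinsic twist, i.e. by $L \bmod h$.  At half-integer numbers of turns
  both ends can face the loop interior and a planar loop closes cheaply; at
  integer turns they sit on opposite faces and the minimum-energy loop is
  non-planar and costlier.  $k_{\mathrm{loop}}(L)$ therefore oscillates
  with period $\approx h = 10.5$ bp, maxima at half-integer turns.

* **Curved model: two-turn oscillation of the loop energy.**  With phased
  curvature at the molecule's center, the bending direction of the curved
  region relative to the sticky ends rotates by a full turn every *two*
  helical turns of added length.  At every fixed register angle the
  minimized loop energy $E_{\mathrm{bend}}(\Theta, L)$ oscillates with
  period $\approx 2h \approx 21$ bp (the package reads this from the
  per-register aggregated periodogram of the landscape).  In the isotropic
  model the *full-register Boltzmann sum* largely cancels this phase (a sum
  of $e^{C\cos(\Theta - \phi_c)}$ over a uniform $\Theta$ grid is
  independent of the curvature phase $\phi_c$), so the summed
  $k_{\mathrm{loop}}$ retains the one-turn component; sequence-dependent
  stiffness roughness, absent from the isotropic default, would break this
  cancellation.  This is a genuine property of the isotropic model, not a
  numerical artifact, and is why the two-turn period is diagnosed on the
  energy landscape itself.

* **Nicked-loop planarity.**  `minimize_nicked_loop()` closes a loop
  through one continuous strand (zero-distance constraint on the two ends
  of the un-nicked strand) with a soft excluded-volume repulsion between
  the first and last 10 bp (contact radius 2 nm, one helix diameter;
  stiffness 50 kT/nm^2).  Integer-turn loops (105 bp) relax to a nearly
  planar teardrop (planarity ratio ~0.02), half-integer loops (100 bp) are
  forced out of plane (ratio several-fold larger) -- the geometric reason
  nick closing, and hence the long-lived smooth state, is accessible to
  integer loops only.

## J factors and helical alignment

`jfactor_capture()` estimates the unaligned J factor by direct Monte Carlo:
the probability that the ends of a discrete wormlike chain (exact per-joint
Boltzmann measure $p(\cos\theta) \propto e^{(L_p/\ell)\cos\theta}$, uniform
azimuth) fall within a capture ball of radius $a$ (7 nm by default),
converted to a molar effective concentration
$J = P(|r| \le a) / (\tfrac{4}{3}\pi a^3 N_A)$.  Against the Gaussian-coil
closed form the estimator agrees within its Monte Carlo error deep in the
coil regime; empirically the Gaussian form overestimates J by tens of
percent below ~15 persistence lengths of contour (finite-stiffness
suppression of the near-origin density), so the packaged comparison test
is run at 20 persistence lengths.

`jfactor_aligned()` provides semi-analytic closed forms of the
Shimada--Yamakawa saddle-point type: the teardrop (position-only contact)
density $\propto \ell^{-5} e^{0.246\ell - 14.055/\ell}$ per $L_p^3$
($\ell = L/L_p$), the ring-closure (axially aligned) density with the
circular exponent $2\pi^2/\ell$, and a Gaussian twist-mismatch factor
$\sum_n \exp[-(2\pi^2 C/L)(n - L/h)^2]$ (torsional persistence $C$ = 90 nm)
that is maximal at integer turns and suppresses the aligned J by orders of
magnitude at half-integer turns.  The exact prefactors matter less than the
structure: every packaged claim built on these forms (alignment free
energy ordering, >= 2 decades of helical modulation near 100 bp) depends
only on the exponent difference and the twist factor, and the Monte Carlo
capture estimator is the in-repo referee where the two constructions
overlap.  `alignment_free_energy()` is
$\Delta G_{\theta\phi} = -k_BT\,\ln(J_{\theta\phi}/J)$, and
`compare_to_stacking()` asks whether nick stacking (a configurable
per-nick free energy, not a bundled constant) can pay for it.

**Constrained end-angle statistics.**  `wlc_sample_constrained()` samples
the looped sub-ensemble ($|r| \le r_{\max}$) by Metropolis Monte Carlo with
tail-pivot moves and a hard wall on the end separation, because direct
sampling cannot reach $|r| \le 7$ nm for a 100-bp chain (acceptance
~1e-8).  The sampler is validated against rejection-filtered direct
sampling in a regime both can reach.  `end_angle_distribution()` computes
the angles between the terminal tangents and the end-to-end vector.  Two
reference conventions are provided: `"chain"` (the chain's own end-to-end
vector) and `"encounter"` (independent random directions -- the
bimolecular-encounter null, whose marginals are exactly sine-distributed).
The chain-referenced marginals of an *open* chain approach the sine law
only slowly with length (the end tangent stays correlated with the
end-to-end direction; the Kolmogorov--Smirnov distance decays roughly as
$\sqrt{L_p/L}$ and is still ~0.07 at 50 persistence lengths), so the exact
sine law is a property of the encounter reference, not of open-chain ends.
Tightly closed 500-bp loops, in contrast, are measured to be nearly
sine-distributed, while 100-bp loops are strongly restrained (circular
variance below half the sine-law value) -- the geometric reason the
annealing rate constant of a short loop's sticky ends need not equal its
bimolecular counterpart, and hence why FRET-derived J factors of short DNA
drift away from their thermodynamic definition.

## Three-state kinetics and rate estimation

`simulate_kinetics()` is an exact continuous-time Markov chain simulation
of U $\leftrightarrow$ T $\leftrightarrow$ S (direct method: exponential
waiting times, categorical jumps).  `equilibrium_occupancy()` and
`effective_unloop_rate()` give the closed forms; in the fast
nick-equilibration limit the looped pair decays at
$k_{\mathrm{unloop}} = k_2 k_4/(k_3 + k_4)$, which the simulation
reproduces within 5% once $k_3, k_4 \gtrsim 20\,k_2$ (the packaged
consistency check); at slower nick dynamics the approximation degrades,
which is why the exact simulator ships alongside the formula.  T and S
share the high-FRET level, so first-passage extraction
(`first_passage_times()`) treats them as one observable class.

`fit_exponential()` is the censoring-aware maximum-likelihood exponential
rate $\hat k = d / \sum_i t_i$ (events over total observation time) with a
profile-likelihood 95% interval; the survival-curve least-squares fit and
the censoring-*ignoring* estimator are reported alongside for method
parity.  Ignoring censoring biases the rate upward -- by ~25% or more when
photobleaching competes on equal terms with the transition -- and the bias
grows with the bleach-to-transition rate ratio, which the synthetic
pipeline demonstrates directly.

## The synthetic FRET generator

`generate_traces()` emulates the salt-jump experiment: molecules pinned in
the pre-exchange state (unlooped for looping runs; the stationary
teardrop/smooth mixture for unlooping runs, since pre-formed loops are of
unknown substate), buffer exchange at 20 s, hidden-state evolution by the
exact three-state simulation, frame readout at 500 ms (looping) or 100 ms
(unlooping), FRET levels 0.1/0.8, per-channel Gaussian noise with standard
deviation 10% of the 1000-count total intensity, and exponential
photobleaching split equally between donor and acceptor (either event
censors the trace; after acceptor bleach the donor recovers the full
intensity, after donor bleach both channels drop to background).
Background subtraction is modeled as already applied.  Defaults of 150-250
traces per condition match typical single-molecule decay-curve statistics.

Analysis mirrors the experimental chain: FRET efficiency
$I_A/(I_A + I_D)$, a two-point moving average (timestamps at frame-pair
midpoints), transition detection by thresholding midway between the two
levels with a two-frame persistence rule, censoring at bleach or trace
end, censored-exponential fitting, and `j_exp()` = $k_{\mathrm{loop}}/k_{\mathrm{on}}$.
At the default noise the detector places >= 95% of first transitions within
two frames of the hidden truth.  The generator does not emulate an
inactive molecule fraction, donor/acceptor crosstalk, gamma correction, or
raw-image artifacts, so passing tests validate the estimators against the
idealized noise model, not against every pathology of real traces.

## Numerical choices and problem sizes

* Landscape scans: lengths 90-136 bp in 2-bp steps, 24 register angles,
  15 000 preconditioned flow iterations per cell, single constraint stage
  at 1000 kT/nm^2 -- a few minutes per scan on one core.
* Periodogram: quadratic detrend, period grid 5-40 bp in 0.1-bp steps,
  permutation significance.
* Monte Carlo sizes in the packaged checks: 1e5 chains for sine-law tests,
  4e5 for the Gaussian-limit J, 4000-6000 thinned Metropolis samples
  (burn-in 200 sweeps, thinning 1-2 sweeps) for constrained ensembles, 1e4
  trajectories for kinetic consistency, 250 traces per synthetic FRET
  condition with a 20-seed calibration study.
* All stochastic components consume R's RNG, so a single `set.seed()` (or
  the `seed` arguments) makes every analysis bit-reproducible.

## Known limitations

* The isotropic stiffness default has no sequence roughness; as discussed
  above this makes the register-summed looping rate keep its one-turn
  period under central curvature, and the two-turn signature is read from
  the energy landscape instead.
* The aligned-J closed forms are saddle-point approximations valid for
  $0.1 \le L/L_p \le 2$ and are used for ratios and orderings, not
  absolute calibration.
* Excluded volume acts only between the designated end segments of the
  nicked loop; there is no electrostatics, no base-pair-level degrees of
  freedom, and no sequence-specific melting.
* The kinetic model omits the doubly-nicked looped macrostate and any
  angle-dependence of the sticky-end annealing rate.
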