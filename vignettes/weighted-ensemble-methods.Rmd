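---
title: "Binless and adaptive resampling for weighted-ensemble path sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binless and adaptive resampling for weighted-ensemble path sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binlesswe)
```

## The weighted-ensemble strategy

Rare events — a ligand leaving a buried binding site, a barrier crossing in
a rugged landscape — are invisible to straightforward simulation because
the waiting time dwarfs any affordable trajectory. Weighted ensemble (WE)
attacks the waiting, not the dynamics: many weighted trajectory segments
(*walkers*) run in parallel, and at a fixed resampling interval τ the
ensemble is reshaped. Walkers advancing into undersampled territory are
*split*, dividing their statistical weight among identical children;
redundant walkers are *merged*, the survivor drawn with probability
proportional to weight and absorbing the group's total. The dynamics
themselves are never biased — only the bookkeeping of which trajectories
carry how much probability changes — so any weighted expectation over the
ensemble remains exact.

Two rules are load-bearing, and this package checks both continuously:

1. **Conservation.** Weights sum to one, always. `assert_conservation()`
   runs after every propagation and resampling step at tolerance 1e-12
   (weights are doubles; demanding exactness to the last bit would force
   rational arithmetic for no statistical gain).
2. **Weight-proportional merging.** The survivor of a merge is selected by
   weight, never by progress. The package ships a deliberately biased
   `violating_merge_resample()` — locked behind `allow_biased = TRUE` —
   that picks the higher-scoring candidate instead. On the three-state
   chain its occupancies drift many standard errors from the matrix-power
   oracle, and on the double well it reproduces the classic pathology in
   which a few heavy walkers make a "bee-line" to the product state and
   the expected decay of walker weight across the barrier collapses. The
   `weight_profile()` diagnostic makes that audit a one-liner.

## The progress score

The binless resampler ranks walkers by

$$S = \Big[\prod_{m=1}^{M} C_m\,\Big(1 - \frac{|q_m - q_{m,t}|}{|q_{m,i} - q_{m,t}|}\Big)\Big]\cdot \frac{1}{-\ln P}\cdot \prod_{\text{windows}} f$$

and each resampling step splits the top *N* and merges the bottom *N*,
keeping the walker count constant. Parameters, with units and defaults:

* **q_init, q_target** (coordinate units): endpoints of normalized
  progress per coordinate; progress is 1 at the target, 0 at the start,
  and direction-agnostic (an interaction energy relaxing from 350 to -200
  works unchanged). Raw progress is clamped into [0, 1] by default
  (`clamp_progress`), since overshoot past a target would otherwise let a
  single coordinate dominate the product with values above 1, and
  backtracking would flip the sign of the whole score.
* **C_m** (dimensionless, default 1): per-coordinate influence. A common
  rescaling of all C_m multiplies every score equally and cannot change
  the rank order — only *ratios* of scale factors matter.
* **Balance term** (dimensionless): `1/(-ln P)`, strictly increasing in
  the weight *P*, so low-weight walkers are softly disfavored for further
  splitting — a continuous replacement for hard min/max weight
  thresholds. It diverges at P = 1 (the very first iteration starts all
  walkers at equal, possibly large, weight), so it is capped at
  `balance_cap = 1e3`; the cap's exact value is immaterial because a
  capped score still outranks everything else. The literal variant
  `one_minus_log` (1 − ln P) is kept selectable for comparison, but note
  it *increases* as weight decreases and therefore rewards exactly the
  oversplitting the balance term is meant to prevent; `none` disables the
  term, which reorders ranks but can never affect conservation or count
  invariants.
* **Region scalings** (window in coordinate units, factor in (0, 1]):
  a walker whose coordinate lies inside a closed window has its *whole*
  score multiplied by the factor (applying it to the single coordinate
  term would have exactly the same effect on ranking only for M = 1; the
  whole-score convention keeps the meaning "de-prioritize this walker"
  independent of which coordinate triggered it). The shipped
  surrogate-unbinding configuration scales by 0.8 inside rmsd [10, 13],
  the window holding its kinetic trap.
* **N** (`n_split_merge`): walkers split and merged per step. N ≤ 50% of
  the count is a hard precondition — a walker cannot be selected for both
  operations in one step — and 10–20% is a practical sweet spot. N = 0 is
  the identity.

Scores only *rank* walkers; weights never depend on the score. That is
what makes the spec safely editable mid-run (`update_spec()`, logged in
the run record): changing endpoints or windows re-ranks future resampling
decisions but cannot bias any recorded weight.

### Merge pairing

"Split the top N, merge the bottom N" leaves open who the bottom walkers
merge *with*. The default (`absorb_up`) selects the bottom N on the
input ranking — provably disjoint from the split set whenever 2N ≤ count,
which is precisely the reason for the 50% rule — and then pairs each
selected walker, worst first, with the lowest-ranked walker above the
bottom block in the post-split pool. Pairing on the post-split pool is
what makes the scheme well-defined even in the minimal five-walker,
N = 2 configuration, where the only available partners are fresh split
children. The alternative `pairwise_bottom` merges the bottom 2N among
themselves and therefore additionally requires 3N ≤ count. Ranking ties
break by weight, then id, so reruns are bit-identical.

## Binned resamplers

For comparison and baseline use, three binned strategies share one
mechanical core (`binned_resample()`: in each occupied bin, split the
largest-weight walker until the target count is reached, or merge the two
smallest-weight walkers — survivor by weight — until it is):

* **Fixed bins**: a static grid, half-open cells `[lo, hi)`, `Inf`
  allowed as the last boundary, target 4 walkers per bin by default. Its
  known failure mode — cost exploding with the number of occupied bins —
  is visible in the shipped comparisons.
* **MAB**: per dimension, interior bins are spaced evenly between the
  lagging and leading edges of current progress and recomputed every τ;
  the edge walkers get dedicated bins, and one more bin isolates the
  *bottleneck* walker — the highest-weight walker in the occupied bin
  just before the largest increase of −ln(bin weight) along the progress
  direction, a free-energy-barrier signature. The criterion is a design
  choice here (the original bottleneck definition lives outside this
  package); it is toggleable, and with all walkers at one point the
  layout degenerates gracefully to a single bin.
* **Multi-MAB**: independent MAB schemes nested inside user-defined outer
  regions, each registered by a placement key that must land in a
  distinct outer cell; a walker entering a region with no registered
  scheme is a configuration error naming the cell, not a silent fallback.

## Toy systems and their oracles

* **Discrete Markov chain** (`markov_propagator`): payload is the state
  index, τ is a configurable number of jumps (default 1). Oracles:
  `exact_markov()` (matrix powers), `markov_mfpt()` (fundamental matrix),
  `markov_stationary()`. Everything statistical in the package is
  ultimately validated against these.
* **1-D double well** (`double_well_propagator`): overdamped Langevin on
  U(x) = h(x²−1)², Euler–Maruyama with defaults h = 5, kT = 1, dt = 1e-3,
  friction 1, 10 steps per τ. At h = 0 it must reproduce free diffusion
  (MSD = 2kTt/γ); at kT = 0.5 the 10 kT barrier shows no unassisted
  crossing on test timescales while the binless resampler crosses within
  a few hundred iterations.
* **2-D surrogate unbinding** (`unbind2d_propagator`): overdamped
  Langevin on a double well along a separation axis x (bound well at 0,
  unbound at 8, barrier 12 kT at x = 4), harmonic lateral confinement
  (k = 2), and an off-pathway Gaussian trap pocket (depth 10 kT, σ =
  0.55) at (3.2, 1.8) on the bound-side slope. Three derived coordinates
  mimic a real unbinding setup: `rmsd` = 2·sqrt(x² + 6y²) (the y-weight
  places the trap at rmsd ≈ 10.9, inside the [10, 13] scaling window,
  while the productive y ≈ 0 channel stays below 10 until past the
  barrier top), `eint` = 550e^(−x/2) − 200 plus a repulsive bump of 250
  near the exit at (7, 0) (so bound ≈ 350, unbound ≈ −200, and
  productive paths transiently move *backward* in eint — through positive
  values — while passing the bump: repulsive interactions near the exit
  help dissociation),
  and `dist` = x. States: bound (dist ≤ 1.5), unbound (dist ≥ 8.5),
  encounter (rmsd in the trap window at dist < 6); boundaries are closed
  on the state side.

  The landscape constants were fixed once, from the physics the fixture
  must embody: spontaneous unbinding must be absent on test timescales
  (0 of 200 brute-force walkers in 300 τ), climbing walkers that stray
  laterally must cascade into the trap and need backward rmsd motion to
  escape (the pocket's lowest rim points back toward the bound state),
  and the per-τ diffusion step (20 integrator steps of dt = 5e-3,
  σ ≈ 0.45) must be comparable to the steepest per-τ drift so that
  leading-edge children have a realistic chance to advance — the same
  consideration that governs the choice of τ in real WE simulations.

What the surrogate does *not* emulate: real molecular coordinates (its
"rmsd" and "interaction energy" are smooth functions of a 2-D position),
conformational gating, solvent memory, or any timescale separation beyond
one trap. Passing tests on it demonstrate the *statistical* machinery and
the *direction* of efficiency claims, not molecular realism or magnitudes.

## Rates, recycling, and the cost metric

With recycling on, walkers reaching the target state are reset to the
source configuration keeping their weight, and the recycled weight per
iteration is the flux series; at steady state mean flux equals 1/MFPT
(Hill relation). `flux_rate_estimate()` reports the post-burn-in mean
with a moving-block bootstrap standard error (block = 10 iterations,
1000 resamples — blocks long enough to span the flux autocorrelation on
the toy chains). On the three-state chain the estimate lands within 10%
of the fundamental-matrix oracle in an 800-iteration run.

The efficiency metric is **first-event aggregate time**: walkers × τ
summed over iterations until the first walker satisfies the target state.
All propagated walker-time counts, from iteration 1, whether or not it
belongs to the successful lineage — the metric is total sampling cost,
not path length. Runs used for first-event studies set `stop_state` so
the loop ends at the close of the event iteration.

## Numerical and design choices

* Splitting computes the child weight once (w/k) and assigns the
  last child the residual, so the sum is bit-exact; for the default
  k = 2 all children are identical.
* One seeded RNG stream per run (R's generator, `set.seed(cfg$seed)`),
  drawn in a fixed documented order — propagation noise, then merge
  survivors in rank order — so a (config, seed) pair reproduces an
  archive byte-for-byte.
* The run archive is a schema-versioned plain-text directory (JSON at 17
  significant digits, which round-trips doubles exactly); truncated
  archives recover every complete iteration and warn. The archive stores
  config, states, coordinates, weights, scores, and all resampling
  events, so every analysis is re-derivable without the original config
  file.
* Histogram and profile binning clamps out-of-range values into the end
  bins; log-probability output floors at 1e-300.
* Single-process execution: WE's parallelism is represented by vectorized
  propagation over walkers, and results are independent of batch
  partitioning by construction.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` use: 1e5 draws for
merge-survivor frequencies; 200 seeded replicates of a 10-iteration,
10-walker run on the three-state chain for the exactness/bias contrast;
an 800-iteration, 20-walker recycling run for rate recovery; 20 paired
seeds with a 600-iteration cap for the surrogate first-event comparisons
(binless with the 0.8 window vs without vs the fixed-bin baseline); and
20 seeds of 300-iteration double-well runs for the weight-profile audit.
These sizes give 3-standard-error resolution on every frequency check
while keeping a full run of everything within a coffee break on one CPU.

## Known limitations

* The balance term mitigates but does not eliminate probability
  accumulation in a few walkers on very long runs; hard thresholds are
  deliberately out of scope.
* Multi-MAB requires explicit coverage of every outer cell walkers can
  reach; there is no default scheme fallback.
* The fixed-count binless resampler assumes the configured
  `walker_count` matches the ensemble exactly; binned resamplers let the
  count float with bin occupancy.
* Rate estimation assumes recycling has reached a steady state;
  `burn_in` is the user's responsibility and the bootstrap SE does not
  correct for an unconverged mean.
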