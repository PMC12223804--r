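# binlesswe

Weighted-ensemble (WE) path sampling with a minimal adaptive **binless**
resampler, for studying rare events — barrier crossings, ligand unbinding —
whose unassisted simulation would spend virtually all of its time waiting.
The package is aimed at people developing or teaching WE resampling
strategies: every statistical rule of the method is exercised on built-in
toy stochastic systems with *exact* oracles, so correctness and efficiency
claims can be tested in seconds on one CPU, without molecular dynamics.

## The method

WE runs many weighted trajectory segments ("walkers") in parallel. After
every resampling interval τ, promising walkers are **split** (their
statistical weight divided among the children) and redundant ones
**merged** (the survivor drawn with probability proportional to weight,
which absorbs the group's weight). Two rules keep the ensemble
statistically exact:

1. trajectory weights always sum to a total probability of one;
2. a merge survivor is chosen by weight (or uniformly among equal
   weights), never by any measure of "progress".

The binless (MABL-style) resampler ranks walkers by a scalar progress
score instead of binning them. For coordinates *q₁…q_M* with user-chosen
initial and target values,

    S = [ ∏ₘ Cₘ · (1 − |qₘ − qₘ,t| / |qₘ,i − qₘ,t|) ] · 1/(−ln P) · ∏ f_regions

where *Cₘ* are per-coordinate scale factors, *P* is the walker's weight,
and each region factor *f* (e.g. 0.8 on an rmsd window [10, 13]) softly
de-prioritizes walkers lingering in a known kinetic trap. The balance term
1/(−ln P) is a *soft* weight threshold: low-weight walkers are less
favored for splitting, which curbs oversplitting without hard cutoffs.
Each resampling step splits the top-*N* scorers and merges the bottom *N*
(pairwise, each with the lowest-ranked walker above the bottom block), so
the walker count never changes; *N* may not exceed half the count.

Also included: adaptive binning (MAB) with leading-edge/lagging-edge and
bottleneck bins, nested multi-MAB schemes over user-defined outer regions,
a fixed-bin baseline, a deliberately rule-violating merge mode that
reproduces the classic "bee-line" weight pathology (for demonstrations
only, behind an explicit flag), recycling boundary conditions with
flux-based rate estimates, and archive/lineage/histogram analysis tools.

Built-in systems: a discrete Markov chain (matrix-power and
fundamental-matrix oracles), a 1-D double-well Langevin system, and a 2-D
surrogate-unbinding landscape with an off-pathway trap whose escape
requires backward motion along the rmsd-like coordinate.

## Worked example

```r
library(binlesswe)

cfg <- read_run_config(system.file("extdata", "unbind2d_production.yaml",
                                   package = "binlesswe"))
rec <- run_simulation(cfg)   # 40 walkers, N = 5, stops at first unbinding
unbound <- state_def("unbound", list(dist = c(8.5, Inf)))
first_event_aggregate_time(rec, unbound)
```

```
[1] 4960
```

4960 walker-τ of aggregate sampling bought the first unbinding event
(124 iterations × 40 walkers); a brute-force ensemble of the same size
shows no event within the configured budget. Weighted histograms
and the weight profile over any recorded coordinate come from
`weighted_histogram(rec, ...)` and `weight_profile(rec, ...)`; lineages
from `trace_lineage(rec, walker_id)`.

A command-line surface wraps the same functions:

```sh
Rscript inst/cli/we.R demo markov3           # oracle comparison, < 1 min
Rscript inst/cli/we.R run -c config.yaml -o run_archive --seed 7
Rscript inst/cli/we.R analyze first-event run_archive --state unbound
```

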