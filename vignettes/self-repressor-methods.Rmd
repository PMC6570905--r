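---
title: "Methods: stochastic self-repressor dynamics and trajectory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic self-repressor dynamics and trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autorep)
```

## The circuit and its model

`autorep` models a single-copy negative auto-regulation circuit: a TetR
repressor, fused to the Venus fluorophore so that every TetR pool is
observable, represses its own promoter through two tet operators. The
inducer anhydrotetracycline (aTc) enters the cell by passive diffusion
and sequesters free TetR into a complex (`Ta`) that cannot bind DNA.
Because the inducer removes the repressor from the free pool, it slows
both operator binding and operator unbinding: it is a knob on the *speed*
of the regulatory switching, not only on its balance.

The reaction network, over the state (gene state, free TetR `n`, complex
`Ta`, internal aTc `I`):

* **Operator binding.** A dimer assembled from two free monomers occupies
  one operator with propensity `h n (n-1) / 2`. The gene state records
  which operators are free: `A11` (both free, synthesis rate `g11`),
  `A10`/`A01` (one occupied), `A00` (both occupied, rate `g00`). Binding
  is quadratic in `n`.
* **Operator unbinding.** A free monomer acts as the competitor that
  displaces a bound dimer, giving propensity `f n` — linear in `n`. The
  displaced dimer returns two monomers to the free pool (net +2). A
  variant with *constant* unbinding propensity `f * n_ref` removes the
  concentration dependence; contrasting the two mechanisms is one of the
  package's main uses.
* **Synthesis and loss.** `0 -> TetR` at `g_ij` for gene state `A^ij`;
  `TetR -> 0` at `k1` (degradation plus dilution; cell division is not an
  explicit event — `k1` absorbs it, since the model only states
  first-order protein loss). Transcription and translation are collapsed
  into one step.
* **Inducer.** `TetR + I <-> Ta` at rates `b` (association) and `a`
  (dissociation); `Ta -> 0` at `k2`; `E <-> I` across the membrane with a
  single diffusion coefficient `c` in both directions, with the external
  abundance `E_aTc` held constant (infinite bath).

Two derived ratios summarise the regime: the adiabaticity parameter
`omega = f / k1` and the operator equilibrium constant `Xeq = f / h`.
When effective operator switching is much faster than protein turnover,
the protein distribution is unimodal; when it is comparable or slower
(the non-adiabatic regime), the gene leaves separate marks for its bound
and unbound episodes, and the population splits into a low- and a
high-expression fate that interconvert stochastically.

Intermediate synthesis rates default to `g10 = g01 = g00`: one bound
dimer is taken to block RNA polymerase completely. The two operators are
symmetric, and the two binding channels out of `A11` each carry the full
`h n (n-1) / 2` rate, as independent equal-rate channels. Whether aTc
binds monomers or dimers is modelled as a single 1:1 complexation step.

## Simulation and exact solution

`ssa_simulate()` is an exact Gillespie direct-method sampler (compiled
core, R's RNG stream, so a seed fixes the trajectory bit-for-bit).
`ssa_stationary()` accumulates a time-weighted histogram of a chosen
coordinate — free TetR `n`, or total fluorescent TetR-Venus
`n + Ta + bound monomers` — after a burn-in. `cme_stationary()` builds
the full truncated generator over (gene state × `n` × `Ta` × `I`) as a
sparse matrix and solves for the null left eigenvector — by a direct
sparse solve of the reduced balance system up to 5000 states, and by
uniformized power iteration (compiled, L1 stopping rule `1e-12`,
validated against the direct solve to total variation below `1e-9`)
beyond that; reactions leaving the truncation box are dropped, and the
stationary mass on any box face must stay below `1e-6` or the call
fails with the measured boundary mass. The master equation is the exact
reference: the test-suite checks the SSA against it in total variation
on a small inducer-coupled system, and checks both against the closed
form in the uncoupled limit (`h = b = c = 0` gives Poisson(`g/k1`)).

## Calibration of the default parameters

The kinetic constants of the real circuit are not part of this package's
inputs, so the defaults (`default_rate_params()`) are *calibration
values*, chosen once by simulation study (and documented here rather
than revisited): protein turnover `k1 = 0.02/min` (≈50 min, a dilution
time), active synthesis `g11 = 10/min` so the fully active state holds
`g11/k1 = 500` molecules, repressed synthesis `g00 = 0.2/min`, operator
rates `h = 4e-7`, `f = 4e-4`, inducer rates `b = 6.15e-5`, `a = 0.01`,
`k2 = 0.01`, `c = 0.02`, with aTc converted from ng/mL to molecules via
molar mass 462.9 g/mol in a configurable reaction volume (default 1 fL,
an *E. coli* scale; ~1.3 molecules per ng/mL).

Two calibration points deserve comment:

* **Adiabaticity bookkeeping.** With concentration-dependent unbinding
  the relevant switching speed is `f*n/k1`, not the bare ratio
  `f/k1 = 0.02`: at zero inducer the free pool is large and effective
  unbinding is several times faster than degradation, while under strong
  induction the free pool collapses and switching becomes far slower
  than turnover. The circuit therefore *crosses* from effectively
  adiabatic to deeply non-adiabatic along the inducer axis, which is
  exactly what produces the unimodal-to-bimodal sequence. A calibration
  with the bare ratio `f/k1` near one at zero inducer is not compatible
  with this crossing: multiplying `f` and `h` together by a large factor
  at fixed `Xeq` is precisely the adiabatic limit, and the test-suite
  confirms it erases the bimodality.
* **What the sweep reproduces.** Across 300-1500 ng/mL the default sweep
  moves from an (almost entirely) unimodal population through rising
  expression into a clearly bimodal regime whose low-expression mode
  gains weight monotonically with inducer. With the constant-unbinding
  variant, the weight trend reverses: the high-expression mode grows
  with inducer — the qualitative signature separating the two unbinding
  mechanisms. At the full calibration scale the constant-variant bimodal
  window falls above the inducer range a cell tolerates, so the
  simulation studies of that contrast use `scaled_rate_params()`, a
  count-scaled system (on-state ≈50 molecules, `k1 = 0.1/min`) with the
  same phenomenology at a fraction of the cost. The validation suite
  runs the trend checks at inducer counts {15, 22, 30} (concentration-
  dependent) and {65, 75, 85} (constant) with three averaged replicates
  of `1e5` simulated minutes each.

## Mode detection

`detect_modes()` smooths the probability mass function with a centred
moving average and counts strict local maxima whose prominence (height
drop to the deepest separating valley toward a taller peak) exceeds a
fraction (default 5%) of the tallest smoothed bin. The threshold is
relative to the peak height rather than to total mass because a broad
mode of a wide count distribution spreads its mass over hundreds of
bins; an absolute per-bin mass criterion would never register it. Mass
is split between modes at the minimum-density valley; on a plateau the
leftmost bin is the mode location.

## Expression-noise statistics

The Fano factor is the population variance over the mean (`1/n`
variance, matching the distribution-level definition). It is 1 for
Poisson counts, far larger for a mixture of two expression states —
the package's property tests include the mixture inequality (a mixture's
Fano factor exceeds the weighted component Fano factors whenever the
component means differ). Fano is *not* scale-invariant
(`fano(a*x) = a*fano(x)`), so fluorescence-unit Fano factors are
trend-level quantities, not absolute Poisson tests; the CV is the
scale-free companion. Fano factors are computed on linear fluorescence
by default. The inhibition probability at a threshold is the fraction of
cells strictly below it; on a threshold grid it is the empirical CDF.
The default threshold is placed at the minimum-density valley between
the two modes of the log10 histogram at the *highest* inducer level of a
run (falling back to the median when unimodal), and the value used is
always reported alongside the statistics.

## The two-state HMM

Single-cell trajectories (log10 mean fluorescence, one frame per 5 min)
are modelled by a two-state hidden Markov chain with Gaussian emissions:
state 1 low, state 2 high (`mu_low < mu_high` is enforced after every
fit, which removes label switching). `fit_hmm()` runs Baum-Welch EM
jointly over all trajectories (shared parameters), initialised from a
2-means split of the pooled emissions plus a sticky transition matrix
`[[0.9, 0.1], [0.1, 0.9]]`, with 10 jittered restarts by default,
stopping at a relative log-likelihood change below `1e-8` or 500
iterations. The log-likelihood is asserted non-decreasing at every
step; a state whose expected occupancy falls below two frames marks the
restart degenerate. Divisions are carried as flags but are not
breakpoints — lineages are tracked across divisions.

The reference model (`default_trajectory_hmm()`) has emission peaks at
2.690 and 2.933 log10 units with variances 0.085 and 0.080, high-state
self-transition 0.963 per frame, high-to-low switching 0.037 and
low-to-high 0.023; its stationary occupancy is 0.617/0.383. On the
log10-of-intensity reading of the emission scale, `10^2.690 ≈ 490` and
`10^2.933 ≈ 857` bracket realistic mean intensities; the scale (log
base) is configurable throughout.

`decode()` is Viterbi; the first and last dwell segments of each
trajectory are flagged censored. At the reference parameters the two
emission components overlap substantially (peak separation 0.243 vs
component standard deviations ≈0.29), so frame-wise decoding accuracy
plateaus near 0.89 — a property of the model at this overlap, computed
before implementation with an independent posterior oracle, not an
implementation ceiling. The emission *parameters* remain precisely
recoverable because temporal persistence accumulates evidence across
frames: over 20 generate-and-refit replicates at the study scale (163
trajectories of 40-60 frames) the median absolute recovery error is
below 0.01 on every transition probability and below 0.02 on every
emission mean and variance.

## Residence times

The mean residence time of a state is the total time spent in it
divided by the number of exits from it. Finite trajectories censor the
first and last dwell of every cell, which biases any single convention;
the estimator therefore reports a bracket: the exclude-censored
convention (only complete dwells, each ending in an exit) and the
include-censored convention (all observed time, exits only where
observed) bound the estimate from below and above. This bracketing is
this package's own substitute for an exact finite-length correction and
is labelled as such in the output. On long chains, where censoring is
negligible, the estimate converges to the geometric dwell expectation
`dt / (1 - p_self)` — the property suite requires agreement within 5%.

## Mixture weights and their identifiability

State occupancies are reported two ways: the stationary distribution of
the fitted transition matrix and the empirical frame occupancy of the
decoded paths; the two differ in finite samples (for the reference
transition matrix they are 0.617/0.383, while decoded-path occupancies
on 8200-frame data sets sit nearer 0.60/0.40). For *static* snapshot
data the two-component Gaussian mixture is the natural model, with one
caveat the package documents loudly: at the reference overlap, the
weight of a mixture whose means, variances *and* weights are all free
is practically unidentified — EM crawls along a likelihood ridge on
which the weight can drift from 0.5 to 0.8 while the log-likelihood
changes by less than 0.1, and independent samples give fitted weights
anywhere in (0, 1). `fit_gaussian_mixture()` therefore accepts fixed
component parameters (in the pipeline they come from the HMM fit, where
temporal information identifies the components); the weight-only EM is
then well-conditioned, converges in ~150 iterations, and recovers
generating weights of 0.599/0.401 to ±0.03 at n = 8200. The free fit
remains available, with its limitation stated in the documentation.

## Synthetic data

`gen_trajectories()` draws hidden state paths from the reference chain
(initial state from its stationary distribution), Gaussian emissions on
log10 scale, and division flags at uniform 40-60 min intervals —
defaults: 163 cells, 40-60 frames each at 5 min, ≈8200 pooled points.
Ground-truth paths are retained so every estimator can be scored.
`gen_snapshots()` draws per-cell intensities from a two-component
log-normal mixture whose schedule of weights and component positions
across 300-1500 ng/mL (seven levels, 3000 cells each) reproduces the
qualitative microscopy sequence: effectively unimodal at the bottom of
the grid, rising expression, bimodality at the two highest levels with
the low-state weight growing across the top; the generated Fano factor
rises steeply into the bimodal region. The schedule is an explicit
config table, not a hidden constant. `ssa_to_fluorescence()` connects
the mechanistic model to the observable: total TetR-Venus sampled at
frame boundaries, scaled, and blurred with multiplicative log-normal
noise (default CV 0.05 — a placeholder for an unspecified microscope
noise level, and swept in the tests).

What the generator does *not* emulate: lineage structure (daughters are
independent trajectories, no partitioning noise at division), cell-size
and focal artefacts, photobleaching, or any dependence of growth rate on
expression state. Passing recovery tests on these synthetics therefore
demonstrates estimator correctness at the stated noise model, not
robustness to every artefact of real microscopy data.

## Numerical choices

* SSA uses R's RNG (one stream per run; replicate seeds derived by
  counter from the root seed, recorded in output metadata).
* Forward-backward is scaled (not log-space) per trajectory; Viterbi is
  log-space. Both are compiled.
* EM variance updates are floored at `1e-8` (HMM) / `1e-10` (GMM) to
  avoid zero-variance collapse; reaching the floor marks a degenerate
  restart.
* The master-equation solve replaces one balance row with the
  normalisation constraint; tiny negative entries from round-off (below
  `1e-12` in magnitude) are clipped to zero before renormalising.
* `detect_modes` ties on plateaus break leftmost; weights renormalise
  over the kept modes.
* The inducer axis is configured in ng/mL and converted once to
  molecule counts; the conversion never enters a rate law.

## Problem sizes used by the validation suite

Parameter-recovery runs use 20 replicates of the full study scale (163
trajectories × 40-60 frames). Master-equation cross-checks use a small
coupled system (free TetR ≤ 40, complex ≤ 8, internal aTc ≤ 10) against
≥5×10^5 SSA events. The bimodality and trend studies run the
count-scaled system for 10^5 simulated minutes per replicate, 2-3
replicates per condition. These sizes were chosen so the entire suite
exercises every claim at meaningful statistical resolution.

## Known limitations

* mRNA is not modelled (transcription and translation are one step), so
  transcriptional bursting enters only through the gene-state dynamics.
* The deterministic bifurcation structure of the model is out of scope;
  all statements are about stationary distributions of the stochastic
  system.
* Rate defaults are calibration values, not measurements; conclusions
  drawn from them are qualitative (mode counts, weight trends,
  dichotomies), and every constant is overridable through the config
  interface.
* The residence-time bracket can be wide when most dwells are censored
  (trajectories much shorter than the dwell time), which is the honest
  statement of what such data support.
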