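# autorep

Stochastic modelling and single-cell trajectory analysis of a
self-repressing (negative auto-regulation) gene circuit whose operator
binding/unbinding speed is tuned by an inducer.

## The problem

A gene that represses its own promoter is usually the textbook example
of noise suppression: one steady state, a narrow unimodal expression
distribution. That picture assumes the repressor binds and unbinds its
operator much faster than the protein is made and degraded (the
*adiabatic* regime). When an inducer — here anhydrotetracycline (aTc)
acting on a TetR-Venus fusion — sequesters the free repressor, both the
operator binding propensity (`h·n(n−1)/2`, quadratic in the free monomer
count `n`) and the unbinding propensity (`f·n`, linear: a free monomer
is the competitor that displaces the bound dimer) slow down. Operator
switching then becomes comparable to or slower than protein turnover
(`ω = f/k₁` and, effectively, `f·n/k₁`), and a single genotype splits
into two interconverting phenotypes: a low- and a high-expression cell
fate, visible as a bimodal fluorescence distribution and as switching
events along single-cell time-lapse trajectories.

`autorep` provides, for users studying this class of circuits:

* an exact Gillespie simulator and a truncated chemical-master-equation
  solver for the full reaction network (gene state × free TetR ×
  TetR·aTc complex × internal aTc), including the constant-unbinding
  variant used to test whether the concentration dependence of
  unbinding matters (it sets the direction of the mode-weight trend);
* inducer sweeps with mode detection (count, location, weight by
  minimum-valley split) and expression-noise statistics: Fano factor
  `F = σ²/μ`, CV, inhibition curves (empirical CDFs);
* a two-state Gaussian-emission hidden Markov model for log10
  fluorescence trajectories: Baum-Welch fitting with restarts, Viterbi
  segmentation, residence-time estimation with censoring brackets,
  occupancy/mixture weights, and fit-quality scoring;
* a synthetic-data generator (trajectories with ground-truth state
  paths; steady-state snapshot populations across an inducer gradient)
  that powers the package's own validation suite;
* a config-driven pipeline (`run_generate()`, `run_simulate()`,
  `run_analyze()`, `run_all()`) plus a thin CLI at
  `inst/cli/autorep.R`.

## Worked example

Fit the two-state HMM to synthetic single-cell trajectories generated
from the package's reference model (peaks at 2.690/2.933 log10 units,
high-state self-transition 0.963), then decode and estimate residence
times:

```r
library(autorep)

g   <- gen_trajectories(trajectory_gen_config(seed = 11))
fit <- fit_hmm(g$trajectories, restarts = 10, seed = 2)
fit$model
#> two_state_hmm (state 1 = low, state 2 = high)
#>   means: 2.696 / 2.936   variances: 0.085 / 0.080
#>   self-transitions: 0.974 / 0.957

segs <- lapply(g$trajectories, decode, model = fit$model)
mixture_weights(fit$model, segs)$stationary
#>       low      high
#> 0.6202753 0.3797247

residence_times(segs)[, c("state", "mean_minutes", "lower", "upper")]
#>   state mean_minutes lower    upper
#> 1   low        91.25 91.25 511.0000
#> 2  high       100.00 100.00 357.8571
```

The fitted emission peaks land on the generating values to two decimal
places; the stationary occupancy of the fitted chain is ≈0.62/0.38. The
residence-time brackets are wide because at these parameters a dwell
(≈100-200 min) often exceeds a trajectory (≈250 min), so most dwells
are censored — the bracket is the honest range the data support.

Sweep the mechanistic model across an inducer gradient (this runs the
SSA for 5×10⁵ simulated minutes per level; a few minutes of wall time):

```r
p  <- default_rate_params()
sw <- sweep_inducer(p, c(300, 700, 1100, 1500), seed = 1)
sw$summary[, c("aTc_ng_per_ml", "mean", "fano", "n_modes", "w_low")]
```

At the calibrated defaults the population is essentially unimodal at
300 ng/mL and clearly bimodal at the top of the gradient, with the
low-expression weight rising monotonically in aTc; rerunning with
`default_rate_params(unbinding_mode = "constant")` reverses the trend
(the high mode grows instead), which is the diagnostic separating
concentration-dependent from constant unbinding.

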