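---
title: "Models and methods: quantifying Lgr5+ stem-cell dynamics in pyloric glands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying Lgr5+ stem-cell dynamics in pyloric glands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyloclone)
```

# The biological setting

Pyloric glands of the mouse stomach are renewed by a small pool of
actively cycling Lgr5+ stem cells at the gland base. In lineage-tracing
experiments, tamoxifen-induced Cre recombination permanently labels a
random subset of Lgr5+ cells (and all their descendants) with a heritable
fluorescent reporter. Following the labelled clones over weeks reveals two
distinct dynamical processes:

* **clonal expansion/contraction at the base** — labelled clones drift by
  neutral competition until one lineage occupies the whole base
  (monoclonal fixation) or the label is displaced (extinction);
* **proliferation and differentiation** — labelled Lgr5+ cells divide
  symmetrically and lose Lgr5 as they differentiate, feeding a growing
  population of labelled Lgr5− progeny.

`pyloclone` implements the models for both processes, an individual-based
simulator of the gland base, Metropolis MCMC fitting of all of them to
longitudinal count tables, and a synthetic-data generator that emulates the
statistical structure of the in-vivo cohorts.

# Neutral-drift clone expansion

The base holds `N` *effective* clone-producing positions (fewer than the
total number of Lgr5+ cells). The labelled clone size `S(t)` is a
continuous-time random walk on `0..N`: it gains one cell at rate `lambda`
(cells/day) and loses one cell at the same rate, with absorbing boundaries
at `0` and `N`. The state-independent rate encodes the field's standard
view that a clone's boundary, not its bulk, exchanges cells.

The transient law `P_ij(t)` is computed from the spectral decomposition of
the tridiagonal interior block of the generator, whose eigensystem is known
in closed form (`sin(k*pi*s/N)` modes with eigenvalues
`-2*lambda*(1 - cos(k*pi/N))`); absorption probabilities follow by
integrating the boundary flux. This is exact to machine precision for any
practical `N` and is cross-checked in the tests against a matrix
exponential of the generator and against Monte-Carlo simulation of the
jump chain.

Because higher tamoxifen doses label several cells per gland, the initial
clone size `i` is itself random. The package supports degenerate, binomial,
empirical, and truncated-Poisson initial laws; the clone-size distribution
is then the mixture `sum_i F(i) P_ij(t)`. Poisson mass above `N` is
reassigned to `N` rather than renormalized: a gland whose labelled count
reaches the number of effective positions is operationally "fully
labelled". Observed counts above `N` are likewise binned into `N` when
histograms are built for fitting with the state space fixed.

Two useful identities follow from the martingale property of neutral
drift: the mean of `S(t)` is conserved, and the fixation probability from
`i` cells is `i/N`. Hence the limiting extinction probability under an
initial law `F` is `sum_i F(i) (1 - i/N)` — independent of `lambda`, which
is what lets `N` be estimated on its own from long-term data
(`fit_extinction_N()`), with `alpha` for the truncated-Poisson initial law
estimated from the zero class, `alpha = -log(p_zero)`
(`estimate_alpha()`; the mean-count estimator `estimate_alpha_mean()` is
provided as the alternative, and the two agree under Poisson labelling).

# Birth–death proliferation and differentiation

The labelled Lgr5+ count per gland, starting from a single labelled cell,
follows a linear birth-death process with symmetric-division rate `mu` and
differentiation rate `delta` (both per cell per day). The classical
solutions are used: for `mu != delta`,

$$P_0(t) = \frac{\delta(w-1)}{\mu w - \delta},\qquad
P_k(t) = (1-P_0)(1-\beta)\beta^{k-1},\qquad
w = e^{(\mu-\delta)t},\ \beta = \frac{\mu(w-1)}{\mu w - \delta},$$

with mean `exp((mu-delta)t)`; for the critical case `mu == delta`,
`P_0 = mu*t/(1+mu*t)` and `P_k = (mu*t)^(k-1)/(1+mu*t)^(k+1)`, with mean
one. The pmf truncation cap grows automatically until the tail mass is
below `1e-8`. Continuity of the two branches as `delta -> mu` is covered
by tests.

The labelled Lgr5− progeny are modelled as mean dynamics,
`dL+/dt = (mu-delta) L+` and `dL-/dt = delta L+ + eta L-`, where `eta` is
the specific growth rate of the differentiated population. The explicit
solution is used, with the resonant case `eta == mu - delta` evaluated by
its `t*exp(eta*t)` limit instead of a numerically cancelling difference
quotient. A stochastic progeny model is deliberately out of scope: the
data fitted here are mean counts per gland.

# The individual-based model

`ibm_config()` describes the simulator: 7 Lgr5+ cells in a single upward
stack of positions, the bottom 5 forming the effective ring; cells divide
with gamma-distributed cycles (mean 11 days); on division of an effective
cell, with probability `P` the new cell displaces another effective cell —
a ring neighbour in scenario 1D, any other effective cell in 2D — and the
displaced cell recursively faces the same choice, so exactly one cell is
exported upward per division; cells pushed at or above the differentiation
boundary lose Lgr5 permanently. Labels are heritable and conserved.

Choices the architecture leaves open, fixed here as package defaults:

* **Gamma shape = 8** (cycle CV about 0.35, a typical cell-cycle
  dispersion); only the 11-day mean is prescribed by the gland biology.
* **Growth rate = ln 2 / cycle mean** (0.063/day at 11 days): binary
  fission doubles the population once per mean cycle.
* **Initial cycle phases** are drawn from the stationary renewal residual
  (length-biased gamma times a uniform fraction), so the cohort is not
  artificially synchronized at induction.
* **Cascade termination**: each displacement draws a fresh Bernoulli(`P`);
  at `P = 1` the cascade ends once every effective position has been
  relocated, guaranteeing one upward export per division.
* **Geometry above the base** is a single stack of positions; "the first
  14 positions" in the uncoupled-differentiation experiment is position
  index below 14 in this stack.
* **Labelled Lgr5− cells** are counted as exported cells; their own
  proliferation is not tracked by the simulator (the compartment model
  handles progeny growth).
* **`p_replace = 0.25` by default.** The replacement probability is the
  IBM's free knob; the package calibrated it once against the
  clone-expansion model by profile likelihood on simulated cohorts
  (1000 glands, 300 days), obtaining a lambda of about 0.014, 0.017,
  0.020, 0.025, 0.034 and 0.044 cells/day at `P` = 0.15, 0.20, 0.25,
  0.30, 0.50 and 1. The default `P = 0.25` therefore reproduces the
  homeostatic replacement rate of about 0.02 cells/day; lambda is
  monotone in `P`, and the 1D/2D scenarios are indistinguishable at this
  resolution.

# Inference

All models are fitted by a hand-rolled symmetric random-walk Metropolis
sampler (`metropolis()`): Gaussian proposals, box support, scale
adaptation toward a 30% acceptance rate during burn-in only, two chains
from jittered starts, split-chain R-hat and an autocorrelation-based
effective sample size. The sampler is validated against closed-form
posteriors in the tests. Defaults are 50,000 iterations with 20% burn-in;
the fits in the examples, tests and acceptance script use 6,000-15,000
iterations, which these low-dimensional, well-conditioned posteriors do
not distinguish from the defaults.

Priors are deliberately weak and documented rather than tuned: flat on
`[0, upper]` with `upper` set to 10 times a coarse pilot estimate (grid
profile mode for `lambda`, moment estimates for `mu`, `delta`, `eta`).
`N` is a count and is enumerated over `{2..12}` instead of being relaxed
to a continuum, either against the limiting extinction probability
(binomial likelihood per sampling time) or jointly with `lambda`
(evidence by trapezoidal integration of the profile over `lambda`).

Observation models, which the original analyses leave unstated, are:

* **multinomial per sampling time** over clone sizes `0..N` (all glands,
  including zero-label glands, which carry the extinction signal) for
  clone-expansion fits;
* **multinomial over `k >= 1` conditioned on observability** for
  birth-death fits to cross-sectional samples, where an extinct clone
  cannot be told apart from a never-labelled gland. For simulated cohorts
  followed from induction, `condition_on_labelled = FALSE` uses the
  genuine zero counts. Near the critical point the conditional
  frequencies identify `(mu, delta)` only weakly (they pin essentially
  one function of the rates per time); `extinction_from_counts = TRUE`
  adds the decline of the absolute number of observed clones relative to
  the day-0 batch as a binomial term, under the assumption that each
  sampling batch initiated the same number of clones. This restores
  identification using numbers already present in the clone matrix;
* **Gaussian on mean counts** with jointly estimated noise scale for the
  compartment fit of `eta`.

When enumerating `N` jointly with `lambda`, candidate models must compete
on a *common* outcome space: the data are never re-binned to each
candidate's state space (which would mechanically favour coarser models),
and a candidate `N` below the largest observed clone size is impossible.
This is why `fit_clonal_N()` requires clone sizes on the effective-position
scale.

# The synthetic-data generator

`generate_experiment()` emulates the cohort designs of the lineage-tracing
experiments: Poisson(`alpha`) labelling per gland (single colour, or four
independent colours whose total is Poisson with the summed intensity),
dynamics by the clone-size chain, the birth-death process, or the IBM, and
**cross-sectional sampling by default** — each sampling time is an
independent set of glands, as in destructive tissue collection. This
matters for inference: with longitudinal records the per-time multinomial
likelihood ignores the within-gland correlation across times and produces
overconfident intervals; under the cross-sectional design the likelihood
is correctly specified, and the seeded replication study in the test suite
recovers 18-20/20 coverage of 95% credible intervals for `lambda`, the
common rate, `mu`, `delta` and `eta`.

Gland-to-gland variation in total Lgr5+ count is drawn from a discretized
normal (mean 6.9, sd 2.2, truncated at 1) purely for realism of the totals
column; no model consumes it. Every dataset carries a `ground_truth`
attribute so that refits are always judged against the recorded generating
parameters, never against values re-derived from the data.

`lineage_fixture()` provides deterministic desk-scale stand-ins shaped
like the published data tables (all of them synthetic, generated at the
published parameter values `N = 5`, `lambda = 0.02`, `mu = delta = 0.064`,
`eta = 0.39`, `alpha = 2.3`): a late-time extinction-percentage table
(3 times, about 500 glands each), a four-colour clone-size matrix
(5 times, 800 initiated clones per batch over days 0-30), a mean-count
matrix over days 0-8 with observation noise (sd 0.05-0.08 cells, chosen
once as the scale of a several-hundred-gland average), and a two-site
tdTomato-style longitudinal cohort (about 150 and 95 glands per time at
days 0, 5, 12, 42, 59).

What the generator does *not* emulate: imaging and segmentation error,
gland fission and lateral clone spread, mouse-to-mouse random effects, and
Lgr5 re-acquisition by differentiated cells. Passing the recovery suite
therefore shows the estimators are correct under the models' own
assumptions plus realistic sampling designs — not that those assumptions
hold in any particular tissue.

# Numerical choices and degenerate inputs

* Clone pmfs: spectral solution, exact for `N` up to at least 50; tiny
  negative round-off (below `1e-12`) is clamped to zero.
* Birth-death pmfs: truncation cap doubles until tail mass < `1e-8`;
  `t = 0`, pure-birth (`delta = 0`), pure-death (`mu = 0`) and critical
  branches are handled explicitly; `bd_pmf()` refuses `mu == delta` and
  points to `bd_pmf_equal()` rather than silently dividing by zero.
* Compartment solution: the resonant case is detected by a relative
  threshold (`|mu - delta - eta| < 1e-10 * scale`).
* `t_limit = 20 N^2 / lambda` serves as the finite-time surrogate wherever
  a limit is needed numerically; at that horizon interior mass is below
  `1e-6` for the tested parameter ranges.
* Zero-probability bins with observed counts yield `-Inf` log-likelihood
  (with the offending bins attached as an attribute), so samplers reject
  such parameters instead of erroring.

# Problem sizes

The simulation studies in the tests and the acceptance script use the
cohort sizes of the original study where those are part of the design
(1000 glands for IBM cohorts, about 500 glands per time for extinction
tables, 800 clones per batch for the clone matrix) and 6,000-15,000
Metropolis iterations per chain; the replication study uses 20 seeded
replicates. These sizes put Monte-Carlo error well inside the tolerances
asserted.

# Known limitations

* The clone-expansion model is an approximation to the IBM's basal
  dynamics; its transition rate is state-independent while the IBM's
  replacement intensity is not, so cohorts started from mid-range clone
  sizes refit with a slightly higher `lambda` (about 0.023 vs 0.021 from
  one initial cell at the default calibration).
* Credible intervals from the per-time multinomial likelihood assume
  cross-sectional sampling; applied to longitudinal data they are
  anticonservative.
* The equal-initiation assumption behind `extinction_from_counts` is an
  experimental-design idealization; batches with very different tissue
  areas would violate it, which is why the term is opt-in.
* The IBM does not model progeny proliferation, gland fission, or
  spatially resolved clone geometry (the equipotency hypothesis makes
  contiguous and mosaic clones dynamically equivalent at the base).
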