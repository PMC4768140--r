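# pyloclone

Quantitative analysis of Lgr5+ stem-cell behaviour in pyloric gastric
glands from lineage-tracing data. The package is for researchers who count
Cre-labelled cells in gland bases over time and want rates out: how fast
equipotent stem-cell clones replace each other, how many cells can found a
monoclonal gland, and how fast the population proliferates and
differentiates.

## The models

**Clonal expansion (neutral drift).** The labelled clone size *S(t)* at
the gland base is a continuous-time random walk on states 0..*N* with
absorbing boundaries: the clone gains one cell at rate *λ* (cells/day) and
loses one at the same rate, until extinction (*S* = 0) or monoclonal
fixation (*S* = *N*). The transient law is computed exactly from the
spectral decomposition of the tridiagonal generator, for any initial
clone-size distribution *F(i)* (degenerate, binomial, truncated Poisson,
or empirical). Neutral drift makes *S(t)* a martingale, so the limiting
extinction probability is

Π₀ = Σᵢ F(i) (1 − i/N),

independent of *λ* — which is what lets *N* be estimated on its own from
long-term data, and *λ* from the transient period with *N* fixed.

**Proliferation and differentiation.** The labelled Lgr5+ count per gland
(one labelled cell at induction) follows a linear birth-death process with
division rate *μ* and differentiation rate *δ* per cell per day (classical
Kendall solutions, including the critical case *μ = δ*); the labelled
Lgr5− progeny follow the compartment model d*L⁻*/dt = *δL⁺* + *ηL⁻*, with
*η* the progeny's specific growth rate.

**Individual-based model.** An event-driven simulator of the gland base
(7 Lgr5+ cells, 5 effective positions, gamma-distributed 11-day cycles,
positional replacement with probability *P* in 1D or 2D, position-triggered
Lgr5 loss) generates cohorts against which all estimators are validated.

All fitting is Bayesian via a built-in random-walk Metropolis sampler,
with broom-style `tidy()`/`glance()` summaries and `autoplot()` methods.

## Worked example

Fit the clone replacement rate on a synthetic two-site cohort generated at
published parameter values, then estimate the effective cell number from a
late-time extinction table:

```r
library(pyloclone)

td  <- lineage_fixture("tdtomato")             # synthetic, lambda = 0.017 / 0.020
sub <- td[td$site == "greater", ]
fit <- fit_clonal_lambda(sub, N = 5, n_iter = 10000, seed = 42)
tidy(fit)
#> # A tibble: 1 × 8
#>   term   estimate std.error conf.low median conf.high  rhat   ess
#>   <chr>     <dbl>     <dbl>    <dbl>  <dbl>     <dbl> <dbl> <dbl>
#> 1 lambda   0.0207   0.00329   0.0147 0.0206    0.0276  1.00 3298.
```

The posterior mean replacement rate is 0.021 cells/day with 95% credible
interval (0.015, 0.028): clones at this site gain or lose a cell roughly
every 50 days, and the interval covers the generating value 0.017.

```r
et <- lineage_fixture("extinction-table")
glance(fit_extinction_N(et, alpha = 2.3))
#> # A tibble: 1 × 5
#>   N_mode N_mean    N_sd alpha n_times
#>    <int>  <dbl>   <dbl> <dbl>   <int>
#> 1      5   5.00 0.00100   2.3       3
```

Five effective cells — the number whose clones can take over the gland —
are recovered from the fraction of glands still carrying unlabelled Lgr5+
cells once the drift process has reached its limit. Finally, time scales
from rates:

```r
bd_time_scales(0.39, 0)   # Lgr5- progeny growing at 0.39/day
#>      mu delta net_rate doubling_time grows extinction_prob
#>    0.39     0     0.39          1.78 TRUE                0
```

a 1.8-day doubling time for the differentiated progeny, against roughly
11 days (ln 2 / 0.064) for the stem-cell pool itself.

See `vignette("pyloclone-methods")` for the models, priors, observation
models, and the IBM calibration.

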