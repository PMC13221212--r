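# sglv: resilience analysis for stochastic Lotka-Volterra communities

How quickly does a microbial community recover after a disturbance — an
antibiotic pulse, a dietary shock — and how does environmental noise change
that answer? `sglv` implements a complete workflow for this question on the
stochastic generalized Lotka-Volterra (SgLV) model

$$dX_i = X_i\Big(\alpha_i + \sum_j B_{ij} X_j\Big)dt
       + X_i \sum_j \tau_{ij}\, dW_j,$$

where $X_i$ is the abundance of taxon $i$, $\alpha$ the intrinsic growth
rates, $B$ the signed interaction matrix (negative diagonal =
self-limitation), and $\Gamma = (\tau_{ij})$ loads a shared $N$-dimensional
white noise onto the per-capita growth rates.

The package provides:

* **Simulation** — positivity-preserving Euler-Maruyama on the log scale,
  with deterministic gLV integration and pulse perturbations
  (`simulate_sglv()`, `simulate_glv()`, `apply_pulse()`).
* **Persistence/extinction classification** — boundary equilibria and their
  spectra for the deterministic system; boundary Gamma laws, analytic
  two-species invasion rates $\lambda_i(\mu)$, Monte-Carlo invasion rates
  for general $N$, and the complete two-species stochastic case analysis
  (`classify_deterministic()`, `boundary_gamma()`, `lyapunov_2sp()`,
  `estimate_invasion_rate()`, `classify_stochastic_2sp()`).
* **Statistical linearization** at the stationary distribution
  (`linearize()`): offset $\Theta = h(m)$, community matrix
  $A = \partial h/\partial x|_m$, diagonal diffusion factors $B_i$.
* **Moment propagation** — the mean ODE $\dot M = AM + \Theta$ and the
  Kronecker-vectorized second-moment ODE $\dot Z = SZ + T(t)$ with the
  mean-square stability matrix
  $S = I\otimes A + A\otimes I + \sum_i B_i\otimes B_i$
  (`moment_path()`, `stability_matrix()`).
* **Four resilience measures** from $W(t) = \mathrm{trace}\,P(t)$: the
  instantaneous return rate $-\tfrac12 W'/W$ (its first zero crossing is the
  *return time*), the average return rate, the convergence rate
  $\mathcal R_c = -\tfrac12\alpha(S)$, and the asymptotic resilience
  (`resilience()` runs the whole pipeline).

Results come back as tibbles or light S3 objects with `tidy()`, `glance()`,
and `autoplot()` methods, so everything composes with the tidyverse.

## Worked example

Four benchmark scenarios (2 noise levels x 2 interaction strengths for a
competitive two-species community) ship with the package:

```r
library(sglv)
s <- glv_scenario(1)          # low noise, strong interaction

classify_stochastic_2sp(s$params)
#> <sglv_verdict> case C4i
#>   strong stochastic persistence: unique interior invariant probability measure

rep <- resilience(s$params, u = c(10, 15), m = s$ref_mean)
rep
#> <resilience_report> scenario 1 (low noise, strong interaction)
#>   pulse u = (10, 15), m from supplied
#>   convergence rate R_c    = 1.2635 per unit time
#>   asymptotic resilience   = 0.6969 (average-at-horizon at t = 3.96)
#>   return time (R_ins = 0) = 2.423
```

The verdict says the community is strongly stochastically persistent (both
species can invade every boundary state), so a stationary distribution
exists and the linearization is well posed. After a pulse that displaces the
two species by (10, 15) abundance units, the mean squared distance to the
stationary state shrinks at an asymptotic exponential rate of
$2\mathcal R_c \approx 2.53$ per unit time and stops shrinking (return time)
2.42 time units after the pulse. Increasing the noise five-fold
(`glv_scenario(2)`) raises the stationary variance, leaves less distance to
recover, and shortens the return time to 1.25 — environmental noise makes
this community *more* resilient by this measure.

Estimating the stationary mean by simulation instead of supplying it:

```r
tr  <- simulate_sglv(s$params, x0 = s$ref_mean, horizon = 5000,
                     dt = 1e-3, seed = 1)
stationary_mean(tr, burn_in = 500)
#> # A tibble: 2 x 3
#>   species  mean   mc_se
#>     <int> <dbl>   <dbl>
#> 1       1  38.7 0.00318
#> 2       2 135.  0.0146
```

`autoplot(rep)` draws the two return-rate curves against the
$\mathcal R_c$/$\mathcal R_\infty$ reference lines; `autoplot(tr)` plots
abundance paths.

A command-line interface wraps the same functions for shell pipelines:

```sh
inst/exec/sglv resilience --scenario 1 --pulse 10,15 \
    --stationary-mean 38.7470,135.3518 --out results/
```

Every CLI run writes a `manifest.json` (config echo, package version, seed)
sufficient to reproduce its outputs exactly.

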