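# patchrsf

Hierarchical Bayesian habitat-selection analysis at the foraging-patch
scale, for use–availability designs.

Ground-foraging insectivorous farmland birds (hoopoe, wryneck, woodlark,
common redstart) choose foraging patches by ground-vegetation structure:
the proportion of bare ground and the sward height measured in a small
circle around each location. The standard field design contrasts observed
foraging locations (`y = 1`) with random points (`y = 0`) drawn inside each
individual's minimum-convex-polygon home range, outside a 10 m buffer
around the foraging locations, in roughly equal numbers per individual.
`patchrsf` implements the complete analysis chain for this design, plus a
synthetic-data generator with known ground truth so every stage can be
validated without field data.

## The model

For record *j* of individual *i* with covariate row
*x* = (1, b, b², h, h²) (squared terms are squares of the standardized
linear terms):

    y_ij ~ Bernoulli( inv_logit( x_ij' B_i ) )
    B_ik ~ Normal( mu_k, sigma_k^2 )   independently across terms k

with vague priors `mu_k ~ N(0, 10^2)`, `sigma_k ~ U(0, 10)`. Every
individual has its own intercept and slopes, so the package reports both
individual functional responses and the marginal (population-level)
selection curve, obtained by averaging over simulated new individuals drawn
from `Normal(mu, sigma^2)` per posterior draw. Fitting is by a bespoke
adaptive Metropolis-within-Gibbs sampler (random-walk blocks per
individual, exact Gibbs draws for `mu` and `sigma`, plus translation and
scaling moves that fix the slow mixing of centered hierarchies).

Candidate models are ranked by DIC with conditional focus
(`DIC = d_bar + pD`, `pD = d_bar − D(posterior mean of B)`) over the fixed
nine-formula set `b+b2+h+h2, b+h+h2, h+h2, b+b2+h, b+b2, b+h, b, h,
intercept` (three formulas when height was not measured). Goodness of fit
is a posterior predictive check on the record-level χ² discrepancy
`Σ (y − p)² / (p(1−p))`, reported as a Bayesian P-value. A concave
quadratic bare-ground effect implies an interior selection optimum
`x* = −β_b / (2 β_b²)`, back-transformed to the raw proportion scale and
summarised over the posterior.

## Worked example

Simulate a wryneck-sized study (8 individuals, 45 used + 45 available
points each) from the default ground truth — a strong concave bare-ground
quadratic with its optimum at 50% bare ground, a mild preference for
shorter swards, and between-individual sds of 0.3 — then run the full
model-selection pipeline:

```r
library(patchrsf)
sim <- simulate_study("wryneck", seed = 7)
sel <- run_selection(sim$records, rsf_priors(),
                     mcmc_config(chains = 2, iterations = 3000,
                                 burn_in = 1000, seed = 7),
                     keep_fits = "best")
print(sel)
```

```
Model selection by DIC
     model deviance    pD     DIC   dDIC rank
 b+b2+h+h2   363.76 17.70  381.46   0.00    1
    b+b2+h   366.35 16.01  382.37   0.90    2
      b+b2   378.88  9.68  388.56   7.10    3
    b+h+h2   835.19 14.75  849.93 468.47    4
      h+h2   917.13 11.74  928.87 547.41    5
       b+h   942.68 11.94  954.62 573.16    6
         b   969.41  7.08  976.49 595.03    7
         h   987.84  7.84  995.68 614.22    8
 intercept  1000.22  2.09 1002.30 620.84    9
```

The generating model (`b+b2+h+h2`) ranks first; every formula missing the
bare-ground quadratic trails by hundreds of DIC units; the intercept-only
model costs ≈2 effective parameters, as the conditional focus implies.
The fitted optimum and the fit check:

```r
fit <- sel$fits[[sel$best]]
optimum_covariate(fit, "b")
#> Optimum b = 0.510 [80% CI 0.493, 0.527], interior in 100% of draws

d <- build_design(sim$records, fit$formula)
bayesian_p_value(fit, d, seed = 8)
#> Posterior predictive check: Bayesian P-value = 0.439 (4000 draws)
```

The true optimum (0.5) is recovered inside the 80% interval and the
P-value is unremarkable, as it should be for a correctly specified fit.
Response curves (individual grey lines, marginal curve with its 80% band,
0.5 neutrality reference) come from `individual_response()`,
`marginal_response()` and `plot_response_curves()`.

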