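---
title: "Hierarchical Bayesian habitat selection at the foraging-patch scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian habitat selection at the foraging-patch scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ground-foraging insectivorous birds in farmland select foraging patches by
the structure of the ground vegetation, in particular the proportion of
bare ground (`b`, a fraction of a small sampling circle) and the sward
height (`h`, in cm). The data come from a use--availability design: each
observed foraging location (response `y = 1`) is contrasted with random
points (`y = 0`) drawn inside the same individual's home range, outside a
10 m exclusion buffer around the foraging locations and in roughly equal
numbers per individual. `patchrsf` implements the full analysis chain for
such a design: the spatial sampling geometry, a hierarchical Bayesian
logistic regression with a bespoke MCMC sampler, DIC model ranking over a
fixed candidate set, posterior predictive goodness-of-fit checks,
selection-probability response curves, and a synthetic-data generator with
known ground truth that stands in for field data.

## The model

For record $j$ of individual $i$ with design row $x_{ij}$,

$$y_{ij} \sim \mathrm{Bernoulli}\!\big(\mathrm{logit}^{-1}(x_{ij}^\top B_i)\big),
\qquad B_{ik} \sim \mathcal{N}(\mu_k, \sigma_k^2)$$

independently across terms $k$. The columns of $x$ are, in fixed order,
an intercept and a subset of $\{b, b^2, h, h^2\}$; the squared terms are
the squares of the *standardized* linear terms. Every individual carries
its own coefficient vector $B_i$ (random intercept and random slopes),
which is what lets the package report both individual functional responses
and a marginal, population-level response.

Assumptions worth stating explicitly:

* **Independent random effects.** The $B_{ik}$ are independent across
  terms; no correlation matrix is estimated. This matches the classic
  independent-normal BUGS-style structure for "random intercept and slope"
  models; with 5--13 individuals per species there is little information to
  estimate a $5 \times 5$ correlation anyway.
* **Conditional independence of records.** No residual spatial or temporal
  autocorrelation; the temporal thinning rule (below) is the only guard.
* **Balanced design neutrality.** With roughly equal used and available
  counts per individual, a fitted selection probability of 0.5 is neutral;
  below 0.5 means avoidance, above means preference. `build_design()`
  warns when any individual's used:available ratio exceeds 1.25, because
  this reading degrades with imbalance.

### Priors

Vague by default and configurable through `rsf_priors()`:
$\mu_k \sim \mathcal{N}(0, 10^2)$ on the standardized covariate scale and
$\sigma_k \sim \mathrm{Uniform}(0, 10)$. With covariates standardized to
unit sd, coefficients of plausible magnitude (say $|\mu| < 5$) sit well
inside the flat region of these priors.

### Standardization

Covariates are centred and scaled before sampling (`b` as a proportion,
`h` in cm), and every user-facing quantity — response curves, the
quadratic optimum — is back-transformed to the raw scale. The conditional
deviance is invariant to this choice (the test suite checks the exact
affine mapping between coefficient scales), so standardization affects
only sampler conditioning, not inference. `build_design()` accepts an
externally supplied `standardization` so that simulation studies can
compare fitted population means against truth on the very scale the truth
was defined on.

## The sampler

`fit_rsf()` runs an adaptive Metropolis-within-Gibbs scan, written for
this model rather than taken from a general-purpose engine:

1. **Individual blocks.** Each $B_i$ is updated by a random-walk
   Metropolis proposal over all its terms at once. Each individual has an
   overall proposal scale tuned toward 35% acceptance during burn-in, and
   per-term relative scales learned from the running posterior spread in
   the same window. All adaptation freezes at the end of burn-in, so the
   retained draws come from a fixed, detailed-balance-preserving kernel.
2. **Population means.** $\mu_k$ has a conjugate normal full conditional
   given $B$ and $\sigma$ and is drawn exactly.
3. **Random-effect spreads.** The precision $1/\sigma_k^2$ has a truncated
   Gamma full conditional under the uniform prior on $\sigma_k$ and is
   drawn exactly by inverse-CDF.
4. **Translation and scaling moves.** Centered hierarchical
   parameterizations mix slowly because $\mu$ can only move where $B$
   already is, and $\sigma$ only as fast as the spread of $B$ changes. Two
   extra Metropolis moves repair this: a *shift* proposing
   $(\mu_k, B_{1k}, \dots, B_{Ik}) \mathrel{+}= \delta$ jointly (the
   random-effect density is invariant, so only the data likelihood and the
   $\mu$ prior enter), and a *scale* move multiplying $\sigma_k$ and the
   spread of $B_{\cdot k}$ about $\mu_k$ by a common log-normal factor
   while holding the standardized residuals fixed. Both moves cost one
   full-data likelihood pass per term and are what make short chains
   usable for the population-level parameters.

Chains are initialized at a pooled (non-hierarchical) logistic fit plus a
chain-specific jitter. Split-chain R-hat is computed for every parameter
and an initial-positive-sequence effective sample size for $\mu$ and
$\sigma$; any R-hat above 1.1 is recorded as a warning inside the returned
object, never thrown as an error. All randomness derives from one integer
seed; the same seed reproduces every draw bit for bit.

Defaults are 3 chains of 6,000 iterations with 1,000 burn-in. The
package's own validation studies use 2 chains of 1,500--3,000 iterations;
each fit's split R-hat and effective sample sizes are stored in the
returned object, so the adequacy of any run can be read off its own
diagnostics rather than assumed.

## DIC with conditional focus

`compute_dic()` uses the deviance conditional on the individual
coefficients, $D(B) = -2 \log p(y \mid B)$, with
$\bar D$ the posterior mean deviance, $p_D = \bar D - D(\hat B)$ the
plug-in at the posterior mean of $B$, and $\mathrm{DIC} = \bar D + p_D$
(an exact identity in the returned object). The conditional focus is what
makes an intercept-only hierarchical model cost about two effective
parameters (the grand mean plus the shrunken individual intercepts), which
is the behaviour the ranked tables in this package display. Negative
$p_D$ is legal and only warns. The candidate set is fixed a priori:
all nine marginality-respecting combinations of
$\{b, b^2, h, h^2\}$ plus the intercept-only model, reduced to
$\{b+b^2,\, b,\, \text{intercept}\}$ when height was not measured. Each
candidate is fitted with a seed derived from one base seed, so a single
integer reproduces the whole table; ties are reported, never resolved.

## Goodness of fit

`bayesian_p_value()` computes, per posterior draw, the variance-
standardized discrepancy
$T = \sum_j (y_j - p_j)^2 / (p_j (1 - p_j))$ on the observed data and on a
replicate $y^* \sim \mathrm{Bernoulli}(p)$, and reports
$\Pr(T^{\mathrm{rep}} \ge T^{\mathrm{obs}})$. Probabilities are clamped to
$[10^{-12}, 1 - 10^{-12}]$ before the ratio, and the number of clamped
record-probabilities is reported — never silently. The discrepancy is
evaluated on individual Bernoulli records (not on binned groups); this is
the weaker but assumption-light variant, and its power characteristics
shaped the validation design below.

## The synthetic-data generator

`make_landscape()` builds a grass/bare mosaic: a Gaussian random field
(white noise smoothed by an isotropic Gaussian kernel via the FFT, on a
torus) thresholded at the empirical quantile matching the target bare
fraction, plus an independent second field for vegetation height,
truncated at zero and zeroed on bare cells. `patch_scale` sets the
autocorrelation range of the mosaic. `simulate_individual()` mirrors the
field protocol: the home range is the MCP of a seeded scatter; candidate
foraging points are drawn uniformly inside it; each candidate's covariates
are measured by the same patch-circle extraction the analysis uses (so
selection operates at the measurement scale); candidates are kept by
rejection against the selection weight $\exp(\beta^\top x)$ normalized by
a pre-scan maximum; availability points are drawn with the 10 m exclusion
buffer. The exclusion buffer couples sample size to home-range area
(each used point removes ~314 m²), so designs with many points per
individual need proportionally larger home ranges — the generator errors
out, reporting the feasible fraction, rather than silently violating the
buffer.

Defaults, chosen once as a realistic rendering of the study system and
then left alone: landscape 400 x 400 m at 0.5 m grain, bare fraction 0.4,
patch scale 3 m (a fine-grained mosaic with patches on the order of the
~3 m² foraging-patch scale; coarser mosaics make 1 m sampling circles
almost always purely bare or purely grass), height mean 15 cm with sd
5 cm, home-range span 200 m, 45 used and 45 available points per
individual. The four species presets reproduce the study structure — 13
hoopoes, 8 wrynecks, 7 woodlarks (5 m patch circles), 5 common redstarts
(no height measured) — for a four-species total of ~2,900 locations.

Truth coefficients are interpreted on a fixed reference standardization
(bare: mean 0.40, sd 0.20; height: mean 15 cm, sd 10 cm) stored in every
`TruthBundle`. With the default truth $\mu_b = 2$, $\mu_{b^2} = -2$ the
raw-scale selection optimum sits at exactly 50% bare ground — an
intermediate optimum of the kind the method exists to estimate. The
generator's intercept is *not* a recovery target: the rejection step
normalizes the selection weight, and with balanced sampling the fitted
intercept reflects the covariate distribution of the home range, not the
generating intercept. The generator also accepts a truth-only cubic term
`b3` that no fitted model contains, used to build deliberately
misspecified truths for goodness-of-fit power studies.

What the generator does not emulate: movement behaviour (no central-place
trips or autocorrelated tracks), telemetry error, observer bias, and any
real covariate distribution — patch covariates inherit the bimodality of
a thresholded random field, which is plausible for herbicide-striped
plantations but is still a model. Passing recovery tests therefore shows
the estimator is consistent with its own design assumptions, not that
field estimates are unbiased.

## Validation design and numerical choices

The test suite runs replicate studies at reduced but honest scale:

* **Parameter recovery**: 20 studies of 13 individuals x 100 points
  (truth $\mu_b = 2$, $\mu_{b^2} = -2$, $\sigma = 0.3$), 2 chains x
  3,000 iterations; 80% intervals must cover each true mean in 12--20 of
  20, and posterior means must land within 3 posterior sds in at least
  18 of 20.
* **Structure recovery**: 10 studies from a quadratic truth and 10 from an
  intercept-only truth, ranked over the height-free candidate set; the
  quadratic truth must put a $b^2$ model first with every $b^2$-free model
  more than 2 DIC behind, and the null truth must keep the intercept model
  within 2 DIC of the best, in at least 8 of 10 each.
* **Optimum recovery**: one ~1,500-location study; the posterior mean
  optimum must fall in [0.45, 0.55].
* **PPC calibration and power**: 20 correctly specified studies must give
  Bayesian P-values inside (0.05, 0.95) at least 18 times. The power half
  generates from a strong cubic selection surface
  ($\mu_{b^3} = 1.5$, 13 individuals x 300 locations) and fits the
  linear-only model; the record-level $\chi^2$ P-value must be extreme in
  a majority of 20 replicates. The cubic misspecification is the
  informative one here: an omitted symmetric quadratic drives the fitted
  linear slope toward zero, and at $\hat p \approx 0.5$ the
  variance-standardized discrepancy has identically zero expected
  inflation — a structural blind spot of the record-level statistic worth
  knowing about when reading P-values near 0.5.
* **Geometry**: hulls are checked vertex-for-vertex against an
  independently written gift-wrapping oracle; the exclusion buffer is
  checked exhaustively; patch extraction is checked against Monte-Carlo
  integration; the thinning rule against a hand-simulated track.
* **Marginalization**: the Monte-Carlo average over simulated individuals
  is checked against 20-node Gauss--Hermite quadrature to $10^{-3}$ for a
  random-intercept-only posterior.

Other numerical choices: patch-circle integrals use a deterministic
subgrid at spacing radius/32 (area-weighting error well under 1%, and
exact on uniform patches); hull containment is boundary-inclusive with a
scaled $10^{-9}$ cross-product tolerance; availability rejection sampling
caps attempts at 1,000 x n and errors below a 0.5% feasible fraction;
collinear location sets are an error rather than a zero-area home range;
the thinning rule keeps a fix at exactly the 5-minute boundary
("at least 5 minutes apart") and treats a move beyond `site_radius`
(default 10 m, the exclusion-buffer scale — the notion of "another
foraging site" is otherwise undefined) as a new site; 80% intervals are
equal-tailed posterior quantiles throughout, never HPD.

## Known limitations

* No spatial autocorrelation model and no step-selection (conditional
  logistic) variant; records are exchangeable given the individual.
* Random effects are uncorrelated across terms by construction.
* DIC is the only ranking criterion, with conditional focus; WAIC/LOO are
  out of scope.
* The record-level $\chi^2$ check is insensitive to misfit that leaves
  fitted probabilities near 0.5 (see above); a binned variant would have
  more power but needs a binning rule the analysis does not otherwise
  define.
* Coordinates must be planar metres; geodetic input is rejected, not
  converted.
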