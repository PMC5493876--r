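---
title: "Small area estimation of binary health indicators with structured additive regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small area estimation of binary health indicators with structured additive regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starsae)
```

## The problem

Health surveys measure binary indicators (overweight, smoking, perceived
health, ...) on a few percent of the adult population. Direct survey
estimates are unusable for neighbourhoods where only a handful of people
— or nobody — was sampled. Unit-level small area estimation solves this
by modelling the individual outcome as a function of predictors that are
known for *everyone* from administrative registries, predicting every
registered adult, and aggregating predictions into area prevalences.

`starsae` implements this pipeline end to end for binary outcomes:
a penalized logistic **structured additive regression** (STAR) model is
fitted per regional stratum to survey respondents linked to registry
predictors; the fitted linear predictor is applied to the stratum's full
registry; respondents keep their observed outcome; person-level values
are averaged into neighbourhood, district and municipality prevalences.
Because the registry and survey microdata this design targets are
confidential, the package ships a synthetic-registry generator with a
known ground truth, so that every stage is testable.

## The model

For adult $i$ the outcome is Bernoulli, $Y_i \sim \mathrm{Bern}(p_i)$,
with $\operatorname{logit}(p_i) = \eta_i$ and a structured additive
predictor

$$
\eta_i = \beta_0 + \beta_{sex}\,sex_i + f_{age}(age_i)
  + f_{age|sex}(age_i)\,sex_i + \textstyle\sum_j \beta_j x_{ij}
  + f_{hhsize} + f_{hhcap} + f_{hhinc} + f_{urb}
  + f_{neigh}(neigh_i),
$$

combining

* **dummy-coded categorical effects** (sex, ethnicity, marital status,
  household type, income source, home ownership), reference level
  absorbed into $\beta_0$;
* **P-splines** for the numeric predictors: cubic B-spline bases on
  equidistant knots with a quadratic penalty
  $\lambda\,\gamma' D_r' D_r \gamma$ on $r$-th order differences of
  adjacent coefficients ($r = 2$ throughout, so $\lambda \to \infty$
  shrinks the fit to a straight line);
* a **varying-coefficient smooth** $f_{age|sex}\cdot sex$ for the
  age-by-sex interaction;
* a **Markov random field** (intrinsic CAR) spatial effect: one
  coefficient per neighbourhood with incidence design and penalty
  $K_{ss} = |N(s)|$, $K_{sr} = -1$ for rook-adjacent pairs, which
  penalises squared differences between adjacent neighbourhoods and
  interpolates to neighbourhoods without respondents;
* optionally a **ridge** (identity-penalty) random intercept per
  neighbourhood; it is off by default, the spatial term having absorbed
  the between-area heterogeneity in our experiments.

Identifiability requires each penalized term to sum to zero over the
estimation sample. Simple column centring is not sufficient for the MRF
(its penalty null space is the constant vector, confounded with the
intercept), so each penalized block $B$ is reparameterised exactly: with
constraint vector $c = B'1$, one coefficient is solved from the others
and the penalty is transformed consistently. The dropped coefficient is
the one with the largest $|c|$ entry, which is always an area or basis
function actually supported by data.

### Smoothing selection

Smoothing parameters are selected by Laplace-approximate restricted
maximum likelihood (LAML). At fixed $\lambda$ the coefficients maximise
the penalized Bernoulli log-likelihood via penalized IRLS (Fisher
scoring with step halving; relative penalized-deviance tolerance
`1e-8`, at most 100 iterations). The REML criterion is

$$
\mathcal{V}(\lambda) = \ell(\hat\beta) - \tfrac12\hat\beta'S\hat\beta
 + \tfrac12\log|S(\lambda)|_+ - \tfrac12\log|H + S(\lambda)|
 + \tfrac{M_p}{2}\log 2\pi,
$$

with $H$ the Fisher information at $\hat\beta$, $S$ the total penalty
and $|\cdot|_+$ the pseudo-determinant over the penalty range space. It
is maximised over $\log_{10}\lambda \in [-12, 12]$ by box-constrained
quasi-Newton with warm-started inner solves (`reml_select()`), to a
criterion tolerance of `1e-6`. A $\lambda$ on the search bound is
reported; separation (fitted probabilities pinned to 0/1) is flagged as
non-convergence rather than silently accepted. `mgcv` implements the
same family of criteria and serves as an independent cross-check in the
test suite, never as the estimation path.

### Knot convention

"A spline with 10 knots" is read as **10 equidistant knots spanning the
observed predictor range**, cubic degree, with the knot grid extended by
`degree` equidistant knots on each side; that yields $10 + 3 - 1 = 12$
basis functions before the constraint. Other conventions (interior-knot
counts, knots at quantiles) exist; this one is fixed here and used
consistently, including the 5-knot household-size smooth. Outside the
training range the basis is continued linearly, so prediction for a
registry member older than any respondent extrapolates the fitted smooth
as a straight line rather than a polynomial tail.

## Spatial preprocessing

Per stratum (health-service region) the estimation set is the stratum's
own neighbourhoods (the *core*) plus every other neighbourhood whose
centroid lies within a 10 km **buffer** of the stratum outline — the
union of its polygons dilated by a disc, computed exactly as
point-to-polygon-union distance. Buffer individuals stabilise the
spatial field near the boundary but are never predicted. Adjacency is
**rook contiguity**: polygons sharing a boundary segment of positive
length (corner contact excluded), detected by collinear-segment overlap
with a $10^{-9}$ m snap tolerance. Buffering can strand islands, so
while the estimation graph has more than one component the two closest
components (Euclidean centroid distance, ties broken by smallest id
pair) are joined by an edge; exactly `components - 1` edges are added
and recorded separately. A one-neighbourhood estimation set drops the
spatial term with a warning — its penalty would be null.

## Registry imputation

The registry's household fields go missing in two groups (type+size;
capital+income+income source+home ownership). Each field is singly
imputed from a multinomial logit on fully observed individual
predictors: a natural cubic spline of age with knots at ages 22, 30, 50
and 80 (boundary knots 22 and 80, linear tails), sex, ethnicity and
marital status. Capital and income percentiles (1..100) are first
reduced to five classes; class $c$ maps to the percentile block
$\{20(c-1)+1, \dots, 20c\}$ — equal blocks being the only symmetric
reading of "five classes of 100 percentiles" — and after a class is
drawn an integer percentile is drawn uniformly within the block.
Because the fields are household attributes, a value observed on any
household member is copied to the others, and fully missing households
receive **one** draw copied to all members. Observed values are never
altered. The multinomial fit itself is delegated to `nnet::multinom`;
the contribution here is the surrounding procedure, and the fitted
coefficients serialise to JSON.

## Prediction, aggregation, uncertainty

`predict_population()` applies the fitted predictor to every imputed
core-region record; `overwrite_observed()` replaces the probabilities of
survey respondents by their observed 0/1 outcome (the standard plug-in
step of unit-level SAE); `aggregate_prevalence()` averages person values
per area at the three levels, so the municipality estimate is exactly
the person-weighted mean of its districts'. Areas with fewer than 10
adults are sanitised — count reported, prevalence suppressed — for
disclosure control. Prevalences are proportions internally and become
percentages with one decimal only in the output CSVs, avoiding double
rounding.

Prediction uncertainty uses the Monte-Carlo recipe: draw coefficient
vectors from $N(\hat\beta, \hat V)$, form person probabilities per
draw, draw Bernoulli outcomes for non-respondents (respondents keep
their observed outcome), aggregate per draw, and summarise across draws
by mean and standard deviation. The default is 1000 draws; at the
package's desk scales this is fully feasible.

## Validation surfaces

Calibration: respondents are split 2/3 train – 1/3 validation (sizes
within one of exact), the model is refitted per stratum on the training
part, and validation predictions are grouped into 200 **equal-count
quantile bins** (ties in the predicted probability broken stably by
record id, so the binning is reproducible and order-invariant). Per bin
the mean prediction and mean observed outcome are compared; a
least-squares slope/intercept across bins summarises the plot — the
slope is an added quantitative surface for what is usually judged
visually. `compare_estimates()` pairs two estimate sets and reports
correlation, mean difference and the attenuation ratio
$\mathrm{sd}(a)/\mathrm{sd}(b)$, quantifying how much model estimates
are shrunk relative to direct ones; `extreme_areas()` ranks areas and
attaches population profiles for plausibility audits.

## The synthetic registry

The generator emulates the nested structure of registry data:
households (truncated-geometric sizes, mean ≈ 2.2, household fields
drawn once per household) inside neighbourhoods (lattice or jittered
polygons with districts, municipalities and strata as nested
partitions). Percentile predictors are person-weighted empirical
percentile ranks of household/neighbourhood latents, giving uniform
marginals up to rounding. The ground-truth outcome model has a smooth
unimodal age effect peaking near 65, an age-by-sex interaction shifting
the female peak towards 75, moderate categorical effects, weak linear
percentile trends, and a spatial field simulated from a zero-mean
intrinsic autoregression on the adjacency graph scaled to SD 0.3 on the
log-odds scale — magnitudes chosen once as typical of adult overweight
modelling, so that recovery tests are neither trivial nor hopeless. The
survey is a ~3% proportional within-neighbourhood sample without
replacement; missingness is injected completely at random per record,
consistent with an imputation model that conditions only on fully
observed fields.

What the generator does **not** emulate: realistic Dutch demography and
its predictor correlations, informative non-response, measurement error
in self-reported outcomes, or irregular real-world polygon topology
(enclaves, multipolygons, slivers). Passing recovery and calibration
tests on these data therefore demonstrates the correctness of the
machinery, not the real-world accuracy of any particular estimate.

## Numerical choices and problem sizes

* Inner IRLS: relative penalized-deviance tolerance `1e-8`; outer REML
  tolerance `1e-6`; $\log_{10}\lambda$ box $[-12, 12]$.
* Designs are sparse (`Matrix`); the MRF incidence stays sparse through
  the constraint because the dropped coefficient is the best-supported
  area.
* Closest-pair and binning ties are broken by id order — all outputs are
  reproducible from the master seed, from which every stochastic stage
  derives its own labelled sub-stream.
* The test suite exercises parameter recovery at 200 neighbourhoods
  with ~30,000 persons across five seeds, and calibration at 100,000
  records — sizes chosen so the whole suite runs in minutes on a single
  core while leaving the statistical assertions well-powered. The full
  Dutch-scale run (13M records, ~1000 coefficients per stratum) is out
  of scope; the per-stratum design keeps memory linear in stratum size.

## Known limitations

* One shared smoothing parameter per term, logit link only, no tensor
  products.
* Direct (survey-weighted) estimation is not implemented;
  `compare_estimates()` accepts such estimates as an external table.
* Single imputation ignores imputation uncertainty by design.
* The Monte-Carlo uncertainty treats $\hat\lambda$ as fixed; smoothing
  parameter uncertainty is not propagated.

## A minimal run

```{r example, eval = FALSE}
cfg <- run_config(
  output_dir = "demo_run",
  population = population_config(n_neighbourhoods = 9L,
                                 mean_persons_per_neighbourhood = 150,
                                 survey_fraction = 0.4, seed = 2L),
  spec = model_spec(term_linear("sex"), term_smooth("age", 10L),
                    term_mrf()),
  run_mc = TRUE, mc_draws = 200L, seed = 2L)
res <- run_pipeline(cfg)
res$estimates$neighbourhood
attr(res$calibration$overweight, "slope")
```
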