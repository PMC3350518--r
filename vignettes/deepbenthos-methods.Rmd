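---
title: "Models and design choices in deepbenthos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in deepbenthos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`deepbenthos` analyses epibenthic sled surveys of deep-sea megabenthos:
tens of samples, hundreds of species, most caught once. This vignette
explains each model, its assumptions, the tunable parameters and the
design choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The synthetic survey generator

Real sled surveys of this kind are rarely deposited, so the package
generates look-alike data with recorded ground truth; every downstream
model is validated by recovering that truth.

**Environment.** A regular lon/lat grid (default 50 × 50 cells at
0.01°, roughly 1 km) carries one layer per covariate: depth, a binary
fished flag, % carbonate, % sand / gravel / mud, and the annual mean
and standard deviation of temperature, salinity, oxygen, nitrate and
phosphate. Depth is a linear offshore ramp (150–1850 m) plus Gaussian
cones subtracted for seamounts; cone heights of 200–300 m are placed so
peaks land at 700–1400 m, mimicking volcanic hills on a continental
margin. Oceanographic *means* are monotone functions of depth plus
noise — consequently strongly correlated with depth (the generated
temperature–depth correlation is below −0.8, checked in the tests).
The *standard-deviation* layers are deliberately not monotone: they are
unimodal with a peak near 800 m (width 300 m), emulating intermittent
intermediate-depth currents, and so are not linearly correlated with
depth. Sand, gravel and mud are normalised exponentials (softmax) of
three smooth random fields — the simplest construction that guarantees
the three fractions sum to exactly 100 in every cell. Carbonate is an
independent west–east gradient; the fished layer is one rectangular
patch covering 15% of cells. All draws come from a single seeded
stream in a documented order, so a grid is reproducible from its seed
alone.

**Species pool.** Species belong to archetypes (default 12 for 493
species). An archetype has a Gaussian depth niche — optimum drawn over
roughly 200–1800 m, width drawn from the `niche_width` range — plus
linear responses to mud and carbonate; on the logit scale this is
linear in (depth, depth², mud, carbonate) with fixed reference scaling,
so the pool is independent of any particular grid. A species' response
is its archetype's plus Gaussian jitter (`jitter_sd`). Occurrence
probabilities are capped at `max_occ_prob` (default 0.6): even perfect
habitat does not guarantee capture, which is what a sled tow through a
patchy seafloor delivers.

**Survey.** Sites are distinct grid cells; swept areas are uniform on
160–2500 m² (a 134–2086 m tow by a ~1.2 m sled mouth). Site totals are
negative binomial with log link on carbonate and log(swept area)
(defaults: intercept 2.6, carbonate 0.073, log-area 0.089, θ = 1.73 —
effect sizes of the magnitude reported for sled surveys of this type,
with the intercept set so totals are in the hundreds-to-thousands).
Presences are Bernoulli draws from the capped probabilities; the site
total is then allocated to the present species by a multinomial whose
rank proportions decay as exp(−β·(r−1)/(S−1)) over a random permutation
(default β = 5). Species allocated zero individuals are undetected —
this coupling of presence and allocation is what produces realistic
singleton fractions.

**Calibration.** The one quantity the generator is explicitly
calibrated to is the singleton fraction: 43% of observed species caught
exactly once, the hallmark of deep-sea sled data. The rarity defaults
(`base_logit = -2.55`, `logit_sd = 1.2`, `niche_width = 0.2–0.45`) were
chosen by a simulation sweep to reproduce it at 39 sites and then
frozen. The trade-off is acknowledged: at these settings a 39-sample
survey observes ~250 of the 493 pool species with ~16 species per
sample, fewer than a real margin survey would record. Passing tests
therefore demonstrate correct behaviour under heavy rarity and
depth-structured turnover; they do not certify performance on data with
richer samples, abundance-dependent detectability, or spatial
autocorrelation beyond the smooth environmental fields — none of which
the generator emulates.

## Aggregated boosted trees

`fit_brt()` is stagewise gradient boosting of the Bernoulli deviance:
at each stage a depth-limited regression tree (exact greedy splits,
via rpart, on a 50% row bag) is fitted to the residuals y − p, its leaf
values replaced by Newton steps Σr / Σp(1−p), and the model updated
with shrinkage ν. `fit_abt()` assigns sites to 10 folds stratified by
the response, trains one boosted model per fold on the other nine,
prunes each at the tree count minimising its held-out deviance, and
averages the 10 fold probabilities — an identity the tests check
exactly. Defaults ν = 0.01, depth 2, bag fraction 0.5, 2000 trees
follow common boosted-tree practice in ecology and are configurable;
nothing in the method fixes them. Relative influence is the squared-
error split improvement summed per covariate over retained trees and
folds, normalised to 100. Partial-dependence sign labels are an
operationalisation of the +/−/peak annotations used in species-model
tables: + when the curve's Spearman correlation with its grid is
≥ 0.6, − when ≤ −0.6, else peak when an interior maximum beats both
endpoints, else flat; the 0.6 threshold is our choice, made once. The
reported AUC is cross-validated — each site is scored by the fold model
that held it out — because resubstitution AUC of a boosted ensemble on
39 sites is essentially 1 and uninformative.

## Generalized dissimilarity modelling

Sørensen dissimilarity of presence/absence is the response; pairs of
sites are the observations. Each predictor enters through an order-2
I-spline basis (default 3 functions, knots at the observed min, median
and max — the conventional GDM configuration), and the design column
for a pair is |I_k(x_i) − I_k(x_j)|. Because every basis function is
monotone and coefficients are constrained non-negative, each fitted
turnover function f_p is non-decreasing, is 0 at the covariate minimum,
and attains its magnitude Σc_p at the maximum. The mean is
μ = 1 − exp(−η); the deviance is the binomial-type deviance with 0·log0
treated as 0. Fitting is projected gradient descent with Armijo
backtracking (tolerance 1e-8, 5000 iterations cap, intercept started
at the null fit, coefficients at zero); the null deviance comes from a
one-dimensional intercept-only optimisation, and percent deviance
explained is 100(1 − D/D₀). Geographic distance is deliberately not a
predictor: the analysis asks how much *environment* explains turnover.
Sites with zero presences are invalid for Sørensen (zero denominator)
and are rejected by the primitive; the pipeline drops them with a log
message before fitting.

For mapping, predicted dissimilarities among a random subset of anchor
cells (default 500) are embedded by classical MDS; remaining cells are
projected onto the first three axes by Gower's out-of-sample formula,
and each axis is min–max scaled to [0, 1] as the R, G, B channels. The
anchor subsample keeps the embedding linear in grid size instead of
quadratic. One numerical subtlety is inherent to the method: predicted
self-dissimilarity is 1 − exp(−a₀) > 0, so the anchor matrix is given
a zero diagonal and the embedding represents between-cell contrasts up
to that constant offset. Degenerate (all-equal) dissimilarities return
a constant mid-grey map with a warning.

## The factorized RAD likelihood

A sample's rank abundance distribution is decomposed into N (sum of
counts over countable species), S (number of countable species with
positive count) and the sorted proportion vector n; the site
log-likelihood is the sum of the three component log-likelihoods. Taxa
flagged non-countable (e.g. colonial corals) are excluded from N, S
and n alike — the exclusion is stated in field protocols for abundance
only, but symmetric exclusion is the only choice under which S ≤ N is
provable, so the package adopts it.

**Abundance** is negative binomial with log link; log(swept area) is an
estimated coefficient, not a fixed offset, because the effort
elasticity of a sled is an empirical quantity (reported with a standard
error in studies of this kind), and θ is estimated by maximum
likelihood (via `MASS::glm.nb`).

**Richness** is negative binomial right-truncated at N: per site the
NB(μ, θ) mass is renormalised over 0..min(N, cap), with cap = 10·mean(S)
for tractability (the renormalising constant is a CDF evaluation, and
predicted means are sums over the truncated support, so an unbounded
support would cost nothing in correctness but much in the map
predictions). The candidate covariates include log(N/a) and N/a, which
together give the power-law-with-saturation richness–abundance
relationship. Note one modelling convention the coherence test makes
explicit: the truncated support includes S = 0 even when N > 0, and
the composition component for S = 0 is a point mass on the empty
vector. The factorized model is a valid probability model — its total
mass over the outcome space is 1, verified by exhaustive enumeration —
at the cost of assigning positive probability to physically impossible
(N > 0, S = 0) outcomes that real data never contain.

**Relative abundances** are multinomial over the S rank cells with
probabilities ∝ exp(βz_r + γz_r²), z_r = (r−1)/(S−1); β and γ are
shared across sites and fitted jointly (the intercept of the
exponential cancels in the normalisation and is not a parameter). The
scaled rank makes curves comparable across S.

**Evenness** is defined as |g′(0)| where g is the least-squares
quadratic fit of log n_r on z_r — the steepness of the RAD at the most
abundant species. For S = 2 this degenerates to |log n₁ − log n₂|, for
S ≤ 1 to 0. The phrase "derivative of the slope" in the RAD literature
is ambiguous between first and second derivative and between
directions; this package fixes the definition (first derivative at
z = 0, absolute value) and asserts only testable consequences: a flat
RAD gives 0, geometric proportions (1, ½, ¼) give exactly 2·ln 2, the
value depends on ratios only, and steeper generative rank slopes give
larger η (i.e. ecologically *less* even communities — larger η means
steeper). Its regression model is gamma with log link (η is positive
and right-skewed; no family is canonical here) on polynomials in
area-scaled, z-standardised N and S only — no direct environmental
terms, since evenness responds to the environment through N and S.
The standardisation moments are stored in the fitted model and reused
for prediction, so grid maps are on the fitting scale.

**Selection** is greedy forward AIC (AIC = −2ℓ + 2k, counting θ) with
the hierarchy rule that an interaction is admissible only once both
mains are in. Forward AIC admits a spurious term with probability
≈ 0.16 per candidate; with several null candidates the *exact* true
set is recovered in under half of replicates even at n = 500, while
the true covariate is selected first essentially always — both
behaviours are measured by the acceptance script rather than hidden.

**Maps.** Plug-in mean maps of N, S and η are computed at a reference
swept area (default 1000 m²). Uncertainty is a parametric bootstrap:
coefficient vectors are drawn from each model's asymptotic normal
distribution (covariance eigendecomposed with negative eigenvalues
clamped to zero, which handles near-boundary θ̂), propagated through
the chain N → S → η, and summarised per cell as CV = sd/mean. The CV
reflects coefficient uncertainty only, not θ uncertainty or process
noise.

## Problem sizes and numerical choices

The test suite and acceptance script run on sizes chosen to exercise
every code path at desk scale: 20-replicate recovery studies use 300
sites (RAD), 100 sites (GDM pairs) and 300 rows (ABT, with depth-1
trees — the generative signal is additive in one covariate, for which
stumps are the matched learner); the enumeration check uses an
abundance mean of 0.2 so the N ≤ 5 outcome space carries all but
~2×10⁻⁷ of the mass; the end-to-end smoke run uses a 2500-cell grid,
40 sites and 300 species. Optimiser guards (linear predictors capped
at ~25–50 before exponentiation, non-finite likelihood values treated
as infeasible) exist solely to keep exploratory steps of BFGS and the
projected gradient inside floating-point range; they do not bind at
the optimum on any tested dataset.

## Known limitations

- The generator produces smooth environmental fields and independent
  Bernoulli presences; it has no spatial autocorrelation beyond the
  fields, no temporal dynamics, no gear-dependent detectability.
- GDM retention/dropping of predictors is left to explicit
  configuration; no automated backward elimination.
- The rank-curve parameters are global, not covariate-dependent; the
  factorized likelihood treats the ranked counts as cell-labelled,
  which is the standard simplification.
- Richness truncation uses a tractability cap; with data where
  S routinely approaches N the cap should be raised via the `cap`
  argument.
- Evenness direction (whether larger η should be read as "more" or
  "less" even) is a convention; the package documents η as steepness
  and leaves the ecological reading to the analyst.
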