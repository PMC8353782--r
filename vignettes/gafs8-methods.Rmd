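---
title: "Models and methods behind the GAFS-8 toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the GAFS-8 toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gafs8)
```

This vignette documents the statistical models the package implements, the
assumptions they carry, the defaults and numerical choices, and the design
decisions taken where several defensible conventions exist. It states no
empirical result beyond what the package's own tests and acceptance script
compute.

## The graded response model

All scoring and estimation rests on the unidimensional logistic graded
response model. A respondent with latent alexithymia level $\theta$ answers
item $j$ (five ordered categories, coded 1–5) with cumulative probabilities

$$P^*_{jk}(\theta) = \frac{1}{1 + \exp\{-(a_j\theta + d_{jk})\}},
\qquad k = 1, \dots, 4,$$

so the category probabilities are successive differences of the $P^*$.
Slopes $a_j$ are on the logistic metric and intercepts are ordered
$d_{j1} > \dots > d_{j4}$, with more positive intercepts meaning an "easier"
category transition. The model assumes a single latent dimension, local
independence given $\theta$, and a normal latent distribution per group.
Responses coded 0–4 (scales anchored at zero) are recognised and shifted up
by one; ties in the modal-category census are not counted as modal, so a
"never-modal" category is one that is never *strictly* most probable.

The equivalent standardized factor loading is
$\lambda = (a/D)\big/\sqrt{1 + (a/D)^2}$ with scaling constant $D = 1.702$.
The published calibration does not state $D$; 1.702 is the conventional
logistic/normal-ogive constant and reproduces the published loadings to
within one unit in the third decimal place from the three-decimal printed
slopes (exact rounding of the slopes themselves accounts for the residual
discrepancy, so the package pins agreement at that granularity rather than
at three decimals).

## Norm-referenced scoring and the embedded calibration

`gafs8_bank()` embeds the published two-group calibration of the eight
GAFS-8 items: item parameters constrained equal across a general-population
group (latent trait fixed to mean 0, SD 1) and a clinical (autistic) group
with free latent moments. Scores are therefore Z-scores on the
general-population metric, and `t_score = 50 + 10 * theta_hat`.

Two latent densities accompany the bank:

* **normative**, $N(0, 1)$ — the default scoring prior, so that every
  respondent is referenced to the general population;
* **clinical**, $N(1.01, 1.237^2)$ — the clinical group's latent density.
  The calibration reports that group's *score-level* mean and SD (1.01 and
  1.17) and a marginal reliability of 0.895; because MAP scores shrink
  toward the prior mean by the reliability factor
  ($\mathrm{Var}(\hat\theta) \approx \rho_{xx}\sigma^2$), the latent SD is
  recovered as $1.17/\sqrt{0.895} \approx 1.237$.

The published bounds of the GAFS-8 score surface (all-lowest pattern
$\approx -2.19$, all-highest $\approx 3.52$) arise when the extreme patterns
are scored under the *clinical* density — the convention of the source
calibration, in which each respondent is scored with their own group's
latent distribution. The acceptance suite therefore evaluates the extreme
patterns under the clinical density, while the package default remains the
normative prior; both are one argument away (`prior =`).

MAP estimation maximises the log posterior by safeguarded one-dimensional
search on $[-8, 8]$ (the log posterior is unimodal for this model) with
tolerance $10^{-8}$; the posterior SD comes from the numeric curvature at
the mode. EAP uses a fixed grid of 161 points spanning the prior mean
$\pm 6$ SD. Missing items are dropped from the likelihood and
`n_items_used` flags partial patterns; the source analyses are silent on
partial patterns, so no imputation is attempted. Conditional reliability is
defined as $r(\theta) = I(\theta)/(I(\theta) + 1/\sigma_{\text{prior}}^2)$,
the proportion of posterior precision contributed by the test; this
definition reproduces the published 0.7-crossing range.

## Estimation: Bock–Aitkin EM

`fit_grm()` / `fit_multigroup_grm()` maximise the marginal likelihood by EM
over a fixed rectangular quadrature grid — 61 equally spaced nodes on
$[-6, 6]$ by default, with normal weights renormalised on the grid. A fixed
grid (rather than adaptive quadrature) keeps runs bit-reproducible and is
accurate to well below reporting precision for banks of this size; the node
count is configurable. Start values are unit slopes and intercepts from the
inverse-logit of the cumulative category proportions. The M-step takes a
few quasi-Newton steps per item (a generalized EM), and Ramsay-type step
acceleration is applied with a safeguard that reverts any accelerated jump
that would decrease the marginal likelihood — the recorded likelihood trace
is therefore monotone, as the tests assert. Convergence is declared when
the largest plain-EM parameter change falls below `tol` (default $10^{-4}$);
non-convergence is flagged on the result, not raised. Items with unobserved
categories are collapsed (with a warning) before fitting.

In multi-group fits the reference group's latent distribution is fixed at
$N(0,1)$ for identification; focal means/SDs are estimated by maximising
the expected complete-data log-likelihood of the grid weights. Constrained
items pool their expected count tables across groups.

Standard errors use the Oakes identity: the observed-information Hessian is
the complete-data expected Hessian (block-diagonal per item set) plus the
derivative of the EM Q-function gradient with respect to the parameters
entering the posterior, the latter obtained by central differences of
E-steps. This costs $O(p)$ E-steps instead of the $O(p^2)$ likelihood
evaluations of a full numerical Hessian; the numerical Hessian is retained
as `method = "numerical"` and the tests require the two to agree within 5%.

## Limited-information fit

`limited_info_fit()` builds the C2 family: the moment vector stacks the
univariate category margins (categories 2..K per item) and one cross-product
moment $E[X_iX_j]$ per item pair, the asymptotic moment covariance is
computed under the fitted model by quadrature (products of conditional
expectations, using local independence), and the statistic is the usual
quadratic form in the orthogonal complement of the model's moment Jacobian.
Degrees of freedom are #moments − #free item parameters; CFI_C2 uses an
independence baseline (zero slopes, intercepts at the observed margins),
RMSEA_C2 $= \sqrt{\max(C2 - df, 0)/(df \cdot n)}$. Residual correlations
are observed-minus-implied Pearson correlations of the integer item scores
(the source does not state the scale; Pearson-on-categories is the default
and a polychoric utility is exported for users who prefer that scale), and
the conventional local-dependence screen is $|r| > 0.1$. Incomplete rows
are dropped for the margin-based statistics. With two items the model is
saturated and the chi-square indices are flagged as undefined.

## Differential item functioning

`iterative_wald_dif()` follows the iterative Wald logic: iteration 1 tests
each item with all other items as anchors (parameters constrained across
groups, focal moments free); omnibus Wald statistics ($\chi^2$ with df =
slope + 4 intercepts = 5 for complete five-category items) are
FDR-corrected (Benjamini–Hochberg) and items with $p_{FDR} < 0.05$ are
flagged. Later iterations re-estimate with only unflagged items as anchors
and re-test; the flag set grows monotonically and the recorded statistics
for a flagged item come from the iteration at which it was flagged, so
`flagged` and the reported $p_{FDR}$ are always coherent. Follow-up
single-parameter Wald tests ($\chi^2_1$, FDR within item) identify which
parameters differ. Warm starts from the fully constrained fit keep the
per-item fits cheap.

Effect sizes: wABC integrates the absolute difference between the two
groups' expected item score curves against the focal group's *estimated
normal* density (mean $\pm 6$ SD, step 0.01) — a normal weight rather than
an empirical posterior histogram, the cleaner of the two conventions in
circulation and the package default. ESSD divides the signed
focal-weighted mean difference by the pooled model-implied item-score SD,
with the sign convention that positive means the focal (clinical) group
scores higher at equal trait level. ETSSD is the test-level analogue;
UETSDS, per its "in the sample" definition, averages the absolute expected
test-score difference over the focal sample's MAP trait estimates. The
practical-significance threshold wABC > 0.30 is exposed as an argument.

## Bifactor indices

PUC counts, by exact pair enumeration, the fraction of item pairs whose
correlation is informed only by the general factor. A pair is contaminated
if it shares *any* non-general factor — a subscale factor or the
reverse-coded method factor. This contamination rule (method factor
included) is a deliberate choice: it is the convention under which the
package's built-in TAS-20 membership structures yield the published PUC
values, and it is stored as data (`tas20_bifactor_structure()`), with the
reverse-coded set {4, 5, 10, 18, 19} taken from the standard TAS-20 key and
overridable. ECV is the general factor's share of common variance, with
item-wise and subscale-wise versions. Omega coefficients use the
categorical construction: expected covariances of the categorised items are
obtained from bivariate-normal probabilities over the model-implied latent
correlations (computed via Plackett's identity with 32-point Gauss–Legendre
quadrature), and each omega is a ratio of targeted true-score variance of
the sum score to total variance. Loadings and thresholds are *inputs* — no
weighted-least-squares factor estimator is shipped; structures come from an
external CFA or from the synthetic generator.

## Robust Bayesian validity statistics

Associations with external variables use heavy-tailed likelihoods so that
gross outliers carry little weight: a bivariate Student-t for Pearson
correlations, a latent-normal link for the ordinal margin of polyserial
correlations (thresholds fixed at the inverse-normal marginals), and
per-group Student-t likelihoods with separate scales for the two-group
comparison. Degrees of freedom are estimated with a shifted-exponential
prior (mean 30). Effect-size priors are weakly informative with scale 1 —
$\tanh(z), z \sim N(0, 1)$ for correlations and $d \sim N(0, 1)$ for the
standardized difference — and are configurable, since the source's exact
prior specifications live in an unavailable supplement. The two-group model
is parameterised directly in $d$, standardised by each group's
*normal-equivalent* scale $\sigma\,q_t(0.75,\nu)/q_z(0.75)$, so the effect
size refers to the bulk of the distribution and is insensitive to the tail
weight the likelihood estimates (without this correction, contamination
that drives $\nu$ down shrinks the t-scale parameters and inflates $d$).

Partial correlations residualise both variables on the control by least
squares and apply the robust correlation model to the residuals; a control
collinear with either variable is an error. Posterior sampling is an
adaptive random-walk Metropolis sampler (diagonal proposal, global scale
adapted toward ~30% acceptance during burn-in; defaults 4000 draws after
1500 burn-in), reproducible under `seed`. Summaries are the posterior
median and shortest 95% HDI. The ROPE Bayes factor is the prior-to-
posterior odds ratio of the effect lying in the region of practical
equivalence — defaults $r \in [-0.2, 0.2]$, $r_p \in [-0.1, 0.1]$,
$d \in [-0.2, 0.2]$ — with the conventional substantial-evidence thresholds
3 and 1/3 exposed in `classify_bf()`.

## Synthetic data: what it emulates, and what it does not

`simulate_responses()` reproduces the two-sample design the analyses
assume: a normative group with latent trait $N(0,1)$ ($n = 721$) and a
clinical group with $N(1.01, 1.17^2)$ ($n = 743$) — the published
score-level moments used directly as generator moments — responding to the
embedded bank, with optional DIF injected as uniform intercept shifts
and/or slope multipliers (ordering re-validated). Covariates are built as
trait + confounder + noise with coefficients solved for target zero-order
correlations and a specified confounder-mediated share; the default
trait–confounder correlation 0.475 mimics a neuroticism-like variable.
`simulate_bifactor_ordinal()` discretises a linear bifactor model at probit
thresholds.

The generator draws exactly normal traits, exactly GRM-conformant
responses, and missingness only by explicit `NA` injection. Real
questionnaire data depart from all three (trait non-normality, local
dependence, careless responding, structured missingness), so green
simulation-based tests certify the *machinery* — estimator consistency,
error-rate control, effect-size calibration — not the behaviour of the
GAFS-8 in any particular applied sample.

## Readability formulas

FORCAST, designed for non-prose material, is
$20 - (\text{monosyllables per 150 words})/10$; texts under 150 words are
scaled by their monosyllable rate and flagged. FKGL and FRE use the
standard coefficients with a documented heuristic syllable counter (vowel
groups, silent-e and silent-ed rules, small exception lexicon). Because
commercial readability software tokenises and syllabifies by proprietary
rules, grade levels for specific copyrighted item texts are not shipped or
asserted; the tests pin the formulas on hand-counted fixtures. The TAS-20
item wording itself is copyrighted and is not distributed — readability
functions operate on user-supplied text only.

## Problem sizes in the test suite

The simulation-backed tests run at deliberately chosen sizes: single-group
recovery at $n = 2000$; focal-moment recovery at $n = 1500$ per group; DIF
type-I and power at the design's $n = 700$ per group over 20 replicates
(with 21 quadrature nodes and tolerance $5\times10^{-4}$ for these
replicated fits — parameter movements at that tolerance are an order of
magnitude below the Wald statistics' resolution); Monte-Carlo oracles at
$2\times10^5$–$10^6$ draws. Seeds are fixed throughout.

## Known limitations

* Only unidimensional GRMs are estimated (no multidimensional, nominal, or
  generalized partial credit models), and the limited-information fit
  machinery covers single-group fits.
* The clinical latent density is reconstructed from published score-level
  moments via the shrinkage identity, not taken from the original model
  object; its SD is accurate only to the precision that reconstruction
  allows.
* Bifactor omegas require user-supplied loadings/thresholds; the package
  deliberately does not estimate confirmatory factor models.
* The Bayesian samplers are random-walk Metropolis: adequate for the 4–6
  parameter models shipped, but posterior tails for very small samples
  deserve longer chains (`n_samples`, `burn`).
* DIF testing supports exactly two groups per contrast; polytomous
  contrasts must be dichotomised.
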