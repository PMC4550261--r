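---
title: "Methods: models, calibration and design choices in pregsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and design choices in pregsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pregsignal)
```

`pregsignal` analyzes multimodal pregnancy signaling in wild Japanese
macaques: whether behavioral, vocal, facial-color and endocrine measures
shift between the pre-conceptive month (PCP) and the first two months of
pregnancy. This vignette documents the statistical models, the synthetic
study generator that stands in for undeposited field data, the numerical
choices, and the places where the design was genuinely open and the package
had to commit.

## Reproductive timelines from fecal hormones

The luteal onset is the first fecal sample whose PdG concentration satisfies

$$\mathrm{PdG}_i \ge \bar x_{B(i)} + k\, s_{B(i)}, \qquad k = 2,$$

where $B(i)$ is the window of the 3–4 samples immediately preceding sample
$i$, $\bar x$ its mean, and $s$ its sample standard deviation ($n-1$
denominator). Two commitments hide in that sentence:

* **Baseline width.** The rule is stated flexibly as "3–4 preceding values";
  the package uses 4 preceding samples when 4 exist and 3 otherwise
  (`baseline_n = "auto"`), maximizing baseline stability. Fixed widths of 3
  or 4 are available.
* **Flat baselines.** With a constant baseline ($s = 0$) the inequality is
  satisfied by *equality* at every sample, which would declare a rise in a
  flat series. A rise must therefore also strictly exceed the baseline mean.
  This changes nothing whenever $s > 0$.

Windows are built in **calendar days**, not sample indices: the 2-day
peri-ovulatory window is $\{r-3, r-2\}$ relative to the fecal rise date $r$
(the 2–3 day excretion lag between circulating progesterone and its fecal
metabolite is absorbed into these offsets), and the 5-day fertile window
$\{r-6, \dots, r-2\}$ adds three days for sperm survival. With sampling gaps
a window day may carry no sample; labeling is by date, so that is harmless.

Conception is dated to the **last fertile day** (the latest possible
fertilization). When a delivery date is known, an independent estimate is
`delivery − round(176.3)` days (the species' mean gestation; the fractional
constant is retained in reporting, the rounded value used where a calendar
date is required). The 2-SD rule is intrinsically false-positive-prone on
noisy baselines — roughly a few percent of baseline samples exceed their own
window's threshold by chance — which is exactly why the delivery
cross-check exists: among candidate rise onsets, the package keeps the one
whose fertile window ends nearest the back-dated estimate and records the
residual discrepancy in days. The source design does not state which of the
5 fertile days was used when the two sources conflicted; nearest-window is
this package's rule, and it is flagged in the output (`method`,
`discrepancy_days`, `n_candidates`).

Pregnancy months are 30-day blocks anchored at conception (month 1 = days
0–29, month 2 = days 30–59, PCP = days −30 to −1); the source analysis
speaks of "1st month"/"2nd month" without defining boundaries, and 30-day
blocks make the three periods commensurate. Days outside the three periods
are labeled `other` and excluded from the contrasts, which also disposes of
non-conceptive cycles: a detected rise not selected for the conceptive cycle
simply contributes no labeled days.

## Receptor-space color

A photo session consists of a face image and a 24-patch reflectance chart
imaged under the same exposure. Per session, an affine map from camera RGB
to modeled long-wave (LW) and medium-wave (MW) receptor captures is fitted
by ordinary least squares to the chart patches (`fit_calibration()`), whose
expected captures are `sensitivity × (illuminant × reflectance)`. Because
face and chart share the exposure, the map cancels it; the scale-consistency
invariant (multiplying all patch RGB by $c$ rescales the map by $1/c$ and
leaves mapped captures unchanged) is tested. At least 4 non-degenerate
patches are required; rank-deficient patch sets are refused.

The outcomes are the red–green opponency ratio $(LW-MW)/(LW+MW)$, bounded in
$(-1, 1)$, and luminance $(LW+MW)/2$. Two deliberate departures from the
source text:

* The source prints the luminance formula as "(MW+LW/2)"; the package
  implements $(MW+LW)/2$, the standard mean-capture luminance of the cited
  colorimetric methods — the printed form is read as a typographical slip.
* The source says all color outcomes were log-transformed. The opponency
  ratio can be zero or negative, so its log is ill-defined; the package
  log-transforms luminance only and models the ratio untransformed.

Macaque LW/MW spectral sensitivities and the camera characterization are
cited but not printed in the source; the package therefore takes them as
**user-supplied tables** (`receptor_model()`). The shipped
`synthetic_receptor_model()` is explicitly non-biological: its sensitivities
are linear combinations of the synthetic camera's bands, which makes
receptor captures an exact linear function of RGB, so calibration recovery
can be tested against a known truth. Pixel linearization (RAW development)
is assumed done upstream; region means are computed on linear RGB over a
user-supplied mask (`extract_region()`, `polygon_mask()`).

## Dominance

Dyadic win proportions $P_{ij} = s_{ij}/n_{ij}$ are chance-corrected,
$D_{ij} = P_{ij} - (P_{ij} - 0.5)/(n_{ij}+1)$, shrinking sparse dyads toward
0.5 (never-interacting dyads sit at 0.5 exactly). David's Score is
$DS = w + w_2 - l - l_2$ with $w_i = \sum_j D_{ij}$,
$w_{2,i} = \sum_j w_j D_{ij}$ and the losing analogues;
$NDS = (DS + N(N-1)/2)/N$. The source cites two NDS variants without
printing formulas; the chance-corrected variant is the default because it is
standard for sparse field matrices, and the raw-proportion variant sits
behind `method = "raw"`. Ordinal ranks break NDS ties by total wins, then by
id, so ranking is deterministic. Rank was unusable as a model covariate in
the source study (perfectly collinear with age in a 5-female group);
`rank_females()` computes it anyway and reports the rank–age Spearman
correlation as a collinearity diagnostic — Spearman, because rank is
ordinal.

## The statistical stage

All models are fitted by maximum likelihood with reproductive status
(3 levels, PCP baseline) and age as fixed effects, and crossed random
intercepts for female identity and observation date. Gaussian assumptions
for the random effects are the standard mixed-model convention; the source
names only its fitting packages.

* **Collinearity screen.** Pairwise phi coefficients on occurrence flags and
  Pearson correlations on counts; pairs exceeding 0.7 in absolute value
  collapse to one representative. The retained member is the one with the
  *smaller* total occurrence count, on the reasoning that the more inclusive
  composite (body contact, which subsumes grooming) duplicates its sparser
  component — reproducing the grooming-over-contact decision. Zero-variance
  behaviors are excluded and reported.
* **Hurdle models.** Occurrence is a binomial GLMM; positive counts are a
  zero-truncated negative binomial GLMM (glmmTMB's `truncated_nbinom2`).
  The total log-likelihood decomposes exactly as binary + truncated-count
  parts. Count parts are refused below 5 positive focals; occurrence without
  variation makes the binary part degenerate (flagged, not fit). With only 5
  females, random-effect variances are often estimated at the boundary; such
  fits are reported (`singular`, `converged`), never errored.
* **Likelihood-ratio tests.** $X^2 = 2(\ell_\text{full} - \ell_\text{null})$
  clipped at zero, df = parameter-count difference, upper-tail chi-square
  p-value; the null drops status but retains age, on identical rows. For
  hurdle models the default `part = "combined"` sums both parts'
  likelihoods, so a 3-level status factor contributes 4 df — matching the
  df accounting printed in the source, whose $\Delta df = 4$ for apparently
  2-df comparisons is best explained by summing hurdle parts. Per-part tests
  (2 df) are also available; the package always reports the true
  parameter-count difference of whatever is compared.
* **Re-leveling.** `relevel_contrasts()` refits with month 1 as baseline to
  expose the month2-vs-month1 contrast and verifies the log-likelihood is
  unchanged (re-leveling is a reparameterization; a moved likelihood means
  optimizer trouble and is warned about).
* **Zero-inflation check.** The binary model is refit with a constant
  structural-zero probability and compared by information criterion. BIC is
  the default: the inflation probability lies on the boundary of its space
  under the simpler model, where AIC's fixed 2-unit penalty over-selects the
  richer structure; in a pre-design simulation AIC falsely chose the
  zero-inflated variant in roughly one run in seven, BIC in roughly one in a
  hundred, with no loss of power at substantial inflation. AIC is reported
  alongside and available via `ic = "AIC"`. Note that a zero-inflated
  Bernoulli is only identifiable when a continuous covariate moves the
  conditional probability; with categorical predictors alone the two models
  coincide.
* **Multiple testing.** None applied, matching the source analysis; the
  pipeline log notes this.
* **p-values.** Wald z for GLMM parts; for Gaussian LMEs the t statistics
  get normal-approximation p-values (degrees of freedom in crossed designs
  are not well-defined), consistent with the z convention.

Numerically, glmmTMB fits use relative tolerance $10^{-8}$ and 500
iterations. The zero-truncated likelihood occasionally defeats the default
nlminb path on small positive-count subsets (a non-finite log-likelihood);
`fit_hurdle()` then falls back through the package-default control and an
`optim`/BFGS restart, and a part that still fails poisons the total
likelihood rather than being dropped — `lrt()` refuses to compare non-finite
fits.

## The synthetic study generator

The generator emulates the study design the analysis assumes, with defaults
fixed to the published design: 5 conceiving females (ages 8, 9, 10, 14, 17 —
mean 11.6, SD 3.8, range 8–17), a December 1 – March 15 study window,
conceptions drawn between December 31 and January 14 so that all three
30-day periods fit inside the window, 46/57/50 focals and 28/35/25 photos
allocated per female to match the published per-female means and ranges, and
fecal sampling every 3 days with 10 % weather dropouts.

**Behavior counts** follow the same two-part structure the models assume.
Occurrence is Bernoulli on the logit scale with crossed Gaussian female
(SD 0.4) and date (SD 0.3) intercepts; positive counts are zero-truncated
negative binomial (dispersion 1.5) with female/date effects of SD 0.2 on the
log-mean. Rates are calibrated **in expectation** to the published
per-period event totals: occurrence probability
$p = \min(0.25, \tfrac{2}{3}\,\text{events-per-focal})$ — capped at 0.25 so
every behavior keeps ≥75 % zero focals in expectation, and floored so the
zero-truncated positive mean stays above its bound of 1 — and the intercepts
are solved *numerically* so the marginal (random-effect-averaged) occurrence
probability and truncated count mean hit their targets despite the nonlinear
links (Gauss quadrature via `integrate()`, root-finding via `uniroot()`).
Calibration is in expectation, not exact totals: counts are stochastic, and
with dispersion 1.5 the per-study mount total has a standard deviation of
tens of events. Grooming totals are not tabulated in the source; the
defaults reproduce the qualitative decrease after conception. Contact is
generated as the sum of both grooming directions plus rare non-grooming
contacts, making the grooming–contact collinearity structural. Grooming and
contact carry Gamma bout durations (shape 2, scale 60 s) for completeness;
the models use counts and occurrence only.

**Hormones** are a step profile: Gaussian baseline PdG (mean 1.0 µg/g, SD
0.12) until the true rise (conception + 2 days, mirroring the excretion lag
the window offsets assume), then lognormal pregnancy levels of 3.0 µg/g
(month 1) dropping to 2.0 µg/g (month 2), with E1C at a constant 30 ng/g —
so pregnancy progestogens decline while the E1C/PdG ratio climbs, the
direction the endocrine models should recover. A configured rise below
baseline mean + 2 SD triggers a detectability warning.

**Color** draws per-photo true LW/MW lognormally around per-period means
chosen so luminance falls from PCP to month 1 and redness falls from month 1
to month 2, renders them to camera RGB through the synthetic camera, applies
a per-session exposure factor (log-SD 0.10) plus measurement noise, and
images the chart under the same exposure — so the calibration stage has
something real to undo.

**Hierarchy** is linear with the planted order equal to the age order
(reproducing the rank–age collinearity); the higher-ranking member of a
dyad wins with probability `plogis(steepness × rank distance / (N−1))`,
steepness 5 by default.

What the generator does **not** emulate: assay error structure (CVs,
sensitivity floors), within-cycle hormone cyclicity before conception and
non-conceptive cycles, acoustic structure of calls (counts only), pixel-level
face images (chart-level RGB suffices; the receptor model is synthetic), and
observer effects. Passing tests therefore show the pipeline recovers truth
*under the study's assumed statistical structure*, not that the structure is
true of real macaques.

All generators are deterministic given a seed; `simulate_study()` derives
per-stage child seeds from one master seed and emits the full ground truth
(conception dates, generating coefficients, color means, planted ranks)
alongside the data.

## Validation design and problem sizes

The test suite validates the machinery by simulation at sizes chosen to
balance statistical resolution against runtime: oracle equivalence of the
rise detector on 1,000 random series and of David's Scores against a naive
four-loop implementation; truncated-NB likelihoods against direct pmf
summation; recovery of a −1.5 logit status effect at 5 females × 150 focals
over 200 replicates; LRT type-I error under a true null in a 5-female ×
150-row Gaussian design, pooled over three 500-replicate blocks (a single
block's Monte-Carlo standard error, about 0.01, is of the same order as the
acceptance band's margin); generator fidelity over 100-replicate sweeps; and
conception-date recovery within ±2 days at 2-day gap-free cadence with exact
gestation back-dating, where the bound is attainable deterministically.
`scripts/acceptance.R` recomputes the generator fixture-fidelity quantities
(zero-focal percentages, expected mount totals) from scratch at 100 and 200
replicates.

## Known limitations

* With 5 females, crossed random-effect variances are weakly identified;
  singular fits are the norm, reported rather than suppressed, and fixed
  effects remain interpretable.
* The conception-date estimator inherits the 2-SD rule's false-positive
  behavior; without a delivery date, a noisy baseline can pull the estimate
  to an earlier spurious rise. The `n_candidates` column makes the
  ambiguity visible.
* The hurdle decomposition treats the occurrence and count processes as
  separate; behaviors whose intensity and occurrence share one latent driver
  are not distinguishable from that structure here.
* The synthetic receptor model is a testing device; scientific use of the
  color stage requires measured sensitivities and a characterized camera.
* Month boundaries at 30 days are a convention; conclusions sensitive to
  ±1-day boundary shifts should be checked against the labeling directly.
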