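---
title: "Models and methods behind edoutcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind edoutcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edoutcomes)
```

`edoutcomes` implements the statistical machinery used to evaluate symptom
change in adolescents treated for eating disorders at higher levels of care
(inpatient, residential, partial hospitalization, intensive outpatient):
psychometric scoring, Jacobson–Truax reliable and clinically significant
change, percent of expected body weight, and longitudinal mixed models for
continuous scores and episode counts. Because cohorts of this kind cannot be
shared, the package also ships a seeded synthetic-cohort generator with the
same longitudinal structure, so every stage of the pipeline is exercised and
tested end to end without any patient data.

## Instruments and scoring

Three self-report instruments are scored from item-level data:

* **EDE-Q global** — 0–6 scale; each attitudinal subscale (restraint, eating
  concern, shape concern, weight concern) is the mean of its items, and the
  global score is the unweighted mean of the four subscale means. A subscale
  is scored when at least half of its items are present (`min_present_prop`,
  default 0.5); if any subscale fails this rule the global is missing. The
  subscale map is *data*, supplied through `scale_spec()`, because published
  versions of the questionnaire differ in item layout.
* **PHQ-9** (depression) and **GAD-7** (anxiety) — items 0–3, summed to 0–27
  and 0–21. By default no missing items are tolerated
  (`proration_max_missing = 0`); when proration is enabled the score is
  `round(mean(present items) * k)`.

Internal consistency uses Cronbach's
$\alpha = \frac{k}{k-1}\left(1 - \sum_i \sigma^2_i / \sigma^2_{total}\right)$
with population (1/n) variances throughout and listwise deletion of
incomplete rows. The denominator convention cancels in the ratio; it is fixed
so that tests and oracles agree to machine precision.

## Reliable and clinically significant change

For a scale with admission standard deviation $s$ and reliability $\alpha$,
the standard error of measurement is $s\sqrt{1-\alpha}$, the standard error
of a difference $S_{diff} = \sqrt{2}\,s\sqrt{1-\alpha}$, and the
reliable-change threshold $RCI = z\,S_{diff}$ with $z = 1.96$. With the
default registry (EDE-Q: 1.59/0.96; PHQ-9: 7.08/0.89; GAD-7: 5.74/0.90) the
thresholds round to 0.88, 6.51 and 5.03 points. Each instrument's printed
reliability is a range across timepoints; the registry pins the
admission-timepoint value, which is the one the thresholds are built from,
and both are overridable.

Clinical significance uses criterion "c": the cutoff
$c = (s_{norm}\,m_{clin} + s_{clin}\,m_{norm}) / (s_{norm} + s_{clin})$,
the SD-weighted point between the clinical and normative population means.
The adolescent community norms behind the defaults (2.71 / 9.48 / 7.97) are
published constants rather than raw means/SDs, so the registry carries the
cutoffs directly; `criterion_c_cutoff()` derives a cutoff whenever norms are
available.

`classify_change()` applies the five-category taxonomy. All comparisons are
strict: a change of exactly the threshold, or a follow-up landing exactly on
the cutoff, does not count as reliable change or as crossing into the
normative range. Participants in the normative range at admission are
*normative* unless they worsen beyond the RCI into the clinical range, in
which case they are *deteriorated* — the published footnotes define the
categories only among those in the clinical range at admission, so this
extension is a package decision, made so that the five categories partition
every complete pair. Change tables count categories among participants with
both timepoints observed (the "reporting sample"), separately per interval
and admitting level-of-care group.

## Percent of expected body weight

Growth references are LMS tables (Box–Cox power $L$, median $M$, coefficient
of variation $S$); the value at normal deviate $z$ is $M(1+LSz)^{1/L}$, with
the $L \to 0$ limit $M e^{Sz}$ taken below $|L| \le 10^{-8}$ (the switch
matches the exact curve to within $10^{-9}$ relative at that scale). L, M and
S are interpolated linearly in age within each sex; ages outside the grid are
flagged and excluded rather than extrapolated.

Expected body weight defaults to *median BMI for sex and age times height
squared*, with median weight-for-age as the explicit fallback when height is
unavailable; the method is recorded in every result because the underlying
clinical guidance can be operationalized either way. Percent of expected body
weight is $100 \cdot observed / expected$.

The package ships a *synthetic* LMS reference — smooth parametric curves of
plausible magnitude covering 24–240 months — so that simulation and testing
need no external download. Real LMS CSVs load through the same
`read_growth_reference()` interface and column layout.

## Mixed models

**Linear.** `fit_lmm()` fits the random-intercept model
$y_{ij} = x_{ij}'\beta + b_i + \epsilon_{ij}$ by maximum likelihood (ML, not
REML, matching the full-information-ML language of the analysis plan and
keeping nested mean structures comparable). $\beta$ and $\sigma^2_e$ are
profiled in closed form — the per-participant compound-symmetric covariance
gives $V_i^{-1}$ and $\log|V_i|$ analytically — leaving a one-dimensional
optimization of the profiled deviance over $\lambda = \sigma^2_b/\sigma^2_e$
(Brent search on $\log\lambda \in [-14, 14]$, tolerance $10^{-9}$; the
boundary $\sigma^2_b = 0$ is always evaluated and flagged when optimal). All
rows with observed outcome and covariates are used (available-case ML),
which is unbiased when missingness depends only on observed quantities.
Wald z tests supply p-values; random slopes, Kenward–Roger degrees of
freedom and multiple imputation are out of scope. The fitter reproduces
lme4's ML fits to ~1e-6 relative on coefficients and log-likelihood in the
test suite.

**Counts.** `fit_nb_glmm()` fits a random-intercept negative-binomial model
(NB2: variance $\mu + \mu^2/\theta$, log link) for binge/vomit episode
frequencies. The marginal likelihood is approximated by the Laplace method:
a vectorized inner Newton iteration (with per-participant step halving)
finds each participant's conditional mode, and BFGS runs over
$(\beta, \log\sigma^2_b, \log\theta)$. Exponent clamping at 30 and a finite
fallback objective keep exploration stable. In tests the Laplace
log-likelihood sits within 0.5% of 31-node adaptive Gauss–Hermite
quadrature on small cohorts, and whole fits agree with glmmTMB.

A caveat the simulations make explicit: with mean counts near or below one
(episode frequencies late in treatment), the Laplace approximation carries a
small systematic bias in the *intercept* and variance components — glmmTMB
shows the same bias to four decimals, so it is a property of the
approximation, not of this implementation. Time slopes, the quantities of
scientific interest, are recovered without detectable bias.

**Effect sizes.** `partial_r2()` reports the semi-partial
$R^2 = qF/(qF + \nu)$ per fixed-effect term, with Wald $F$ and containment
denominator degrees of freedom: $n_{obs} - \mathrm{rank}(X) -
(n_{participants}-1)$ for terms that vary within participant,
$n_{participants} - \mathrm{rank}(X_{between})$ for between-participant
terms. Confidence intervals come from a seeded parametric bootstrap (default
200 refits) rather than an analytic beta approximation, because the exact
small-sample variant used in published tables is not identifiable from the
reports it backs.

**Multiplicity.** `bonferroni()` returns the per-test threshold
$\alpha/m$; the default family of 17 models gives 0.05/17, reported as 0.003
but compared at full precision.

**Contrasts.** Diagnosis enters predictor models with simple coding
(`simple_code()`): level $j$ versus the AN reference coded $(k-1)/k$ vs
$-1/k$, so coefficients are level-vs-reference mean differences while the
intercept is the unweighted grand mean of level means. Post-hoc site-region
models use plain dummies against a South reference plus a level-of-care
indicator (`region_dummies()`).

## The synthetic cohort

`cohort_config()` encodes the study conditions the generator emulates:
1,971 participants; diagnostic mixture AN-R .464, AN-BP .141, BN .057,
BED .019, OSFED/UFED .319; comorbidity .797; admitting level-of-care mixture
IP .153 / RES .435 / PHP .351 / IOP .061; age 14.84 (1.64), bounded 9–18;
total length of stay 79.97 (49.56) days with stepdown timing drawn from the
admitting level of care's stay distribution; admission score means/SDs of
3.62 (1.59), 14.87 (7.08), 12.93 (5.74); item reliabilities 0.96/0.89/0.90;
%EBW for AN admissions 87.46 (10.48) with a mean gain of 16.43 (10.87) by
discharge. Time slopes default to the published fixed-effect magnitudes
(−0.017, −0.057, −0.029 score units/day — the admission-to-discharge change
over a mean stay; binge/vomit log-slopes −0.04/−0.08 per day with intercepts
1.44/2.76, dispersion 1.5, intercept variance 0.5). These defaults are
calibration to published magnitudes, not ground truth about any population.
Values the source tables do not print were chosen once as plausible: a
region mixture of .35/.30/.20/.15 (South/West/Midwest/Northeast), non-AN
admission %EBW of 117 (25) — the value that reproduces the full-sample
admission mean given the AN share — with a gain of 7 (10), and an
within-person correlation (ICC) of 0.6 splitting each admission variance
into intercept and residual components.

Latent symptom trajectories follow the random-intercept model exactly and
are observed through calibrated items: each item is the per-item true score
plus Gaussian noise, rounded to the response grid and clipped to the range.
The noise SD is calibrated on a fixed internal error matrix (independent of
the user's seed) so the *discretized* items reach the target Cronbach's
alpha; the Spearman–Brown closed form provides the bracket and a two-stage
grid search the refinement. Discretization has a visible cost: observed
scores are attenuated at the range edges, so admission means/SDs sit a few
percent below the latent targets and scored slopes are slightly shrunk. The
cohort therefore carries both the observed score and the model-scale latent
column (`edeq_latent`, ...); parameter-recovery tests target the latent
scale, while classification and descriptive stages consume the realistic
discrete scores.

`impose_missingness()` drives stepdown/discharge missingness with a logistic
model on observed admission covariates (admission %EBW, gender, diagnosis,
comorbidity, discharge reason — signs follow the reported
more-likely-complete associations), and calibrates the logit intercept by
bisection so the marginal rates hit 23.3% and 55.6%. Admission data are
never missing, making the mechanism missing-at-random with respect to
modelled covariates — the property available-case ML relies on, and the one
the end-to-end recovery tests verify.

What the generator does *not* emulate: site/center clustering beyond a
region label, COVID-era effects, causal structure in discharge reasons,
within-stay transitions between levels of care, or growth in height over the
stay (height is fixed at its admission draw). Passing tests on this cohort
demonstrate the pipeline's statistical correctness under its stated
assumptions, not the clinical validity of any particular dataset.

## Numerical choices and problem sizes

* LMM: profiled-deviance optimization tolerance $10^{-9}$ on $\log\lambda$;
  boundary fits flagged. Degenerate designs (rank deficiency after dropping
  incomplete rows, fewer than 2 participants) are errors, not warnings.
* NB-GLMM: inner Newton gradient tolerance $10^{-9}$, 50 iterations with
  per-participant step halving; outer BFGS with relative tolerance
  $10^{-12}$; all-zero outcomes are an error.
* Item-noise calibration: 41-point log-spaced grid then 21-point local
  refinement, on a fixed internal error matrix.
* Ties: all reliable-change comparisons are strict, as the category
  definitions require ("greater than", "above ... to below").
* Test suite problem sizes, chosen to make Monte-Carlo bands meaningful while
  keeping a default run fast: oracle-equivalence on 20 randomized small
  datasets; parameter recovery at 100 replicates of 500 participants x 3
  timepoints per model family; calibration checks on one shared cohort of
  2,000.

## Known limitations

* The Laplace intercept bias at low counts, described above.
* Criterion-c cutoffs are configured constants unless population norms are
  supplied; different norm sets move the normative/clinical boundary.
* `%EBW` depends on the growth reference supplied; the bundled reference is
  synthetic and for testing/simulation only.
* Random intercepts only; no random slopes or serial correlation within
  participant.
* The generator's stepdown timing and non-AN weight parameters are plausible
  defaults, not published values; analyses sensitive to them should supply
  their own configuration.
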