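---
title: "Thermal-performance inference for jar-replicated rearing experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal-performance inference for jar-replicated rearing experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`thermopt` implements the statistical core of a multi-experiment study of
temperature effects on marine invertebrate early life stages — embryos and
larvae reared in replicate jars across a temperature series, juveniles grown
in factorial temperature designs, and juveniles assayed behaviourally under a
simulated marine heatwave. This vignette explains each model, the choices the
package makes where the analysis was genuinely open, and what the synthetic
generators do and do not emulate.

```{r setup}
library(thermopt)
```

## Composite development scores

Morphometric characters measured on the same larva (body length, stomach
length, arm length, ...) are strongly correlated: they all track one
underlying developmental progression. `fit_pc1()` summarises a character set
by the first principal component and `score_composite()` projects larvae onto
it, giving one development score per larva.

Two choices here are the package's own:

* **Correlation-matrix PCA.** Characters mix micrometre lengths with ordinal
  stage scores, so each character is standardised (centered, unit variance)
  before the eigendecomposition. Loadings are then invariant to measurement
  units, which a covariance PCA would not be.
* **Sign orientation.** A principal component is defined up to sign. The
  component is flipped, if necessary, so that the loadings of size-type
  characters sum to a non-negative value: a higher score always reads
  "larger / more developed".

Missingness is handled by complete-case analysis within the character set by
default (scorers who cannot see a feature leave it blank, and those blanks
must not become zeros); an explicit mean-imputation mode
(`complete_case = FALSE`) keeps partially measured larvae at the cost of
shrinking their scores toward the centre. The PCA is fit per stage, pooling
all temperatures, since a single composite axis is needed across the whole
temperature series.

## Quadratic thermal-performance curves and the clamped optimum

The composite score is modelled against temperature as a quadratic,
$y = a t^2 + b t + c$, by ordinary least squares on individual larvae (not
jar means — the replicate structure is handled by the bootstrap, below). The
thermal optimum is

$$
t_{\mathrm{opt}} =
\begin{cases}
-b / 2a & a < 0 \text{ and } -b/2a \in [t_{\min}, t_{\max}] \\
\arg\max_{t \in \{t_{\min}, t_{\max}\}} \hat y(t) & \text{otherwise,}
\end{cases}
$$

i.e. the vertex when the fit is concave with an interior peak, and the better
tested extreme otherwise. Clamping to the tested range matters twice over:
scientifically, the data cannot support an optimum outside the conditions
tested (monotone responses legitimately estimate a boundary optimum); and
computationally, bootstrap resamples are occasionally convex or monotone, and
the peak statistic must stay defined on every resample rather than fail or
wander to infinity. A fit with $a = b = 0$ is flagged as flat with a warning.
The estimator is exercised against a dense-grid argmax (0.001 °C) in the test
suite, including boundary and convex cases.

## Two-stage cluster bootstrap

Larvae within a jar share a rearing environment, so they are not independent;
confidence intervals that ignore this are too narrow. `bootstrap_peak_ci()`
resamples in two stages: jars with replacement first, then larvae with
replacement within each drawn jar (every drawn copy of a jar gets an
independent larva redraw, and keeps the jar's original size). The quadratic
peak is recomputed on each of `n_boot` resamples (default 1000) and the
interval is the empirical 2.5% and 97.5% quantiles (linear-interpolation
quantiles, the common empirical default).

Design choices:

* **Stage-1 stratification.** Jars are resampled within temperature by
  default. With three jars per temperature, pooled jar resampling frequently
  yields resamples spanning fewer than three temperatures, where a quadratic
  is unidentifiable; stratification preserves the design's temperature
  coverage. A pooled-urn mode (`stratify = FALSE`) is provided, with
  degenerate resamples redrawn (up to 100 attempts) so `n_boot` stays exact.
* **Percentile interval.** Plain percentile rather than BCa or studentised —
  it is the transparent default, and the clamping makes the statistic's
  distribution mixed (point masses at the range ends) where studentisation is
  ill-behaved.

The package's simulation study (`analysis/06_coverage_study.R`, also the
acceptance script) checks the interval at the study's own scale — 5
temperatures × 3 jars × 10 larvae, a unit-curvature concave quadratic with an
interior peak at 15 °C, jar SD 0.2 and residual SD 0.5 score units, 200
simulated datasets with 500 resamples each. Percentile intervals with three
clusters per stratum are expected to run slightly below nominal; that is the
method's honest behaviour, not a tuning target.

### Jar influence screening

One replicate jar behaving abnormally (a "jar effect") can drag the optimum.
`jar_effect_screen()` reports, per jar, a leave-one-jar-out shift in
$t_{\mathrm{opt}}$ and a standardised jar-mean residual, and flags jars
beyond 3 SD. The standardisation is leave-one-out: each jar mean is compared
with the mean of the *other* jars at its temperature, scaled by the pooled SD
of the other jars' deviations. Including the candidate jar in its own scale
would cap the statistic near $(J-1)/\sqrt{J} \approx 1.15$ at $J = 3$ jars,
making a 3 SD screen vacuous exactly where it is needed. Flagged jars are
never dropped automatically; exclusion is an analyst decision recorded in the
run configuration.

## Proportion models: settlement and cloning

Settlement and cloning are binomial outcomes on groups of larvae sharing a
replicate exposure. `fit_binomial_mixed()` fits a logistic mixed model with a
random intercept per replicate (maximum likelihood, Laplace approximation —
deterministic and adequate at these cluster sizes), reporting Wald z tests
per coefficient, a likelihood-ratio omnibus test, and Bonferroni-adjusted
pairwise contrasts. Two caveats are built in: non-convergent fits fall back
to ordinary logistic regression (random SD pinned at zero) with a warning,
and the contrasts carry a between-replicate degrees-of-freedom column
because Wald z intervals undercover when replicates are few — t intervals on
that df are the recommended small-sample route.

The temperature-shift settlement factorial is instead analysed as a two-way
ANOVA with interaction on replicate-level proportions
(`factorial_proportion_anova()`), the route matching that design's F
statistics; the mixed-model route remains available. The cloning trend
(`cloning_trend()`) is ordinary least squares of the per-jar clone proportion
on temperature, with $F = \frac{R^2}{1-R^2}(n-2)$ on $(1, n-2)$ df; the three
clone classes (mostly-complete regenerating, half-size, tiny) are combined
into one "clone" count over the jar's total classified larvae.

## Juvenile growth and fates

Growth is either absolute, $(D_T - D_0)/T$ in µm/day, or relative,
$(D_T - D_0)/D_0$, with $T$ the day of the juvenile's last measurement —
truncated records (juveniles lost mid-experiment) contribute growth up to
that day, while bona fide mortality records are excluded (their pre-death
shrinkage is not growth). `factorial_growth_anova()` fits the 2×2
larval-by-juvenile temperature ANOVA with interaction and Tukey HSD on cell
means.

Fate categories (disappeared without remains; stranded above the waterline;
died in place) are tested per design factor with one-way linear-model F tests
on the binary indicator, matching the F-statistic style of the factorial
experiments, with a Fisher exact test reported alongside since normal-theory
F on a handful of events is fragile. The F statistic is computed from
explicit group sums rather than a QR-based ANOVA so that a fate spread
exactly evenly across treatments yields $F = 0$ and $p = 1$ exactly, not
$10^{-30}$.

## Righting performance under a simulated heatwave

Each star is flipped continuously for 10 minutes at ambient temperature
(phase T0) and again a week later at its treatment's test temperature (phase
T1). `fit_did()` fits the difference-in-differences mixed model

$$
y_{ijk} = \mu + \alpha_j + \beta_k + (\alpha\beta)_{jk} + u_i +
\varepsilon_{ijk},
$$

righting time in seconds on treatment, phase, their interaction, and a
random intercept per star (REML). The interaction coefficients are the DiD
estimates: each warmed treatment's T0→T1 change minus the control's.
Choices:

* **Raw seconds by default.** No transform is applied to the response; a
  log-scale option exists because righting times are right-skewed, but the
  raw scale is the default for fidelity to the original analysis style.
* **Percent change from model-adjusted means.** Per-treatment percent change
  of T1 versus T0 is computed from the model's adjusted phase means (equal to
  raw cell means under balance), not from raw means, so imbalance in flips
  per star does not leak into the headline percentages.
* **First-minute sensitivity.** Early flips are over-represented among
  outliers (stars acclimating to the chamber); `exclude_first_minute = TRUE`
  refits without flips starting before 60 s. The headline fit retains them.

`ambient_summary()` gives the baseline mean with a per-flip t interval plus a
clustered (per-star means) alternative, since flips within a star are
dependent and the per-flip interval is anti-conservative.
`fatigue_trend()` tests for drift over the 10-minute clock: an overall
mixed-model slope with a Satterthwaite t test, per-run OLS slopes, and a
one-sided Wilcoxon diagnostic comparing minute-1 flips against minutes 2–10
in each run. `growth_compare()` handles the week's growth: paired t within
treatment on diameters, Welch t between treatments on per-star fractional
growth, Holm-adjusted.

## Synthetic data: what the generators emulate

Every design has a generator returning records plus a truth object
(`gen_morphometrics()`, `gen_cloning()`, `gen_settlement()`, `gen_growth()`,
`gen_flips()`), so each analysis can be tested for parameter recovery and
calibration without any external data. Defaults mirror the study designs:
five-temperature series with 3 jars per temperature and 10 measured larvae
per jar; ~80 classified larvae per cloning jar with clone odds elevated 1.5×
at the warmest temperature; 2×2 settlement cells of 6 wells × 5 larvae; 2×2
growth cells of 12 juveniles over 41 days; and 7/6/8 stars per heatwave
treatment flipping ~14 times per phase around a 34.5 s ambient mean, with T1
multipliers defaulting to the observed pattern (none, −18.8%, −10.3%).

Structural features, chosen once: characters correlate through a shared
latent development factor per larva, so PC1 is meaningful by construction;
jar effects are a single Gaussian draw per jar entering each character
through its loading; righting residuals are multiplicative lognormal (times
are positive and right-skewed, with an optional minute-1 inflation for
acclimation outliers) and clock times accumulate from the previous flips
plus a 3 s handling pause.

What the generators do *not* emulate — and therefore what passing tests do
not establish about real data: measurement error structure from manual
morphometry, non-quadratic (asymmetric) thermal responses, overdispersion
beyond the replicate intercept in settlement counts, mechanistic links
between cloning and temperature, fate processes correlated with growth, or
heteroskedastic righting variance across phases. Tests demonstrate that the
estimators recover the truth when the model family is correct, and keep
their error rates under the null; they cannot validate the model family
itself against the original observations.

## Numerical notes

* Quadratic OLS solves the 3×3 normal equations from raw sums — shared by
  the full-data fit and the bootstrap loop so both use the identical
  estimator; well-conditioned at experimental temperature magnitudes.
* Quantiles are linear-interpolation empirical quantiles; ties and
  zero-width intervals (all resamples identical) pass through exactly.
* CSV writers emit shortest round-trip-exact decimal strings, so
  `read_table(write_table(x))` reproduces doubles bit-for-bit and blanks
  (never zeros) encode missingness.
* Test-suite problem sizes: coverage at 200 datasets × 500 resamples;
  parameter recovery at 100 simulations per model; null calibration at 500
  simulations of four omnibus tests; the peak-vs-grid property at 1000
  random fits.

## Limitations

Only the quadratic TPC family is implemented (no Gaussian or
Sharpe–Schoolfield alternatives, no model selection); intervals are
percentile-only; settlement overdispersion beyond a replicate intercept is
not modelled (no beta-binomial); and survival is treated as fate-category
tests, not time-to-event analysis.
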