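---
title: "Brain structural vulnerability indices: models, assumptions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain structural vulnerability indices: models, assumptions, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainvuln)
```

## The problem

Consortium meta-analyses of psychiatric disorders publish *patterns* of
regional structural brain deficits — per-region standardized case-control
effect sizes for cortical gray-matter thickness, white-matter tract
fractional anisotropy (FA), and subcortical gray-matter volumes. Those
patterns are group-level findings. This package implements two
individual-level translations of such findings and the analyses used to
evaluate them:

* **The meta-analytic dot-product index** (here the `edp` column): for a
  subject with covariate-adjusted, rank-normalized regional deviations
  $P_1, \dots, P_N$ and a published signed effect vector $E_1, \dots, E_N$
  (deficits negative),
  $$\mathrm{DP} = \frac{1}{N} \sum_{i=1}^{N} P_i E_i .$$
  A high value means the subject's anatomy deviates from the reference
  population *in the direction of* the disorder's deficit pattern — both the
  size of the deviation and its alignment matter.

* **The quantile regression index (QRI)**: a linear analog of "brain age".
  For each region, linear quantile regressions of the measure on age are
  fitted at the 5th, 50th and 95th percentiles over the whole sample. A
  subject scores $+1$ in a region whose value falls strictly below the
  fitted 5th-percentile line at their age (older-looking than expected),
  $-1$ strictly above the 95th-percentile line (younger-looking), else $0$.
  Regional scores are averaged within tissue class, and the whole-brain QRI
  is the unweighted mean of the three tissue indices, so all indices lie in
  $[-1, 1]$.

Both are compared against the conventional whole-brain means of the
Z-deviations per tissue class (`mean_thickness_z`, `mean_subcort_z`,
`mean_fa_z`).

## Harmonization: from raw regional measures to P vectors

`harmonize()` is the composition of two steps, each exposed on its own:

1. **Residualization** (`residualize()`): per phenotype, ordinary least
   squares on an intercept plus age, sex and intracranial volume (ICV),
   fitted over the reference sample and applied to everyone. ICV is
   regressed from *all* phenotype classes by default; `icv_volumes_only =
   TRUE` restricts it to subcortical volumes, the common convention when one
   prefers not to adjust thickness or FA for head size. Missing values are
   never imputed — they stay missing through every stage.

2. **Rank-based inverse-normal transform**
   (`inverse_normal_transform()`): the residual with (average-tie) rank $r$
   among $n$ becomes $\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$. The Blom
   constant $3/8$ is the standard choice in the heritability and
   vulnerability-index literature; it is a tunable `blom_offset` because
   nothing downstream depends on the exact constant. An all-constant column
   is mapped to zeros with a warning rather than an error.

The **reference sample** is the whole cohort by default. The alternative,
`reference = "controls"`, estimates the regression on controls only and
anchors the normal scores in the control distribution (controls get Blom
scores from control-only ranks; other subjects are mapped through the
control empirical distribution by linear interpolation, clamped at the
control extremes). We default to the whole sample because that is how the
published vulnerability-index tooling behaves; the flag exists because the
prose definition — "deviation of the individual from the mean of the group"
— is genuinely ambiguous about which group anchors the deviation. Signed
deviations are used throughout; the magnitude-only reading of "deviation" is
interpretive, and an absolute-value variant would change the index
qualitatively (it would no longer distinguish deficit-aligned from
anti-aligned deviations).

With no planted signal the Z columns are approximately standard normal; the
test suite checks a Kolmogorov–Smirnov calibration across 100 seeded
replicates at $n = 1000$ and that planted age slopes are removed at
$n = 5000$.

## The dot-product index

`compute_edp()` normalizes by the *per-subject* count of non-missing
phenotypes shared with the effect vector, not the global $N$, so the scale
of the index is comparable across subjects with missing regions. The index
is linear in the effect vector and invariant to matched column
permutations; both are tested to machine precision, and a naive per-subject
loop oracle pins the vectorized implementation at $10^{-12}$.

Published consortium effect sizes are not bundled (they are not printed in
the source literature); a template file
(`inst/extdata/effect_vector_template.tsv`) carries the phenotype names with
zero placeholders, and the synthetic pipeline uses its own planted vector
(`effect_vector_synthetic.tsv`, labelled synthetic).

## The quantile regression index

Quantile lines are fitted with `quantreg::rq.fit.br`, the exact simplex
(Barrodale–Roberts) solver; the minimizing line interpolates two data
points, and the test suite verifies the fitted line against exhaustive
enumeration of all two-point candidate lines on small datasets, to
$10^{-8}$ in check loss and coefficients. For continuous data the optimal
vertex is almost surely unique; in the measure-zero event of ties the solver
returns one optimal vertex (we do not impose a lexicographic tie-break — a
degenerate case a practitioner will not encounter with continuous
phenotypes). A constant response is short-circuited to the exact
zero-loss solution (intercept = the constant, slope 0).

Scoring uses strict inequalities, so a value exactly on a percentile line
scores 0. Quantile *crossing* (fitted 5th line above the 95th at some age)
is possible because the three fits are independent; the package scores such
points by the same rules and logs every crossing with phenotype, subject and
age rather than imposing a non-crossing constraint the procedure does not
define. Fits use age as the only predictor by default, on the whole sample;
`by_sex = TRUE` fits within sex strata, a mode we expose because the
original procedure is silent on sex adjustment.

Under a null simulation (linear age trend + Gaussian noise, no pathology),
in-sample calibration puts $\approx 5\%$ of regional scores in each tail;
the acceptance checks verify $5\% \pm 1$ point at 2000 subjects × 200
regions and a mean whole-brain QRI within $\pm 0.01$ of zero.

## Group-severity and cognition analyses

All biomarkers are residualized on age and sex over the cohort and z-scaled
before group averaging (`group_profile()`). The correlation between the four
group means and the four group mean severities (`groupmean_correlation()`)
has two degrees of freedom; it is reported descriptively with the df
annotated and deliberately carries no p-value. Individual-level symptom
associations (`symptom_association()`) pool the three depression groups by
default (controls excluded, matching the published analysis) and report the
exact $t = r\sqrt{n-2}/\sqrt{1-r^2}$ and its two-sided p.

The cognition analyses build per-test t-score profiles:

* `cognitive_deficit_profile()` — pooled-variance two-sample t per test,
  cases (three depression groups pooled) vs controls;
* `biomarker_cognition_profile()` — per test, the slope t of the simple
  regression of the age/sex-corrected score on the age/sex-corrected
  biomarker, within controls or within the pooled case groups.

Both default to a *deficit-positive* sign convention (worse performance in
cases, or association of a higher biomarker with worse performance, is
positive), so the two kinds of profile are directly comparable;
`compare_profiles()` then reports the Pearson correlation of the two
9-vectors of t (with its df = 7 caveat attached) and a paired t-test across
tests on $|t|$. We compare magnitudes because the published "average
t-score" values are positive summaries of explained variance; a `compare_on
= "signed"` flag keeps the signed alternative available.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` generates, per subject $s$ and phenotype $i$:
$$y_{si} = b_i + \beta^{age}_i \mathrm{age}_s + \beta^{sex}_i \mathrm{sex}_s
          + \beta^{icv}_i \mathrm{ICV}_s + v_s E_i + \varepsilon_{si},
  \qquad \varepsilon_{si} \sim N(0, \sigma^2),$$
with latent vulnerability $v_s = \text{deficit\_scale} \times
\text{severity}_s$, severity drawn as the group mean plus Gaussian jitter
clamped to $[0, 4]$, and cognitive score $t$ generated as
$-c_t v_s + N(0, \sigma_t^2)$. Cognitive coupling acts through the
*realized* vulnerability scalar, not the group label, so controls also carry
a cognition–anatomy association — the property the control analyses probe.
Severity is continuous so individual-level symptom correlations have
something to estimate. Sex is a 0/1 offset and ICV is log-normal, giving
residualization real work to do.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| `n_per_group` | 2000 | desk-scale cohort; large enough for stable profiles |
| `age_range` | 45–80 y | population-imaging age window |
| `severity_means` | 0.5, 1.5, 2.2, 3.0 | ordered groups on the 0–4 scale |
| `severity_sd` | 0.5 | within-group spread; controls retain variance |
| `deficit_scale` | 1.0 | severity-to-anatomy gain (see power note) |
| `noise_sd` | 1.0 | phenotype unit scale |
| effect vector | FA all negative; thickness mixed-sign, near-zero mean; subcortical small | mirrors the qualitative published structure: FA tracks severity, whole-brain mean thickness is uninformative even though individual regions carry signal |
| cognitive coupling | 0.6 on 3 of 9 tests | three affected domains, the rest null |

**Power note.** Planted effects are deliberately larger than real
epidemiological effect sizes (which are estimated on tens of thousands of
subjects). The defaults were chosen a priori by a standard power argument:
with 2000 controls, the correlation between the dot-product index and latent
vulnerability is $\approx 0.5$–0.6 under these settings, cognitive coupling
of 0.6 gives affected-test slope t's of roughly 5–9 against a null of
$|t| \lesssim 2$, which is what a 9-point pattern correlation needs to be
stable. The mixed-sign thickness vector is what makes the dot-product index
structurally better than the whole-brain thickness mean — the contrast the
analyses are designed to exhibit — rather than a tuning artifact.

What the generator does **not** emulate: real questionnaire-based
classification, site/scanner effects, non-linear aging, heteroscedastic
age-variance growth, missing-not-at-random dropout, correlated regional
noise (regions are conditionally independent given the latent scalar), or
the actual published effect-size values. Passing recovery tests therefore
shows the *pipeline* is correct and powered under its stated generative
model, not that the indices perform equivalently on real cohort data.

## Numerical and reproducibility choices

* All randomness flows from the single config seed; `simulate_cohort()`
  saves and restores the caller's RNG state, and identical configs yield
  bit-identical cohorts.
* On-disk tables are written with `%.17g` formatting and read back with the
  base-R parser, which round-trips doubles bit-identically; this is what
  makes staged pipeline re-runs (`stages =` subsets of the pipeline) exactly
  equal to a single full run, and two full runs byte-identical.
* Degenerate inputs fail loudly with typed conditions: constant covariates
  (`brainvuln_design_error`), misaligned subject ids
  (`brainvuln_alignment_error`), too-few observations
  (`brainvuln_data_error`), invalid configuration
  (`brainvuln_config_error`). Constant biomarkers or test columns degrade to
  warnings with well-defined outputs (zeros / `NA` t) where an analysis can
  meaningfully continue.
* Validation problem sizes: the recovery checks use 20 seeded replicates of
  the default 4 × 2000 cohort; oracle checks use 100 random 10 × 8
  instances (dot product) and 20 random 12-point datasets (quantile
  vertices); calibration checks use 2000 subjects × 200 regions (QRI null)
  and 100 replicates of $n = 1000$ (normal-score calibration).

## Known limitations

* The 64-phenotype set excludes lateral-ventricle volume by default (it is
  not part of the three-tissue index set and is the one "larger-is-older"
  structure); supply a custom `phenotype_spec` to include it, with the
  caveat that QRI's direction convention assumes lower = older.
* The group-mean severity correlation is a 4-point summary; treat its
  `r_squared` as descriptive.
* Quantile fits are linear in age. Curvilinear aging would leak into the
  tails near the age extremes; the published procedure is linear, and we
  keep it that way.
* `compare_profiles()` inherits the usual caveats of correlating 9 paired
  t-statistics; the df = 7 annotation travels with the result.

## A minimal run

```{r example, eval = FALSE}
library(brainvuln)

cfg <- pipeline_config(cohort = cohort_config(n_per_group = 500, seed = 1))
report <- run_pipeline(cfg, outdir = "brainvuln_out")
report$groupmean_correlations
report$profile_comparisons
```
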