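---
title: "Polyconnectomic scoring and its validation on synthetic twin cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polyconnectomic scoring and its validation on synthetic twin cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcscore)
```

## The model

Polyconnectomic scoring condenses an individual resting-state connectome into
one number: its alignment with a disorder-specific connectivity pattern. The
pattern is a connectome-summary-statistic (CSS) template — a meta-analytic
Cohen's *d* per connection, positive where patients show stronger
connectivity than controls, negative where weaker. For a subject with
functional connectivity $C_i$ (raw Pearson correlation of parcel-mean BOLD
signals; no Fisher-Z transform, no covariate regression) at connection $i$,

$$\mathrm{PCS} \;=\; \frac{1}{n}\sum_{i\,:\,\beta_i \neq 0} \beta_i\, C_i ,$$

with $\beta_i$ the template weight and $n$ the count of non-zero-weight
connections. Only informative connections enter the average and no additional
scaling is applied, so the score is in units of $d \times r$ and is comparable
across subjects scored against the same template. It is a relative index of
pattern alignment, not a diagnostic quantity.

Edge bookkeeping is fixed once, package-wide: edges are the strict upper
triangle of the symmetric connectivity matrix, enumerated row-major
((1,2), (1,3), …, (P−1,P)). The on-disk template format carries explicit
parcel labels (edge TSV or square CSV plus a JSON sidecar with the atlas and
network partition), so file-based scoring never depends on implicit order.

Template introspection works on the template alone — never on subject data:
`top_edges()` ranks signed contributors; `network_aggregate()` collapses
weights onto a parcel→network partition into within/between-network blocks.
Because it is not stated whether published network-level summaries are means
or sums of *d*, both statistics are available; the default is the mean
(comparable across blocks of unequal size), while the sum is what satisfies
the conservation property used in testing.

## Inference layer

Cohorts of relatives violate independence, so every association is fit, by
default, as a linear mixed model with a per-family random intercept (lme4).
Conventions, chosen where the surrounding literature leaves latitude:

* **Standardized coefficients.** Continuous outcome, predictor, moderator and
  covariates are z-scored (n−1 denominator) inside the fitting functions;
  binary covariates keep their 0/1 coding. Reported betas are therefore
  dimensionless.
* **Inference.** Wald z intervals and p-values for mixed models;
  t-based for the OLS engine (used for the independent clinical-style arm).
  Satterthwaite/Kenward-Roger refinements are deliberately out of scope.
* **Moderation.** `fit_moderation()` fits `Y ~ X + W + X:W + covariates`
  (plus the random intercept), and reports the interaction coefficient,
  conditional slopes of X at W = mean ± 1 SD (delta-method CIs from the
  fitted covariance), and ΔR².
* **ΔR² definition.** For a mixed model there is no single R²; we use the
  squared correlation between fixed-effect-only predictions and the observed
  outcome, differenced between the models with and without the interaction,
  clipped at zero. This marginal-style definition matches the
  moderation-literature convention, is engine-agnostic (it reduces to the
  ordinary R² difference under OLS — a property the tests exploit), and is
  invariant to affine rescaling of X and W. It is documented as this
  package's convention, not claimed to match any published value.
* **Change scores.** Follow-up minus baseline per repeated measure, with
  follow-up duration (age difference, years) as a covariate; subjects lacking
  follow-up are excluded and counted. Non-positive durations are
  data-integrity errors, not warnings.
* **Multiplicity.** Bonferroni within analysis blocks: family size = number
  of outcomes tested in the block (2 for the emotional pair, 6 for the
  cognitive subscales).
* **Missing data.** Complete cases per model.
* **Grouping.** `tertile_split()` orders by score and cuts into three groups
  whose sizes differ by at most one, extras to the lower groups, ties by
  stable input order. `ancova_group_compare()` tests the group factor by an
  F-comparison of covariate-only vs full linear models and reports adjusted
  group means at covariate sample means.

Degenerate inputs: zero-variance parcels make correlations undefined; strict
mode (default) raises an error naming the parcels, lenient mode zeroes their
correlations with a warning. Whether published pipelines average over
template edges where a subject's connectivity is undefined is unstated;
strict mode here refuses such subjects.

## What the synthetic generator states — and what it does not

Real cohorts of this design are restricted-access, so validation runs on a
generator whose ground truth is known. One latent vulnerability $v$ per
subject (standard normal) enters twice:

1. **Connectomes.** Subject covariance $\Sigma(v) = \Sigma_0 + \alpha v
   \tilde W$, where $\Sigma_0$ is a fixed well-conditioned two-factor
   correlation matrix, $\tilde W$ the symmetrized template scaled to unit
   spectral norm, and $\alpha$ the coupling. BOLD series are i.i.d. Gaussian
   draws from $\Sigma(v)$, so the subject's PCS increases in $v$ by
   construction. If $\Sigma(v)$ loses positive semidefiniteness it is
   ridge-repaired (add $(|\lambda_{\min}| + 10^{-6})I$, renormalize the
   diagonal) with the relative Frobenius distortion logged; repairs beyond a
   configurable bound abort with advice to lower $\alpha$.
2. **Outcomes.** Symptom change
   $\Delta Y = b_0 + b_1 \Delta X + b_2 v + b_3 \Delta X \cdot v + u_{fam} +
   \varepsilon$ with $\Delta X$ the stress change, $u_{fam}$ a family
   intercept; baseline symptoms analogous without the interaction; six
   cognitive subscales with near-zero stress coupling and no interaction,
   mirroring null cognitive findings.

Defaults were frozen once, before any acceptance measurement, and chosen for
test power rather than physiological realism (no effect-size anchor links PCS
variance to symptom variance in the motivating literature): 407 subjects in
two-twin families with deterministic 298/407 follow-up retention; a
20-parcel atlas (desk-fast; 400 is configurable) with 300 timepoints;
template density 0.3 at weight scale 0.3 *d*, with all within-somatomotor
edges negative and all somatomotor–salience edges positive (the sign
structure described for the MDD map); $b_1 = 0.5$, $b_2 = 0.2$,
$b_3 = 0.15$, family-intercept SD 0.4, residual SD solved so the planted
outcome has unit total variance — making standardized recovery target the
planted coefficients directly. $\alpha = 0.25$ was selected by a design
analysis: with $\Sigma_0 = \mathrm{cov2cor}(LL^\top + 2I)$ (loading SD 0.35)
the minimal eigenvalue stays above ~0.63 across seeds, worst-case repair
distortion at $|v| = 3.8$ is 3.6%, and the PCS–$v$ correlation at T = 300 is
about 0.96.

Because $v$ drives both the connectome and the outcome, the PCS is a noisy
proxy of the true moderator: end-to-end tests demonstrate (mild) attenuation
rather than assuming perfect measurement, while per-stage statistical tests
use $v$ itself. The generator does **not** emulate fMRI noise physics
(drift, motion spikes, physiological confounds), zygosity-specific genetic
covariance (families are exchangeable random intercepts), scanner/site
effects, or bounded questionnaire integers by default (an optional
discretization mode rounds and clips to instrument-like ranges). A green
end-to-end test therefore establishes that the code recovers the planted
statistical structure — not that real adolescent cohorts behave this way.

## Numerical choices

* Pearson correlations come from `stats::cor`; matrices are symmetrized
  (`(R + Rᵀ)/2`) against floating-point asymmetry and clipped to [−1, 1].
  Series shorter than 3 timepoints are rejected.
* The non-zero test on template weights is exact (`β ≠ 0`), since weights
  are stored values; an optional tolerance exists for templates that passed
  through lossy processing.
* Ties in `top_edges()` and `tertile_split()` resolve by canonical/stable
  input order, so results are permutation-reproducible.
* Mixed-model non-convergence is reported via a `converged` flag with
  optimizer diagnostics attached — never an exception — and singular fits
  are flagged separately.
* All randomness derives from one master seed via fixed sub-stream offsets
  (kept below 2³¹), so identical configs reproduce every result table
  byte-for-byte; manifests record a config hash (MD5 of the canonical JSON
  serialization).

## Known limitations

* Wald/z inference is anti-conservative in small samples relative to
  Satterthwaite-corrected tests; the default cohort sizes (hundreds of
  subjects) make the difference negligible, but results at a few dozen
  subjects deserve caution.
* The conditional-slope CIs use the delta method on the fitted covariance;
  they inherit any misspecification of the random-effects structure.
* The exploratory clinical-style arm shares the generator's template and
  base covariance; it probes pipeline mechanics (tertiles, ANCOVA, OLS
  engine), not cross-cohort harmonization.
* Published CSS maps are not redistributed; `load_template()` defines this
  package's own plain-text format, and converting released maps into it is
  the user's (licensing-aware) step.
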