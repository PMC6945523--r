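---
title: "Methods: two-sample and multivariable Mendelian randomization in adipomr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample and multivariable Mendelian randomization in adipomr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

adipomr estimates the causal effect of a continuous exposure — body mass
index or another body-composition index, measured in kg/m² — on binary
disease outcomes, using independent genetic variants as instrumental
variables and nothing but GWAS summary statistics. This vignette is the
package's own account of the statistical machinery: the models, the
assumptions they lean on, the tunable parameters, the numerical choices,
and what the synthetic-data generator does and does not emulate.

## The two-sample summary-data model

For each instrument $j$ we observe an estimated per-allele association with
the exposure, $\hat\gamma_j$ (SE $\sigma_{Xj}$), from one cohort, and with
the outcome on the log-odds scale, $\hat\Gamma_j$ (SE $\sigma_{Yj}$), from
a disjoint cohort. Under the instrumental-variable assumptions (the variant
is associated with the exposure, independent of confounders, and affects
the outcome only through the exposure), each variant supplies a Wald ratio
estimate of the causal log odds ratio per unit exposure,

$$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j,
  \qquad \mathrm{se}(\hat\beta_j) = \sigma_{Yj}/|\hat\gamma_j|,$$

the first-order delta approximation that ignores $\sigma_{Xj}$. That
approximation is deliberate: with weights $w_j = 1/\mathrm{se}(\hat\beta_j)^2$
the inverse-variance weighted (IVW) combination

$$\hat\beta_{\mathrm{IVW}} = \frac{\sum_j w_j \hat\beta_j}{\sum_j w_j}$$

is algebraically identical to the weighted no-intercept regression of
$\hat\Gamma$ on $\hat\gamma$ with weights $1/\sigma_{Yj}^2$, an identity the
test suite checks to $10^{-10}$. A second-order delta SE is available via
`ratio_estimates(second_order = TRUE)` for comparison, but the IVW path
always uses the first-order form.

### Random effects

The paper-grade convention for summary MR is *multiplicative* random
effects: the fixed-effect SE $(\sum_j w_j)^{-1/2}$ is inflated by
$\max\{1, \sqrt{Q/(J-1)}\}$, where
$Q = \sum_j w_j(\hat\beta_j - \hat\beta_{\mathrm{IVW}})^2$ is Cochran's
heterogeneity statistic. Heterogeneity can therefore widen but never
narrow the interval, and the point estimate is untouched. An additive
DerSimonian–Laird variant (`effects_model = "additive_random"`) is kept
behind a flag for comparison only. With a single instrument the IVW
estimate collapses to the Wald ratio and $Q$ is reported as absent.

### Weighted median

The weighted median is the inverse of the weighted empirical CDF of the
ratio estimates, evaluated at cumulative weight 0.5 with IVW weights. Two
boundary conventions are fixed on purpose: when the cumulative weight hits
0.5 exactly between two ratios the two are averaged (so equal weights
reproduce the ordinary sample median), and a single SNP carrying more than
half the total weight returns exactly that SNP's ratio. The usual
midpoint-interpolation convention does not have the second property, which
we consider the right dominance behaviour for a "majority valid weight"
estimator. Its SE comes from a parametric bootstrap (default
`n_boot = 1000`, seeded): each $\hat\gamma_j$, $\hat\Gamma_j$ is resampled
from a normal with its reported SE, the median recomputed, and the SD over
replicates taken. The estimator is consistent when at least 50% of the
weight comes from valid instruments.

### MR-Egger

MR-Egger is the weighted regression of $\hat\Gamma$ on $\hat\gamma$ *with*
an intercept, weights $1/\sigma_{Yj}^2$: the slope estimates the causal
effect under the InSIDE assumption (instrument strength independent of
direct effects), the intercept the average directional pleiotropic effect.
Identifiability of the intercept requires a fixed orientation, so each
pair is first oriented to the exposure-increasing allele
($\hat\gamma_j \ge 0$, negating both coordinates where needed); IVW and
the weighted median are invariant to that orientation. Both coefficient
SEs carry the multiplicative inflation $\max\{1,\sqrt{Q'/(J-2)}\}$ from
the residual heterogeneity $Q'$. Coefficient p-values use the standard
normal by default; `t_dist = TRUE` switches to $t_{J-2}$. A degenerate
design — fewer than 3 instruments, or no spread in $|\hat\gamma|$ — is a
hard error rather than a silent collapse.

### Multivariable MR

With two exposures instrumented by the same variants (fat mass and
fat-free mass indices are the motivating pair), the weighted no-intercept
regression of $\hat\Gamma$ on $(\hat\gamma_{1}, \hat\gamma_{2})$ estimates
each exposure's *direct* effect, mutually adjusted. SEs are inflated by
$\max\{1,\sqrt{Q/(J-k)}\}$ with $k$ fitted exposures. An exposure whose
instrument effects are identically zero is unidentified and dropped (the
other exposure's estimate then equals univariable IVW exactly — a nested
collapse the tests rely on); non-trivially collinear effect vectors are a
hard error.

## MR-PRESSO

The global test statistic is the residual sum of squares
$\mathrm{RSS} = \sum_j (\hat\Gamma_j - \hat\beta_{(-j)}\hat\gamma_j)^2 / \sigma_{Yj}^2$,
where $\hat\beta_{(-j)}$ is the leave-one-out *fixed-effect* IVW estimate
(fixed effects for stability at small $J$; computed in $O(J)$ via running
sums). Its null distribution is simulated `n_sim` times (default 1000) by
drawing $\gamma^*_j \sim N(\hat\gamma_j, \sigma_{Xj})$ and
$\Gamma^*_j \sim N(\hat\beta_{(-j)}\hat\gamma_j, \sigma_{Yj})$ and
recomputing the statistic, including its leave-one-out fits. The global
p-value uses the $(1+k)/(1+n_\mathrm{sim})$ convention and is therefore
never exactly zero.

The per-SNP outlier test compares each observed residual term with its own
simulated distribution. Here the raw empirical tail probability is
$k/n_\mathrm{sim}$ and *may* be exactly zero — deliberately so: the
default Bonferroni scaling by $J$ would otherwise floor the adjusted p at
$J/(n_\mathrm{sim}+1)$, and at $J = 96$ with moderate simulation counts no
SNP could ever reach the 0.10 exclusion rule. SNPs with adjusted p below
`alpha` (default 0.10, the conventional exclusion threshold) are flagged,
the IVW estimate is recomputed without them, and a distortion test
compares the raw-minus-corrected difference against random pseudo-outlier
sets of the same size. `multiple_testing = "raw"` switches the threshold
to the unadjusted p.

## Diagnostics

* Variance explained: summary route
  $R^2 = \sum_j 2 p_j (1-p_j)\hat\gamma_j^2 / \mathrm{var}(X)$ (unit
  variance assumed for standardized effects), or the multiple-regression
  $R^2$ from raw data.
* F statistic: $F = \frac{n-k-1}{k}\,\frac{R^2}{1-R^2}$, with the
  conventional $F > 10$ weak-instrument flag. At the scale of the large
  published BMI GWAS ($R^2 = 0.016$, $n = 339{,}224$, $k = 96$) this
  formula gives $F \approx 57$; published instrument tables sometimes
  print slightly different values whose sample basis is not recoverable,
  so the package documents the formula and asserts only the formula.
* Conditional instrument strength for two exposures: in the
  Sanderson–Windmeijer spirit, the other exposure's instrument effects are
  regressed out (weighted by $1/\sigma_{Xj}^2$ of the exposure of
  interest) and the conditional F is the mean weighted squared residual,
  $\sum_j w_j e_j^2/(J-p)$. Orthogonal or absent conditioning effects
  collapse it to the mean per-SNP chi-square (the univariable strength);
  identical effect vectors drive it to zero with a warning rather than an
  error. The implementation is validated against a brute-force two-stage
  individual-level regression oracle at a 15% tolerance, not against any
  published value.
* Power: the normal-approximation power for a binary outcome uses the
  non-centrality $\mathrm{NCP} = N R^2 \phi(1-\phi)\log(\mathrm{OR})^2$
  ($\phi$ the case fraction) and the two-sided form
  $\Phi(\sqrt{\mathrm{NCP}} - z_{1-\alpha/2}) +
   \Phi(-\sqrt{\mathrm{NCP}} - z_{1-\alpha/2})$, so the null returns
  exactly $\alpha$ and swapping cases and controls changes nothing. The
  formula describes the *fixed-effect* Wald test; the multiplicative
  random-effects estimator is conservative under homogeneity (its SE is
  inflated whenever $Q/(J-1) > 1$), so Monte-Carlo comparisons with the
  formula are made against the fixed-effect IVW.

## Harmonization rules

Records are aligned to the exposure's effect allele. Label match or
swapped labels (sign-flip), then strand complements, are tried in that
order; anything else is dropped as an allele mismatch. Palindromic (A/T,
C/G) SNPs cannot be resolved by labels, so they are retained only when
allele frequencies are present on both sides, both fall outside the
uninformative band $0.5 \pm w$ (default window $w = 0.08$), and both lie
on the same side of 0.5; discordant or uninformative frequencies drop the
SNP. This is the conservative end of common practice and is configurable.
Every drop carries a reason in the provenance log, and harmonization is
involutive under per-record allele re-representation and idempotent on its
own output.

Instrument selection applies the published criteria: genome-wide
significance with a strict `p < 5e-8`, imputation quality strictly above
0.8, and a Hardy–Weinberg p-value floor (default `1e-6` — the literature
typically says only "in Hardy–Weinberg equilibrium", so the numeric floor
is an explicit, configurable choice). Optional columns that are absent
never exclude a record, because published instrument lists often lack
them.

## The synthetic-data generator

`generate_two_sample_dataset()` simulates the full causal chain at desk
scale so that every estimator can be checked against ground truth:

* Genotypes: $J$ unlinked biallelic SNPs, MAF uniform in
  `[maf_low, maf_high]` (default 0.05–0.5), dosages Binomial(2, MAF), two
  disjoint cohorts sharing allele frequencies. Default cohort sizes are
  50,000 each — large enough for logistic asymptotics and small enough
  for hundreds of replicates on one CPU.
* Exposure: $X = \sum_j \gamma_j g_j + \varepsilon$ with effects scaled so
  the instruments explain exactly `exposure_h2` (default 0.016, matching
  the ~1.6% of BMI variance explained by ~96 index SNPs) of a
  unit-variance exposure; the default `n_snps = 96`.
* Outcome: logistic,
  $\mathrm{logit}\,P(Y{=}1) = \beta_0 + \theta X + \sum_j \alpha_j g_j$,
  with $\theta$ the causal log OR per unit exposure (default
  $\log 1.10$) and $\beta_0$ solved by root-finding so the marginal event
  rate hits `outcome_prevalence` (default 0.10) to within 5e-4 in
  expectation.
* Pleiotropy scenarios: `balanced` ($\alpha_j$ zero-mean normal, InSIDE
  holds), `directional` (nonzero mean), and `planted_outliers` (a few
  SNPs with a fixed large direct effect; the replication scenarios use
  0.2 per allele — about eight outcome-association SEs at the default
  cohort size, i.e. gross, unambiguous pleiotropy). Directional
  and planted effects are oriented to the exposure-increasing allele;
  without that orientation, sign-symmetric instrument effects would
  cancel the directional bias and neither the Egger intercept nor the
  robustness ordering would be exercised.
* Second exposure: per-SNP effects correlated with the first at
  `cor` (default 0.5), its own h², its own causal effect — the fat
  mass / fat-free mass configuration for multivariable MR.
* Summary statistics: per-SNP simple linear regression (continuous) or
  per-SNP logistic regression (binary), exactly as GWAS summary
  statistics are produced, implemented in compiled code for cohort-scale
  throughput and verified against `lm()`/`glm()` in the tests.

Seeding: the master seed spawns fixed per-stage sub-streams, and genotype
columns and per-SNP effects additionally use per-SNP streams, so enlarging
`n_snps` leaves earlier SNPs' draws untouched and identical configurations
are byte-identical on disk.

What the generator does **not** emulate: linkage disequilibrium (the
instruments are index SNPs assumed independent), population structure and
principal-component adjustment (per-SNP models are univariable;
a PC-adjusted synthetic cohort would be a no-op), genotyping error,
imputation noise, relatedness, case–control ascertainment, and distinct
aetiologies across outcomes (outcomes differ only in prevalence and effect
parameters). Passing tests therefore demonstrate the *inference machinery*
under a clean two-sample design, not robustness to the full messiness of
biobank data. The generator writes non-palindromic allele pairs, so its
own output harmonizes losslessly; palindromic handling is exercised by
hand-built fixtures instead.

## Known numerical and statistical limitations

* **Weak-instrument attenuation.** Two-sample IVW with estimated
  $\hat\gamma$ in the weights is attenuated towards the null by roughly
  $\sum_j \sigma_{Xj}^2 / \sum_j \hat\gamma_j^2$. At the default desk
  scale (h² = 0.016 split over 96 SNPs in a 50,000 cohort, mean per-SNP
  F ≈ 8–9) that is about 10% of the effect — for a true OR of 1.10,
  a mean log-OR recovery of ≈ 0.085 instead of 0.0953. At the sample
  size of the published BMI meta-analysis (n ≈ 339,000, F ≈ 57) the same
  attenuation is ~2‰ and immaterial. The package deliberately ships no
  weak-instrument correction, matching the analysis it reimplements; the
  replication suite measures this attenuation rather than hiding it.
* For the same reason — zero-centred instrument effects — an outlier
  planted on a near-null instrument induces little bias in the combined
  estimate, so MR-PRESSO outlier-corrected re-estimation moves the point
  estimate towards the truth in most, but not quite all, replicates even
  when every planted outlier is flagged. Selected real instruments have
  effect sizes bounded away from zero and do not show this edge.
* Empirical p-values are bounded below by their simulation counts; the
  per-SNP outlier p intentionally departs from the never-zero convention
  (see above) so the Bonferroni-adjusted exclusion rule remains reachable.
* The bootstrap SE of the weighted median can be unstable when resampled
  $\hat\gamma_j$ cross zero; this is inherent to the parametric bootstrap
  and mitigated only by instrument strength.
* `uniroot` solves the prevalence intercept on $[-40, 20]$; prevalences
  beyond ~1e-15 of the boundaries are out of scope.

## Problem sizes used by the replication suite

The test suite and the acceptance script regenerate everything from code.
Unit tests run at reduced scale (cohorts of a few thousand, $J \le 40$).
The calibration and recovery studies use the generator defaults
(J = 96, two cohorts of 50,000, 200 replicates for null calibration and
recovery, 100 replicates for the outlier and contamination scenarios,
MR-PRESSO at `n_sim = 500`), sizes chosen to keep Monte-Carlo error
around or below one percentage point on rejection rates while remaining
a single-CPU desk-scale job. Power checks compare the analytic formula
with 500-replicate Monte-Carlo reject rates at two parameter points
(J = 20, h² = 0.05, outcome cohort 10,000 at 50% prevalence, OR 1.2 and
1.35), where the formula's assumptions (strong instruments, known R²)
hold to within Monte-Carlo error.
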