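---
title: "Methods: two-sample MR screening, sensitivity analysis and mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening, sensitivity analysis and mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

# The model

Two-sample Mendelian randomization treats genetic variants as instrumental
variables for a modifiable exposure. For variant $i$ with effect
$\hat\beta_{X,i}$ (SE $\sigma_{X,i}$) on the exposure and
$\hat\beta_{Y,i}$ (SE $\sigma_{Y,i}$) on the outcome, each variant gives a
Wald ratio $\hat\theta_i = \hat\beta_{Y,i}/\hat\beta_{X,i}$ with
first-order SE $\sigma_{Y,i}/|\hat\beta_{X,i}|$. Under the instrumental
assumptions (relevance, independence, exclusion restriction) every
$\hat\theta_i$ estimates the same causal effect $\theta$, and the package's
estimators differ in how they pool the ratios when some instruments are
invalid:

* **IVW** is the weighted regression of $\hat\beta_Y$ on $\hat\beta_X$
  through the origin with weights $1/\sigma_Y^2$ — efficient when all
  instruments are valid. The fixed-effects SE is
  $(\sum w_i \hat\beta_{X,i}^2)^{-1/2}$; the random-effects model inflates
  it by $\sqrt{\max(1, Q/(k-1))}$ (multiplicative, floored at 1, so it
  reduces to fixed effects without excess heterogeneity).
* **MR-Egger** frees the intercept; the slope is a pleiotropy-adjusted
  estimate and the intercept estimates average directional pleiotropy.
  Records are re-signed to $\hat\beta_X \ge 0$ first — without that
  orientation convention the intercept is not identified.
* **Weighted median**: the inverse-variance-weighted median of the ratios
  (cumulative weight 0.5, linear interpolation); consistent while valid
  instruments hold more than half the weight. Its SE comes from a seeded
  parametric bootstrap of the per-SNP betas.
* **Modes**: the argmax of a normal-kernel density of the ratios with
  bandwidth `bandwidth_factor × 1.4826·MAD` (simple = unweighted,
  weighted = inverse-variance); consistent when the largest cluster of
  ratios is the valid one. A zero MAD (majority of identical ratios)
  degenerates to the discrete weighted mode; exact ties resolve to the
  smaller ratio.

All estimates carry normal-based 95% CIs ($\beta \pm 1.959964\,se$) and
two-sided normal p-values; odds ratios are `exp(beta)` for binary traits.

Diagnostics follow the conventional battery. Cochran's
$Q=\sum_i w_i(\hat\theta_i - \hat\theta_{IVW})^2$ on the per-SNP ratios
(weights $1/se_{ratio}^2$, matching the estimator's weights), with
$I^2 = \max(0, (Q-df)/Q)$; the IVW effects model is random *iff*
$P_Q < 0.05$ **and** $I^2 > 25\%$ (both thresholds strict, both
configurable — many tools condition on $P_Q$ alone, recoverable with
`i2_threshold = 0`). Steiger directionality sums per-SNP explained
variance $R^2 = z^2/(z^2+n)$ over instruments for each trait and compares
$\mathrm{atanh}(|r|)$ across traits with variances $1/(n-3)$.

Instrument strength uses $F = \frac{N-K-1}{K}\cdot\frac{R^2}{1-R^2}$ with
the conventional weak-instrument flag at $F<10$; instrument sets are
flagged, never auto-dropped.

# Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `p_threshold` | 5e-8 | genome-wide significance for candidacy |
| `clump_r2`, `clump_kb` | 0.001, 10000 | LD pruning threshold and window (kb) |
| `palindrome_eaf_window` | 0.08 | A/T and C/G SNPs are ambiguous when either EAF is in [0.42, 0.58]; 0.5 drops all palindromes |
| `min_f` | 10 | weak-instrument flag |
| `alpha`, `m_nominal` | 0.05, panel size | Bonferroni threshold `alpha/m`; the denominator is the *nominal* panel size (e.g. 191), with `use_m_tested` for the analyzable count |
| `n_boot` | 1000 | bootstrap resamples for median/mode SEs; seed mandatory |
| `bandwidth_factor` | 1 | multiplier on 1.4826·MAD for the mode kernel |

The palindrome window and the Bonferroni-denominator convention are the two
places where published pipelines genuinely differ; both defaults follow the
dominant practice and both are exposed.

Greedy clumping sorts candidates by ascending p-value (ties broken by
chromosome, position, SNP ID for determinism) and drops a candidate within
the window of a retained SNP when its LD $r^2$ exceeds the threshold — or
on co-location alone when no LD matrix is supplied, which is conservative
and recorded in the result.

# The synthetic-data generator

`sim_study()` generates per-SNP summary statistics directly (no
individual-level genotypes), because two-sample MR consumes nothing else.
For each of `n_snps` instruments: MAF $\sim U(0.05, 0.40)$; the true
exposure effect is $\gamma_i = \pm\sqrt{R^2_{snp}/(2p_iq_i)}$, so each SNP
explains exactly `exposure_r2_per_snp` of the (unit-variance) exposure; the
mediator effect is $b_2\gamma_i$ and the outcome effect
$(\theta + b_2 b_3)\gamma_i + \mathrm{sign}(\gamma_i)\,\alpha_i$. Reported
betas add independent normal noise with $SE = 1/\sqrt{2p_iq_i n}$ per trait
(non-overlapping samples); p-values follow from the z-statistic. Binary
outcomes are emulated on the log-OR scale with the same machinery. When the
mediated path is active, the mediator additionally gets `n_snps_med`
instruments of its own, unrelated to the exposure — without them the
mediator→outcome step of two-step MR is not identifiable.

Pleiotropic effects $\alpha_i$ are defined *per exposure-increasing
allele*: they ride on $\mathrm{sign}(\gamma_i)$. With randomly oriented
SNPs, adding a nonzero-mean $\alpha$ directly to the outcome beta would
cancel across SNPs in the causal frame, making "directional" pleiotropy
operationally identical to balanced pleiotropy and leaving the Egger
intercept with no target; the sign convention is how simulation studies in
this field define directionality. `pleiotropy_frac` selects an exact count
`round(frac × n_snps)` of invalid instruments rather than an i.i.d. coin
flip per SNP, so "40% invalid" means 40% in every replicate — Bernoulli
sampling lets the invalid weight fraction cross 50% in a non-trivial share
of replicates, at which point the weighted median's consistency condition
itself fails.

Defaults (30 SNPs, per-SNP $R^2 = 1\%$, $n = 10^4$ per trait,
$\theta = 0.3$, pleiotropy mean 0.02 / sd 0.01) are the package's reference
study conditions used throughout the tests. The MAF range stops at 0.40 so
palindromic variants (a fifth of SNPs by default) remain orientable by
frequency. Allele-coding corruption (`frac_allele_swapped`,
`frac_strand_flipped`) applies exactly invertible transformations and keeps
the uncorrupted twin tables in `$clean`, which is what makes the
harmonization oracle exact to numerical precision: estimates after
harmonizing corrupted data must equal the clean twin's to 1e-9.

What the generator does *not* emulate: LD between instruments (SNPs are
placed ≥21 Mb apart; LD enters only through explicit `sim_ld_block()`
matrices for clumping tests), winner's curse at the selection threshold,
sample overlap between the two GWAS, and allele-frequency differences
between ancestries. Passing tests therefore validate the statistical
machinery, not robustness to those real-data complications.

# Two-step mediation

The total effect $\beta_1$ (exposure→outcome), step 1 $\beta_2$
(exposure→mediator) and step 2 $\beta_3$ (mediator→outcome) are estimated
by the ordinary pipeline; the indirect effect is the product
$\beta_2\beta_3$ with the first-order Delta SE
$\sqrt{\beta_3^2 se_2^2 + \beta_2^2 se_3^2}$, the direct effect
$\beta_1 - \beta_2\beta_3$, and the proportion mediated
$\beta_2\beta_3/\beta_1$ — always on the log-odds scale. Proportions
outside $[0,1]$ (inconsistent mediation) are reported and flagged, never
clamped; a zero total effect flags the proportion as undefined while the
indirect effect is still reported.

`mr_mediation()` excludes exposure-associated SNPs (exposure $p <$
`exclude_p`, default 0.05) from the step-2 instrument set. A SNP acting on
the mediator *through the exposure* also reaches the outcome through the
exposure's direct path, so using it to instrument the mediator biases
$\hat\beta_3$ toward $(\theta + b_2b_3)/b_2$; barring exposure-associated
variants is the standard two-step-MR safeguard, and it costs only the ~5%
of valid mediator instruments lost to chance association.

# Validation design and known limitations

The test suite validates every estimator against an independent oracle
(generic weighted least squares via `lm`, brute-force cumulative-weight and
dense-grid scans, literal summation, exhaustive greedy clumping) to 1e-9,
and the pipeline's statistical behaviour by simulation at the reference
conditions: estimator recovery and IVW coverage (1000 replicates), type-I
error under the null (1000), Egger intercept detection (500, mean 0.02 at
50 SNPs), weighted-median robustness (500 replicates, 40% invalid
instruments with pleiotropy mean 0.1 — chosen so the pleiotropic effect is
of the same order as the per-SNP causal outcome effect, i.e. the
instruments are *genuinely* invalid rather than mildly perturbed),
mediation recovery (500 chains with true proportion 0.4 at cohort sizes
typical of the motivating setting: exposure GWAS n = 7,800, biobank
mediator n = 300,000, case-control outcome n = 80,000), and Steiger
direction (500 replicates). These sizes keep the full suite to a few
minutes on one core.

Two behaviours of the standard estimators are worth knowing and are visible
in the package's own simulations:

* **Weak-instrument regression dilution.** With per-SNP $F = z^2 = R^2 n$,
  the IVW slope is attenuated by roughly $1/(1+1/F)$ — about 0.3% of
  $\theta$ at the reference conditions ($F \approx 100$), and similar for
  the median and weighted mode. MR-Egger is diluted much more (measured
  mean slope ≈ 0.23 for $\theta = 0.3$) because its slope is identified
  only by the *spread* of instrument strengths (the $I^2_{GX}$ problem):
  with homogeneous per-SNP $R^2$, the spread comes from MAF alone and
  $I^2_{GX} \approx 0.83$. These are properties of the estimators, not
  implementation artifacts; the oracle tests confirm the arithmetic is
  exact while the simulation tests measure the statistical behaviour
  honestly, and the dilution also leaks into the Egger intercept, which
  is why its pleiotropy test runs anti-conservative under balanced
  pleiotropy at these instrument strengths.
* **IVW SE ignores exposure-side noise.** The fixed-effects SE conditions
  on $\hat\beta_X$; empirical CI coverage at the reference conditions is
  ≈ 0.93–0.94 rather than 0.95.

Leave-one-out analysis, MR-PRESSO-style outlier removal, multivariable MR,
proxy-SNP lookup and LD estimation from genotype panels are out of scope.
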