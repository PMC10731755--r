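---
title: "Methods: balance selection, the MMI, and the synthetic ICU cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: balance selection, the MMI, and the synthetic ICU cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmindex)
```

## The problem and the model

Critically ill patients undergo rapid gut dysbiosis, and particular
compositional shifts — enrichment of pathobionts such as *Enterobacteriaceae*
and Gram-positive anaerobic cocci at the expense of commensals — appear to
carry prognostic information for short-term mortality. Because 16S count
tables are compositional (only relative information is meaningful), effects
are modeled through log-contrasts rather than raw abundances. The statistic
at the core of this package is a **balance**: for disjoint taxa subsets
$N$ (size $p$) and $D$ (size $q$) with geometric means $g(\cdot)$ over a
sample's positive abundances $x$,

$$ B(x) = \sqrt{\frac{pq}{p+q}}\ \log_{10}\frac{g(x_N)}{g(x_D)} . $$

The normalization coefficient makes balances of different sizes comparable;
for the $p = q = 2$ case it equals 1, so a 4-taxon balance is simply the
log10 ratio of two geometric means. Base 10 is used for interpretability
(one unit = one order of magnitude); the CLR transform used for ordination
uses the conventional natural log. Balances are scale-invariant per sample,
so they may be computed equivalently on zero-replaced counts or on closed
proportions — a property the test suite asserts.

The fitted balance, oriented so that larger values accompany 28-day death,
is the per-subject **microbiome mortality index (MMI)**; binarizing at zero
splits the cohort into high- and low-risk groups.

## Selection procedure

`fit_mmi()` runs the full sequence:

1. **Prevalence filter.** Taxa unobserved in at least 20% of samples are
   excluded (inclusive threshold: a taxon with exactly 20% zeros is
   dropped). The threshold is a parameter.
2. **Zero replacement.** Remaining zeros are replaced by i.i.d. uniform
   draws on $[0.01, 1)$ under a user seed, once per dataset before closure.
   The interval's openness is unimportant at double precision; half-open is
   what the uniform sampler provides and is documented. Replacement is
   deliberately performed once on the full table rather than per CV fold:
   the draw ignores the outcome, so leakage is negligible, and a single
   draw keeps the procedure reproducible from one seed.
3. **Greedy search.** All taxon pairs are scored first; the best pair is
   grown one taxon at a time (each remaining taxon tried on each side).
   A candidate's score is the AUC of a logistic regression of 28-day death
   on the balance value plus clinical covariates (age, APACHE II). Exact
   score ties break lexicographically on taxon ids so results are
   reproducible. Quasi-separation (unbounded logistic coefficients) is
   handled by refitting with a small ridge penalty (1e-4), which leaves
   ranks — and hence AUC — effectively unchanged.
4. **Size selection.** Stratified 5-fold cross-validation repeated 10
   times: the greedy path is grown on each training fold and each size is
   scored on the held-out fold. The **1-SE rule** picks the smallest size
   whose mean held-out AUC is within one standard error of the best size —
   the simplest balance with comparable predictive ability. `rule = "max"`
   is available. Fold counts, repeats, and the cap `max_size = 8` are
   parameters of `mmi_config()`.
5. **Final refit and orientation.** The greedy search is rerun on all
   samples at the selected size, and the balance is oriented so mean MMI
   among deaths is at least that among survivors.

Greedy search is not exhaustive; for small taxa sets the exhaustive
optimum can differ, which is why the recovery claims below are stated over
seeds rather than per-instance.

## Downstream statistics

* **Diversity** is computed on raw counts — zero replacement would distort
  richness. Shannon entropy is reported in bits (log2), Pielou as
  $H/\log_2 S$, dominance as Simpson's $\sum p_i^2$ (so dominance and
  Simpson diversity are exact complements), Simpson evenness as the
  inverse-Simpson effective taxon count over observed richness, Chao1 in
  its classic form $S + F_1^2/2F_2$ with the bias-corrected branch when no
  doubletons exist, and Fisher's alpha by bracketed root-finding of
  $S = \alpha\ln(1 + N/\alpha)$ to 1e-9. Chao1 and Fisher's alpha are
  count-based and intentionally not scale-invariant.
* **Bivariate tests** follow variable type: Wilcoxon rank-sum for
  quantitative variables, Fisher's exact (probability-of-table rule,
  two-sided) for 0/1 flags, Student's pooled t for diversity contrasts by
  binarized MMI.
* **Survival.** Kaplan-Meier product-limit curves per MMI group, and Cox
  proportional hazards over the first 28 days (administrative censoring at
  day 28 applied inside `cox_fit()`). Penalized fits use the elastic net
  (`l1_ratio` 0.5, `penalizer` 0.05 by default; both parameters). Point
  estimates come from the penalized partial likelihood; confidence
  intervals and p-values use the observed information of the unpenalized
  partial likelihood evaluated at the penalized coefficients, a documented
  approximation — penalized CIs are descriptive, not exact. Ties are
  handled by Efron's method in that information evaluation (the penalized
  solver itself uses the Breslow approximation, its fixed behavior). The
  penalizer reproducing any particular published fit is generally
  unknowable without subject-level data, which is why the package treats
  it as a sensitivity parameter rather than a constant.
* **Sparse supervised PCA.** "Sparse supervised PCA" admits several
  formulations; this package implements supervised pre-screening (drop
  features whose |Spearman correlation| with the supervisor falls below a
  configurable quantile) followed by truncated power iteration with hard
  thresholding to a per-component nonzero budget and projection deflation.
  Both steps are optional: with no supervision and a full budget the
  procedure reduces exactly to dense PCA, an equivalence the tests assert.
  Components are sign-oriented toward positive supervisor correlation.

## The synthetic cohort generator

No subject-level data accompany the study this design emulates, so every
claim is exercised on `generate_cohort()`, which plants a known signal:

* **Latent abundances** are log-normal: fixed per-taxon locations spread
  over ±4 natural-log units (dominant to rare genera) plus per-sample
  noise with sd 2. The heavy-tailed noise reproduces single-taxon
  dominance in a realistic fraction of samples. Log-normal rather than
  Dirichlet noise is chosen so the planted log-contrast is an exactly
  linear signal on the log scale.
* **The planted balance** is 2-vs-2 by default (taxa 1,2 over 3,4). Its
  per-sample value $B^\*$ enters a logistic model for 28-day death with
  effect `balance_effect_beta` (default 2) and intercept calibrated by
  bisection so marginal mortality hits the configured 54% target; with
  `beta = 0` the intercept is the closed-form logit.
* **Death timing.** 28-day deaths receive a truncated-exponential death
  day on (0, 28] whose rate scales with `exp(gamma * B*)` (higher balance,
  earlier death); survivors of day 28 receive an exponential tail
  calibrated so cumulative one-year mortality is ~73%, censored at day
  365. This construction makes `death28` and the death day consistent by
  definition while letting the logistic and hazard effects act separately.
* **Counts** are multinomial draws at 30,000 reads per sample. Structural
  zeros are then applied with probability
  `zero_inflation_rate * exp(-count / dropout_scale)` (defaults 0.15 and
  50 reads): detection dropout concentrates in low-count cells, as in real
  16S tables, where a taxon at thousands of reads is never lost outright.
  At the 52-sample scale this yields a median of roughly 15% zeros per
  taxon and about 24 of 40 taxa passing the 20% prevalence rule.
* **Clinical covariates** (age ~ N(67, 10), APACHE II ~ N(27, 7) clipped
  at zero, comorbidity/antibiotic flags at ICU-typical frequencies) are
  independent of the microbiome by default so recovery tests are
  unconfounded; `confound_covariates = TRUE` adds a balance loading to age
  and APACHE II for robustness checks.

**What the generator does not emulate.** Real ICU cohorts couple low
diversity itself to mortality; here diversity varies across subjects but
is not linked to the outcome, so a null diversity contrast on synthetic
data is expected and says nothing about real data. Taxon-taxon ecological
correlations (co-occurrence networks, GPAC co-enrichment) are likewise
absent: taxa are independent given their abundance ranks. Passing
recovery tests therefore demonstrates that the selection machinery finds a
planted log-contrast signal under realistic sparsity and dominance — not
that every biological structure of a real cohort is reproduced.

## Numerical and design choices

* Geometric means and balances are computed in log space; CLR rows sum to
  zero within 1e-9 and closure is idempotent.
* The fast logistic scorer uses IRLS with at most 25 iterations and a
  ridge fallback triggered by singular information or runaway
  coefficients.
* AUC is the rank-statistic (Mann-Whitney) form with average ranks for
  ties, identical to pairwise concordance.
* Cross-validation folds are stratified by outcome; if a class is smaller
  than the fold count the fold count is reduced with a warning. A held-out
  fold that still ends up single-class is skipped (its row is missing from
  the per-size aggregation) rather than scored meaninglessly.
* Problem sizes in the validation suite were chosen to keep each check
  sharp at desk scale: recovery runs use 200-subject cohorts with 40 taxa
  over 20 seeds; hazard-ratio recovery uses 50 replicates of n = 500; the
  Fisher-uniformity null probe uses 1000-subject cohorts because Fisher's
  exact test is conditionally conservative and discrete — at smaller n a
  uniformity test measures that well-known property of the test itself
  rather than the calibration of this pipeline.
* Configuration files are YAML with keys mirroring `mmi_config()`.

## Known limitations

* Greedy search can miss the exhaustive optimum; the 1-SE rule can select
  a size other than the planted one when sub-balances are nearly as
  predictive (at 52 samples this is common — the held-out SE is large).
* Penalized-Cox intervals are information-based approximations; for
  inference-grade intervals refit with `penalizer = 0`.
* The exact-mode Wilcoxon falls back to the corrected normal
  approximation in the presence of ties, with a warning.
* No phylogenetic diversity, no tree-aware (ILR basis) balance selection,
  and no continuous-outcome balance search.
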