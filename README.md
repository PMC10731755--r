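# mmindex

Links gut-microbiome composition to 28-day mortality in critically ill ICU
patients through a **microbiome mortality index (MMI)**: a cross-validated
greedy search over microbial *balances* — normalized log-ratios of
geometric means of two disjoint taxa subsets — with clinical covariates in
the predictive model, plus the downstream diversity, bivariate, survival,
and sparse-PCA analyses that characterize the high- and low-risk groups.

For disjoint taxa subsets $N$ (size $p$) and $D$ (size $q$) of a sample's
positive abundances $x$, a balance is

$$ B(x) = \sqrt{\tfrac{pq}{p+q}}\,\log_{10}\frac{g(x_N)}{g(x_D)}, $$

where $g(\cdot)$ is the geometric mean. The fitted balance, oriented so
larger values accompany death, is the per-subject MMI; binarized at zero it
defines high- and low-risk groups for Fisher tests, Kaplan–Meier curves and
elastic-net Cox models over the first 28 days of admission.

The intended users are microbiome/biostatistics researchers who want a
tested, seed-reproducible re-implementation of this analysis chain —
including a synthetic ICU cohort generator that plants a known
balance→mortality signal, so every stage is verifiable without access to
patient data.

## Worked example

```r
library(mmindex)

coh <- generate_cohort(synthetic_config(seed = 20230919))  # 52 subjects, 40 taxa
fit <- fit_mmi(coh$counts, coh$metadata, mmi_config(seed = 20230919))
print(fit)
#> Microbiome mortality index fit
#> <balance> log10 [ g(Taxon01,Taxon02,Taxon12) / g(Taxon04,Taxon03,Taxon22) ] * 1.2247
#>   selected size 6 (rule 1se); apparent AUC 0.975
#>   MMI > 0 in 36 / 52 samples
```

The cross-validated search selected a 6-taxon balance containing all four
planted taxa (`Taxon01`, `Taxon02` over `Taxon03`, `Taxon04`); the held-out
AUC curve behind the choice is in `fit$scores_by_size`. Binarized MMI then
separates survival sharply on this strongly-signaled cohort:

```r
md <- coh$metadata
km_hi <- km_estimator(md$death_free_days[fit$mmi_positive],
                      md$event_observed[fit$mmi_positive])
km_survival_at(km_hi, 28)
#> [1] 0.1111111
cox_fit(data.frame(apache2 = md$apache2, ards = md$ards,
                   mmi_positive = as.integer(fit$mmi_positive)),
        md$death_free_days, md$event_observed, penalizer = 0.05)
#> Cox PH fit (l1_ratio 0.50, penalizer 0.05, horizon 28 days, 32 events / 52)
#>       variable    coef hazard_ratio ci_lower ci_upper     se        p
#> 1      apache2 -0.0140        0.986    0.942     1.03 0.0222 5.55e-01
#> 2         ards  0.0000        1.000    0.498     2.01 0.3572 1.00e+00
#> 3 mmi_positive  1.9266        6.867    2.331    20.23 0.5515 4.73e-04
```

Here the index carries mortality information independent of APACHE II and
ARDS (hazard ratio 6.9 for MMI > 0 with both in the model; the clinical
covariates are simulated independent of the microbiome, so their null
hazard ratios are expected).

The numbered scripts under `analysis/` run the complete workflow on a
simulated cohort — `01_simulate.R` through `06_report.R` — writing tables
under `results/` (per-sample MMI, CV score curve, diversity panel and
contrast, bivariate table, Cox suite, sparse supervised PCA, and a
consolidated JSON report).

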