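# mclrad

PET radiomics and metabolic risk modelling for mantle cell lymphoma (MCL).

Pretherapy [18F]FDG PET/CT carries prognostic information in lymphoma, but
in MCL the established prognostic indices (MIPI, MIPI-b) use only clinical
and laboratory variables. `mclrad` implements, as a tested and reusable R
pipeline, a radiomics analysis that asks whether the *level* (SUVmean) and
*heterogeneity* (co-occurrence Entropy) of glucose metabolism across the
total metabolic tumour volume (TMTV) predict 2-year progression-free
survival (PFS), and whether a "metabolic risk" category built from them
improves MIPI-based prognostication. It is written for imaging scientists
and biostatisticians who want each stage of such an analysis as an
auditable, separately testable function.

## The method

1. **Segmentation** — TMTVs are grown from lesion seed points with the 41%
   SUVmax threshold, iterated to a fixed point: `mask = ` connected
   component of `{SUV >= 0.41 x max(SUV over mask)}` containing the seed.
2. **Features** — first-order: SUVmax, SUVmean, SUVpeak (1 mL sphere), TMTV
   (mL), TLG = TMTV x SUVmean; texture: the 16 Haralick features (Entropy
   `-sum p_ij log2 p_ij`, Homogeneity, Contrast, Correlation, Angular second
   moment, Difference entropy/variance, Inverse difference moment, Sum
   average/entropy/variance, Cluster prominence/shade, Maximum probability,
   IMC1/IMC2) from 3D grey-level co-occurrence matrices at interpixel
   distance 1 over the 13 canonical directions, with a 20-pair minimum per
   direction and arithmetic averaging over valid directions.
3. **Harmonization** — parametric empirical-Bayes ComBat applied to the
   feature table across scanner batches.
4. **Risk models** — MIPI `= 0.03535 age + 0.6978 [ECOG>=2] +
   1.367 log10(LDH/ULN) + 0.9393 log10(WBC)` (MIPI-b adds
   `0.02142 Ki-67%`); metabolic risk by majority vote over dichotomized
   SUVmean (> 3.55) and Entropy (> 3.5); MIPI-m/MIPI-bm shift the MIPI
   category by +-1 for high/low metabolic risk, capped at the extremes.
5. **Survival & prediction** — Kaplan-Meier, log-rank, Cox hazard ratios
   (Breslow ties), ROC/Youden cutoffs, univariate logistic screening +
   forward selection (likelihood ratio), and an MLP (one hidden layer,
   softmax output) over five stratified 70/30 splits for 2-year PFS.

No imaging cohort of this kind is public, so the package includes a
synthetic PET cohort generator (`cohort_config()`, `generate_cohort()`)
with known ground truth — lesion uptake, heterogeneity, scanner batch
effects, and outcome models — against which every stage is validated. See
`vignettes/mcl-pet-radiomics.Rmd` for the full methods account.

## Worked example

```r
library(mclrad)

cfg <- pipeline_config(
  cohort = cohort_config(n_patients = 107, seed = 11),
  recut = TRUE, recut_method = "median",  # cohort-specific cutoffs
  seed = 11)
res <- run_pipeline(cfg)
print(res)
#> <pipeline_result: 107 patients, signature = suv_mean + entropy>
#>   3-category metabolic risk log-rank: chi2 3.39, p = 0.1837
#>   median validation AUC: 0.59 (radiomic) / 0.57 (+clinical)

res$survival$metabolic_2cat$cox
#>   group       hr     lower    upper    p_value
#> 1  high 1.611148 0.9646444 2.690936 0.06839074

km <- res$survival$metabolic_2cat$km
c(high = km$high$median, low = km$low$median)   # median PFS, months
#>     high      low
#> 20.90187 39.86286

round(100 * mean(res$risk$pfs2y_event), 1)
#> [1] 30.8
```

Reading the output: the simulated cohort reproduces the intended study
conditions — a 2-year progression rate near the 37.2% calibration target;
patients with high metabolic risk (both SUVmean and Entropy above their
cohort cutoffs) have a median PFS of ~21 months against ~40 months for the
rest, with a hazard ratio of 1.6. At n = 107 the default, study-calibrated
effect size is deliberately borderline — single cohorts scatter around
these values (this seed's two-category Cox p is 0.068), which is why the
package's statistical guarantees are tested on parameter-recovery and power
simulations at larger n rather than on one draw. The clinical covariates
are pure noise in the default generator, so adding them does not raise the
MLP validation AUC here — on real data the study found the opposite, and
the `run_prediction_experiment()` tests show the pipeline does report
higher AUC when clinical variables genuinely carry signal.

Single patients work too:

```r
p <- generate_lesion_volume(cohort_config(seed = 7), 1)
tmtv <- build_tmtv(p$volume, p$seeds)             # 41% SUVmax region growing
extract_all(p$volume, tmtv)                       # one feature row
```

A thin CLI is included: `inst/cli/mclrad simulate --n 107 --out dir --seed 17`
writes a cohort (NIfTI volumes + seed/patient CSVs); `inst/cli/mclrad run`
runs the pipeline from a YAML config.

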