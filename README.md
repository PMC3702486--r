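# mclegz

Infarct-heterogeneity analysis for late-enhancement cardiac MR: simulate an
infarcted left-ventricular phantom, fit per-voxel inversion-recovery
relaxometry, quantify the core infarct and the peri-infarct **gray zone**
by two independent routes, score papillary-muscle (PM) involvement, and run
the two-group cohort statistics used to compare patients with and without
appropriate ICD therapy.

## The problem

After myocardial infarction, the border between dense scar and viable
myocardium — the peri-infarct gray zone — is a putative substrate for
ventricular arrhythmia. Its extent can be measured from
late-gadolinium-enhancement (LGE) images in two ways:

* **FWHM thresholding** on a conventional single-TI inversion-recovery
  image (IR-FGRE). With remote-myocardium statistics
  (`Mean_remote`, `Peak_remote`, `SD_remote`), core and gray zone are

  ```
  SI_core > 0.5 · Peak_infarct
  Peak_remote < SI_gz ≤ 0.5 · Peak_infarct
  ```

  where `Peak_infarct` is the peak intensity over the hyperenhanced
  myocardium.

* **Multi-contrast late enhancement (MCLE)**: a stack of images at
  increasing inversion times is fit per voxel with the signal model

  ```
  S(t) = A − B · e^(−t / T1*)
  ```

  yielding T1* and steady-state (A) maps. Fuzzy C-means (k = 3, m = 2) on
  the (T1*, A) scatter classifies voxels as infarct, healthy myocardium,
  or blood; the gray zone is the band of voxels with infarct membership
  between 25% and 75%.

Both routes report core / gray-zone / total infarct in grams and as a
percentage of LV myocardial mass, plus a 0/1/2 PM involvement score, and a
pooled Student *t* / Fisher-exact report compares the two outcome groups.

## Worked example

```r
library(mclegz)

cfg <- run_config(phantom = phantom_spec(noise_sd = 2.4), seed = 7)
res <- run_pipeline(cfg)
res$heterogeneity
#> # A tibble: 3 × 8
#>   method       core_g  gz_g total_g lvm_g core_pct gz_pct total_pct
#>   <chr>         <dbl> <dbl>   <dbl> <dbl>    <dbl>  <dbl>     <dbl>
#> 1 ground_truth   9.75  1.13    10.9  40.1   24.3     2.82      27.1
#> 2 mcle           9.75  1.13    10.9  40.1   24.3     2.82      27.1
#> 3 ir_fgre        9.75  1.15    10.9  40.1   24.3     2.87      27.2
res$pm_mcle$score
#> [1] 1
```

The phantom is a three-slice short-axis left ventricle (1.5 mm in-plane,
8 mm slices) with a transmural 90° infarct wedge, a 3 mm gray-zone rim,
and two papillary muscles (one infarcted). At 2% noise both segmentation
routes recover the ground-truth gray zone (2.8% of LV mass) to within a
tenth of a percentage point, and the PM score is 1 — one involved muscle.

Cohort-level statistics reproduce published mean ± SD tables directly:

```r
t_test_summary(1.67, 0.49, 12, 1.00, 0.93, 13)$p_value  # PM-MI score
#> [1] 0.03621304
```

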