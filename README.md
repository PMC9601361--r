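# radsig

Multiregional radiomic signatures of hormone-receptor status from
dynamic contrast-enhanced breast MRI (DCE-MRI).

## What it does

Receptor status (estrogen, ER; progesterone, PR) steers breast-cancer
subtyping and treatment but is measured from invasive biopsies. A DCE-MRI
study — one pre-contrast and eight post-contrast frames — gives each pixel
a time–intensity curve \(SI_0..SI_8\) whose wash-in/wash-out shape carries
information about the tumor and its microenvironment. `radsig` implements
the full analysis chain from frames to validated signatures:

1. **Kinetic parametric maps** (pixel-wise):
   MSI = max(SI<sub>i+1</sub> − SI<sub>i</sub>);
   SI<sub>slope</sub> = 100·(SI₈ − SI<sub>mean</sub>)/SI<sub>mean</sub> with
   SI<sub>mean</sub> = (SI₁ + SI₂)/2;
   E<sub>initial</sub> = 100·(SI₁ − SI₀)/SI₀;
   ESER = 100·(SI₁ − SI₀)/(SI₂ − SI₀);
   E<sub>peak</sub> = 100·(SI<sub>peak</sub> − SI₀)/SI₀;
   SEP = 100·(SI₂ − SI₀)/SI₀.
2. **Segmentation**: Otsu (maximum between-class variance) thresholding of
   a subtraction image inside a seed box → intratumoral mask; exact
   Euclidean dilation by 4 mm, clipped to the breast mask → peritumoral
   ring.
3. **Feature bank**: per region × map, μ±3σ normalization to 8-bit levels,
   then 15 first-order + 60 GLCM/Haralick + 100 Laws + 240 Gabor features
   = 415; 2 regions × 6 maps × 415 = **4980 features per case**.
4. **Signature selection**: ICC(2,1) > 0.8 reproducibility filter (two
   readers) → Welch t-test (p < 0.1) → LASSO logistic regression (λ by
   10-fold CV deviance) → backward stepwise AIC → logistic rad-score.
   Multiregional signature = selected intra ∪ peri features re-fed to
   LASSO + stepwise.
5. **Evaluation**: ROC AUC with DeLong 95% CIs, Youden operating points,
   a 2 endpoints × 3 scopes × 2 cohorts report grid and ROC overlay
   figures.

A seeded synthetic DCE cohort generator (`synthetic_config()`,
`generate_cohort()`) emulates the statistical structure this analysis
assumes — class-dependent enhancement kinetics, an independently
informative peritumoral rim, breast parenchyma, spatial texture,
acquisition noise, and a simulated second reader — so the whole pipeline
is testable end-to-end with no patient data.

## Worked example

```r
library(radsig)
cfg <- synthetic_config(n_patients = 100, seed = 7)
cohort <- generate_cohort(cfg)
tab <- build_feature_table(cohort, families = "firstorder")
er <- vapply(cohort, function(s) s$er_label, 0L)
split <- split_cohort(cohort)          # temporal 4:1
run <- run_endpoint(tab, er, split, endpoint = "ER", seed = 7)
evaluate_endpoint(run, er)
```

```
  endpoint scope     cohort    auc ci_low ci_high sensitivity specificity threshold n_pos n_neg
1       ER intra   training 1.0000 1.0000       1      1.0000      1.0000   -0.0842    54    26
2       ER intra validation 0.9405 0.8411       1      0.8571      0.8333   -0.0842    14     6
3       ER  peri   training 0.9907 0.9765       1      0.9630      1.0000    1.0869    54    26
4       ER  peri validation 0.9286 0.7886       1      0.9286      1.0000    1.0869    14     6
5       ER multi   training 0.9943 0.9849       1      0.9630      1.0000    1.6307    54    26
6       ER multi validation 0.9881 0.9551       1      0.8571      1.0000    1.6307    14     6
```

Each row is one (signature, cohort) cell: AUC with its DeLong 95% CI, and
the sensitivity/specificity at the Youden threshold fixed on the training
cohort. At this small n the planted synthetic signal is strong, so AUCs
run high; the multiregional signature's validation AUC (0.988) is at
least as good as the better single region (0.941), the qualitative
headline the recovery tests assert at n = 300 over 10 seeds.

A single case's feature vector:

```r
s <- generate_study(cfg, 0)
rois <- build_roi_set(s)               # intratumoral + 4 mm peritumoral ring
fv <- extract_all_features(s, rois)
length(fv)                             # 4980
```

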