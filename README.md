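# ChemoFusion

Multi-platform data fusion for chemometric origin discrimination.

## The problem

Telling apart the geographical origins of a natural product from its
chemistry is rarely possible with one analytical platform: LC-MS,
GC-MS, ¹H NMR and mid-infrared (MIR) spectroscopy each see a different
slice of the metabolome. ChemoFusion implements the complete
multi-block workflow used in origin-discrimination studies of herbal
raw materials: per-platform spectral preprocessing, three levels of
data fusion, a seven-classifier comparison, screening of the top
characteristic variables from the best model, and validation of that
panel on an external sample set from origins the model never saw.
Because raw data for such studies are typically not deposited, the
package ships a seeded synthetic multi-block generator with planted
group-discriminative features, so every stage is testable end to end.

## The method

Four blocks X₁…X₄ (samples × features; NMR spectra are bucketed at
0.002 ppm over 0.4–12.0 ppm with the 4.8–5.0 ppm water window
excluded, MIR spectra are Savitzky–Golay smoothed, vector normalized
and masked to informative regions) are Z-scored on the model samples
and combined at three levels:

* **LLDF** — direct concatenation `[X₁|X₂|X₃|X₄]`;
* **MLDF** — per-block extraction (PCA / PLS-DA scores at 95%
  cumulative variance, or top-40 variables by DT / RF Gini importance)
  followed by a second-stage classifier (`SELECTOR-CLASSIFIER`, e.g.
  `RF-RF`);
* **HLDF** — per block, a 100-tree random forest selects the top 120
  variables, a refit forest selects the top 40 with importances
  g⁽ᵇ⁾; the fused importance of variable j in block b is

  &nbsp;&nbsp;&nbsp;&nbsp;ĝⱼ⁽ᵇ⁾ = w · gⱼ⁽ᵇ⁾, w = 1/4,

  the 4 × 40 = 160 weighted candidates are merged, sorted, and the top
  40 train the final forest (`RF-RF-RF`).

Models are compared by OOB accuracy, train/test accuracy, precision,
recall, F1 and trapezoidal ROC AUC (AUC ≡ Mann–Whitney concordance;
verified against exhaustive pair counting). The top-38 variables of
the best traceable model are screened and the external samples,
restricted to those variables, are projected by PCA; group separation
is quantified by the ratio of between- to within-group mean pairwise
distance.

## Worked example

```r
library(ChemoFusion)

study <- generateStudy(defaultStudySpec(seed = 1))
study
#> FusionStudy: 84 samples (70 model, 14 external), 4 blocks
#>   LCMS   feature table (171 features)
#>   GCMS   feature table (78 features)
#>   NMR    spectra (49601 points)
#>   MIR    spectra (451 points)

res <- runFusionPipeline(study, fusionConfig(seed = 1),
                         classifiers = c("SVM", "kNN", "DT", "RF"),
                         selectors = c("PCA", "DT", "RF"),
                         runSingle = FALSE)
head(res$comparison, 5)
#>      model       oob accuracy_train accuracy_test precision f1 recall auc
#> 1  LLDF:RF 0.9795918              1             1         1  1      1   1
#> 2    DT-RF 1.0000000              1             1         1  1      1   1
#> 3   RF-SVM        NA              1             1         1  1      1   1
#> 4    RF-RF 1.0000000              1             1         1  1      1   1
#> 5 RF-RF-RF 0.9795918              1             1         1  1      1   1

res$bestScreenable
#> [1] "RF-RF"
res$variableSet
#> CharacteristicVariableSet: top 38 from RF-RF
#>  rank block   feature raw_importance fused_importance
#>     1  GCMS GCMS_F054     0.05593431       0.05593431
#>     2   MIR   wn_2928     0.05519476       0.05519476
#>     3  LCMS LCMS_F152     0.05334941       0.05334941
#>     4  GCMS GCMS_F059     0.04786664       0.04786664
#>     5  GCMS GCMS_F055     0.04691390       0.04691390
#>   ... 33 more
```

On this synthetic study the planted signal is strong enough that
several fusion strategies reach perfect test metrics (21 test
samples); the interesting outputs are the screened panel and the
external validation. The 14 external samples, projected on the 38
screened variables versus on the full ~6,700-column concatenation:

```r
res$projection
#> ProjectionReport: 14 samples, 4 groups, PC1+PC2 = 79.5% var, separation index 2.124
res$baselineProjection
#> ProjectionReport: 14 samples, 4 groups, PC1+PC2 = 62.6% var, separation index 1.251

plantedRecovery(study, res$variableSet)
#> [1] 0.8666667
```

The screened panel separates the four external origins markedly better
than the raw concatenation (separation index 2.12 vs 1.25), and 26 of
the 30 planted discriminative features are recovered among the 38
screened variables.

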