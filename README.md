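# radexplore

Radiomics studies map large sets of image-derived features — shape,
first-order intensity histogram, and texture matrices computed inside a
segmented region of interest (ROI) — onto a binary clinical outcome with a
supervised model. Finding a good model means sweeping a whole grid of
pipeline choices: how to normalize features, how to strip redundant ones,
which selector and how many features to keep, and which classifier to fit.
`radexplore` is a headless R toolkit that automates that sweep end to end
for radiologists and imaging scientists:

1. **Feature extraction** — batch processing of case folders of NIfTI
   image/ROI volumes into a case-by-feature CSV. Families: shape,
   first-order histogram, and the gray level co-occurrence (GLCM), run
   length (GLRLM), and size zone (GLSZM) matrices, all under the IBSI
   reference definitions.
2. **Data preparation** — validity audit with a removal log, stratified
   train/test splitting that preserves the class ratio, and class
   balancing (down/up-sampling, SMOTE, SMOTETomek) of the training set.
3. **Model development** — exhaustive enumeration of every
   {normalizer × reducer × selector × feature count × classifier}
   combination, each evaluated by stratified k-fold cross-validation with
   every stage refit inside each training fold (no leakage), under fixed
   per-component seeds.
4. **Result inspection** — models ranked by validation AUC
   (the Mann–Whitney statistic: `AUC = P(score⁺ > score⁻)`, ties ½), 95%
   percentile-bootstrap confidence intervals, accuracy / sensitivity /
   specificity at the training Youden cutoff, the one-standard-error rule
   (smallest feature count with mean AUC ≥ max AUC − SE(argmax)), and
   report export including a plain-language model description.

A synthetic-data module (`make_phantom`, `make_table`) generates image
phantoms and feature tables with known ground truth, so the entire
workflow is testable without any imaging dataset.

## Worked example

Sweep a grid on a synthetic table with 5 informative features (standardized
mean difference 1.5) hidden among 50, 100 cases per class:

```r
library(radexplore)

tab <- make_table(table_spec(n_pos = 100, n_neg = 100, n_features = 50,
                             n_informative = 5, effect_size = 1.5, seed = 42))
specs <- enumerate_pipelines(normalizers = "zscore", reducers = "pcc",
                             selectors = c("anova", "relief"),
                             classifiers = c("lda", "logistic_regression"),
                             feature_range = 1:10, seed = 1)
run <- run_pipelines(tab, specs, k = 5, seed = 1)
sel <- select_model(run)
sel$best
#> <cv_result> zscore_pcc_anova_5_lda: validation AUC 0.991 (SE 0.007), training AUC 0.993
model <- evaluate_model(sel$selected, tab, is_selected = TRUE, seed = 1)
model
#> The model normalizes features by zscore normalization, reduces dimension by pcc,
#> selects 4 feature(s) by anova, and classifies with lda. It was developed with
#> stratified 5-fold cross-validation.
#> On the train dataset: AUC 0.987 (95% CI 0.975-0.996), accuracy 0.945, ...
#> On the validation dataset: AUC 0.983 (95% CI 0.969-0.993), accuracy 0.935, ...
#>   feature feat_004: selector score 144.6, coefficient 0.7064
#>   feature feat_001: selector score 138, coefficient 0.7464
#>   ...
```

The top-ranked pipeline (ANOVA selector + LDA, 5 features) reaches a mean
validation AUC of 0.991; the one-standard-error rule trades it for a
simpler 4-feature model at AUC 0.983. The listed selector scores are the
ANOVA F-values of the chosen features and the coefficients are the LDA
discriminant weights — the quantities a radiomics report typically prints.
All four selected features are among the five planted informative ones.

`export_report(run, "report/")` writes `results.csv` (all pipelines
ranked), per-dataset ROC point files, the AUC-versus-feature-count curve,
per-class feature histograms, and the description text. The command-layer
wrappers `cmd_extract`, `cmd_prepare`, `cmd_run`, `cmd_report` (and the
shell front end `inst/scripts/radexplore.R`) chain the same steps from
CSV/NIfTI files on disk.

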