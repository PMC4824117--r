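# delvar

Classify missense protein variants as **deleterious** (directly disrupting
protein molecular function — stability, active site, interface or folding)
or **neutral**, by integrating sequence conservation with structural
energetics, and explain *why* a variant is predicted deleterious.

`delvar` is aimed at structural bioinformaticians and variant-curation
groups who have, for each protein of interest, a PSIBLAST position-specific
scoring matrix (PSSM), a structural model (crystal structure or homology
model) and Rosetta-style refinement score files for the native and variant
structures, and who want a ranked, physically interpretable deleteriousness
call per variant.

## The model

Each variant is characterized by a fixed 106-feature vector:

* **5 sequence features** from the PSSM: the log-odds of the native and
  variant amino acid at the position (`pssm_nat`, `pssm_mut`), their
  difference (`pssm_diff`), the position's information content in bits
  (`info_cont`), and a broad chemical-change score (`aminochange` ∈
  {0, 1, 2}).
* **17 ddg_monomer features**: for each Rosetta score term *t* (16
  components + `total_score`), the normalized shift of the variant's
  best-scoring decoys relative to the native ensemble,

  z_t = ( mean(variant_t) − mean(native_t) ) / sd(native_t).

* **83 FastRelax features**: for each of 20 score terms, four ensemble
  statistics (normalized mean shift, normalized minimum shift, the native
  quantile of the variant mean, and the native-range overlap fraction),
  plus three whole-ensemble statistics on `total_score`.
* **1 surface feature**: the PROBE accessible surface area at the variant
  position.

Classification is sparse logistic regression:

P(deleterious | x) = σ( β₀ + Σ_j β_j z_j ),

where the z_j are the selected features standardized by training-set
center/scale. The feature subset (at most 20) is chosen by **stability
selection**: L1-penalized logistic fits over 100 protein-level subsamples
across a 25-point lambda grid, keeping features selected in ≥60% of
subsamples at some penalty. Scores above 0.5 (strictly) are labelled
deleterious, and each call carries a physical interpretation summing the
per-feature contributions into categories (packing, hydrogen bonding,
disulfide, backbone, solvation, electrostatics, surface, global).

Variants without a usable structural model are routed automatically to a
sequence-only classifier fitted on the 5 PSSM features.

## Worked example

Generate a synthetic labeled dataset with a planted signal on 3 of the 106
features, select features, fit and evaluate on a held-out protein-level
split:

```r
library(delvar)
planted <- c(pssm_diff = 2, ddg_total_score = 2, relax_fa_rep_mean = 2)
d <- generate_labeled_dataset(informative = planted, seed = 1)   # 200 proteins x 5 variants
sel <- stability_select(d, seed = 2)
head(sel, 5)
#> "pssm_diff" "ddg_total_score" "relax_fa_rep_mean" "relax_fa_elec_mean" "relax_pro_close_mean"

split <- protein_level_splits(d$protein, n_splits = 1, seed = 3)[[1]]
fit <- delvar(d[split$train, ], features = sel)
fit
#> deleteriousness classifier (combined mode)
#>   20 features, fitted on 800 variants in 160 proteins
#>   intercept 2.2531; ridge lambda 0.001

test <- d[split$test, ]
roc_pr(predict(fit, test), test$label)
#> evaluation curves: AUROC 0.9937, AUPR 0.9961 (201 ROC points)

precision_at_cutoff(predict(fit, test), test$label, 0.95)$precision
#> 1
```

All three planted features are recovered, the classifier generalizes to
held-out proteins (AUROC 0.994), and filtering by confidence raises
precision to 1.0 on the variants scoring above 0.95. Interpreting
individual predictions:

```r
preds <- classify_variants(fit, test[1:3, ])
interpret_predictions(preds)[[1]]
#> predicted deleterious (0.997); evidence: global
```

For real inputs, `run_predict()` (or the `inst/scripts/delvar` command-line
wrapper) orchestrates the full pipeline: PSSM parsing, structure
standardization and variant mapping, score-file parsing and
native-ensemble normalization, routing to the combined or sequence-only
model, and a predictions TSV with per-variant interpretations. See the
methods vignette (`vignettes/delvar-methods.Rmd`) for the model's
assumptions and numerical choices.

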