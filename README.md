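# cmot — cross-modality optimal transport for single-cell multi-omics

Most single-cell datasets measure one molecular modality, yet analyses
increasingly need several. `cmot` infers the **missing modality** of cells
profiled in only one: trained on source cells carrying both modalities —
gene expression and chromatin accessibility, or transcriptome and surface
proteins — it predicts the unobserved profiles of target cells measured
only in the shared modality. It is aimed at computational biologists
working with 10x Multiome / CITE-seq / sci-CAR-style data who want
cross-modality imputation without requiring every cell to be jointly
profiled.

## Method

Three stages, each exposed as ordinary R functions:

1. **Alignment** (`align_modalities()`, only needed when source cells are
   partially corresponding): a nonlinear manifold alignment of the two
   source modalities X and Y. With K-NN similarity graphs `W_X`, `W_Y` and
   a binary correspondence matrix `W` covering a fraction *p* of cells, the
   joint graph-Laplacian eigenproblem `L v = γ D v` under the constraint
   `PᵀDP = I` yields a shared d-dimensional embedding that preserves each
   modality's local geometry (weight `μ`) while pulling corresponding
   cells together (weight `1 − μ`).
2. **Optimal transport** (`sinkhorn()`, `sinkhorn_label_reg()`): an
   entropically regularized coupling `π` between source and target cells on
   the shared modality,
   `min ⟨π, C⟩ + ε Σ π log π + η Σ_j Σ_c ‖π(I_c, j)‖₁^½`,
   solved by stabilized Sinkhorn scaling with
   majorization–minimization for the group-lasso label term (labels are
   known cell types, or clusters induced by `induce_labels()`). Poorly
   mapped target cells are flagged from `P = π*ᵀ ∘ Cᵀ` by PCA + isolation
   forest, and source cells are barycentrically mapped into target space
   (`barycentric_map()`).
3. **Inference** (`knn_infer()`): each target cell's missing-modality
   profile is the weighted average of its k nearest transported source
   cells, with weights `w ∝ exp(−‖ŷ − y‖)` normalized to sum to one.

`run_cmot()` chains all stages; `generate_multiome()` provides a coupled
two-modality synthetic generator with known ground truth; the evaluation
module implements cell-/feature-wise Pearson correlation, one-sided
Wilcoxon rank-sum tests, AUPRC with its positive-rate baseline, peak-wise
AUROC and silhouette scores.

## Worked example

```r
library(cmot)

sim <- generate_multiome(synthetic_spec(n_source = 200, n_target = 100, seed = 1))
res <- run_cmot(sim$X, sim$Y, sim$Yhat, labels = sim$labels,
                lambda = 50, eta = 1, k = 10, d = 5, seed = 1)

print(res)
r_cell <- cellwise_pearson(res$Xhat, sim$Xhat_true)
r_gene <- featurewise_pearson(res$Xhat, sim$Xhat_true)
sil    <- silhouette_scores(res$Xhat, sim$target_labels)
```

Output:

```
<InferenceResult> inferred 100 cells x 50 features (k = 10)
  17 target cells flagged as poorly mapped
median cell-wise r:  0.988
median gene-wise r:  0.857
median silhouette by true cluster: 0.722
```

The inferred matrix `res$Xhat` recovers the held-out ground truth with a
median per-cell correlation of 0.988 on this low-noise fixture, and its
rows cluster by the true cell types (median silhouette 0.72). The
isolation-forest filter errs on the side of caution with `contamination =
"auto"` — the 17 flagged cells here are borderline mappings on clean data;
flags are advisory and the cells are still inferred.

A shell entry point mirrors the R API
(`inst/cli/cmot simulate|align|transport|infer|evaluate|run`), reading and
writing delimited text or matrix-market matrices with id sidecars.

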