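# morphgcn

Classification of multiple-sclerosis clinical forms from **morphological
brain connectivity**: graphs built from regional cortical-thickness
distributions, classified with a compact graph convolutional network (GCN).

MS evolves along distinct clinical courses — relapsing-remitting (RR),
secondary-progressive (SP), primary-progressive (PP) — and separating them
from conventional T1-weighted MRI alone is a hard, clinically useful
problem. Cortical gray-matter atrophy patterns carry that signal. This
package implements the full downstream pipeline for researchers who already
have vertex-level cortical thickness (e.g. from a FreeSurfer-style surface
pipeline) or region-level summaries:

1. **Region features** — each of the N atlas regions (Desikan-Killiany 68,
   Destrieux 148, Glasser 360) is summarized by the first four moments of
   its thickness distribution, x_i = (μ_i, σ_i, γ_i, k_i), giving a feature
   matrix X ∈ R^{N×4} per scan.
2. **Age/sex normalization** — fitted on healthy controls only: either the
   *proportional* correction (per-sex OLS of whole-brain thickness on age,
   Cth = a·age + b; scans rescaled to age 20 by α = Cth20/Cth with
   Cth20 = 20a + Cth − a·age) or the *residual* correction (per sex, region
   and statistic, the residual r = (a·age + b) − x).
3. **Graph generation** — edge weights are pairwise dissimilarities between
   region vectors, Mahalanobis d_M(x_i,x_j) = ((x_i−x_j)ᵀS⁻¹(x_i−x_j))^{1/2}
   (S estimated per scan from its N region vectors) or taxicab
   d_T = Σ_k |x_ik − x_jk|. A per-scan rejection quantile τ removes the
   lowest distances, so every subject keeps the same graph density.
4. **GCN classification** — H^(l+1) = ReLU(D̃^{-1/2}(A+I)D̃^{-1/2} H^(l) W^(l) + b^(l)),
   three 64-channel layers, global mean pooling, dropout 0.3, affine head:
   exactly **8835** trainable parameters for a 3-class task. Training is
   explicit backpropagation with Adam (lr 0.001) implemented in matrix
   algebra — no deep-learning framework required, fully seeded.
5. **Evaluation** — six clinical tasks, patient-grouped stratified 5-fold
   cross-validation (no patient ever straddles train and test), weighted
   and macro precision/recall/F1, and the full 72-cell experiment grid
   (3 atlases × 2 distances × 4 thresholds × 3 normalization modes).

Because cohorts of this kind are private, the package ships a first-class
**synthetic cohort simulator** (vertex-level thickness with healthy aging,
sex effects, class-specific regional atrophy, longitudinal visits and
patient random effects) that reproduces the study-scale cohort structure
(42/21/28 RR/PP/SP patients with 299/143/218 scans; 335 healthy reference
scans) and makes every stage testable end to end.

## Worked example

A small two-class cohort with one-vertex-SD thinning in 10% of regions for
the PP-like class, residually normalized, classified at the pipeline's
best-performing operating point (Mahalanobis, τ = 0.8). Runs in about two
minutes on one CPU.

```r
library(morphgcn)

base <- sim_config(atlas_size = 68, vertices_per_region = 50, seed = 42)
cfg <- sim_config(atlas_size = 68, vertices_per_region = 50, seed = 42,
                  n_patients_per_class = c(RR = 12, PP = 12),
                  scans_per_class = c(RR = 60, PP = 60),
                  class_effect = list(
                    RR = list(regions = integer(0), effect_mm = 0),
                    PP = list(regions = 1:7,
                              effect_mm = standardized_effect_mm(base, 1))))
cohort <- simulate_cohort(cfg)
cohort
#> scan_cohort: 120 scans, 24 patients, 68 regions
#> PP RR
#> 60 60

parc <- parcellation("desikan-killiany")
feats <- featurize_cohort(cohort, parc)
round(feats[[1]][1:3, ], 3)
#>      mu sigma gamma     k
#> 1 2.682 0.287 0.179 2.329
#> 2 2.726 0.390 0.761 3.405
#> 3 2.014 0.289 0.510 2.940

# healthy reference sharing the same regional baselines
hcfg <- sim_config(atlas_size = 68, vertices_per_region = 50, seed = 42,
                   baseline_mean_mm = cohort$baseline_mean_mm)
healthy <- simulate_healthy_reference(hcfg, n_subjects = c(amsep = 21, ixi = 100))
rmodel <- fit_residual(featurize_cohort(healthy, parc), healthy$metadata)
featsr <- normalize_features(feats, cohort$metadata, "residual", rmodel)

graphs <- lapply(featsr, build_brain_graph, metric = "mahalanobis", tau = 0.8)
graphs[[1]]
#> brain_graph: 68 nodes, 456 edges (metric=mahalanobis, tau=0.8)

count_parameters(gcn_model(2))
#> [1] 8770

rep <- cross_validate_gcn(graphs, cohort$metadata, "RR_vs_PP", k = 5,
                          config = train_config(epochs = 150, patience = 20,
                                                seed = 1),
                          seed = 1)
rep
#> metrics_report: RR_vs_PP ( 5 folds )
#>   weighted precision 0.869 +/- 0.111
#>   weighted recall    0.806 +/- 0.196
#>   weighted f1        0.781 +/- 0.237
```

The 456 edges are the top 20% of the 68·67/2 = 2278 pairwise distances —
the same count for every scan by construction. The cross-validated weighted
F1 of 0.78 ± 0.24 is obtained from only 24 patients; the package-level
benchmark at the full 60-patient scale (`signal_recovery_benchmark()`)
reaches F1 ≈ 0.99, and drops to chance when the simulated effect is removed.
Without the residual normalization the same cohort classifies far worse —
regional atrophy is masked by between-subject and age-related global
variation, which is exactly what the normalization stage removes.

Larger experiments run through `run_experiment_grid()` (any sub-grid of the
72 configurations) or the thin CLI wrapper
`inst/cli/morphgcn.R` (`simulate`, `featurize`, `fit-norm`, `apply-norm`,
`graph`, `train`, `predict`, `evaluate`, `grid` subcommands).

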