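# triomics

Trio-structured transcriptomic analysis of immune cell composition.

`triomics` is an R package for proband-parent-control expression studies of
the kind used to dissect inherited immune phenotypes (the motivating case is
cystic fibrosis: an affected child, two obligate-carrier parents, unrelated
healthy controls). Given a pre-normalized log2 gene-by-sample matrix and
per-sample metadata, it provides the full analysis chain:

- **Moderated differential expression** — empirical-Bayes variance
  shrinkage: per-gene pooled variances s²_g are shrunk toward a prior
  (d₀, s₀²) fitted by moment matching on log s²_g (trigamma inversion);
  the moderated t uses the posterior variance
  s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g) with d_g + d₀ df. DEGs must pass
  both a 2-fold gate (|log₂FC| ≥ 1) and a Benjamini–Hochberg FDR gate
  (q < 0.05), with paired within-trio contrasts paired on family.
- **Trio set logic** — trio-shared vs proband-unique DEG partitions, and a
  direction-consistent cross-model "input gene set" construction for
  enrichment queries.
- **Marker-based cell composition scores** — candidate markers are screened
  per gene by mean within-subset pairwise Pearson correlation
  (mean r > 0.50, Fisher-z p < 0.01); the raw score of a subset is the sum
  over panel groups of the simple mean of marker log2 expression.
- **Group comparisons** — unpaired pooled-variance t (trio vs HC), paired t
  (within trio), Holm–Šidák family-wise adjustment *within each score*;
  Kruskal–Wallis with Dunn's control comparisons for multi-group designs.
- **Clinical association** — Pearson r/R², simple regression against sweat
  chloride and percent-predicted FEV1; severity-subgroup comparisons.
- **Family-structure clustering** — PCA and hierarchical clustering
  (1 − Pearson r, average linkage) with a quantitative family-adjacency
  fraction and its analytic chance level.
- **Overlap enrichment** — one-sided hypergeometric tests against GMT
  collections, BH q, top-k reporting.
- **A synthetic-study generator** — trio-structured expression with known
  ground truth (Dirichlet cell mixtures, familial random effects, myeloid
  suppression in probands and carrier parents, severity-linked clinical
  covariates) used to validate every stage by recovery.

Everything is tibble-in/tibble-out and pipe-friendly, with `tidy()` /
`glance()` methods and `plot_*()` / `autoplot()` helpers.

## Worked example

```r
library(triomics)
library(dplyr)

study <- simulate_study(sim_config(seed = 42))   # 14 trios + 18 HC, 2000 genes

de <- fit_moderated(study$expression, study$metadata, contrast("proband", "HC"))
glance(de)
#> # A tibble: 1 × 12
#>   contrast      paired n_case n_ref n_genes n_deg  n_up n_down    d0 s0_sq ...
#> 1 proband_vs_HC FALSE      14    18    2000    18     0     18  5.03 0.109 ...
```

All 18 DEGs are downregulated: the generator plants a myeloid suppression
(δ = 0.8 log2 units) in trio samples, and only genes whose fold change also
clears the 2-fold gate are flagged. The fitted prior (d₀ ≈ 5, s₀² ≈ 0.11)
shows the variance moderation at work.

```r
panel  <- select_markers(study$expression, study$candidates)  # mean r > 0.5, p < 0.01
scores <- composition_scores(study$expression, panel)
compare_scores(scores, study$metadata) |>
  filter(comparison == "parent:HC") |> arrange(p_adjusted) |> head(4)
#>   score        comparison test          estimate n_case n_ref   p_raw p_adjusted
#> 1 DC           parent:HC  t_independent   -0.892     14    18 1.49e-6 0.00000298
#> 2 macrophage   parent:HC  t_independent   -0.912     14    18 3.14e-6 0.00000943
#> 3 monocyte     parent:HC  t_independent   -0.710     14    18 1.26e-5 0.0000378
#> 4 monocyte_act parent:HC  t_independent   -0.683     14    18 3.88e-4 0.00116
```

Carrier parents show significantly lower mononuclear-phagocyte scores than
controls (negative estimates, Holm–Šidák-adjusted p), while lymphoid scores
stay quiet — the planted direction structure, recovered.

```r
correlate_clinical(scores, study$metadata) |>
  filter(score %in% c("monocyte", "macrophage"))
#>   score      covariate          n      r r_squared p_value slope intercept
#> 1 macrophage sweat_chloride    14 -0.588    0.345   0.0271 -7.30   175.
#> 2 macrophage fev1_pct          14  0.453    0.206   0.104    9.01    0.450
#> 3 monocyte   sweat_chloride    14 -0.479    0.230   0.0829  -4.40  144.
#> 4 monocyte   fev1_pct          14  0.271    0.0736  0.348    3.99   47.3
```

Lower phagocyte abundance tracks higher sweat chloride and lower lung
function in probands, with the correlation sign matching the planted
severity links. `run_study("out/", seed = 42)` drives the whole chain —
simulation to enrichment — writing deterministic TSVs.

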