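---
title: "Methods: trio-structured transcriptomic analysis with triomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio-structured transcriptomic analysis with triomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomics)
library(dplyr)
```

## The analysis problem

`triomics` implements the statistical core of a proband-parent-control
transcriptomic study design. The motivating setting is cystic fibrosis (CF):
an affected child (proband) carries two defective *CFTR* alleles, both
parents are obligate heterozygous carriers, and unrelated healthy controls
(HC) carry none. Bulk log2 expression profiles (microarray-style, assumed
pre-normalized) are compared across these groups to ask three questions:

1. Which transcripts are differentially expressed in probands and in carrier
   parents relative to controls, and how much of that signal is shared
   within families ("trio-shared") versus private to the proband?
2. Does the relative abundance of immune cell subsets - estimated from
   marker-gene expression - differ between trios and controls, and does it
   track clinical severity (CFTR mutation class, pancreatic status,
   *P. aeruginosa* infection, sweat chloride, percent-predicted FEV1)?
3. Do the resulting gene signatures overlap known gene sets (e.g.
   LPS-response signatures), assessed by hypergeometric overlap?

Every stage is a tibble-in / tibble-out function, so the pipeline composes
with the usual tidyverse verbs, and `run_study()` drives the whole chain on
simulated data.

## Moderated differential expression

Per-gene two-group comparisons use a moderated t statistic. For gene $g$,
the pooled within-group variance $s_g^2$ (with $d_g$ residual df; for paired
contrasts the variance of within-family differences) is shrunk toward a
prior $(d_0, s_0^2)$ estimated by moment matching on $\log s_g^2$: with
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, the prior df solves
$\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d_g/2)$ by Newton inversion of the
trigamma function, and $s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$.
The posterior variance is
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and
$t_g = \mathrm{log_2FC}_g / (\tilde s_g \cdot \mathrm{SE factor})$ is referred
to a t distribution with $d_g + d_0$ df. When the trigamma equation has no
positive root the prior df is infinite and the prior scale is the mean
variance. The unit tests cross-check this construction gene-by-gene against
an independent empirical-Bayes implementation (`limma::eBayes`) to 1e-10,
and against the ordinary pooled t when $d_0 = 0$.

A transcript is a DEG when it passes both gates: $|\mathrm{log_2FC}| \ge
\log_2(\text{fold threshold})$ (default 2-fold) **and** Benjamini-Hochberg
$q < 0.05$ (strict). The fold gate compounds the FDR gate, which is why the
global-null false-flag rate is essentially zero rather than 5%.
Multi-group F tests are deliberately out of scope: every reported contrast
is a two-group comparison (proband vs HC, parent vs HC, proband vs parent
paired on family), and comparisons are fitted unadjusted for covariates.

## Set logic

`venn_partition()` splits two DEG lists on a common universe into
trio-shared and unique sets. `build_input_gene_set()` follows the
three-step construction used for enrichment queries: intersect the coding
DEGs of two proband contrasts from different cellular models, intersect
with the parent contrast's DEGs, then keep genes whose fold-change
*direction* agrees across the two models (sign only - magnitude is not
compared). "Coding" includes the `multiple_complex` locus-type category,
which array annotation treats as protein-coding; this is configurable.
All three intermediate counts are reported rather than privileging one.

## Immune cell composition scoring

The deconvolution stage is marker-based, not regression-based. Candidate
markers (by default >20 per subset for the ten PBMC subsets) are screened
by within-subset coherence: for each candidate, `mean_r` is the average of
its pairwise Pearson correlations with co-subset candidates across samples,
with significance from the Fisher z transform of `mean_r` at the sample
count. A gene is kept iff `mean_r > 0.50` and `p < 0.01` (both strict).
The criterion is deliberately *per gene* (the mean of its pairwise
correlations) rather than per pair, because selection acts on genes; a
`pairwise_all` mode requiring every pairwise correlation to clear the
threshold is available.

The raw composition score of subset $k$ in sample $s$ is the **sum over the
subset's panel groups of the simple mean** of each group's marker log2
expression - for single-group panels, just the marker mean. Scores are
reported raw, in log2 units, with no simplex normalization: they are
relative abundance proxies comparable *across groups within a score*, not
absolute cell fractions. Consequences the tests exercise: adding a constant
to all expression shifts single-group scores by exactly that constant, and
scores are invariant to marker and sample order.

## Group comparisons and multiplicity

Scores are compared with unpaired pooled-variance two-sided t tests for
trio-vs-HC contrasts (normality, equal variances assumed) and paired t
tests within trios (paired on family, incomplete pairs dropped). The
special group `parent` pools fathers and mothers, one value per family
(their mean), which keeps the family the unit of independence. The
adjustment family is **all comparisons within one score**, corrected by
Holm-Sidak step-down
($\mathrm{adj}_{(i)} = \max_{j \le i}\,[1 - (1 - p_{(j)})^{m - j + 1}]$);
the number of scores is deliberately not adjusted for. Zero-variance
degenerate comparisons conservatively return p = 1 so the family stays
intact. For multi-group growth-assay-style designs, `kruskal_dunn()` runs a
tie-corrected Kruskal-Wallis gate at 0.05 followed, only on success, by
Dunn's z comparisons against the control with Bonferroni multiplication by
the number of control comparisons (the convention of common GUI statistics
software).

Clinical association uses plain Pearson correlation with the t transform of
r at n-2 df and a simple least-squares line, dropping missing covariate
pairs and excluding HC samples (their covariates do not describe disease).
Correlation p values are *not* multiplicity-adjusted by default - an
explicit, documented choice mirroring common practice when scores are
strongly inter-correlated - and `adjust = TRUE` turns Holm-Sidak on.

## Family structure

`pca_embed()` standardizes each gene and eigendecomposes the sample
covariance restricted to a gene set. `hier_cluster()` clusters samples on
`1 - Pearson r` with average linkage by default (the common
microarray-heatmap convention; both are flags, since neither choice is
canonical). The qualitative claim "samples organize by family" is made
quantitative by `family_adjacency()`: the fraction of non-HC samples whose
cophenetic nearest neighbour belongs to the same family, with the analytic
permutation-chance level $(m-1)/(n-1)$ for a family of $m$ clustered
members reported alongside.

## Overlap enrichment

`enrich()` is the offline stand-in for an MSigDB overlap query: one-sided
hypergeometric tail $P[X \ge k]$ for each set against a chosen universe
(default: all genes on the expression matrix - universe choice dominates
these p values, so it is explicit), BH q across the collection, ranking by
q, then p, then set name, and a stable `top_k()`. Gene symbols are matched
case-insensitively so lower-case array IDs meet upper-case MSigDB symbols.
Ranked/weighted GSEA with permutation nulls is a non-goal.

## The synthetic-study generator

`simulate_study()` generates the study conditions every test measures
against. For sample $s$ with mixing weights
$w_s \sim \mathrm{Dirichlet}(\alpha)$, a marker gene $g$ of subset $k$ has

$$x_{gs} = b_g + a\,\log_2(w_{ks}/\bar w_k) - \delta_f\,
\mathbf{1}[k\ \text{myeloid} \wedge s\ \text{in a trio}] + \gamma_{gf} +
\varepsilon_{gs},$$

with baseline $b_g \sim U(4, 12)$ log2 units, noise
$\varepsilon \sim N(0, \sigma^2)$, a familial effect
$\gamma_{gf} \sim N(0, \tau^2)$ shared by all members of family $f$ on a
declared background gene subset (HCs form singleton pseudo-families so
pairing logic is exercised), and a per-family suppression
$\delta_f = \delta \cdot s_f$ applied to myeloid markers of probands *and*
carrier parents. The mixture signal enters through the log-ratio of weights
rather than linear mixing, keeping the additive log2 model that the scoring
stage assumes. The severity draw $s_f$ is bimodal (0.6 or 1.4, small
jitter, mean 1), giving a clean severe/mild dichotomy: CFTR class I/II/III
versus IV is assigned from it, pancreatic status follows it with noise, and
*P. aeruginosa* infection is Bernoulli with probability increasing in it.
Sweat chloride is $100 + 20\,\delta_f$ mmol/L plus noise for probands
(10-40 for others), percent-predicted FEV1 is $95 - 35\,\delta_f$ plus
noise - linear Gaussian links, because only Pearson-correlation recovery is
tested downstream.

Defaults: 14 trio families and 18 HCs (60 samples), 2000 genes, 10 subsets
with 20 true markers and 4 decoy candidates each, $a = 1$, $\sigma = 0.3$,
$\tau = 0.6$, $\delta = 0.8$, locus-type fractions 0.45 / 0.25 / 0.20
coding / multiple-complex / noncoding. The Dirichlet concentration is a
constant 6.8 per subset. That equality is a deliberate statistical choice,
not a biological one: with a common concentration, every subset's
log-weight variance is comparable (~0.5 log2 units), which is the only
regime in which marker selection (which *needs* weight variance to create
within-subset correlation at $a = 1$) and group-difference detection (for
which weight variance is noise) both operate with margin. Real PBMC
compositions are far more skewed - T cells dominate, dendritic cells are
rare - and rare subsets would carry proportionally noisier scores; the
generator does not emulate that, nor probe-level artifacts, batch effects,
or count-based mean-variance relationships. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
additive log2 model, not performance on arbitrary real arrays.

One subtlety: with a planted suppression, a myeloid score should *not*
correlate perfectly with mixture weight alone - the score estimates marker
expression, whose ground truth is the weight log-ratio *plus* the
suppression. `score_recovery_report()` therefore reports correlation
against that full deterministic signal (`recovery_r`) as the primary
recovery metric, with the raw-weight correlation (`recovery_r_weight`)
alongside for the unsuppressed lymphoid subsets.

## Numerical and reproducibility choices

- All tables are tab-delimited UTF-8 with floats at 6 significant digits;
  `run_study()` output is byte-identical across runs with the same seed.
- BH ties are resolved by stable sorting; enrichment ranking breaks q/p
  ties by set name; merge ties in `hclust` resolve by lowest member index.
- Degenerate inputs fail loudly and specifically: duplicate IDs, non-finite
  values, sample mismatches between expression and metadata (both
  directions listed), constant profiles under correlation distance,
  all-tied Kruskal-Wallis inputs, and all-zero-variance moderation priors
  are errors; empty intermediate gene sets and markerless subsets are
  warnings with NA results.
- Test and acceptance problem sizes (2000 genes x 60 samples, 20-100 seeds
  per Monte-Carlo property, 300-1000 replicates for exact-oracle and FWER
  checks) were chosen so the full suite exercises every property at
  3-standard-error resolution while remaining desk-scale.

## Known limitations

- The moderated test assumes exchangeable gene variances around one prior;
  no mean-variance trend or robustification is fitted.
- Marker selection assumes candidate panels are supplied (or simulated);
  no reference signature matrix ships with the package, and scores are not
  absolute fractions.
- Family pooling for the `parent` group averages parents rather than
  modelling a random family effect; mixed models are out of scope.
- Clustering metrics are reported for samples only; gene dendrograms are
  not scored.
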