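---
title: "Knowledge-constrained latent variables for DNA methylation arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-constrained latent variables for DNA methylation arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methlv)
```

## The problem

Methylation BeadChip studies report a beta value — the methylated fraction,
in [0, 1] — for each of hundreds of thousands of CpG probes. Public cohorts
are preprocessed with different pipelines (and some come from bisulfite
sequencing rather than arrays), so their beta distributions carry systematic,
platform- and pipeline-specific distortions that confound joint analysis.
methlv addresses this the way transfer-learning factorizations do for
transcriptomes: learn a latent feature matrix once, on a large reference
cohort, with gene-set knowledge baked into the factors; then *freeze* it and
decompose any new cohort against it. Downstream analysis happens on the
per-sample loadings, a low-dimensional space in which much of the
platform-specific variation — anything outside the span of the frozen
factors — has been discarded, and in which each factor carries gene-set
annotation for free.

## From probes to transcript-wise features

Gene-set knowledge lives at the gene level, so probe-level data must be
compressed to gene-level features first. For each transcript we take the
probes within 1500 bp of its TSS (the promoter neighborhood most tied to
expression; `select_region_probes()`, with a strand-aware upstream-only
variant and a first-exon mode as alternatives), center each probe at its
training mean, and run a PCA with samples as observations. We keep the
smallest number of leading components whose cumulative explained-variance
fraction reaches 0.8 (`cum_threshold`). The retained eigenvectors and probe
means are the `CompressionModel`; projecting a new cohort uses the *training*
means and eigenvectors, so training and new cohorts land in the same feature
space (`project_compression()`).

Numerical conventions worth knowing:

* The window test is `|pos - tss_pos| <= window_bp`, boundary inclusive,
  coordinates 1-based. The symmetric window is the default because probes
  just downstream of the TSS (TSS200/first-exon territory) are as
  expression-linked as upstream ones; `upstream_only = TRUE` reproduces the
  array's TSS1500 convention.
* Probes missing in more than 20% of samples are dropped from their
  transcript before PCA; remaining gaps are imputed at the probe mean. PCA
  needs complete blocks and beta missingness is typically sparse; the 20%
  cut keeps badly assayed probes from distorting eigenvectors.
* Each eigenvector's sign is fixed so its largest-magnitude element is
  positive, making archives byte-stable across platforms.
* An all-constant transcript keeps one zero-variance feature (q = 1,
  explained variance defined as 1) rather than disappearing, so feature
  spaces stay aligned across refits.
* At projection time, probes absent from the new data are imputed at the
  training mean (zero after centering) and counted in the imputation
  report; a transcript with no observed probes yields `NA` features.

## The factorization

With the compressed matrix `D` (features x samples, rows standardized by
default) and a binary knowledge matrix `C` (features x gene sets, built by
`build_knowledge()` from GMT collections, every PC feature inheriting its
gene's memberships, sets with fewer than `min_genes = 10` distinct overlapping
genes dropped), `plier_fit()` solves

    min  ||D - ZB||_F^2 + l1 ||Z - CU||_F^2 + l2 ||B||_F^2 + l3 |U|_1
    s.t. Z >= 0, U >= 0

`Z` (features x k) holds the latent variables, `B` (k x samples) the sample
loadings, and `U` (sets x k) says which gene sets each latent variable
expresses. Strict positivity is implemented as the closed constraint
`>= 0` — sparse solutions necessarily sit on the boundary.

### Updates

Each iteration updates `B`, then `Z`, then `U`:

* **B** — exact ridge minimizer `(Z'Z + l2 I)^{-1} Z' D`.
* **Z** — the positive part of the unconstrained minimizer
  `(DB' + l1 CU)(BB' + l1 I)^{-1}` is the candidate. Clipping alone is not
  a descent step (it can and does climb on real fixtures), so the solver
  takes the exact minimizer of the objective along the segment from the
  current `Z` to the clipped candidate. The segment lies inside the
  non-negative cone and the objective is quadratic along it, so the step
  has a closed form and every iteration is guaranteed non-increasing.
* **U** — per latent variable, a non-negative elastic-net regression of
  `z_j` on the columns of `C`, solved by cyclic coordinate descent with
  warm starts. The displayed objective has a pure L1 penalty, but the
  elastic-net mixing `l1_fraction = 0.9` matches the glmnet-style
  hyperparameter the method is tuned with; `l1_fraction = 1` recovers pure
  L1. Since the global objective weights the fit term by `l1`, the fit
  passes `l3 / l1` as the subproblem penalty so the U step descends the
  global objective too. If a column's support exceeds `max_path = 10`, the
  largest coefficients are kept and the problem re-solved on that support.

Convergence is declared when the relative change of the solver objective
(the elastic-net-penalized one it actually minimizes; the pure-L1 four-term
value is also traced) falls below `tol = 1e-6`, up to `max_iter = 350`
iterations.

### Hyperparameters

| parameter | default | meaning |
|---|---|---|
| `k` | user-supplied | number of latent variables; no auto-selection is attempted |
| `lambda1` | `lambda2 / 2` | pull of `Z` toward `CU` |
| `lambda2` | `sigma_k(D)^2 / sigma_1(D)` | ridge on `B` |
| `lambda3` | adapted | sparsity of `U` |
| `l1_fraction` | 0.9 | elastic-net mixing of the U penalty |
| `frac` | 0.7 | target fraction of LVs with at least one gene set |
| `max_path` | 10 | gene sets allowed per LV |
| `min_genes` | 10 | distinct-gene support required per set |
| `tol`, `max_iter` | 1e-6, 350 | convergence control |

The `lambda2` auto default is scaled to the spectrum of `D`: the k-th
singular value squared over the spectral scale (largest singular value).
This keeps the penalties commensurate with the reconstruction term under
rescaling of `D`. The choice matters more than it looks: penalties of order
`sigma_k^2` collapse weak latent variables entirely (a death spiral — ridge
shrinkage of `B` starves the corresponding `Z` column, which further
shrinks `B`), while penalties of order `sigma_k` over-shrink `B` enough to
merge correlated latent variables. The spectral-ratio scale avoids both
regimes and recovers planted factors cleanly across seeds.

`lambda3` is found by geometric search: starting from the scale at which
roughly half the LV columns would shrink to zero, it is halved between
rounds of 20 iterations until at least `frac` of the latent variables carry
a nonzero gene-set weight, then frozen for the run to convergence. If
support decays below the target during that final run, the search resumes
with further halvings (at most 6). A user-supplied `lambda3` is never
adapted.

## Transfer, and what the loadings are for

`transfer_loadings()` re-solves the B step only, against the frozen `Z`:
`B_new = (Z'Z + l2 I)^{-1} Z' D_new`, after standardizing the new cohort's
feature rows with the *training* centers and scales. It is deterministic and
exactly the solver's own B update — one shared kernel, tested as such.

Downstream, the package provides the loading-space analyses practitioners
run: Ward hierarchical clustering on Euclidean distances (`hca_clusters()`),
Hartigan–Wong k-means capped at 100 iterations (`kmeans_clusters()`), UMAP
embeddings with neighbors = 15, components = 2, epochs = 200
(`umap_embed()`, via uwot), per-LV two-sided Welch t tests with
Benjamini–Hochberg adjustment across the k LVs (`differential_lv()`;
pooled-variance Student available by flag), per-probe DMP tests with BH
across the tested probe subset and hypo/hyper direction relative to a named
reference group (`dmp_test()`), and the two-group log-rank test computed
from the observed/expected/variance summation over event times
(`logrank_test()`). Welch and two-sided were chosen where the variant was
unstated; BH families follow the per-analysis convention (LV tests adjust
over LVs, DMP tests over tested probes).

`liftover_to_probes()` converts per-CpG bisulfite calls to array probe-wise
betas by exact coordinate match (forward-strand cytosine at the probe
coordinate, reverse-strand cytosine at the next base), combining strands by
coverage-weighted mean, masking probes under `min_total = 5` reads, and
reporting the matched fraction — typically low for reduced-representation
protocols, which is exactly what the coverage report is for.

## The synthetic-data generator

All tests and the acceptance analyses run on generated data with known
ground truth. `simulate_plier_dataset()` inverts the pipeline: draw a sparse
non-negative `Utrue` (each LV active in ~`u_density` of the sets), set
`Ztrue = C Utrue` plus half-normal noise (SD 0.1), draw group-structured
loadings `Btrue` (group means N(0,1), within-group SD 0.5), form the gene
signal `G = Ztrue Btrue + N(0, noise_sd)`, and emit probe betas through an
inverse-logit link of the per-gene standardized signal (slope 1.5,
per-probe offsets N(0, 0.5) — chosen so beta mass sits mostly in
[0.05, 0.95]). Probes of a gene are therefore correlated, and PCA
compression recovers `G` up to an affine transform.

Two generator choices deserve explanation:

* **Default conditions.** The standard fixture uses 120 genes, 12 sets,
  k = 6, 80 samples, `noise_sd = 0.3`, seed 17 — small enough for seconds-
  scale tests, large enough that compression, knowledge filtering and the
  factorization all operate nontrivially. `u_density = 0.25` (about 3
  active sets per LV) reflects that a latent methylation program typically
  expresses a handful of related gene sets, not one and not most.
* **Support overlap is bounded.** Active-set supports are drawn with at
  most `n_active - 2` sets shared between any two LVs. Unconstrained
  draws occasionally plant two latent variables whose `Ztrue` columns
  correlate at 0.7: such near-collinear factors are not identifiable by
  *any* method, and a recovery benchmark built on them measures luck, not
  correctness. Bounding the overlap keeps planted factors mutually
  distinguishable, which is the property a planted-truth oracle must have.

What the generator does *not* emulate: array chemistry (type I/II probe
bias), preprocessing artifacts, spatial correlation along the genome beyond
shared gene signal, realistic LD-like probe dependence, or cell-type
mixture. Passing tests therefore demonstrate correctness of the algorithms
under the stated generative model, not performance claims on real cohorts.

`simulate_survival()` generates exponential event times with a group hazard
ratio and independent exponential censoring calibrated to a target censored
fraction; it is used to verify the log-rank test's null calibration
(uniform p, ~5% type-I error) and power.

## Scale of the built-in analyses

The test suite and the acceptance script run the default fixture
(600 probes, 80 samples, k = 6), twenty random ridge-oracle instances,
exhaustive log-rank checks on all two-group layouts of up to six subjects,
and 500-replicate null calibrations — sizes chosen so the whole analysis
reruns in a couple of minutes while still exercising every code path at
meaningful problem dimensions.

## Known limitations

* `k` must be chosen by the user; the method offers no selection rule.
* The factorization objective is non-convex; the solver guarantees
  monotone descent and deterministic results for a fixed seed, not a
  global optimum. Planted-recovery results show the default penalties work
  well on identifiable problems, but heavily correlated true factors will
  still be merged or rotated.
* Per-column support truncation (`max_path`) is a hard combinatorial
  constraint; the re-fit after truncation is locally optimal on the kept
  support, and in pathological cases the truncation step itself may not
  decrease the objective (the only step with that caveat).
* The liftover is an exact-coordinate join; it does not remap assemblies,
  and the choice to merge opposite-strand CpG calls (coverage-weighted) is
  a convention — forward-only analysis requires pre-filtering the calls.
* UMAP coordinates are reproducible for a fixed seed but, like all SGD
  layouts, are not a metric embedding; exact duplicates land near- but not
  exactly-coincident.
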