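---
title: "Methods: stress-pathway gene-set profiling of pseudobulk Perturb-seq data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stress-pathway gene-set profiling of pseudobulk Perturb-seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbstress)
```

## The data model

The unit of analysis is a pseudobulk perturbation × gene matrix of
z-normalized expression. Each entry is a gene's pseudobulk expression in
one CRISPRi perturbation, expressed in standard deviations relative to the
mean and SD of a control-sgRNA group from the same 10X gemgroup (library
preparation batch). Under the null — a perturbation that leaves a gene's
expression untouched — z is approximately standard normal; a planted or
biological effect appears as a mean shift on the z scale, in control-SD
units. Per-perturbation metadata carry the targeted gene and the fraction
knockdown; per-gene metadata carry class flags, by default an
`mtdna_encoded` flag derived from the standard human `MT-` symbol prefix
(overridable with `annotate_gene_classes()`).

Two on-disk dialects are supported: a three-file TSV sidecar layout whose
`%.17g` serialization round-trips doubles bit-identically (the fixture
dialect — tests need no HDF5 tooling), and the AnnData `.h5ad` HDF5 layout
used by published pseudobulk resources, with `fraction knockdown` read from
`obs`. Because resource versions differ on whether perturbations are rows
or columns, the reader sniffs orientation by matching matrix dimensions
against the `obs` index length and logs the decision.

## Gene-set scoring and its assumptions

A pathway's activation in a perturbation is summarized by the **activation
score**: the arithmetic mean z of the pathway's target genes. The score is
location-equivariant (shifting every set gene by δ shifts the score by
exactly δ), order-independent, and blind to genes outside the set — the
properties the test suite asserts.

Significance is assessed against a designated **control gene set** of
stably expressed genes, per perturbation, treating the set's z-values and
the control's z-values as two samples:

* `p_value`: Welch's unequal-variance two-sample t test for a mean shift.
* `bf_p_value`: the Brown–Forsythe test — the Levene test centred at group
  medians — for a difference in spread. We read "Brown–Forsythe" as the
  variance test (its role is detecting statistically different SDs), not
  the Brown–Forsythe ANOVA on means.
* `omnibus_test()`: the k-group Welch heteroscedastic ANOVA across all
  panels plus control, with Games–Howell post hoc contrasts of each
  pathway against control. Games–Howell was chosen as the standard
  unequal-variance companion to Welch's ANOVA; the implementation
  (studentized range on Welch–Satterthwaite df) is a small self-contained
  function and is straightforward to swap for Dunnett T3 if preferred.

The two-group test is the volcano p-value (each pathway is compared to the
control panel directly); the omnibus form serves multi-panel bar-style
comparisons. Both are provided because figure-level usage of the two is
conventionally interchangeable.

The key inferential assumption is independence of gene-level z-values
within a set. Co-regulated target genes are positively correlated in real
data, which makes the Welch test anticonservative there; the generator's
correlated-module mode (below) exists to quantify that.

**Degenerate-variance conventions.** Batch scoring over thousands of
perturbations must not abort on pathological rows: if both groups are
constant and equal, p = 1; constant and unequal, p = 0; a spread-free pair
of groups has equal spreads, so the variance test returns p = 1. These
conventions are unit-tested and surface as values, never exceptions.

**Tunable parameters.** α defaults to 0.05 (0.01 and 0.005 being the
conventional asterisk tiers); no multiple-testing adjustment is applied by
default, with Benjamini–Hochberg available via `adjust = "BH"` (applied
within pathway, across perturbations — when enabled, the table's `p_value`
column and the significance calls are the adjusted values).
`map_to_panel()` restricts sets to the measured panel and flags sets below
`min_fraction = 0.5` coverage with a warning (a hard error only at zero
coverage); matching is exact string equality after uppercasing, with no
alias resolution, so joins are deterministic and auditable.

## Transcriptome-wide comparison

`filter_by_z()` implements the union rule with strict inequality: a gene
enters the comparison if |z| > threshold (default 0.5) in *either*
perturbation. Strictness matters only on ties and is pinned by tests; the
filter is antitone in the threshold. `regress_perturbations()` then fits
ordinary least squares of one profile on the other over the filtered
genes; the first-named perturbation is the explanatory axis, R² being
orientation-free. A zero-variance explanatory axis yields a flagged
undefined fit. Grouped comparisons average member perturbations gene-wise
(`group_profile()`) *before* filtering and regression; per-member
regressions remain available by calling `regress_perturbations()` per
member.

`pca_perturbations()` wraps `prcomp` with observations = perturbations,
centring genes and not scaling by default: z-scores already share a scale,
and variance-scaling would equalize informative and noise genes. Variance
fractions are the normalized squared singular values; component signs are
arbitrary; a constant input matrix yields a flagged degenerate result.

## The synthetic generator

The generator emulates the structure the analysis assumes, not the full
messiness of real screens. A `synthetic_spec()` fixes the gene panel
(every gene-set member, a 13-gene `MT-` block standing for the
protein-coding mtDNA transcripts, anonymous filler up to `n_genes = 2000`),
the gemgroup layout (4 gemgroups × 50 control sgRNAs), the noise SD
(1, the null-model value), and the perturbation classes. The default
classes encode the canonical selectivity patterns of stress-pathway
biology in K562 CRISPRi data:

| class | planted shifts | reading |
|---|---|---|
| `mito_like` | ISR +1.5; mtDNA −0.8 | mitochondrial proteostasis factor depletion |
| `er_like` | UPR +1.5; ISR +0.5 | ER proteostasis factor depletion (PERK arm gives the weak ISR echo) |
| `keap1_like` | OSR +1.5 | loss of the NRF2 repressor |
| `uba1_like` | HSR +1.5 | proteasomal stress |
| `eif2b_like` | ISR +1.5 | ISR induction via ternary-complex starvation |
| `null` | none | no effect |

Effect size 1.5 gives high per-perturbation power for 10–20-gene panels
against a 19-gene control at α = 0.05, while 0.5 is deliberately
under-powered — the ER-like class's weak ISR component is *meant* to be
called at an intermediate rate, which is exactly what the selectivity test
asserts (≥90 % for full-strength shifts, ≤10 % for unplanted pathways,
strictly between for the weak plant). Knockdown fractions are drawn from a
Beta(5, 2) independent of effect size, so the knockdown-independence check
has a true null.

`simulate_raw()` produces raw-scale expression (per-gene Gaussian
baselines with log-normal spreads) in which planted effects are injected
in units of the per-gene control SD; `z_normalize()` then applies the
per-gemgroup control normalization using the **sample SD (n − 1)**
convention — stated explicitly because published resources do not print
theirs. Re-normalizing a control group against itself gives exactly mean 0
and SD 1 per gene per gemgroup, an identity the tests check to 1e−12.
`simulate_study(scale = "z")` instead plants effects directly on the z
scale (z = δ + noise): the idealized model, free of the small
finite-control-group artefacts of the raw route (the sample-SD estimate in
the denominator inflates scores multiplicatively by ≈ 1 + 3/(4·(n_c − 1))
and correlates perturbations sharing a gemgroup's controls). Calibration
and effect-recovery checks use the z-scale mode; the raw mode exercises
the normalization machinery end to end at looser, empirical-SE tolerances.

An optional correlated-module mode (`module_cor` = λ) adds a shared
per-set latent factor with loading λ, scaling idiosyncratic noise by
√(1 − λ²) to preserve marginal SDs — a stress test for the independence
assumption above. What the generator does **not** emulate: heavy-tailed
per-gene z distributions, count-level (UMI) noise, guide-assignment
errors, or gene–gene correlation outside the planted modules. Passing
tests therefore demonstrate correctness of the computations and
calibration under the stated model, not robustness to every property of
real screens.

Determinism: every simulation entry point seeds R's default RNG
(Mersenne-Twister) from `spec$seed` and draws in a fixed order, so a fixed
seed reproduces output bit-for-bit.

## Problem sizes and numerical tolerances

The test suite runs at desk scale, chosen to keep the full suite under a
minute while leaving comfortable statistical margins: 1,000 null
perturbations for type-I calibration (3 binomial SEs around α); 500
perturbations per planted δ ∈ {0.5, 1.0, 2.0} for recovery (|bias| < 4 SE);
the default 360-perturbation study across 3 seeds for selectivity; 20–40
two-profile draws of 2,000 genes for null-pair regression. Statistical
kernels are compared with independent textbook-formula oracles
(Welch–Satterthwaite t, Welch's 1951 ANOVA, median-centred Levene F,
normal-equation OLS) at 1e−10; exact identities (normalization, PCA
spectra) at 1e−10 to 1e−12. `scripts/acceptance.R` recomputes the same
quantities from scratch at the same sizes.

## Design choices and limitations

* The packaged panels (`stress_genesets()`) are curated reference sets:
  13 ATF4-driven ISR targets, a 20-gene UPR panel that is the union of
  10-gene ATF6 and IRE1/XBP1s arms, 12 HSF1 targets (HSR), 12 NRF2 targets
  (OSR), and 19 stably expressed control genes. They ship as an editable
  GMT file (`inst/extdata/stress_genesets.gmt`); any collection in GMT
  format can replace them. The shipped proteostasis factor list is a small
  synthetic stand-in (named accordingly) illustrating the factor-list
  interface; real analyses should supply their own curated TSV.
* Gene sets are treated as inputs; the package does not attempt to derive
  or refine them, nor to test gene-level differential expression.
* Pathway sets other than the UPR/arm triplet are kept pairwise disjoint
  in the packaged collection so that planted-shift closure (unplanted
  pathways score 0 in expectation) holds exactly; user collections with
  overlapping sets are legal, but overlap couples their scores.
* No clustering, GO enrichment, or single-cell-level processing: the
  pseudobulk z matrix is the modeling boundary.
* The interface is R functions plus `run_pipeline()` for orchestration;
  every plotted quantity is also written as TSV, and each run writes its
  resolved configuration, log, seed and input checksums beside the
  outputs.
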