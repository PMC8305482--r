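---
title: "Annotation-refined polygenic risk scores: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-refined polygenic risk scores: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adprs)
```

## The model

A polygenic risk score aggregates many small genetic effects into one
number per person. Given GWAS summary statistics — for variant $i$ an
effect allele, a log odds ratio $\beta_i$, a p-value $p_i$ and an effect
allele frequency — and a genotype panel with dosages
$x_{ij} \in [0, 2]$, the conventional score is

$$ S_j = \sum_{i \in \mathcal{R}(t)} \beta_i \, x_{ij}, $$

where $\mathcal{R}(t)$ is the set of variants surviving LD thinning and a
p-value threshold $t$. `adprs` refines the per-allele weight to

$$ w_i = \beta_i \; g_i \, f_i \, s_i, $$

with three annotation multipliers:

* **Gene proximity** $g_i$: `gene_locus_bonus` if the variant falls within
  `gene_window_bp` of at least one curated disease gene, else 1. The
  bonus is applied at most once per variant regardless of how many genes
  overlap: risk loci cluster, and a variant sitting amid several curated
  genes — or several haplotypes of one region — carries no more
  *independent* evidence than one hit, so stacking would re-introduce
  exactly the co-inheritance bias the layer exists to counter.
* **Functional impact** $f_i$: a tier ladder, first match wins.
  Missense changes that create or destroy a post-translational
  modification site can rewire signalling, hence the top multiplier;
  plain missense changes alter protein sequence, hence the second; for
  non-coding variants, joint overlap with open chromatin *and* an eQTL in
  a disease-relevant tissue is the strongest regulatory evidence, a
  single overlap weaker. Tissue matters: an overlap in liver says little
  about a neurodegenerative phenotype, so overlaps outside
  `tissue_filter` (default `brain`) count as none. Coding tiers take
  precedence over regulatory tiers — coding and regulatory evidence are
  different branches, and a missense variant's chromatin context is not
  what makes it functional.
* **Severity** $s_i$: GWAS-catalog traits for the same disease can encode
  clinical severity. Variants reported only for the severe trait
  (Alzheimer's disease, EFO_0000249) receive `severity_bonus`; variants
  unique to the milder late-onset trait (EFO_1001870) receive
  `severity_penalty`; variants in both sets, or in neither, are neutral.
  The three sets are a disjoint partition of the catalog union, built by
  plain set algebra in `build_severity_sets()`.

**Why multiplicative?** The source ideas are phrased as bonuses and
penalties without an algebra. A product on $\beta_i$ has three properties
we consider essential: the identity configuration (all multipliers 1)
reduces the refined score to the baseline *exactly*, sign is preserved —a
protective allele stays protective under any positive multiplier — and
layers compose without order dependence. An additive scheme has none of
these.

**Default magnitudes.** The layer magnitudes (1.5 gene bonus, 2.0/1.5
missense tiers, 1.5/1.25 regulatory tiers, 1.5/0.5 severity
bonus/penalty) are benchmarking defaults, chosen to be moderate (within
the range of annotation enrichments reported across the functional-PRS
literature) and strictly ordered by evidence strength. Nothing in the
package depends on their exact values; all are `weight_config()` fields.

## Conventional machinery

*Harmonization* drops summary-stat variants absent from the panel and —
by default — strand-ambiguous A/T and C/G variants, which cannot be
oriented without strand metadata (standard PRS hygiene). *LD* is the
squared Pearson correlation of dosage columns, estimated from the
analysis cohort itself (no external reference panel is supported; using
the scored cohort is the conservative desk-scale choice). *Clumping*
greedily retains the smallest-p variant and removes its correlated
neighbours (same chromosome, within `clump_window_bp`, $r^2 \ge$
`clump_r2`); ties on p break by position then id so results are
platform-deterministic. Removed variants are gone for good — the
annotation layers act on retained variants only. *Pruning* is offered as
the frequency-driven alternative: greedy by descending MAF, keeping a
variant only if its $r^2$ with every kept variant is below threshold (no
positional window; the rule is purely correlation-based). *Thresholding*
scans `p_thresholds` and, when training labels are available, keeps the
threshold with the best training AUC per arm — a pragmatic choice at desk
scale; a nested validation split would cost more simulation time than the
Monte-Carlo noise it removes. Missing dosages are imputed as $2 \times$
EAF, the population mean under Hardy–Weinberg equilibrium.

Internally every coordinate is 1-based closed (the VCF and summary-stat
convention); BED input is converted at the boundary and back on write, so
the conversion is self-inverse.

## What the simulator emulates — and what it does not

`simulate_cohort()` is the test bed: it must produce realistic-enough
LD-blocked genotypes, a binary phenotype with known genetic architecture,
a GWAS, and annotation tracks whose alignment with causality is under
experimental control.

* **Genotypes.** Each haplotype is a latent standard-normal vector with
  block-diagonal AR(1) correlation ($\rho^{|i-j|}$ within blocks of
  `block_size` variants, default $\rho = 0.8$, independence across
  blocks); the allele is present iff the latent value falls below the
  frequency quantile, and the dosage is the sum of two independent
  haplotypes — so Hardy–Weinberg holds exactly, which is also what makes
  the allelic (trend) chi-square test calibrated. The latent-Gaussian
  construction was chosen over coalescent simulation because it gives
  closed-form control of LD and frequency at desk scale.
* **Spacing.** Variants sit 10 kb apart on one chromosome. A 10-variant
  block then spans 90 kb — inside the default 250 kb clump window, so
  clumping can see a whole block — while the 50 kb gene window reaches
  about ±5 variants, i.e. proximity annotation stays aligned with the LD
  structure instead of leaking across blocks.
* **Phenotype.** Liability = standardized-genotype genetic value, scaled
  within the cohort so its variance is `h2_liability`, plus
  $N(0, 1 - h^2)$ noise; case iff liability exceeds the prevalence
  quantile (default prevalence 0.2, typical of an enriched case-control
  design rather than population incidence).
* **GWAS.** Per variant, a 2×2 allele-by-status table; $\beta$ is the log
  allelic odds ratio (0.5 added to all cells only when a cell is zero —
  the standard Haldane–Anscombe usage, which keeps hand-computable tables
  exact) and the p-value is the 1-df allelic chi-square. No iterative
  optimizer: deterministic and fast.
* **Annotations.** Independently per layer, causal variants receive the
  favorable annotation with probability `p_annot_causal` (default 0.9)
  and non-causal with `p_annot_null` (0.1); the mild-trait penalty layer
  is anti-aligned (non-causal variants hit with 0.9). A favored
  functional variant draws one of the four favorable tiers uniformly so
  every code path is exercised. Setting both probabilities equal makes
  annotation independent of causality — the neutrality control.

Not emulated: recombination-map realism, population structure,
imputation noise, covariates, strand errors, or annotation errors
*correlated across layers*. Passing benchmarks therefore show that the
refinement exploits informative annotations and is harmless under
uninformative ones *within this generative family* — not that any real
annotation resource has informativeness 0.9/0.1.

## Evaluation

AUC uses the Mann–Whitney mid-rank formulation (exactly
$P(\text{case} > \text{control}) + \tfrac12 P(=)$, invariant to monotone
transforms). Nagelkerke $R^2$ rescales the likelihood ratio of a
univariate logistic fit (IRLS, 100-iteration cap); complete separation is
flagged and reported as 1. The quantile contrast is the top-vs-bottom
quintile odds ratio with the same only-on-zero-cells 0.5 correction;
quantile boundaries are score ranks with ties broken by sample order
(documented, deterministic). `compare_pipelines()` reports paired
(same-replicate) differences, which cancels most of the between-replicate
Monte-Carlo variance.

## Problem sizes and numerical choices

The shipped tests run the full benchmark at the default study conditions
(2000 training / 1000 test samples, 1000 variants, 50 causal,
$h^2 = 0.5$, prevalence 0.2, 25 replicates per annotation regime) and the
calibration checks at $n = 3000$–$5000$; smaller fixtures (tens of
variants) drive the unit and oracle tests. Degenerate inputs are handled
explicitly: monomorphic variants get $r^2 = 0$ off-diagonal, chi-square
NaNs become $p = 1$, p-values are floored at $10^{-300}$ to respect the
$(0, 1]$ contract, observed frequencies are clamped away from 0 and 1,
and `h2_liability = 0` zeroes the genetic value exactly rather than
scaling by $0/0$.

## Open choices resolved here

The data-fusion join uses `gene_id` only; symbols and aliases are
ambiguous and are never used as keys. Gene spans are required for
proximity weighting even though a curated map location string would not
provide them — span columns are part of the gene-table schema and the
simulator emits them. Whether weights should act on $\beta$, on the final
score, or on inclusion probability was genuinely open; acting on $\beta$
is the only option compatible with the identity reduction and with
per-variant auditability (`weight_audit()` exposes
$\beta, g, f, s, w$ per variant). The curated gene table's size is
treated as data-dependent throughout: no count is hard-coded, and the
fusion obeys the conservation invariant
$|merged| = |gene\text{-}only| + |protein\text{-}only| + |shared|$.

## Known limitations

Cohort-estimated LD only; no Bayesian shrinkage weights (LDpred-style);
no PTM prediction (the PTM flag is an input annotation); no survival
modelling or covariate adjustment in evaluation; severity is a binary
two-trait contrast, though the multiplier interface would admit finer
grading. These bound the claims: the package demonstrates the weighting
architecture and quantifies when it helps, on synthetic cohorts whose
assumptions are stated above.
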