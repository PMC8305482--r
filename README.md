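# adprs

Annotation-refined polygenic risk scores (PRS) for Alzheimer's disease.

## The problem

A conventional PRS sums a person's risk-allele counts weighted by GWAS log
odds ratios, after p-value thresholding and LD thinning:

    S_j = sum_i  beta_i * x_ij ,    x_ij in [0, 2]

where `beta_i = log OR_i` for the effect allele of variant *i* and `x_ij`
is the dosage of that allele in sample *j*. This treats a co-inherited
passenger SNP, a missense SNP at a phosphorylation site, and a SNP seen
only in a mild-phenotype GWAS identically. `adprs` refines the weight of
each retained variant with three multiplicative annotation layers:

    w_i = beta_i * g_i * f_i * s_i

* **g — gene proximity**: `gene_locus_bonus` (default 1.5) if the variant
  lies within `gene_window_bp` (50 kb) of a curated disease gene; applied
  at most once however many genes overlap, so clustered loci cannot stack.
* **f — functional impact**: tiered, first match wins — missense hitting a
  post-translational-modification site (2.0), other missense (1.5),
  non-coding overlapping *both* open chromatin and an eQTL in a filtered
  tissue such as brain (1.5), exactly one of the two (1.25), otherwise 1.
* **s — phenotype severity**: variants unique to the severe trait
  (Alzheimer's disease, EFO_0000249) get `severity_bonus` (1.5); variants
  unique to the milder late-onset trait (EFO_1001870) get
  `severity_penalty` (0.5); variants in both, or in neither, stay neutral.

With every multiplier set to 1 the refined score equals the baseline PRS
bit for bit. The package also implements the gene/protein data-fusion step
that builds the curated, Origin-annotated gene table, a liability-threshold
case-control simulator with LD-blocked genotypes and tunable annotation
informativeness, and an evaluation harness (AUC, Nagelkerke R², top-vs-
bottom-quintile odds ratio) that benchmarks refined against baseline.

It is aimed at statistical geneticists who want to prototype and stress-test
annotation-weighted PRS construction on simulated cohorts before committing
to a real-cohort analysis.

## Worked example

```r
library(adprs)

params <- sim_params(n_train = 300, n_test = 150, m_variants = 60,
                     n_causal = 6)
co  <- simulate_cohort(params, seed = 7)
sev <- build_severity_sets(co$tracks$catalog)
ann <- build_variant_annotations(co$sumstats, co$tracks$genes,
                                 co$tracks$consequences,
                                 co$tracks$open_chromatin,
                                 co$tracks$eqtl, sev)

fit <- prs_fit(co$sumstats, co$dosages_train, labels = co$labels_train,
               annotations = ann)
fit
#> Refined PRS fit
#>   p-value threshold : 1 (train AUC 0.8786)
#>   variants used     : 19 (of 19 clumped; 0 dropped at harmonization)

auc(predict(fit, co$dosages_test), co$labels_test)
#> [1] 0.84256
```

The fit clumps the 60 simulated variants down to 19 LD-independent ones,
scans the p-value grid and keeps the threshold with the best training AUC
(here 1, retaining all 19), then scores the held-out cohort, where the
refined score discriminates cases from controls with AUC 0.84.
`summary(fit)` prints the threshold scan and the tier composition;
`weight_audit(fit)` returns the per-variant `beta, g, f, s, final_weight`
breakdown. The full benchmark is one call:

```r
compare_pipelines(sim_params(), weight_config(), n_replicates = 25, seed = 1)
#> Refined vs baseline PRS benchmark (25 replicates)
#>   auc          baseline  mean   0.7335  sd   0.0220
#>   auc          refined   mean   0.8022  sd   0.0185
#>   ...
#>   paired test-AUC difference (refined - baseline): +0.0686 (sd 0.0153)
```

A thin command-line wrapper with subcommands `fuse-genes`, `annotate`,
`clump`, `score`, `simulate` and `benchmark` is installed at
`inst/cli/prs.R` (`Rscript $(Rscript -e 'cat(system.file("cli", "prs.R", package = "adprs"))') simulate --seed 1 --out dir/`).

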