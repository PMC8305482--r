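small_params <- function(...) {
  sim_params(n_train = 400L, n_test = 200L, m_variants = 60L,
             block_size = 6L, n_causal = 8L, ...)
}

test_that("genotype generation is deterministic and frequency-calibrated", {
  p <- sim_params(n_train = 5000L, m_variants = 40L, block_size = 4L,
                  n_causal = 8L)
  g1 <- simulate_genotypes(p, seed = 99)
  g2 <- simulate_genotypes(p, seed = 99)
  expect_identical(g1$dosages, g2$dosages)
  expect_true(all(g1$dosages %in% 0:2))

  # sample allele frequency within 3 binomial SEs of the target
  n2 <- 2 * nrow(g1$dosages)
  obs <- colMeans(g1$dosages) / 2
  se <- sqrt(g1$eaf * (1 - g1$eaf) / n2)
  expect_true(all(abs(obs - g1$eaf) < 3.5 * se))
})

test_that("rho = 0 yields uncorrelated variants; rho > 0 yields within-block LD", {
  p0 <- sim_params(n_train = 5000L, m_variants = 20L, block_size = 5L,
                   n_causal = 5L, within_block_rho = 0)
  g0 <- simulate_genotypes(p0, seed = 5)
  ld0 <- estimate_ld(g0$dosages)
  off <- ld0[upper.tri(ld0)]
  expect_lt(mean(off), 0.01)

  p8 <- sim_params(n_train = 5000L, m_variants = 20L, block_size = 5L,
                   n_causal = 5L, within_block_rho = 0.8)
  g8 <- simulate_genotypes(p8, seed = 5)
  ld8 <- estimate_ld(g8$dosages)
  # adjacent within-block pairs clearly correlated, across-block pairs not
  expect_gt(ld8[1, 2], 0.2)
  expect_lt(ld8[5, 6], 0.05)
})

test_that("liability-threshold phenotypes recover prevalence and the null", {
  p <- sim_params(n_train = 3000L, m_variants = 50L, block_size = 5L,
                  n_causal = 10L, prevalence = 0.2)
  g <- simulate_genotypes(p, seed = 12)
  tr <- simulate_truth(p, seed = 13, g$variants$variant_id)
  ph <- simulate_phenotypes(g$dosages, tr, p, seed = 14)
  se <- sqrt(0.2 * 0.8 / p$n_train)
  expect_lt(abs(mean(ph$labels) - 0.2), 3 * se)

  # h2 = 0: any genotype-based score is uninformative
  p0 <- sim_params(n_train = 3000L, m_variants = 50L, block_size = 5L,
                   n_causal = 10L, h2_liability = 0)
  ph0 <- simulate_phenotypes(g$dosages, tr, p0, seed = 15)
  sc <- as.vector(g$dosages %*% tr$true_betas[colnames(g$dosages)])
  expect_lt(abs(auc(sc, ph0$labels) - 0.5), 0.05)

  # near-deterministic liability: oracle PRS separates well
  p99 <- sim_params(n_train = 2000L, m_variants = 50L, block_size = 5L,
                    n_causal = 10L, h2_liability = 0.99, prevalence = 0.5)
  g99 <- simulate_genotypes(p99, seed = 16)
  tr99 <- simulate_truth(p99, seed = 17, g99$variants$variant_id)
  ph99 <- simulate_phenotypes(g99$dosages, tr99, p99, seed = 18)
  oracle <- as.vector(scale(g99$dosages) %*%
                      tr99$true_betas[colnames(g99$dosages)])
  expect_gt(auc(oracle, ph99$labels), 0.9)
})

test_that("marginal GWAS reproduces the closed-form allelic odds ratio", {
  # 20 cases with dosage 30/20 effect alleles... construct exact table:
  # cases: a = 30 effect, b = 10 other; controls: c = 10, d = 30
  dos <- matrix(c(rep(2, 15), rep(0, 5),    # cases: 30 effect alleles
                  rep(1, 10), rep(0, 10)),  # controls: 10 effect alleles
                ncol = 1, dimnames = list(NULL, "v1"))
  labels <- c(rep(1, 20), rep(0, 20))
  variants <- data.frame(variant_id = "v1", chrom = "1", pos = 100L,
                         ref = "A", alt = "G", effect_allele = "G")
  g <- run_marginal_gwas(dos, labels, variants)
  expect_equal(g$beta, log(9), tolerance = 1e-12)
  expect_lt(g$p_value, 0.05)

  # identical allele counts in cases and controls: beta 0, p 1
  dos2 <- matrix(rep(c(rep(1, 10), rep(0, 10)), 2), ncol = 1,
                 dimnames = list(NULL, "v1"))
  g2 <- run_marginal_gwas(dos2, labels, variants)
  expect_equal(g2$beta, 0)
  expect_equal(g2$p_value, 1)

  expect_error(run_marginal_gwas(dos, rep(1, 40), variants), "both")
})

test_that("null GWAS p-values are calibrated (type-I error near 5%)", {
  p <- sim_params(n_train = 3000L, m_variants = 1000L, block_size = 10L,
                  h2_liability = 0, within_block_rho = 0)
  g <- simulate_genotypes(p, seed = 21)
  tr <- simulate_truth(p, seed = 22, g$variants$variant_id)
  ph <- simulate_phenotypes(g$dosages, tr, p, seed = 23)
  gw <- run_marginal_gwas(g$dosages, ph$labels, g$variants)
  frac <- mean(gw$p_value < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("estimated effects track true effects for causal variants", {
  p <- sim_params(n_train = 4000L, m_variants = 100L, block_size = 5L,
                  n_causal = 30L, h2_liability = 0.6)
  co <- simulate_cohort(p, seed = 31)
  caus <- co$truth$causal_ids
  est <- co$sumstats$beta[match(caus, co$sumstats$variant_id)]
  true <- co$truth$true_betas[caus]
  expect_gt(cor(est, true, method = "spearman"), 0.5)
})

test_that("annotation informativeness behaves at its extremes", {
  p <- small_params(p_annot_causal = 1, p_annot_null = 0)
  g <- simulate_genotypes(p, seed = 41)
  tr <- simulate_truth(p, seed = 42, g$variants$variant_id)
  ann <- simulate_annotations(tr, g$variants, p, seed = 43)
  # perfectly informative: favored variants are exactly the causal set
  expect_setequal(sub("^G_", "", ann$genes$gene_id), tr$causal_ids)
  sev <- build_severity_sets(ann$catalog, ann$severe_trait,
                             ann$mild_trait)
  expect_setequal(sev$severe_only, tr$causal_ids)
  expect_true(all(!sev$mild_only %in% tr$causal_ids))

  # symmetric probabilities: annotation independent of causal status
  p5 <- small_params(p_annot_causal = 0.5, p_annot_null = 0.5)
  pvals <- vapply(1:40, function(s) {
    a <- simulate_annotations(tr, g$variants, p5, seed = 100 + s)
    fav <- g$variants$variant_id %in% sub("^G_", "", a$genes$gene_id)
    caus <- g$variants$variant_id %in% tr$causal_ids
    suppressWarnings(chisq.test(table(fav, caus))$p.value)
  }, numeric(1))
  expect_gt(mean(pvals > 0.05), 0.8)
})

test_that("simulated tracks round-trip through the on-disk formats", {
  p <- sim_params(n_train = 30L, n_test = 10L, m_variants = 20L,
                  block_size = 4L, n_causal = 5L)
  co <- simulate_cohort(p, seed = 51)
  dir <- tempfile("cohort")
  write_sim_cohort(co, dir)

  ss <- read_summary_stats(file.path(dir, "summary_stats.tsv"))
  expect_equal(ss$variant_id, co$sumstats$variant_id)
  expect_equal(ss$beta, co$sumstats$beta, tolerance = 1e-12)

  genes <- read_gene_table(file.path(dir, "genes.tsv"))
  expect_equal(genes$gene_id, co$tracks$genes$gene_id)
  expect_equal(genes$span_start, co$tracks$genes$span_start)

  bed <- read_bed(file.path(dir, "open_chromatin.bed"), "brain")
  expect_equal(bed$start, co$tracks$open_chromatin$start)
  expect_equal(bed$end, co$tracks$open_chromatin$end)

  cons <- read_consequences(file.path(dir, "consequences.tsv"))
  expect_equal(cons$ptm_site_hit, co$tracks$consequences$ptm_site_hit)

  cat_rows <- read_catalog(file.path(dir, "catalog.tsv"))
  expect_equal(cat_rows, co$tracks$catalog, ignore_attr = TRUE)

  eff <- setNames(co$variants$effect_allele, co$variants$variant_id)
  dos <- read_vcf_dosages(file.path(dir, "genotypes_train.vcf"), eff)
  expect_equal(dos, co$dosages_train)

  # rebuilt annotations equal the in-memory ones
  sev <- build_severity_sets(cat_rows)
  eq <- read_eqtl(file.path(dir, "eqtl.tsv"))
  a_disk <- build_variant_annotations(ss, genes, cons, bed, eq, sev)
  sev_mem <- build_severity_sets(co$tracks$catalog)
  a_mem <- build_variant_annotations(co$sumstats, co$tracks$genes,
                                     co$tracks$consequences,
                                     co$tracks$open_chromatin,
                                     co$tracks$eqtl, sev_mem)
  expect_equal(a_disk, a_mem)
})

test_that("the full generator chain is deterministic under one seed", {
  p <- small_params()
  a <- simulate_cohort(p, seed = 61)
  b <- simulate_cohort(p, seed = 61)
  expect_identical(a$dosages_train, b$dosages_train)
  expect_identical(a$labels_test, b$labels_test)
  expect_identical(a$sumstats, b$sumstats)
  expect_identical(a$tracks, b$tracks)
  c <- simulate_cohort(p, seed = 62)
  expect_false(identical(a$dosages_train, c$dosages_train))
})

test_that("parameter validation rejects impossible study designs", {
  expect_error(sim_params(n_causal = 100, m_variants = 50), "n_causal")
  expect_error(sim_params(within_block_rho = 1), "rho")
  expect_error(sim_params(prevalence = 0), "prevalence")
  expect_error(sim_params(eaf_range = c(0.5, 0.05)), "eaf_range")
})
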