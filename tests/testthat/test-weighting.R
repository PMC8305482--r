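ann_row <- function(n_gene_hits = 0L, consequence = "other",
                    ptm = FALSE, oc = "", eq = "", sev = "absent") {
  data.frame(variant_id = "v", n_gene_hits = n_gene_hits, gene_hits = "",
             consequence = consequence, ptm_site_hit = ptm,
             oc_tissues = oc, eqtl_tissues = eq, severity_group = sev,
             stringsAsFactors = FALSE)
}

test_that("gene-locus bonus applies once and never stacks", {
  cfg <- weight_config()
  expect_equal(gene_locus_multiplier(ann_row(0L), cfg), 1)
  expect_equal(gene_locus_multiplier(ann_row(1L), cfg), 1.5)
  # three overlapping genes: still a single bonus, not 1.5^3
  expect_equal(gene_locus_multiplier(ann_row(3L), cfg), 1.5)
})

test_that("functional tiers follow first-match precedence with tissue filter", {
  cfg <- weight_config()
  expect_equal(functional_multiplier(ann_row(consequence = "missense",
                                             ptm = TRUE), cfg), 2.0)
  expect_equal(functional_multiplier(ann_row(consequence = "missense"),
                                     cfg), 1.5)
  expect_equal(functional_multiplier(ann_row(consequence = "noncoding",
                                             oc = "brain", eq = "brain"),
                                     cfg), 1.5)
  expect_equal(functional_multiplier(ann_row(consequence = "noncoding",
                                             oc = "brain"), cfg), 1.25)
  expect_equal(functional_multiplier(ann_row(consequence = "noncoding",
                                             eq = "brain"), cfg), 1.25)
  # tissue-mismatched overlap counts as no overlap
  expect_equal(functional_multiplier(ann_row(consequence = "noncoding",
                                             oc = "liver", eq = "liver"),
                                     cfg), 1)
  # coding tier takes precedence over regulatory evidence
  expect_equal(functional_multiplier(ann_row(consequence = "missense",
                                             oc = "brain", eq = "brain"),
                                     cfg), 1.5)
  expect_equal(functional_multiplier(ann_row(), cfg), 1)
})

test_that("functional multiplier always returns exactly one documented tier", {
  cfg <- weight_config()
  tiers <- c(cfg$missense_ptm_mult, cfg$missense_mult,
             cfg$regulatory_both_mult, cfg$regulatory_one_mult, 1)
  set.seed(21)
  for (i in 1:200) {
    a <- ann_row(consequence = sample(c("missense", "synonymous",
                                        "noncoding", "other"), 1),
                 ptm = sample(c(TRUE, FALSE), 1),
                 oc = sample(c("", "brain", "liver", "brain,liver"), 1),
                 eq = sample(c("", "brain", "liver"), 1))
    expect_true(functional_multiplier(a, cfg) %in% tiers)
  }
})

test_that("severity groups map to bonus, penalty or neutrality", {
  cfg <- weight_config()
  expect_equal(severity_multiplier(ann_row(sev = "both"), cfg), 1)
  expect_equal(severity_multiplier(ann_row(sev = "severe_only"), cfg), 1.5)
  expect_equal(severity_multiplier(ann_row(sev = "mild_only"), cfg), 0.5)
  expect_equal(severity_multiplier(ann_row(sev = "absent"), cfg), 1)
})

test_that("refined weights are the product of beta and the three layers", {
  v <- data.frame(variant_id = c("v1", "v2", "v3"), chrom = "1",
                  pos = c(100L, 200L, 300L), ref = "A", alt = "G",
                  effect_allele = "G", beta = c(0.2, 0.3, -0.1),
                  p_value = 0.01, eaf = 0.3)
  anns <- rbind(ann_row(n_gene_hits = 1L, consequence = "missense",
                        ptm = TRUE),
                ann_row(),
                ann_row(n_gene_hits = 2L))
  anns$variant_id <- c("v1", "v2", "v3")
  bw <- apply_refined_weights(v, anns, weight_config())
  expect_equal(bw$final_weight[1], 0.2 * 1.5 * 2.0 * 1.0)
  expect_equal(bw$final_weight[2], 0.3)
  # protective allele keeps its sign under a bonus
  expect_equal(bw$final_weight[3], -0.1 * 1.5)
  expect_equal(bw$final_weight, bw$beta * bw$g * bw$f * bw$s)

  # missing annotation row is fully neutral
  bw2 <- apply_refined_weights(v, anns[1, ], weight_config())
  expect_identical(bw2$final_weight[2:3], v$beta[2:3])
})

test_that("identity configuration reduces refined weights to raw betas exactly", {
  set.seed(14)
  v <- random_variants(30)
  anns <- data.frame(variant_id = v$variant_id,
                     n_gene_hits = sample(0:3, 30, TRUE), gene_hits = "",
                     consequence = sample(c("missense", "noncoding"), 30,
                                          TRUE),
                     ptm_site_hit = sample(c(TRUE, FALSE), 30, TRUE),
                     oc_tissues = sample(c("", "brain"), 30, TRUE),
                     eqtl_tissues = sample(c("", "brain"), 30, TRUE),
                     severity_group = sample(c("severe_only", "mild_only",
                                               "both", "absent"), 30, TRUE))
  bw <- apply_refined_weights(v, anns, identity_weight_config())
  expect_identical(bw$final_weight, v$beta)
})

test_that("sign preservation and monotonicity in single multipliers", {
  set.seed(15)
  v <- random_variants(20)
  anns <- data.frame(variant_id = v$variant_id,
                     n_gene_hits = rep(c(1L, 0L), 10), gene_hits = "",
                     consequence = "other", ptm_site_hit = FALSE,
                     oc_tissues = "", eqtl_tissues = "",
                     severity_group = "absent")
  base <- apply_refined_weights(v, anns, weight_config())
  expect_equal(sign(base$final_weight), sign(v$beta))

  up <- apply_refined_weights(v, anns, weight_config(gene_locus_bonus = 2))
  affected <- anns$n_gene_hits > 0
  expect_true(all(abs(up$final_weight[affected]) >=
                  abs(base$final_weight[affected])))
  expect_identical(up$final_weight[!affected],
                   base$final_weight[!affected])
})

test_that("annotation assembly wires tracks into the expected fields", {
  v <- data.frame(variant_id = c("v1", "v2"), chrom = "1",
                  pos = c(1000L, 90000L), ref = "A", alt = "G",
                  effect_allele = "G", beta = 0.1, p_value = 0.5,
                  eaf = 0.3)
  genes <- data.frame(gene_id = "gA", chromosome = "1",
                      span_start = 900L, span_end = 1100L)
  cons <- data.frame(variant_id = "v2", gene_id = "gA",
                     consequence = "missense", aa_change = "A1T",
                     ptm_site_hit = TRUE)
  oc <- data.frame(chrom = "1", start = 950L, end = 1050L, label = "pk",
                   tissue = "brain")
  eq <- data.frame(variant_id = "v1", gene_id = "gA", tissue = "brain")
  sev <- build_severity_sets(
    data.frame(variant_id = c("v1", "v2"),
               trait_id = c("EFO_0000249", "EFO_1001870")))
  ann <- build_variant_annotations(v, genes, cons, oc, eq, sev,
                                   config = weight_config(gene_window_bp = 0))
  expect_equal(ann$n_gene_hits, c(1L, 0L))
  expect_equal(ann$consequence, c("other", "missense"))
  expect_true(ann$ptm_site_hit[2])
  expect_equal(ann$oc_tissues, c("brain", ""))
  expect_equal(ann$eqtl_tissues, c("brain", ""))
  expect_equal(ann$severity_group, c("severe_only", "mild_only"))
  # v1: regulatory both, severe bonus; v2: missense+PTM, mild penalty
  expect_equal(functional_multiplier(ann, weight_config()), c(1.5, 2.0))
  expect_equal(severity_multiplier(ann, weight_config()), c(1.5, 0.5))
})
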