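# Synthetic-cohort generator: LD-blocked genotypes from a latent-Gaussian
# haplotype model, liability-threshold case/control phenotypes, marginal
# allelic GWAS, and annotation tracks whose alignment with the causal set
# is tunable.

#' Simulation parameters
#'
#' Defines the study conditions for the synthetic benchmark: cohort sizes,
#' LD-block structure (latent AR(1) with correlation `within_block_rho`
#' inside blocks of `block_size` variants, independence across blocks),
#' allele-frequency range, genetic architecture (`n_causal` causal variants
#' summing to liability heritability `h2_liability`), disease prevalence,
#' and annotation informativeness: a causal variant receives each favorable
#' annotation with probability `p_annot_causal`, a non-causal one with
#' `p_annot_null` (the mild-trait penalty layer is anti-aligned, hitting
#' non-causal variants with `p_annot_causal`).
#'
#' @param n_train,n_test Training/testing cohort sizes.
#' @param m_variants Number of variants.
#' @param block_size Variants per LD block (last block may be shorter).
#' @param within_block_rho Latent AR(1) correlation within a block, \[0, 1).
#' @param eaf_range Range of effect-allele frequencies (uniform draw).
#' @param n_causal Number of causal variants (<= `m_variants`).
#' @param h2_liability Liability-scale heritability in \[0, 1).
#' @param prevalence Disease prevalence in (0, 1).
#' @param p_annot_causal,p_annot_null Favorable-annotation probabilities
#'   for causal / non-causal variants.
#' @param spacing_bp Base-pair spacing between adjacent variants.  10 kb by
#'   default, so a default 10-variant block spans 90 kb — inside the
#'   default 250 kb clump window — and the default 50 kb gene-proximity
#'   window stays mostly within one block.
#' @return An object of class `sim_params` (named list).
#' @export
sim_params <- function(n_train = 2000L, n_test = 1000L, m_variants = 1000L,
                       block_size = 10L, within_block_rho = 0.8,
                       eaf_range = c(0.05, 0.5), n_causal = 50L,
                       h2_liability = 0.5, prevalence = 0.2,
                       p_annot_causal = 0.9, p_annot_null = 0.1,
                       spacing_bp = 10000L) {
  p <- list(n_train = as.integer(n_train), n_test = as.integer(n_test),
            m_variants = as.integer(m_variants),
            block_size = as.integer(block_size),
            within_block_rho = within_block_rho,
            eaf_range = as.numeric(eaf_range),
            n_causal = as.integer(n_causal),
            h2_liability = h2_liability, prevalence = prevalence,
            p_annot_causal = p_annot_causal, p_annot_null = p_annot_null,
            spacing_bp = as.integer(spacing_bp))
  if (p$n_causal > p$m_variants) abort("n_causal must be <= m_variants")
  if (p$within_block_rho < 0 || p$within_block_rho >= 1)
    abort("within_block_rho must be in [0, 1)")
  if (p$h2_liability < 0 || p$h2_liability >= 1)
    abort("h2_liability must be in [0, 1)")
  if (p$prevalence <= 0 || p$prevalence >= 1)
    abort("prevalence must be in (0, 1)")
  if (p$block_size < 1 || p$m_variants < 1 || p$n_train < 2 || p$n_test < 1)
    abort("invalid cohort or variant dimensions")
  if (any(p$eaf_range <= 0) || any(p$eaf_range >= 1) ||
      p$eaf_range[1] > p$eaf_range[2])
    abort("eaf_range must satisfy 0 < low <= high < 1")
  structure(p, class = "sim_params")
}

# variant metadata shared by train and test cohorts
sim_variant_frame <- function(params) {
  m <- params$m_variants
  data.frame(variant_id = sprintf("v%05d", seq_len(m)),
             chrom = "1",
             pos = seq_len(m) * params$spacing_bp,
             ref = "A", alt = "G", effect_allele = "G",
             stringsAsFactors = FALSE)
}

# latent haplotype field: block-diagonal AR(1) rows
sim_latent <- function(n, m, block_size, rho) {
  z <- matrix(stats::rnorm(n * m), n, m)
  if (rho > 0 && m > 1) {
    w <- sqrt(1 - rho^2)
    for (j in 2:m)
      if ((j - 1) %% block_size != 0)
        z[, j] <- rho * z[, j - 1] + w * z[, j]
  }
  z
}

#' Simulate LD-blocked genotype dosages
#'
#' Each of the two haplotypes per sample is a thresholded latent Gaussian
#' vector with block-diagonal AR(1) correlation (`rho^|i-j|` within a
#' block, 0 across blocks); the allele is present iff the latent value is
#' below the allele-frequency quantile, and the dosage is the sum of the
#' two haplotypes.  Frequencies are drawn uniformly from
#' `params$eaf_range` unless supplied.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed (full determinism).
#' @param n Number of samples (defaults to `params$n_train`).
#' @param eaf Optional vector of effect-allele frequencies to reuse across
#'   cohorts.
#' @return List with `dosages` (samples x variants integer-valued matrix),
#'   `eaf` (named vector) and `variants` (metadata frame).
#' @export
simulate_genotypes <- function(params, seed, n = params$n_train,
                               eaf = NULL) {
  set.seed(seed)
  m <- params$m_variants
  variants <- sim_variant_frame(params)
  if (is.null(eaf))
    eaf <- stats::runif(m, params$eaf_range[1], params$eaf_range[2])
  eaf <- unname(eaf)
  thr <- matrix(stats::qnorm(eaf), n, m, byrow = TRUE)
  h1 <- sim_latent(n, m, params$block_size, params$within_block_rho) < thr
  h2 <- sim_latent(n, m, params$block_size, params$within_block_rho) < thr
  dos <- h1 + h2
  storage.mode(dos) <- "double"
  dimnames(dos) <- list(sprintf("s%05d", seq_len(n)), variants$variant_id)
  list(dosages = dos, eaf = stats::setNames(eaf, variants$variant_id),
       variants = variants)
}

#' Draw the causal architecture
#'
#' Samples `n_causal` causal variants and standard-normal raw effect sizes
#' (rescaled to the target heritability inside
#' [simulate_phenotypes()]).
#'
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @param variant_ids Variant ids to draw from.
#' @return An object of class `sim_truth`: list with `causal_ids`,
#'   `true_betas` (named, zero for non-causal variants) and
#'   `liability_threshold`.
#' @export
simulate_truth <- function(params, seed, variant_ids) {
  set.seed(seed)
  causal <- sort(sample(variant_ids, params$n_causal))
  betas <- stats::setNames(rep(0, length(variant_ids)), variant_ids)
  betas[causal] <- stats::rnorm(params$n_causal)
  structure(list(causal_ids = causal, true_betas = betas,
                 liability_threshold = stats::qnorm(1 - params$prevalence)),
            class = "sim_truth")
}

#' Simulate liability-threshold case/control labels
#'
#' Liability is the standardized-genotype genetic value (true betas scaled
#' within the cohort so its variance equals `h2_liability`) plus
#' independent Gaussian noise of variance `1 - h2`; a sample is a case iff
#' its liability exceeds the prevalence quantile.
#'
#' @param dosages Samples x variants dosage matrix.
#' @param truth A `sim_truth` object.
#' @param params A [sim_params()].
#' @param seed Integer seed (noise draw).
#' @return List with `labels` (0/1 integer vector), `liability` and the
#'   cohort-scaled `scaled_betas`.
#' @export
simulate_phenotypes <- function(dosages, truth, params, seed) {
  set.seed(seed)
  n <- nrow(dosages)
  b <- truth$true_betas[colnames(dosages)]
  b[is.na(b)] <- 0
  idx <- which(b != 0)
  g <- rep(0, n)
  if (params$h2_liability > 0 && length(idx)) {
    x <- scale(dosages[, idx, drop = FALSE])
    x[is.nan(x)] <- 0
    g <- as.vector(x %*% b[idx])
    vg <- stats::var(g)
    scl <- if (vg > 0) sqrt(params$h2_liability / vg) else 0
    g <- g * scl
    b[idx] <- b[idx] * scl
  } else {
    b[] <- 0
  }
  liability <- g + stats::rnorm(n, 0, sqrt(1 - params$h2_liability))
  labels <- as.integer(liability > truth$liability_threshold)
  list(labels = labels, liability = liability, scaled_betas = b)
}

#' Marginal allelic GWAS on a case/control cohort
#'
#' Per variant, a 2x2 effect-allele x case-status count table is formed
#' from the dosages.  The effect size is the log allelic odds ratio, with
#' 0.5 added to all four cells when any cell is zero (Haldane–Anscombe);
#' the p-value comes from the 1-df allelic chi-square (trend) test on the
#' uncorrected counts.
#'
#' @param dosages Samples x variants dosage matrix.
#' @param labels 0/1 case labels (both classes required).
#' @param variants Variant metadata frame (`variant_id, chrom, pos, ref,
#'   alt, effect_allele`).
#' @return A summary-statistics data frame ([read_summary_stats()] layout)
#'   with `beta`, `p_value` and the observed effect-allele frequency.
#' @export
run_marginal_gwas <- function(dosages, labels, variants) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    abort("GWAS requires both cases and controls")
  case <- labels == 1
  n_obs_case <- colSums(!is.na(dosages[case, , drop = FALSE]))
  n_obs_ctrl <- colSums(!is.na(dosages[!case, , drop = FALSE]))
  a <- colSums(dosages[case, , drop = FALSE], na.rm = TRUE)    # effect, cases
  c_ <- colSums(dosages[!case, , drop = FALSE], na.rm = TRUE)  # effect, ctrls
  b <- 2 * n_obs_case - a
  d <- 2 * n_obs_ctrl - c_
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  ah <- a + 0.5 * zero; bh <- b + 0.5 * zero
  ch <- c_ + 0.5 * zero; dh <- d + 0.5 * zero
  beta <- log((ah * dh) / (bh * ch))
  n_tot <- a + b + c_ + d
  chi <- n_tot * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  chi[!is.finite(chi)] <- 0
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  p <- pmax(p, 1e-300)
  f <- (a + c_) / n_tot
  f <- pmin(pmax(f, 0.5 / n_tot), 1 - 0.5 / n_tot)
  out <- variants[match(colnames(dosages), variants$variant_id), ,
                  drop = FALSE]
  out$beta <- unname(beta)
  out$p_value <- unname(p)
  out$eaf <- unname(f)
  out$trait_id <- NA_character_
  rownames(out) <- NULL
  out
}

sim_severe_trait <- "EFO_0000249"
sim_mild_trait <- "EFO_1001870"

#' Simulate annotation tracks aligned with the causal set
#'
#' Independently per layer, causal variants receive the favorable
#' annotation with probability `p_annot_causal` and non-causal variants
#' with `p_annot_null`.  The gene layer emits a curated gene span around
#' each favored variant; the functional layer assigns a favored variant one
#' of the four favorable tiers (missense+PTM, missense, regulatory-both,
#' regulatory-one) uniformly, emitting consequence rows, brain-tagged
#' open-chromatin intervals and eQTL rows accordingly; the severity layer
#' emits catalog rows, with severe-trait membership aligned with causality
#' and mild-trait membership anti-aligned (non-causal variants hit with
#' `p_annot_causal`).
#'
#' @param truth A `sim_truth` object.
#' @param variants Variant metadata frame.
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return List of tracks: `genes`, `consequences`, `open_chromatin`
#'   (1-based closed, `tissue = "brain"`), `eqtl`, `catalog`, plus the two
#'   trait ids `severe_trait` and `mild_trait`.
#' @export
simulate_annotations <- function(truth, variants, params, seed) {
  set.seed(seed)
  n <- nrow(variants)
  vid <- variants$variant_id
  causal <- vid %in% truth$causal_ids
  p_fav <- ifelse(causal, params$p_annot_causal, params$p_annot_null)
  fav_gene <- stats::runif(n) < p_fav
  fav_fun <- stats::runif(n) < p_fav
  severe <- stats::runif(n) < p_fav
  mild <- stats::runif(n) < ifelse(causal, params$p_annot_null,
                                   params$p_annot_causal)

  gi <- which(fav_gene)
  genes <- data.frame(gene_id = paste0("G_", vid[gi]),
                      symbol = paste0("SYM", seq_along(gi)),
                      map_location = paste0(variants$chrom[gi], "q1"),
                      chromosome = variants$chrom[gi],
                      span_start = pmax(1L, variants$pos[gi] - 100L),
                      span_end = variants$pos[gi] + 100L,
                      origin = "common",
                      protein_accessions = "",
                      stringsAsFactors = FALSE)

  fi <- which(fav_fun)
  tier <- if (length(fi))
    sample(c("missense_ptm", "missense", "regulatory_both",
             "regulatory_one"), length(fi), replace = TRUE)
  else character(0)
  one_side <- if (length(fi))
    sample(c("oc", "eqtl"), length(fi), replace = TRUE)
  else character(0)

  mi <- fi[tier %in% c("missense_ptm", "missense")]
  consequences <- data.frame(variant_id = vid[mi],
                             gene_id = paste0("G_", vid[mi]),
                             consequence = "missense",
                             aa_change = "A123T",
                             ptm_site_hit = tier[tier %in% c(
                               "missense_ptm", "missense")] == "missense_ptm",
                             stringsAsFactors = FALSE)

  oc_take <- fi[tier == "regulatory_both" |
                (tier == "regulatory_one" & one_side == "oc")]
  open_chromatin <- data.frame(chrom = variants$chrom[match(vid[oc_take],
                                                            vid)],
                               start = pmax(1L, variants$pos[oc_take] - 200L),
                               end = variants$pos[oc_take] + 200L,
                               label = paste0("peak_", vid[oc_take]),
                               tissue = "brain",
                               stringsAsFactors = FALSE)

  eq_take <- fi[tier == "regulatory_both" |
                (tier == "regulatory_one" & one_side == "eqtl")]
  eqtl <- data.frame(variant_id = vid[eq_take],
                     gene_id = paste0("G_", vid[eq_take]),
                     tissue = "brain",
                     stringsAsFactors = FALSE)

  catalog <- rbind(
    data.frame(variant_id = vid[severe], trait_id = sim_severe_trait,
               stringsAsFactors = FALSE),
    data.frame(variant_id = vid[mild], trait_id = sim_mild_trait,
               stringsAsFactors = FALSE))

  list(genes = genes, consequences = consequences,
       open_chromatin = open_chromatin, eqtl = eqtl, catalog = catalog,
       severe_trait = sim_severe_trait, mild_trait = sim_mild_trait)
}

#' Simulate a full train/test cohort with GWAS and annotations
#'
#' Orchestrates the generator chain under one master seed: allele
#' frequencies, training and testing genotypes sharing them, the causal
#' architecture, liability-threshold phenotypes for both cohorts, a
#' marginal GWAS on the training cohort, and annotation tracks.
#'
#' @param params A [sim_params()].
#' @param seed Integer master seed; sub-seeds are derived deterministically.
#' @return List with `params`, `variants`, `eaf`, `truth`,
#'   `dosages_train`, `dosages_test`, `labels_train`, `labels_test`,
#'   `sumstats` and `tracks`.
#' @export
simulate_cohort <- function(params, seed) {
  base <- as.integer(seed) %% 2147480000L
  set.seed(base)
  eaf <- stats::runif(params$m_variants, params$eaf_range[1],
                      params$eaf_range[2])
  train <- simulate_genotypes(params, base + 1L, n = params$n_train,
                              eaf = eaf)
  test <- simulate_genotypes(params, base + 2L, n = params$n_test,
                             eaf = eaf)
  rownames(test$dosages) <- sprintf("t%05d", seq_len(params$n_test))
  truth <- simulate_truth(params, base + 3L, train$variants$variant_id)
  ph_tr <- simulate_phenotypes(train$dosages, truth, params, base + 4L)
  ph_te <- simulate_phenotypes(test$dosages, truth, params, base + 5L)
  tracks <- simulate_annotations(truth, train$variants, params, base + 6L)
  sumstats <- run_marginal_gwas(train$dosages, ph_tr$labels,
                                train$variants)
  list(params = params, variants = train$variants,
       eaf = train$eaf, truth = truth,
       dosages_train = train$dosages, dosages_test = test$dosages,
       labels_train = ph_tr$labels, labels_test = ph_te$labels,
       sumstats = sumstats, tracks = tracks)
}

#' Write a simulated cohort to disk as fixture files
#'
#' Emits the cohort as the concrete file formats the toolkit reads:
#' `genotypes_train.vcf`, `genotypes_test.vcf`, `summary_stats.tsv`,
#' `genes.tsv`, `open_chromatin.bed`, `eqtl.tsv`, `consequences.tsv`,
#' `catalog.tsv`, `truth.tsv` and `labels.tsv`.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_vcf_dosages(cohort$dosages_train, cohort$variants,
                    p("genotypes_train.vcf"))
  write_vcf_dosages(cohort$dosages_test, cohort$variants,
                    p("genotypes_test.vcf"))
  write_summary_stats(cohort$sumstats, p("summary_stats.tsv"))
  write_gene_table(cohort$tracks$genes, p("genes.tsv"))
  write_bed(cohort$tracks$open_chromatin, p("open_chromatin.bed"))
  write_tsv(cohort$tracks$eqtl, p("eqtl.tsv"))
  write_tsv(cohort$tracks$consequences, p("consequences.tsv"))
  write_tsv(cohort$tracks$catalog, p("catalog.tsv"))
  write_tsv(data.frame(variant_id = names(cohort$truth$true_betas),
                       true_beta = unname(cohort$truth$true_betas),
                       causal = as.integer(names(cohort$truth$true_betas)
                                           %in% cohort$truth$causal_ids)),
            p("truth.tsv"))
  write_tsv(data.frame(sample_id = c(rownames(cohort$dosages_train),
                                     rownames(cohort$dosages_test)),
                       cohort = rep(c("train", "test"),
                                    c(nrow(cohort$dosages_train),
                                      nrow(cohort$dosages_test))),
                       label = c(cohort$labels_train, cohort$labels_test)),
            p("labels.tsv"))
  invisible(dir)
}
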