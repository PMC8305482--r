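# Independent brute-force oracles and in-code fixtures.  The oracles are
# deliberately written as direct transcriptions of the stated rules,
# sharing no code with the package internals they check.

# greedy clumping, literal restatement: pick smallest p among unprocessed
# (ties: pos, then id), drop unprocessed same-chrom variants within the
# window at r2 >= threshold, retain the index
oracle_clump <- function(variants, ld, r2_thresh, window_bp) {
  v <- variants
  v$.state <- "unprocessed"
  retained <- character(0)
  repeat {
    un <- v[v$.state == "unprocessed", ]
    if (nrow(un) == 0) break
    un <- un[order(un$p_value, un$pos, un$variant_id), ]
    idx <- un$variant_id[1]
    retained <- c(retained, idx)
    v$.state[v$variant_id == idx] <- "retained"
    for (j in which(v$.state == "unprocessed")) {
      same_chrom <- v$chrom[j] == v$chrom[v$variant_id == idx]
      close_by <- abs(v$pos[j] - v$pos[v$variant_id == idx]) <= window_bp
      correlated <- ld[idx, v$variant_id[j]] >= r2_thresh
      if (same_chrom && close_by && correlated) v$.state[j] <- "removed"
    }
  }
  sort(retained)
}

# greedy pruning by descending MAF (ties: pos, then id); keep iff r2 with
# every kept variant is below the threshold
oracle_prune <- function(variants, ld, r2_thresh) {
  maf <- pmin(variants$eaf, 1 - variants$eaf)
  v <- variants[order(-maf, variants$pos, variants$variant_id), ]
  kept <- character(0)
  for (j in seq_len(nrow(v))) {
    id <- v$variant_id[j]
    if (all(ld[id, kept] < r2_thresh)) kept <- c(kept, id)
  }
  sort(kept)
}

# AUC by explicit enumeration of all case-control pairs
oracle_auc <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# random variant table on a handful of chromosomes
random_variants <- function(n, n_chrom = 2, pos_max = 500000) {
  data.frame(variant_id = sprintf("rs%03d", sample(1000, n)),
             chrom = as.character(sample(n_chrom, n, replace = TRUE)),
             pos = sample(pos_max, n),
             ref = "A", alt = "G", effect_allele = "G",
             beta = rnorm(n),
             p_value = runif(n),
             eaf = runif(n, 0.01, 0.99),
             trait_id = NA_character_,
             stringsAsFactors = FALSE)
}

# random symmetric r2 matrix with unit diagonal
random_ld <- function(variant_ids) {
  n <- length(variant_ids)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(variant_ids, variant_ids)
  m
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal well-formed summary-stats fixture (3 rows)
toy_sumstats_lines <- c(
  "#source: fixture",
  "variant_id\tchrom\tpos\tref\talt\teffect_allele\tbeta\tp_value\teaf\ttrait_id",
  "rs1\t1\t1000\tA\tG\tG\t0.25\t1e-6\t0.30\tEFO_0000249",
  "rs2\t1\t5000\tC\tT\tC\t-0.10\t0.02\t0.45\tEFO_0000249",
  "rs3\t2\t800\tG\tA\tA\t0.05\t0.70\t0.12\t")

# 2-variant, 1-sample VCF matching the hand-computable scoring example
toy_vcf_lines <- c(
  "##fileformat=VCFv4.2",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
  "1\t1000\tv1\tA\tG\t.\t.\t.\tGT\t0/1",
  "1\t2000\tv2\tA\tG\t.\t.\t.\tGT\t1/1")
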