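# Conventional PRS machinery: harmonization, LD estimation, clumping,
# pruning, p-value thresholding and the weighted allele-count score.

#' Harmonize summary statistics against a genotype panel
#'
#' Drops variants absent from the genotype matrix and, when
#' `config$drop_ambiguous` is set, strand-ambiguous (A/T, C/G) variants,
#' which cannot be oriented without strand information.  Effect-allele
#' orientation itself is already encoded in the dosages by
#' [read_vcf_dosages()].
#'
#' @param variants Variant data frame.
#' @param genotype_variant_ids Character vector of variant ids present in
#'   the genotypes.
#' @param config A [weight_config()].
#' @return The retained variant data frame, with a `drop_report` attribute
#'   (data frame `variant_id, reason`).
#' @export
harmonize <- function(variants, genotype_variant_ids,
                      config = weight_config()) {
  absent <- !variants$variant_id %in% genotype_variant_ids
  ambiguous <- rep(FALSE, nrow(variants))
  if (config$drop_ambiguous)
    ambiguous <- is_ambiguous_pair(variants$ref, variants$alt)
  drop <- absent | ambiguous
  report <- data.frame(variant_id = variants$variant_id[drop],
                       reason = ifelse(absent[drop], "absent_from_genotypes",
                                       "strand_ambiguous"),
                       stringsAsFactors = FALSE)
  out <- variants[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_report") <- report
  out
}

#' Estimate pairwise LD (r-squared) from dosages
#'
#' LD between two variants is the squared Pearson correlation of their
#' dosage columns, with missing entries pairwise-excluded.  Monomorphic
#' variants (zero variance) get r-squared 0 with all others and 1 with
#' themselves.
#'
#' @param dosages Samples x variants dosage matrix (>= 2 samples).
#' @return A symmetric variants x variants matrix with unit diagonal and
#'   entries in \[0, 1\].
#' @export
estimate_ld <- function(dosages) {
  if (nrow(dosages) < 2)
    abort("LD estimation requires at least 2 samples")
  # complete data takes the BLAS path; pairwise exclusion only when needed
  r <- if (anyNA(dosages))
    suppressWarnings(stats::cor(dosages, use = "pairwise.complete.obs"))
  else
    suppressWarnings(stats::cor(dosages))
  r2 <- r * r
  r2[!is.finite(r2)] <- 0
  diag(r2) <- 1
  r2
}

#' LD clumping: keep the most significant variant per correlated region
#'
#' Greedy rule: repeatedly take the unprocessed variant with the smallest
#' p-value (ties broken by smaller position, then lexicographic variant id)
#' as the index; every unprocessed variant on the same chromosome within
#' `window_bp` of the index (closed interval) with r-squared >=
#' `r2_thresh` against it is removed; the index is retained.  The output is
#' ordered by (chromosome, position) and is invariant to the input order.
#'
#' @param variants Variant data frame; all ids must appear in `ld`.
#' @param ld Symmetric r-squared matrix with variant-id dimnames.
#' @param r2_thresh Removal threshold in \[0, 1\].
#' @param window_bp Window around the index variant in base pairs.
#' @return The retained subset of `variants`, sorted by (chrom, pos).
#' @export
clump <- function(variants, ld, r2_thresh, window_bp) {
  check_ld_args(variants, ld, r2_thresh)
  ord <- order(variants$p_value, variants$pos, variants$variant_id)
  v <- variants[ord, , drop = FALSE]
  r2 <- ld[v$variant_id, v$variant_id, drop = FALSE]
  n <- nrow(v)
  active <- rep(TRUE, n)
  retained <- logical(n)
  for (i in seq_len(n)) {
    if (!active[i]) next
    active[i] <- FALSE
    retained[i] <- TRUE
    kill <- active & v$chrom == v$chrom[i] &
      abs(v$pos - v$pos[i]) <= window_bp & r2[i, ] >= r2_thresh
    active[kill] <- FALSE
  }
  out <- v[retained, , drop = FALSE]
  out <- out[order_chrom_pos(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_report") <- NULL
  out
}

#' LD pruning: keep the highest-MAF variant per correlated set
#'
#' Greedy rule by descending minor allele frequency (`MAF = min(eaf,
#' 1 - eaf)`; ties broken by smaller position, then id): a variant is kept
#' iff its r-squared with every already-kept variant is below `r2_thresh`.
#' Unlike [clump()], no positional window applies.
#'
#' @inheritParams clump
#' @return The retained subset of `variants`, sorted by (chrom, pos).
#' @export
prune <- function(variants, ld, r2_thresh) {
  check_ld_args(variants, ld, r2_thresh)
  maf <- pmin(variants$eaf, 1 - variants$eaf)
  ord <- order(-maf, variants$pos, variants$variant_id)
  v <- variants[ord, , drop = FALSE]
  r2 <- ld[v$variant_id, v$variant_id, drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(v))) {
    if (length(kept) == 0 || all(r2[i, kept] < r2_thresh))
      kept <- c(kept, i)
  }
  out <- v[kept, , drop = FALSE]
  out <- out[order_chrom_pos(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_ld_args <- function(variants, ld, r2_thresh) {
  if (!is.numeric(r2_thresh) || length(r2_thresh) != 1 ||
      is.na(r2_thresh) || r2_thresh < 0 || r2_thresh > 1)
    abort("r2_thresh must be a single value in [0, 1]")
  if (!all(variants$variant_id %in% colnames(ld)))
    abort("all variants must be present in the LD matrix")
}

#' Select variants by p-value threshold
#'
#' @param variants Variant data frame.
#' @param p_thresh Threshold in (0, 1]; variants with `p_value <= p_thresh`
#'   are retained.
#' @return The retained subset, in input order.
#' @export
threshold_select <- function(variants, p_thresh) {
  if (!is.numeric(p_thresh) || length(p_thresh) != 1 ||
      is.na(p_thresh) || p_thresh <= 0 || p_thresh > 1)
    abort("p_thresh must be a single value in (0, 1]")
  out <- variants[variants$p_value <= p_thresh, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute a weighted allele-count polygenic score
#'
#' For each sample, the score is the weighted sum of effect-allele dosages,
#' `S_j = sum_i w_i x_ij`.  Missing dosages are mean-imputed as `2 * eaf`.
#' With `config$normalize_scores`, scores are z-scored over samples.
#'
#' @param dosages Samples x variants dosage matrix.
#' @param weights Named numeric vector of per-allele weights; every name
#'   must be a dosage column (otherwise an error naming the variant).
#' @param config A [weight_config()].
#' @param eaf Named effect-allele-frequency vector, needed only to impute
#'   missing dosages.
#' @return An object of class `prs_result`: list with `sample_ids`,
#'   `scores` (named numeric), `threshold_used`, `variant_weights`,
#'   `n_variants_used`.
#' @export
compute_prs <- function(dosages, weights, config = weight_config(),
                        eaf = NULL) {
  missing_v <- setdiff(names(weights), colnames(dosages))
  if (length(missing_v))
    abort("weight refers to variant absent from dosages: ", missing_v[1])
  x <- dosages[, names(weights), drop = FALSE]
  if (anyNA(x)) {
    na_cols <- which(colSums(is.na(x)) > 0)
    for (k in na_cols) {
      vid <- colnames(x)[k]
      f <- eaf[[vid]] %||% NA_real_
      if (is.na(f))
        abort("missing dosages for ", vid, " but no eaf supplied to impute")
      x[is.na(x[, k]), k] <- 2 * f
    }
  }
  scores <- as.vector(x %*% weights)
  if (config$normalize_scores) {
    s <- stats::sd(scores)
    scores <- if (s > 0) (scores - mean(scores)) / s else scores * 0
  }
  names(scores) <- rownames(dosages)
  structure(list(sample_ids = rownames(dosages),
                 scores = scores,
                 threshold_used = NA_real_,
                 variant_weights = weights,
                 n_variants_used = length(weights)),
            class = "prs_result")
}

#' @export
print.prs_result <- function(x, ...) {
  cat("PRS over", length(x$scores), "samples using",
      x$n_variants_used, "variants\n")
  if (!is.na(x$threshold_used))
    cat("  p-value threshold:", format(x$threshold_used), "\n")
  cat("  score range:", format(range(x$scores), digits = 4), "\n")
  invisible(x)
}
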