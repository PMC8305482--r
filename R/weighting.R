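# The three annotation weight layers.  Each layer returns a multiplicative
# factor per variant; the refined per-allele weight is
# beta * g(gene proximity) * f(functional tier) * s(severity group).

#' Assemble per-variant annotations from evidence tracks
#'
#' Builds the annotation table consumed by the weight layers from the raw
#' evidence: curated gene spans (proximity computed with
#' `config$gene_window_bp` via [map_snps_to_genes()]), a consequence table
#' (missense/PTM), open-chromatin intervals and eQTL rows (tissue-tagged),
#' and severity sets from [build_severity_sets()].  Any track may be `NULL`,
#' in which case that layer is neutral for all variants.
#'
#' @param variants Variant data frame.
#' @param genes Gene-record data frame with spans, or `NULL`.
#' @param consequences Consequence data frame, or `NULL`.
#' @param open_chromatin Interval data frame from [read_bed()] (1-based
#'   closed, tissue-tagged), or `NULL`.
#' @param eqtl eQTL data frame (`variant_id, gene_id, tissue`), or `NULL`.
#' @param severity A `severity_sets` object, or `NULL`.
#' @param config A [weight_config()].
#' @return A data frame with one row per variant: `variant_id,
#'   n_gene_hits, gene_hits, consequence, ptm_site_hit, oc_tissues,
#'   eqtl_tissues, severity_group` (tissue fields comma-separated).
#' @export
build_variant_annotations <- function(variants, genes = NULL,
                                      consequences = NULL,
                                      open_chromatin = NULL, eqtl = NULL,
                                      severity = NULL,
                                      config = weight_config()) {
  n <- nrow(variants)
  vid <- variants$variant_id
  ann <- data.frame(variant_id = vid,
                    n_gene_hits = 0L,
                    gene_hits = "",
                    consequence = "other",
                    ptm_site_hit = FALSE,
                    oc_tissues = "",
                    eqtl_tissues = "",
                    severity_group = "absent",
                    stringsAsFactors = FALSE)
  if (!is.null(genes) && nrow(genes)) {
    hits <- map_snps_to_genes(variants, genes, config$gene_window_bp)
    ann$n_gene_hits <- lengths(hits)
    ann$gene_hits <- vapply(hits, join_csv_field, character(1))
  }
  if (!is.null(consequences) && nrow(consequences)) {
    rank <- c(missense = 1L, synonymous = 2L, noncoding = 3L, other = 4L)
    for (i in which(vid %in% consequences$variant_id)) {
      rows <- consequences[consequences$variant_id == vid[i], , drop = FALSE]
      ann$consequence[i] <- rows$consequence[which.min(rank[rows$consequence])]
      if (ann$consequence[i] == "missense")
        ann$ptm_site_hit[i] <- any(rows$ptm_site_hit[rows$consequence ==
                                                       "missense"])
    }
  }
  if (!is.null(open_chromatin) && nrow(open_chromatin)) {
    for (j in seq_len(nrow(open_chromatin))) {
      hit <- which(variants$chrom == open_chromatin$chrom[j] &
                   variants$pos >= open_chromatin$start[j] &
                   variants$pos <= open_chromatin$end[j])
      for (i in hit)
        ann$oc_tissues[i] <- join_csv_field(c(
          split_csv_field(ann$oc_tissues[i])[[1]],
          open_chromatin$tissue[j]))
    }
  }
  if (!is.null(eqtl) && nrow(eqtl)) {
    for (i in which(vid %in% eqtl$variant_id)) {
      tis <- eqtl$tissue[eqtl$variant_id == vid[i]]
      ann$eqtl_tissues[i] <- join_csv_field(tis[!is.na(tis)])
    }
  }
  if (!is.null(severity))
    ann$severity_group <- severity_group_of(vid, severity)
  ann
}

#' Gene-locus proximity multiplier
#'
#' Returns `config$gene_locus_bonus` for variants near at least one curated
#' disease gene and 1 otherwise.  The bonus is applied at most once per
#' variant no matter how many genes overlap — co-located or co-inherited
#' gene loci must not compound the score.
#'
#' @param ann Annotation data frame from [build_variant_annotations()] (or
#'   any data frame with an `n_gene_hits` column).
#' @param config A [weight_config()].
#' @return Numeric vector of multipliers, one per annotation row.
#' @export
gene_locus_multiplier <- function(ann, config = weight_config()) {
  ifelse(ann$n_gene_hits > 0, config$gene_locus_bonus, 1)
}

#' Functional-impact multiplier
#'
#' Tiered, first match wins: missense with a PTM-site hit ->
#' `missense_ptm_mult`; other missense -> `missense_mult`; non-coding with
#' both open-chromatin and eQTL overlap in a tissue of
#' `config$tissue_filter` -> `regulatory_both_mult`; exactly one of the two
#' (tissue-matched) -> `regulatory_one_mult`; otherwise 1.  Overlaps in
#' tissues outside the filter count as no overlap.
#'
#' @inheritParams gene_locus_multiplier
#' @return Numeric vector of multipliers.
#' @export
functional_multiplier <- function(ann, config = weight_config()) {
  tiers <- functional_tier(ann, config)
  unname(c(missense_ptm = config$missense_ptm_mult,
           missense = config$missense_mult,
           regulatory_both = config$regulatory_both_mult,
           regulatory_one = config$regulatory_one_mult,
           none = 1)[tiers])
}

functional_tier <- function(ann, config) {
  oc <- vapply(split_csv_field(ann$oc_tissues),
               function(t) any(t %in% config$tissue_filter), logical(1))
  eq <- vapply(split_csv_field(ann$eqtl_tissues),
               function(t) any(t %in% config$tissue_filter), logical(1))
  miss <- ann$consequence == "missense"
  ifelse(miss & ann$ptm_site_hit, "missense_ptm",
         ifelse(miss, "missense",
                ifelse(oc & eq, "regulatory_both",
                       ifelse(xor(oc, eq), "regulatory_one", "none"))))
}

#' Phenotype-severity multiplier
#'
#' Variants unique to the severe trait receive `severity_bonus`; variants
#' unique to the mild trait receive `severity_penalty`; variants in both
#' trait sets, or in neither, are neutral (1).
#'
#' @inheritParams gene_locus_multiplier
#' @return Numeric vector of multipliers.
#' @export
severity_multiplier <- function(ann, config = weight_config()) {
  unname(c(severe_only = config$severity_bonus,
           mild_only = config$severity_penalty,
           both = 1, absent = 1)[ann$severity_group])
}

#' Apply the three weight layers to variant effects
#'
#' Computes the refined per-allele weight `beta * g * f * s` for every
#' variant and records the full breakdown for audit.  Variants without an
#' annotation row are fully neutral (g = f = s = 1), so with all
#' multipliers at 1 the refined weights equal the raw betas exactly.
#'
#' @param variants Variant data frame.
#' @param anns Annotation data frame from [build_variant_annotations()], or
#'   `NULL` for an all-neutral (baseline) breakdown.
#' @param config A [weight_config()].
#' @return A data frame with one row per variant, in input order:
#'   `variant_id, beta, g, f, s, final_weight, severity_group, tier`.
#' @export
apply_refined_weights <- function(variants, anns = NULL,
                                  config = weight_config()) {
  n <- nrow(variants)
  out <- data.frame(variant_id = variants$variant_id,
                    beta = variants$beta,
                    g = rep(1, n), f = rep(1, n), s = rep(1, n),
                    final_weight = variants$beta,
                    severity_group = "absent",
                    tier = "none",
                    stringsAsFactors = FALSE)
  if (!is.null(anns) && nrow(anns)) {
    i <- match(out$variant_id, anns$variant_id)
    hit <- !is.na(i)
    a <- anns[i[hit], , drop = FALSE]
    out$g[hit] <- gene_locus_multiplier(a, config)
    out$f[hit] <- functional_multiplier(a, config)
    out$s[hit] <- severity_multiplier(a, config)
    out$severity_group[hit] <- a$severity_group
    out$tier[hit] <- functional_tier(a, config)
    out$final_weight <- out$beta * out$g * out$f * out$s
  }
  out
}
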