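#' Weight configuration for refined PRS construction
#'
#' Collects every multiplier, window and threshold used by the refined
#' polygenic risk score.  The three annotation layers are multiplicative on
#' the per-allele log odds ratio: a gene-proximity bonus, a functional tier
#' (missense / post-translational-modification site / tissue-matched
#' regulatory overlap) and a trait-severity bonus or penalty.  Setting every
#' multiplier to 1 reduces the refined score to the conventional baseline
#' PRS exactly (see [identity_weight_config()]).
#'
#' @param gene_locus_bonus Multiplier (> 0) applied once to variants within
#'   `gene_window_bp` of at least one curated disease gene.  The bonus never
#'   stacks across multiple overlapping genes.
#' @param gene_window_bp Gene proximity window in base pairs, applied on
#'   both sides of the gene span (closed interval).
#' @param missense_ptm_mult Multiplier for missense variants hitting a
#'   post-translational-modification site.
#' @param missense_mult Multiplier for other missense variants.
#' @param regulatory_both_mult Multiplier for non-coding variants
#'   overlapping both open chromatin and an eQTL in a tissue of
#'   `tissue_filter`.
#' @param regulatory_one_mult Multiplier when exactly one of the two
#'   regulatory overlaps (tissue-matched) is present.
#' @param severity_bonus Multiplier for variants unique to the severe trait
#'   (must be >= 1).
#' @param severity_penalty Multiplier for variants unique to the mild trait
#'   (must be in (0, 1]).
#' @param tissue_filter Character vector of tissues whose regulatory
#'   evidence counts; overlaps in other tissues are ignored.
#' @param clump_r2 Squared-correlation threshold for LD clumping/pruning,
#'   in \[0, 1\].
#' @param clump_window_bp Clumping window in base pairs around the index
#'   variant (closed interval).
#' @param p_thresholds Strictly increasing p-value thresholds, each in
#'   (0, 1\], scanned when a training phenotype is available.
#' @param drop_ambiguous Drop strand-ambiguous (A/T, C/G) variants during
#'   harmonization.
#' @param normalize_scores Z-score PRS values over samples.
#'
#' @return An object of class `weight_config` (a named list).
#' @examples
#' cfg <- weight_config(severity_penalty = 0.8)
#' cfg$gene_locus_bonus
#' @export
weight_config <- function(gene_locus_bonus = 1.5,
                          gene_window_bp = 50000L,
                          missense_ptm_mult = 2.0,
                          missense_mult = 1.5,
                          regulatory_both_mult = 1.5,
                          regulatory_one_mult = 1.25,
                          severity_bonus = 1.5,
                          severity_penalty = 0.5,
                          tissue_filter = "brain",
                          clump_r2 = 0.1,
                          clump_window_bp = 250000L,
                          p_thresholds = c(5e-8, 1e-6, 1e-4, 1e-3,
                                           0.01, 0.05, 0.1, 0.5, 1.0),
                          drop_ambiguous = TRUE,
                          normalize_scores = FALSE) {
  cfg <- list(gene_locus_bonus = as.numeric(gene_locus_bonus),
              gene_window_bp = as.integer(gene_window_bp),
              missense_ptm_mult = as.numeric(missense_ptm_mult),
              missense_mult = as.numeric(missense_mult),
              regulatory_both_mult = as.numeric(regulatory_both_mult),
              regulatory_one_mult = as.numeric(regulatory_one_mult),
              severity_bonus = as.numeric(severity_bonus),
              severity_penalty = as.numeric(severity_penalty),
              tissue_filter = as.character(tissue_filter),
              clump_r2 = as.numeric(clump_r2),
              clump_window_bp = as.integer(clump_window_bp),
              p_thresholds = as.numeric(p_thresholds),
              drop_ambiguous = isTRUE(drop_ambiguous),
              normalize_scores = isTRUE(normalize_scores))
  validate_weight_config(cfg)
  structure(cfg, class = "weight_config")
}

validate_weight_config <- function(cfg) {
  mults <- c("gene_locus_bonus", "missense_ptm_mult", "missense_mult",
             "regulatory_both_mult", "regulatory_one_mult",
             "severity_bonus", "severity_penalty")
  for (m in mults) {
    v <- cfg[[m]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      abort("config error: '", m, "' must be a single positive number")
  }
  if (cfg$severity_penalty > 1)
    abort("config error: severity_penalty must be <= 1")
  if (cfg$severity_bonus < 1)
    abort("config error: severity_bonus must be >= 1")
  if (is.na(cfg$gene_window_bp) || cfg$gene_window_bp < 0)
    abort("config error: gene_window_bp must be >= 0")
  if (is.na(cfg$clump_window_bp) || cfg$clump_window_bp < 0)
    abort("config error: clump_window_bp must be >= 0")
  if (!is.numeric(cfg$clump_r2) || is.na(cfg$clump_r2) ||
      cfg$clump_r2 < 0 || cfg$clump_r2 > 1)
    abort("config error: clump_r2 must be in [0, 1]")
  th <- cfg$p_thresholds
  if (length(th) < 1 || any(is.na(th)) || any(th <= 0) || any(th > 1))
    abort("config error: p_thresholds must each be in (0, 1]")
  if (length(th) > 1 && any(diff(th) <= 0))
    abort("config error: p_thresholds must be strictly increasing")
  invisible(cfg)
}

#' Identity weight configuration
#'
#' A [weight_config()] with every annotation multiplier equal to 1, under
#' which the refined PRS equals the baseline PRS bit for bit.  Other
#' settings (clumping, thresholds) can still be overridden via `...`.
#'
#' @param ... Passed on to [weight_config()].
#' @return A `weight_config` object.
#' @export
identity_weight_config <- function(...) {
  weight_config(gene_locus_bonus = 1, missense_ptm_mult = 1,
                missense_mult = 1, regulatory_both_mult = 1,
                regulatory_one_mult = 1, severity_bonus = 1,
                severity_penalty = 1, ...)
}

#' Read a weight configuration from a YAML file
#'
#' Keys absent from the file take the documented [weight_config()] defaults;
#' unknown keys are an error.  All invariants are re-checked.
#'
#' @param path Path to a YAML `key: value` file (may be empty).
#' @return A `weight_config` object.
#' @export
read_weight_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) abort("config error: expected a key: value mapping")
  known <- names(formals(weight_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    abort("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(vals$tissue_filter))
    vals$tissue_filter <- unlist(vals$tissue_filter)
  if (!is.null(vals$p_thresholds))
    vals$p_thresholds <- as.numeric(unlist(vals$p_thresholds))
  do.call(weight_config, vals)
}

#' Write a weight configuration to a YAML file
#'
#' Inverse of [read_weight_config()]: the written file reads back to an
#' identical configuration.
#'
#' @param config A `weight_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_config <- function(config, path) {
  stopifnot(inherits(config, "weight_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.weight_config <- function(x, ...) {
  cat("Refined-PRS weight configuration\n")
  cat(sprintf("  gene locus bonus     : %.3g (window %d bp)\n",
              x$gene_locus_bonus, x$gene_window_bp))
  cat(sprintf("  functional tiers     : missense+PTM %.3g, missense %.3g, regulatory both %.3g / one %.3g\n",
              x$missense_ptm_mult, x$missense_mult,
              x$regulatory_both_mult, x$regulatory_one_mult))
  cat(sprintf("  severity bonus/penalty: %.3g / %.3g\n",
              x$severity_bonus, x$severity_penalty))
  cat(sprintf("  tissue filter        : %s\n",
              paste(x$tissue_filter, collapse = ", ")))
  cat(sprintf("  clumping             : r2 >= %.3g within %d bp\n",
              x$clump_r2, x$clump_window_bp))
  cat(sprintf("  p thresholds         : %s\n",
              paste(format(x$p_thresholds), collapse = " ")))
  invisible(x)
}
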