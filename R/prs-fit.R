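#' Fit a (refined) polygenic risk score
#'
#' The central estimator.  Starting from GWAS summary statistics and a
#' genotype panel it (1) harmonizes the variants against the panel,
#' (2) estimates LD from the panel and clumps (`config$clump_r2`,
#' `config$clump_window_bp`), (3) applies the three annotation weight
#' layers to the retained betas ([apply_refined_weights()]; with
#' `annotations = NULL` the fit is the conventional baseline PRS), and
#' (4) selects the p-value threshold: when training `labels` are supplied,
#' every `config$p_thresholds` value is scored on the training panel and
#' the threshold maximizing training AUC is kept (ties: the smallest
#' threshold); otherwise the largest threshold is used.
#'
#' @param sumstats Summary-statistics data frame
#'   ([read_summary_stats()] layout).
#' @param dosages Samples x variants training dosage matrix.
#' @param labels Optional 0/1 training labels for threshold selection.
#' @param annotations Optional annotation table from
#'   [build_variant_annotations()]; `NULL` fits the baseline arm.
#' @param config A [weight_config()].
#' @param ld Optional precomputed LD matrix (else estimated from
#'   `dosages`).
#' @return An object of class `prs_fit` with components `weights` (the
#'   per-variant weight breakdown at the selected threshold),
#'   `threshold_used`, `n_variants_used`, `threshold_scan` (per-threshold
#'   variant counts and training AUCs), `train_auc`, `eaf`, `config`,
#'   `drop_report` and `call`.  Methods: [print.prs_fit()],
#'   [summary.prs_fit()], [coef.prs_fit()], [predict.prs_fit()].
#' @examples
#' params <- sim_params(n_train = 300, n_test = 150, m_variants = 60,
#'                      n_causal = 6)
#' co <- simulate_cohort(params, seed = 7)
#' fit <- prs_fit(co$sumstats, co$dosages_train, labels = co$labels_train)
#' fit
#' scores <- predict(fit, co$dosages_test)
#' auc(scores, co$labels_test)
#' @export
prs_fit <- function(sumstats, dosages, labels = NULL, annotations = NULL,
                    config = weight_config(), ld = NULL) {
  vars <- harmonize(sumstats, colnames(dosages), config)
  drop_report <- attr(vars, "drop_report")
  if (nrow(vars) == 0) abort("no variants remain after harmonization")
  if (is.null(ld))
    ld <- estimate_ld(dosages[, vars$variant_id, drop = FALSE])
  retained <- clump(vars, ld, config$clump_r2, config$clump_window_bp)
  breakdown <- apply_refined_weights(retained, annotations, config)
  eaf_map <- stats::setNames(retained$eaf, retained$variant_id)

  ths <- config$p_thresholds
  scan <- data.frame(threshold = ths, n_variants = NA_integer_,
                     train_auc = NA_real_)
  if (!is.null(labels)) {
    for (k in seq_along(ths)) {
      keep <- retained$p_value <= ths[k]
      scan$n_variants[k] <- sum(keep)
      if (!any(keep)) next
      w <- stats::setNames(breakdown$final_weight[keep],
                           breakdown$variant_id[keep])
      sc <- compute_prs(dosages, w, config, eaf = eaf_map)$scores
      scan$train_auc[k] <- auc(sc, labels)
    }
    if (all(is.na(scan$train_auc)))
      abort("no threshold retains any variant")
    best <- which.max(scan$train_auc)   # ties -> smallest threshold
  } else {
    scan$n_variants <- vapply(ths, function(t) sum(retained$p_value <= t),
                              integer(1))
    best <- length(ths)
  }
  thr <- ths[best]
  keep <- retained$p_value <= thr
  weights <- breakdown[keep, , drop = FALSE]
  rownames(weights) <- NULL

  structure(list(weights = weights,
                 threshold_used = thr,
                 n_variants_used = nrow(weights),
                 threshold_scan = scan,
                 train_auc = if (is.null(labels)) NA_real_
                             else scan$train_auc[best],
                 eaf = eaf_map,
                 refined = !is.null(annotations),
                 config = config,
                 drop_report = drop_report,
                 call = match.call()),
            class = "prs_fit")
}

#' @export
print.prs_fit <- function(x, ...) {
  cat(if (x$refined) "Refined" else "Baseline", "PRS fit\n")
  cat(sprintf("  p-value threshold : %s (train AUC %s)\n",
              format(x$threshold_used),
              if (is.na(x$train_auc)) "not scanned"
              else sprintf("%.4f", x$train_auc)))
  cat(sprintf("  variants used     : %d (of %d clumped; %d dropped at harmonization)\n",
              x$n_variants_used, length(x$eaf), nrow(x$drop_report)))
  invisible(x)
}

#' Summary of a PRS fit
#'
#' @param object A `prs_fit` object.
#' @param ... Ignored.
#' @return `object`, invisibly; prints the threshold scan and, for a
#'   refined fit, the multiplier-tier composition of the selected variants.
#' @export
summary.prs_fit <- function(object, ...) {
  print(object)
  cat("\nThreshold scan:\n")
  print(object$threshold_scan, row.names = FALSE)
  if (object$refined && nrow(object$weights)) {
    cat("\nFunctional tiers of selected variants:\n")
    print(table(object$weights$tier))
    cat("\nSeverity groups:\n")
    print(table(object$weights$severity_group))
    cat("\nGene-proximity bonus applied to",
        sum(object$weights$g != 1), "of", nrow(object$weights),
        "variants\n")
  }
  invisible(object)
}

#' Per-allele weights of a PRS fit
#'
#' @param object A `prs_fit` object.
#' @param ... Ignored.
#' @return Named numeric vector of final per-allele weights.
#' @export
coef.prs_fit <- function(object, ...) {
  stats::setNames(object$weights$final_weight, object$weights$variant_id)
}

#' Score samples with a fitted PRS
#'
#' @param object A `prs_fit` object.
#' @param dosages Samples x variants dosage matrix containing the fitted
#'   variants.
#' @param eaf Optional effect-allele frequencies for imputing missing
#'   dosages (defaults to the training frequencies stored in the fit).
#' @param ... Ignored.
#' @return Named numeric vector of scores, one per sample.
#' @export
predict.prs_fit <- function(object, dosages, eaf = NULL, ...) {
  compute_prs(dosages, coef(object), object$config,
              eaf = eaf %||% object$eaf)$scores
}

#' Audit table of a PRS fit
#'
#' The per-variant weight breakdown (`variant_id, beta, g, f, s,
#' final_weight, severity_group, tier`) for the selected variants, suitable
#' for writing with [write_tsv_audit()].
#'
#' @param object A `prs_fit` object.
#' @return A data frame.
#' @export
weight_audit <- function(object) {
  stopifnot(inherits(object, "prs_fit"))
  object$weights
}

#' Write a weight-audit table as TSV
#' @param audit Data frame from [weight_audit()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_audit <- function(audit, path) write_tsv(audit, path)
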