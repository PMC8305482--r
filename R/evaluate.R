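# Discrimination and contrast metrics, and the baseline-vs-refined
# benchmark over simulated replicates.

#' Area under the ROC curve (Mann–Whitney)
#'
#' `P(score_case > score_control) + 0.5 P(equal)` over all case-control
#' pairs, computed via mid-ranks; invariant under strictly monotone score
#' transforms.
#'
#' @param scores Numeric score vector.
#' @param labels 0/1 labels (both classes required).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("AUC requires both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Nagelkerke pseudo R-squared of a univariate logistic fit
#'
#' `R2 = [1 - exp((2/n)(LL0 - LL1))] / [1 - exp((2/n) LL0)]`, with `LL1`
#' the maximized log-likelihood of `labels ~ scores` (logistic regression
#' by IRLS, 100-iteration cap) and `LL0` the intercept-only model.  Under
#' complete separation the fit is flagged: the function warns and returns
#' 1.0 with attribute `separation = TRUE`.
#'
#' @inheritParams auc
#' @return R-squared in \[0, 1\] (possibly with a `separation` attribute).
#' @export
nagelkerke_r2 <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    abort("Nagelkerke R2 requires both classes")
  n <- length(labels)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(labels ~ scores, family = stats::binomial(),
               control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged || fit$deviance < 1e-6) separated <- TRUE
  if (separated && fit$deviance < 1e-6) {
    warning("complete separation: Nagelkerke R2 reported as 1")
    return(structure(1.0, separation = TRUE))
  }
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(stats::glm(labels ~ 1,
                                             family = stats::binomial())))
  r2 <- (1 - exp((2 / n) * (ll0 - ll1))) / (1 - exp((2 / n) * ll0))
  min(max(r2, 0), 1)
}

#' Top-vs-bottom quantile odds-ratio contrast
#'
#' Ranks samples by score (ties broken by sample order) and contrasts case
#' odds in the top fraction `q` against the bottom fraction `q` as an odds
#' ratio, adding 0.5 to all four cells when any cell is zero
#' (Haldane–Anscombe).
#'
#' @inheritParams auc
#' @param q Quantile fraction in (0, 0.5\] (default 0.2, i.e. quintiles).
#' @return The odds ratio (>= 0).
#' @export
quantile_contrast <- function(scores, labels, q = 0.2) {
  if (!is.numeric(q) || length(q) != 1 || is.na(q) || q <= 0 || q > 0.5)
    abort("q must be in (0, 0.5]")
  labels <- as.integer(labels)
  n <- length(scores)
  k <- floor(n * q)
  if (k < 1) abort("too few samples for quantile contrast (need n >= 1/q)")
  if (length(unique(labels)) < 2)
    abort("quantile contrast requires both classes overall")
  ord <- order(scores)           # stable: ties keep sample order
  bottom <- ord[seq_len(k)]
  top <- ord[seq.int(n - k + 1L, n)]
  a <- sum(labels[top] == 1); b <- sum(labels[top] == 0)
  c_ <- sum(labels[bottom] == 1); d <- sum(labels[bottom] == 0)
  if (a == 0 || b == 0 || c_ == 0 || d == 0) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  (a / b) / (c_ / d)
}

#' Benchmark the refined PRS against the baseline on simulated cohorts
#'
#' Per replicate: simulate a train/test cohort, run the marginal GWAS on
#' the training half, harmonize and clump once, then fit each arm —
#' baseline (weights = beta) and refined ([apply_refined_weights()] on the
#' simulated annotation tracks) — scanning `config$p_thresholds` and
#' keeping the threshold with the best training AUC per arm, and finally
#' score the held-out cohort.  Reports per-replicate and aggregate AUC,
#' Nagelkerke R-squared and top-vs-bottom-quintile odds ratio, plus the
#' paired (same replicate) test-AUC difference refined - baseline.
#'
#' @param params A [sim_params()] describing the study conditions.
#' @param config A [weight_config()].
#' @param n_replicates Number of simulation replicates.
#' @param seed Integer master seed; replicate seeds are derived from it.
#' @return An object of class `prs_benchmark`: list with `replicates`
#'   (long data frame: replicate, arm, threshold, n_variants, auc, r2,
#'   quantile_or), `summary` (per-arm means and SDs),
#'   `paired_auc_diff_mean`, `paired_auc_diff_sd`, `params`, `config`.
#' @export
compare_pipelines <- function(params = sim_params(),
                              config = weight_config(),
                              n_replicates = 25L, seed = 1L) {
  rows <- vector("list", 2L * n_replicates)
  diffs <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    co <- simulate_cohort(params, as.integer(seed) + 1000L * r)
    sev <- build_severity_sets(co$tracks$catalog, co$tracks$severe_trait,
                               co$tracks$mild_trait)
    anns <- build_variant_annotations(co$sumstats,
                                      genes = co$tracks$genes,
                                      consequences = co$tracks$consequences,
                                      open_chromatin = co$tracks$open_chromatin,
                                      eqtl = co$tracks$eqtl,
                                      severity = sev,
                                      config = config)
    ld <- estimate_ld(co$dosages_train)
    eaf_map <- stats::setNames(co$sumstats$eaf, co$sumstats$variant_id)
    res <- list()
    for (arm in c("baseline", "refined")) {
      fit <- prs_fit(co$sumstats, co$dosages_train,
                     labels = co$labels_train,
                     annotations = if (arm == "refined") anns else NULL,
                     config = config, ld = ld)
      sc <- predict(fit, co$dosages_test, eaf = eaf_map)
      res[[arm]] <- data.frame(replicate = r, arm = arm,
                               threshold = fit$threshold_used,
                               n_variants = fit$n_variants_used,
                               auc = auc(sc, co$labels_test),
                               r2 = as.numeric(nagelkerke_r2(sc,
                                                             co$labels_test)),
                               quantile_or = quantile_contrast(sc,
                                                               co$labels_test),
                               stringsAsFactors = FALSE)
    }
    diffs[r] <- res$refined$auc - res$baseline$auc
    rows[[2L * r - 1L]] <- res$baseline
    rows[[2L * r]] <- res$refined
  }
  reps <- do.call(rbind, rows)
  agg <- function(metric) {
    sapply(split(reps[[metric]], reps$arm), function(x)
      c(mean = mean(x), sd = stats::sd(x)))
  }
  summ <- do.call(rbind, lapply(c("auc", "r2", "quantile_or"), function(m) {
    a <- agg(m)
    data.frame(metric = m, arm = colnames(a), mean = a["mean", ],
               sd = a["sd", ], row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(replicates = reps, summary = summ,
                 paired_auc_diff_mean = mean(diffs),
                 paired_auc_diff_sd = stats::sd(diffs),
                 params = params, config = config),
            class = "prs_benchmark")
}

#' @export
print.prs_benchmark <- function(x, ...) {
  n <- length(unique(x$replicates$replicate))
  cat("Refined vs baseline PRS benchmark (", n, " replicates)\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %-9s mean %8.4f  sd %8.4f\n",
                s$metric[i], s$arm[i], s$mean[i], s$sd[i]))
  cat(sprintf("  paired test-AUC difference (refined - baseline): %+.4f (sd %.4f)\n",
              x$paired_auc_diff_mean, x$paired_auc_diff_sd))
  invisible(x)
}

#' Boxplot of per-replicate test AUC by arm
#' @param x A `prs_benchmark` object.
#' @param ... Passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.prs_benchmark <- function(x, ...) {
  graphics::boxplot(auc ~ arm, data = x$replicates,
                    ylab = "held-out AUC", ...)
  invisible(x)
}
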