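#' Bonferroni-adjusted significance level
#'
#' @param family_alpha family-wise level.
#' @param n_tests number of tests corrected for.
#' @return \code{family_alpha / n_tests}.
#' @examples
#' bonferroni_alpha(0.05, 2)       # 0.025
#' bonferroni_alpha(0.05, 30000)   # 1.67e-6
#' @export
bonferroni_alpha <- function(family_alpha, n_tests) {
  stopifnot(family_alpha > 0, family_alpha < 1, n_tests >= 1)
  family_alpha / n_tests
}

#' Rejection rate of a test over simulation replicates
#'
#' Runs either the joint reverse-regression test (\code{method = "marv"},
#' full model over both phenotypes) or the univariate forward burden test
#' (\code{method = "univariate"}, each phenotype tested separately with a
#' Bonferroni-corrected per-test level \code{alpha / K}) on every
#' replicate of a stream and reports the proportion of replicates with a
#' significant result, with a Clopper-Pearson 95\% confidence interval.
#' Under a null scenario this estimates the type-I error rate; under an
#' effect scenario, power.  Each replicate's genotypes pass through the
#' standard analysis path: rare-variant filter on the sample MAF, carrier
#' collapse, weighted regression.
#'
#' A third-party test can be plugged in by passing a function
#' \code{(burden, phenotypes) -> p-value} as \code{method}.
#'
#' @param stream a \code{\link{replicate_stream}}, or a scenario (a stream
#'   is built from it).
#' @param method "marv", "univariate", or a function.
#' @param alpha nominal family-wise level.
#' @param n_reps number of replicates; default the scenario's.
#' @param maf_max rare-variant filter applied per replicate sample.
#' @param keep_pvalues store the per-replicate p-values in the result, so
#'   re-thresholding at other levels needs no re-simulation.
#' @return an object of class \code{marv_eval}: a one-row data frame with
#'   scenario descriptors, method, alpha, n_reps, n_excluded,
#'   rejection_rate, ci_low, ci_high; per-replicate p-values in
#'   \code{attr(, "pvalues")}.
#' @export
rejection_rate <- function(stream, method = "marv", alpha = 0.05,
                           n_reps = NULL, maf_max = 0.05,
                           keep_pvalues = TRUE) {
  if (inherits(stream, "marv_scenario")) stream <- replicate_stream(stream)
  pv <- replicate_pvalues(stream, list(method), n_reps = n_reps,
                          maf_max = maf_max)
  summarise_rejections(pv[, 1], stream$scenario,
                       method_label(method), alpha,
                       k_pheno = 2, keep_pvalues = keep_pvalues)
}

method_label <- function(method)
  if (is.function(method)) "custom" else
    match.arg(method, c("marv", "univariate"))

# run each replicate once and apply every method to the shared burden,
# returning an n_reps x length(methods) p-value matrix
replicate_pvalues <- function(stream, methods, n_reps = NULL,
                              maf_max = 0.05) {
  sc <- stream$scenario
  n_reps <- n_reps %||% sc$n_replicates
  stopifnot(n_reps >= 1, n_reps <= sc$n_replicates)
  labels <- vapply(methods, method_label, "")
  pv <- matrix(NA_real_, n_reps, length(methods),
               dimnames = list(NULL, labels))
  for (i in seq_len(n_reps)) {
    rep_i <- stream$draw(i)
    cm <- genotype_carriers(rep_i$genotypes, maf_max = maf_max)
    if (ncol(cm$values) == 0) next
    bd <- tryCatch(collapse_region(cm), error = function(e) NULL)
    if (is.null(bd)) next
    pm <- rep_i$phenotypes
    for (j in seq_along(methods)) {
      pv[i, j] <- tryCatch({
        if (is.function(methods[[j]])) methods[[j]](bd, pm)
        else if (labels[j] == "marv") {
          fit <- marv(bd, pm)
          if (isTRUE(fit$skipped)) NA_real_ else as.numeric(fit$p_value)
        } else {
          min(vapply(pm$phenotype_names, function(nm)
            as.numeric(univariate_burden_test(bd, pm, nm)), 0))
        }
      }, error = function(e) NA_real_)
    }
  }
  pv
}

summarise_rejections <- function(pv, sc, method_name, alpha, k_pheno = 2,
                                 keep_pvalues = TRUE) {
  thr <- if (method_name == "univariate")
    bonferroni_alpha(alpha, k_pheno) else alpha
  n_reps <- length(pv)
  excluded <- sum(is.na(pv))
  if (excluded > 0.01 * n_reps)
    warning(excluded, " of ", n_reps,
            " replicates excluded (degenerate burden or failed fit)")
  ok <- !is.na(pv)
  n_eff <- sum(ok)
  hits <- sum(pv[ok] < thr)
  ci <- binom.test(hits, n_eff)$conf.int
  out <- data.frame(n_individuals = sc$n_individuals, beta = sc$beta,
                    effect_pattern = sc$effect_pattern,
                    direction_mix = sc$direction_mix, rho = sc$rho,
                    method = method_name, alpha = alpha,
                    n_reps = n_eff, n_excluded = excluded,
                    rejection_rate = hits / n_eff,
                    ci_low = ci[1], ci_high = ci[2],
                    stringsAsFactors = FALSE)
  if (keep_pvalues) attr(out, "pvalues") <- pv
  class(out) <- c("marv_eval", "data.frame")
  out
}

#' Re-threshold stored p-values at another level
#'
#' @param eval_result a \code{marv_eval} carrying stored p-values.
#' @param alpha new family-wise level.
#' @return updated \code{marv_eval}.
#' @export
rethreshold <- function(eval_result, alpha) {
  pv <- attr(eval_result, "pvalues")
  if (is.null(pv)) stop("no stored p-values; rerun with keep_pvalues = TRUE")
  thr <- if (eval_result$method == "univariate")
    bonferroni_alpha(alpha, 2) else alpha
  ok <- !is.na(pv)
  hits <- sum(pv[ok] < thr)
  ci <- binom.test(hits, sum(ok))$conf.int
  eval_result$alpha <- alpha
  eval_result$rejection_rate <- hits / sum(ok)
  eval_result$ci_low <- ci[1]; eval_result$ci_high <- ci[2]
  eval_result
}

#' Type-I error / power over a grid of scenarios
#'
#' One row per scenario x method.  For the univariate comparator the
#' family level is Bonferroni-split over the phenotypes, so at
#' \code{alpha = 0.05} each univariate test is judged at 0.025 and the
#' replicate counts as a rejection when the smaller of the two p-values
#' clears that bound.
#'
#' @param scenarios list of \code{\link{sim_scenario}} objects.
#' @param methods subset of c("marv", "univariate").
#' @param alpha family-wise level.
#' @param n_reps replicates per cell; default each scenario's own count.
#' @param keep_pvalues attach the per-cell p-value vectors (one list
#'   entry per output row) as \code{attr(, "pvalues")}.
#' @return a data frame of stacked \code{\link{rejection_rate}} rows.
#'   Methods evaluated on the same scenario share the same simulated
#'   replicates, so their rejection rates are directly comparable.
#' @export
power_grid <- function(scenarios, methods = c("marv", "univariate"),
                       alpha = 0.05, n_reps = NULL, keep_pvalues = FALSE) {
  rows <- list()
  for (sc in scenarios) {
    stream <- replicate_stream(sc)
    pv <- replicate_pvalues(stream, as.list(methods), n_reps = n_reps)
    for (j in seq_along(methods))
      rows[[length(rows) + 1L]] <-
        summarise_rejections(pv[, j], sc, colnames(pv)[j], alpha,
                             keep_pvalues = keep_pvalues)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  pvs <- lapply(rows, attr, "pvalues")
  attr(out, "pvalues") <- if (keep_pvalues) pvs else NULL
  class(out) <- c("marv_eval", "data.frame")
  out
}
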