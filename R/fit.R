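#' Weighted reverse regression of burden on phenotypes
#'
#' Fits, by weighted least squares, the linear model
#' \deqn{p_i = \alpha + y_i^T \beta + e_i,}{p_i = a + y_i' b + e_i,}
#' where \eqn{p_i} is individual i's burden proportion and \eqn{y_i} the
#' phenotype vector restricted to \code{subset}, with per-individual
#' weights \eqn{w_i} (the proportion of the region's variants successfully
#' typed).  The empty subset gives the intercept-only null model.
#'
#' The weighted Gaussian log-likelihood is evaluated at the WLS solution as
#' \deqn{L = -\frac{n}{2}\left[\ln(2\pi\hat\sigma^2) + 1\right]
#'   + \frac12 \sum_i \ln w_i,}{L = -(n/2)[ln(2 pi s2) + 1] + sum(ln w)/2,}
#' with \eqn{\hat\sigma^2 = RSS_w / n}.  The \eqn{\sum \ln w_i} term is the
#' same for every phenotype subset fitted on the same individuals, so it
#' cancels in likelihood-ratio statistics and in BIC differences; with unit
#' weights the likelihood is the classical Gaussian one.
#'
#' @param bd a \code{\link{collapse_region}} result.
#' @param pm a \code{\link{phenotype_matrix}} (sample IDs are matched to
#'   the burden object's).
#' @param subset character vector of phenotype names to include;
#'   \code{character(0)} fits the null model.
#' @param use optional logical/integer index (relative to \code{bd}'s
#'   sample order) fixing the analysis rows, so that several subsets can be
#'   fitted on an identical complete-case set; by default the complete-case
#'   set of \code{subset} itself is used.
#' @return an object of class \code{marv_fit}: subset, intercept,
#'   coefficients, weighted RSS, log-likelihood, BIC, n_used, and the
#'   fitted values/residuals/weights on the analysis set.
#' @seealso \code{\link{marv}} for the full region test.
#' @export
fit_weighted_lm <- function(bd, pm, subset = character(0), use = NULL) {
  stopifnot(inherits(bd, "marv_burden"), inherits(pm, "marv_phenotypes"))
  subset <- as.character(subset)
  bad <- setdiff(subset, pm$phenotype_names)
  if (length(bad))
    stop("unknown phenotype(s): ", paste(bad, collapse = ", "))
  idx <- match(bd$sample_ids, pm$sample_ids)
  y_all <- pm$values[idx, subset, drop = FALSE]
  if (is.null(use)) {
    use <- !bd$excluded & bd$weight > 0 & !is.na(bd$proportion) &
      complete.cases(y_all)
  }
  p <- bd$proportion[use]
  w <- bd$weight[use]
  y <- y_all[use, , drop = FALSE]
  n <- length(p)
  if (n < length(subset) + 2)
    stop("too few individuals (", n, ") to fit ", length(subset),
         " phenotype(s)")
  x <- cbind(`(Intercept)` = 1, y)
  fit <- lm.wfit(x, p, w)
  if (fit$rank < ncol(x)) {
    drop_cols <- colnames(x)[is.na(fit$coefficients)]
    stop("singular fit: design matrix rank-deficient (",
         paste(drop_cols, collapse = ", "), ")")
  }
  res <- fit$residuals
  rss_w <- sum(w * res^2)
  sigma2 <- rss_w / n
  loglik <- if (sigma2 > 0)
    -(n / 2) * (log(2 * pi * sigma2) + 1) + 0.5 * sum(log(w))
  else Inf
  k_bic <- length(subset) + 2  # slopes + intercept + residual variance
  structure(list(subset = subset,
                 intercept = unname(fit$coefficients[1]),
                 coefficients = fit$coefficients[-1],
                 rss_w = rss_w, loglik = loglik, n_used = n,
                 bic = -2 * loglik + k_bic * log(n),
                 fitted = fit$fitted.values, residuals = res,
                 weights = w, use = use),
            class = "marv_fit")
}

#' @export
print.marv_fit <- function(x, ...) {
  lab <- if (length(x$subset)) paste(x$subset, collapse = "+") else "NULL"
  cat("Weighted reverse regression [", lab, "], n =", x$n_used, "\n")
  print(c(`(Intercept)` = x$intercept, x$coefficients))
  cat("weighted RSS:", format(x$rss_w, digits = 6),
      "  logLik:", format(x$loglik, digits = 6),
      "  BIC:", format(x$bic, digits = 6), "\n")
  invisible(x)
}

#' BIC of a fitted reverse regression
#'
#' \code{-2 ln L + K ln N} with \code{K} counting the phenotype slopes,
#' the intercept and the residual variance.  Because every subset is
#' compared on the same analysis set, only BIC differences matter, and any
#' consistent parameter-count convention ranks models identically.
#'
#' @param fit a \code{marv_fit}.
#' @return the BIC value.
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "marv_fit"))
  fit$bic
}

# smallest p-value reported; smaller values are floored and flagged
P_FLOOR <- 1e-300

#' Likelihood-ratio test between nested reverse regressions
#'
#' The statistic \code{2(L_full - L_null)} equals
#' \code{N ln(RSS_null / RSS_full)} under the weighted Gaussian likelihood
#' and is computed in that form for numerical robustness.  It is referred
#' to a chi-square with degrees of freedom equal to the number of
#' phenotypes in the full model.
#'
#' @param full,null \code{marv_fit} objects fitted on the identical
#'   individual set and weights; \code{null} must be the intercept-only
#'   fit.
#' @return a list with \code{statistic}, \code{df} and \code{p} (floored
#'   at 1e-300 with attribute \code{floored}).
#' @export
lrt_pvalue <- function(full, null) {
  stopifnot(inherits(full, "marv_fit"), inherits(null, "marv_fit"))
  if (length(null$subset) != 0)
    stop("null fit must be the intercept-only model")
  if (full$n_used != null$n_used)
    stop("full and null fits use different individual sets")
  n <- full$n_used
  if (full$rss_w > null$rss_w * (1 + 1e-10))
    stop("internal inconsistency: nested WLS fit has larger RSS than null")
  stat <- if (full$rss_w <= 0) Inf else
    n * log(null$rss_w / full$rss_w)
  stat <- max(stat, 0)
  df <- length(full$subset)
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  floored <- p < P_FLOOR
  p <- max(p, P_FLOOR)
  attr(p, "floored") <- floored
  list(statistic = stat, df = df, p = p)
}

#' Enumerate phenotype subsets
#'
#' All \code{2^K - 1} non-empty subsets of the phenotype labels, ordered by
#' subset size and lexicographically (in the order the labels are given)
#' within size, so every singleton — i.e. every univariate test — comes
#' first.
#'
#' @param names K phenotype labels.
#' @param cap refuse enumeration above this K (default 10); pass explicit
#'   subsets to \code{\link{marv}} instead for larger K.
#' @return a list of character vectors.
#' @examples
#' enumerate_subsets(c("TG", "HDL", "LDL"))
#' @export
enumerate_subsets <- function(names, cap = 10) {
  k <- length(names)
  stopifnot(k >= 1)
  if (k > cap)
    stop("K = ", k, " exceeds the subset-enumeration cap (", cap,
         "); supply explicit subsets instead")
  out <- list()
  for (size in seq_len(k))
    out <- c(out, apply(utils::combn(k, size), 2,
                        function(ix) names[ix], simplify = FALSE))
  out
}

#' Multi-phenotype rare-variant burden test for one region
#'
#' The central fitting function.  Collapsed burden proportions are
#' regressed on all K phenotypes jointly by weighted least squares and the
#' joint null of no phenotype effect is tested with a likelihood-ratio
#' statistic on K degrees of freedom ("full model").  With
#' \code{all_subsets = TRUE} every non-empty phenotype combination is
#' refitted on the same complete-case individual set, each with its own
#' LRT p-value and BIC, and the minimum-BIC combination is reported as the
#' best-fitting model (ties broken toward fewer phenotypes, then
#' enumeration order).
#'
#' Individuals missing any phenotype of the full model, with no typed
#' variant, or with zero weight are dropped once, and all models are fitted
#' on the identical remaining set so that BIC values are comparable.
#'
#' @param burden a \code{\link{collapse_region}} result (or a
#'   \code{\link{carrier_matrix}}, which is collapsed first).
#' @param phenotypes a \code{\link{phenotype_matrix}}.
#' @param subset phenotype names forming the full model; default all.
#' @param all_subsets fit every phenotype combination and select by BIC.
#' @param region optional one-row region data frame carried into the
#'   result for reporting.
#' @param n_variants number of collapsed variants (taken from the carrier
#'   matrix when one is supplied).
#' @return an object of class \code{marv}, with \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{fitted} and
#'   \code{residuals} methods.  Fields: \code{full_fit}, \code{null_fit},
#'   \code{lrt_stat}, \code{df}, \code{p_value}, \code{subset_fits}
#'   (data frame, when requested), \code{best_subset}, \code{skipped}.
#'   A region whose burden is constant on the analysis set is skipped:
#'   \code{skipped = TRUE}, no p-value, and \code{reason} says why.
#' @examples
#' sc <- sim_scenario(n_individuals = 300, seed = 7)
#' rep1 <- replicate_stream(sc)$draw(1)
#' bd <- collapse_region(genotype_carriers(rep1$genotypes))
#' marv(bd, rep1$phenotypes)
#' @export
marv <- function(burden, phenotypes, subset = NULL, all_subsets = FALSE,
                 region = NULL, n_variants = NULL) {
  if (inherits(burden, "marv_carriers")) {
    n_variants <- ncol(burden$values)
    burden <- collapse_region(burden)
  }
  stopifnot(inherits(burden, "marv_burden"),
            inherits(phenotypes, "marv_phenotypes"))
  subset <- subset %||% phenotypes$phenotype_names
  n_variants <- n_variants %||% burden$n_variants

  idx <- match(burden$sample_ids, phenotypes$sample_ids)
  y_all <- phenotypes$values[idx, subset, drop = FALSE]
  use <- !burden$excluded & burden$weight > 0 &
    !is.na(burden$proportion) & complete.cases(y_all)
  if (sum(use) == 0)
    stop("no overlapping samples between burden and phenotype data")
  out <- list(region = region, n_variants = n_variants,
              phenotypes = subset, n_used = sum(use))

  if (length(unique(burden$proportion[use])) <= 1) {
    out$skipped <- TRUE
    out$reason <- "constant burden proportion on the analysis set"
    class(out) <- "marv"
    return(out)
  }
  null_fit <- fit_weighted_lm(burden, phenotypes, character(0), use = use)
  full_fit <- fit_weighted_lm(burden, phenotypes, subset, use = use)
  lrt <- lrt_pvalue(full_fit, null_fit)
  out <- c(out, list(skipped = FALSE, full_fit = full_fit,
                     null_fit = null_fit, lrt_stat = lrt$statistic,
                     df = lrt$df, p_value = lrt$p))
  if (all_subsets) {
    subsets <- enumerate_subsets(subset)
    fits <- lapply(subsets, function(s)
      fit_weighted_lm(burden, phenotypes, s, use = use))
    tab <- data.frame(
      model = vapply(subsets, paste, "", collapse = "+"),
      size = lengths(subsets),
      stringsAsFactors = FALSE)
    lrts <- lapply(fits, lrt_pvalue, null = null_fit)
    tab$lrt_stat <- vapply(lrts, `[[`, 0, "statistic")
    tab$df <- vapply(lrts, `[[`, 0L, "df")
    tab$p_value <- vapply(lrts, function(l) as.numeric(l$p), 0)
    tab$bic <- vapply(fits, bic, 0)
    best <- order(tab$bic, tab$size, seq_len(nrow(tab)))[1]
    tab$best <- seq_len(nrow(tab)) == best
    out$subset_fits <- tab
    out$fits <- fits
    out$best_subset <- tab$model[best]
  }
  class(out) <- "marv"
  out
}

#' @export
print.marv <- function(x, ...) {
  cat("Multi-phenotype rare-variant burden test\n")
  if (!is.null(x$region))
    cat("  region:", x$region$name, sprintf("(%s:%d-%d)", x$region$chrom,
        x$region$start, x$region$end), "\n")
  cat("  rare variants:", x$n_variants,
      "  individuals analysed:", x$n_used, "\n")
  if (isTRUE(x$skipped)) {
    cat("  SKIPPED:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  full model [%s]: LRT = %.4f, df = %d, p = %.4g%s\n",
              paste(x$phenotypes, collapse = "+"), x$lrt_stat, x$df,
              x$p_value,
              if (isTRUE(attr(x$p_value, "floored"))) " (floored)" else ""))
  if (!is.null(x$best_subset))
    cat("  best subset (BIC):", x$best_subset, "\n")
  invisible(x)
}

#' @export
summary.marv <- function(object, ...) {
  print(object)
  if (!isTRUE(object$skipped)) {
    cat("\nFull-model coefficients:\n")
    print(c(`(Intercept)` = object$full_fit$intercept,
            object$full_fit$coefficients))
    if (!is.null(object$subset_fits)) {
      cat("\nAll phenotype combinations:\n")
      print(object$subset_fits, row.names = FALSE, digits = 4)
    }
  }
  invisible(object)
}

#' @export
coef.marv <- function(object, ...) {
  if (isTRUE(object$skipped)) return(NULL)
  c(`(Intercept)` = object$full_fit$intercept,
    object$full_fit$coefficients)
}

#' @export
fitted.marv <- function(object, ...) {
  if (isTRUE(object$skipped)) return(NULL)
  object$full_fit$fitted
}

#' @export
residuals.marv <- function(object, ...) {
  if (isTRUE(object$skipped)) return(NULL)
  object$full_fit$residuals
}

#' Predict burden proportions from phenotypes
#'
#' @param object a fitted \code{marv} object.
#' @param newdata matrix or data frame containing the full-model phenotype
#'   columns; default the fitted values.
#' @param ... unused.
#' @export
predict.marv <- function(object, newdata = NULL, ...) {
  if (isTRUE(object$skipped)) return(NULL)
  if (is.null(newdata)) return(object$full_fit$fitted)
  y <- as.matrix(as.data.frame(newdata)[, object$phenotypes, drop = FALSE])
  drop(object$full_fit$intercept +
       y %*% object$full_fit$coefficients[object$phenotypes])
}

#' @export
plot.marv <- function(x, ...) {
  if (is.null(x$subset_fits))
    stop("plot requires a fit with all_subsets = TRUE")
  tab <- x$subset_fits
  d <- tab$bic - min(tab$bic)
  graphics::barplot(d, names.arg = tab$model, las = 2,
                    ylab = expression(Delta * "BIC"),
                    main = "Phenotype combinations", ...)
  invisible(x)
}

#' Univariate forward burden test
#'
#' The classical single-phenotype comparator: the phenotype is regressed
#' on the burden proportion by weighted least squares (same weights as the
#' reverse regression) and the burden slope is tested with a 1-df
#' likelihood-ratio statistic \code{N ln(RSS_0 / RSS_1)}.  With unit
#' weights and a single phenotype this is numerically identical to the
#' reverse-regression test, by symmetry of the squared correlation.
#'
#' @param bd a \code{marv_burden}.
#' @param pm a \code{marv_phenotypes}.
#' @param name the phenotype to test (default the first).
#' @return the p-value, with attributes \code{statistic} and \code{df}.
#' @export
univariate_burden_test <- function(bd, pm, name = pm$phenotype_names[1]) {
  stopifnot(inherits(bd, "marv_burden"), inherits(pm, "marv_phenotypes"))
  idx <- match(bd$sample_ids, pm$sample_ids)
  y <- pm$values[idx, name]
  use <- !bd$excluded & bd$weight > 0 & !is.na(bd$proportion) & !is.na(y)
  p <- bd$proportion[use]; yy <- y[use]; w <- bd$weight[use]
  n <- length(yy)
  if (n < 3) stop("too few individuals for the univariate test")
  x <- cbind(1, p)
  fit <- lm.wfit(x, yy, w)
  if (fit$rank < 2) stop("singular fit: burden proportion is constant")
  rss1 <- sum(w * fit$residuals^2)
  mu <- sum(w * yy) / sum(w)
  rss0 <- sum(w * (yy - mu)^2)
  stat <- if (rss1 <= 0) Inf else max(n * log(rss0 / rss1), 0)
  pv <- max(pchisq(stat, df = 1, lower.tail = FALSE), P_FLOOR)
  attr(pv, "statistic") <- stat
  attr(pv, "df") <- 1L
  pv
}

#' Rank-based inverse-normal transform
#'
#' Maps the non-missing values onto standard-normal quantiles by
#' \eqn{\Phi^{-1}((r_i - c) / (n + 1 - 2c))} with the Blom offset
#' \eqn{c = 3/8}; ties receive average ranks and missing entries are
#' preserved.
#'
#' @param values numeric vector, possibly with NAs.
#' @param c rank offset (default 3/8).
#' @return the transformed vector.
#' @examples
#' inverse_normal_transform(c(1, 2, 3))  # middle value maps to 0
#' @export
inverse_normal_transform <- function(values, c = 3/8) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2) stop("need at least 2 non-missing values to transform")
  out <- rep(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- qnorm((r - c) / (n + 1 - 2 * c))
  out
}

#' Residualise a phenotype on covariates
#'
#' Ordinary least-squares residuals of a phenotype on an intercept plus
#' covariates (e.g. sex, BMI, leading genetic principal components),
#' the standard pre-adjustment applied before the inverse-normal
#' transform.  Rows with a missing phenotype or covariate get NA residuals.
#'
#' @param pheno numeric vector.
#' @param covariates N x C numeric matrix or data frame.
#' @return residual vector of the same length as \code{pheno}.
#' @export
adjust_covariates <- function(pheno, covariates) {
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == length(pheno))
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("C", seq_len(ncol(covariates)))
  ok <- !is.na(pheno) & complete.cases(covariates)
  x <- cbind(`(Intercept)` = 1, covariates[ok, , drop = FALSE])
  fit <- stats::lm.fit(x, pheno[ok])
  if (fit$rank < ncol(x))
    stop("rank-deficient covariates: ",
         paste(colnames(x)[is.na(fit$coefficients)], collapse = ", "))
  out <- rep(NA_real_, length(pheno))
  out[ok] <- fit$residuals
  out
}
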