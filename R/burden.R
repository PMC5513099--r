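#' Collapse a region's carrier matrix into burden proportions
#'
#' For each individual, sums carrier values over the region's rare variants
#' (each variant contributing at most 1 — an indicator for hard calls, a
#' posterior carrier probability for dosages) and divides by the number of
#' variants successfully typed for that individual.  The analysis weight is
#' the proportion of the region's variants that were successfully typed, so
#' data completeness enters the regression exactly once, through the
#' weight.
#'
#' @param cm a \code{\link{carrier_matrix}} with at least one variant.
#' @return an object of class \code{marv_burden}: list with
#'   \code{sample_ids}, \code{proportion} (p_i), \code{weight} (w_i),
#'   \code{n_variants}, \code{n_observed} and logical \code{excluded}
#'   (individuals with no typed variant).
#' @examples
#' cm <- carrier_matrix(matrix(c(1, 0, 1, 0, 0, 1), nrow = 2),
#'                      c("a", "b"),
#'                      data.frame(id = c("v1", "v2", "v3"),
#'                                 chrom = "1", pos = 1:3, maf = 0.01))
#' collapse_region(cm)
#' @export
collapse_region <- function(cm) {
  stopifnot(inherits(cm, "marv_carriers"))
  m <- ncol(cm$values)
  if (m == 0) stop("empty region: no variants to collapse")
  obs <- !is.na(cm$values)
  n_obs <- unname(rowSums(obs))
  r <- unname(rowSums(cm$values, na.rm = TRUE))
  p <- ifelse(n_obs > 0, r / n_obs, NA_real_)
  w <- n_obs / m
  excluded <- n_obs == 0
  if (all(excluded))
    stop("degenerate region: every individual has only missing genotypes")
  structure(list(sample_ids = cm$sample_ids, proportion = p, weight = w,
                 n_variants = m, n_observed = n_obs, excluded = excluded),
            class = "marv_burden")
}

#' @export
print.marv_burden <- function(x, ...) {
  s <- burden_summary(x)
  cat("Burden over", s$n_variants, "rare variants,",
      s$n_individuals, "individuals\n")
  cat("  mean proportion:", format(s$mean_proportion, digits = 4),
      "  mean weight:", format(s$mean_weight, digits = 4), "\n")
  if (s$n_excluded) cat("  excluded individuals:", s$n_excluded, "\n")
  if (s$degenerate) cat("  NOTE: burden is constant (degenerate)\n")
  invisible(x)
}

#' Summarise a burden object
#'
#' Deterministic per-region summary used in logs and result tables.
#'
#' @param bd a \code{marv_burden} object.
#' @return a one-row data frame: variant count, analysed individuals,
#'   excluded count, mean burden proportion, mean weight, and a
#'   \code{degenerate} flag (TRUE when the burden proportion is constant
#'   over the non-excluded individuals, so no test is possible).
#' @export
burden_summary <- function(bd) {
  stopifnot(inherits(bd, "marv_burden"))
  keep <- !bd$excluded
  p <- bd$proportion[keep]
  data.frame(n_variants = bd$n_variants, n_individuals = sum(keep),
             n_excluded = sum(bd$excluded),
             mean_proportion = mean(p),
             mean_weight = mean(bd$weight[keep]),
             degenerate = length(unique(p)) <= 1)
}
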