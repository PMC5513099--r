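test_that("weighted reverse regression recovers exact linear relations", {
  y <- c(-1, 0, 0.5, 1, 2, 3)
  fx <- bd_pm_fixture(p = 0.1 + 0.2 * (y + 2) / 10, y = (y + 2) / 10)
  fit <- fit_weighted_lm(fx$bd, fx$pm, "P1")
  expect_equal(unname(fit$coefficients), 0.2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-12)
  expect_equal(fit$rss_w, 0)
})

test_that("the null fit is the weighted mean", {
  p <- c(0.1, 0.3, 0.2, 0.4)
  fx <- bd_pm_fixture(p, y = rnorm(4))
  null <- fit_weighted_lm(fx$bd, fx$pm, character(0))
  expect_equal(null$intercept, mean(p))
  expect_equal(null$rss_w, sum((p - mean(p))^2))

  w <- c(1, 0.5, 0.8, 0.6)
  fxw <- bd_pm_fixture(p, y = rnorm(4), w = w)
  nullw <- fit_weighted_lm(fxw$bd, fxw$pm, character(0))
  expect_equal(nullw$intercept, sum(w * p) / sum(w))
})

test_that("WLS coefficients match explicit weighted normal equations", {
  set.seed(31)
  w <- c(1, 1, 0.8, 0.8, 0.6, 1)
  y <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("A", "B")))
  p <- 0.1 + 0.05 * y[, 1] - 0.02 * y[, 2] + rnorm(6, sd = 0.03)
  fx <- bd_pm_fixture(p, y, w = w)
  fit <- fit_weighted_lm(fx$bd, fx$pm, c("A", "B"))

  # independent oracle: solve (X' W X) b = X' W p by explicit inversion
  x <- cbind(1, y)
  bhat <- solve(t(x) %*% diag(w) %*% x, t(x) %*% (w * p))
  expect_equal(unname(c(fit$intercept, fit$coefficients)),
               unname(drop(bhat)), tolerance = 1e-10)
  expect_equal(fit$rss_w, sum(w * (p - x %*% bhat)^2), tolerance = 1e-10)
})

test_that("singular designs and tiny samples are rejected with names", {
  set.seed(5)
  y <- cbind(A = rnorm(8), B = 0)
  fx <- bd_pm_fixture(runif(8), y)
  expect_error(fit_weighted_lm(fx$bd, fx$pm, c("A", "B")), "B")
  fx2 <- bd_pm_fixture(runif(2), cbind(A = rnorm(2)))
  expect_error(fit_weighted_lm(fx2$bd, fx2$pm, "A"), "too few")
  expect_error(fit_weighted_lm(fx$bd, fx$pm, "C"), "unknown phenotype")
})

test_that("likelihood-ratio test matches the chi-square oracle", {
  set.seed(8)
  fx <- bd_pm_fixture(runif(10), cbind(A = rnorm(10)))
  null <- fit_weighted_lm(fx$bd, fx$pm, character(0))
  full <- fit_weighted_lm(fx$bd, fx$pm, "A")
  lrt <- lrt_pvalue(full, null)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$statistic,
               10 * log(null$rss_w / full$rss_w), tolerance = 1e-12)
  expect_equal(as.numeric(lrt$p),
               pchisq(lrt$statistic, 1, lower.tail = FALSE))

  # frozen chi-square reference points
  expect_equal(pchisq(3.8415, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-4)
  # N = 100, RSS ratio 1.10, df 2
  expect_equal(100 * log(1.10), 9.531018, tolerance = 1e-6)
  expect_equal(pchisq(100 * log(1.10), 2, lower.tail = FALSE),
               8.5185513e-03, tolerance = 1e-6)
})

test_that("a full fit no better than the null gives statistic 0, p = 1", {
  # phenotype orthogonal to the burden in-sample
  p <- c(0.1, 0.2, 0.3, 0.4)
  y <- cbind(A = c(1, -1, -1, 1))  # orthogonal to the linear trend
  fx <- bd_pm_fixture(p, y)
  null <- fit_weighted_lm(fx$bd, fx$pm, character(0))
  full <- fit_weighted_lm(fx$bd, fx$pm, "A")
  lrt <- lrt_pvalue(full, null)
  expect_equal(lrt$statistic, 0, tolerance = 1e-6)
  expect_equal(as.numeric(lrt$p), 1, tolerance = 1e-6)
})

test_that("BIC follows -2 logLik + K log N with an independent oracle", {
  fake <- structure(list(subset = "A", loglik = -10, n_used = 100,
                         rss_w = 1, bic = -2 * (-10) + 3 * log(100)),
                    class = "marv_fit")
  expect_equal(bic(fake), 20 + 3 * log(100), tolerance = 1e-12)
  expect_equal(bic(fake), 33.81551, tolerance = 1e-5)

  # recompute the likelihood from first principles on a real fit
  set.seed(12)
  w <- runif(30, 0.5, 1)
  fx <- bd_pm_fixture(runif(30), cbind(A = rnorm(30)), w = w)
  fit <- fit_weighted_lm(fx$bd, fx$pm, "A")
  n <- fit$n_used
  s2 <- fit$rss_w / n
  loglik_oracle <- -(n / 2) * (log(2 * pi * s2) + 1) + 0.5 * sum(log(w))
  expect_equal(fit$loglik, loglik_oracle, tolerance = 1e-8)
  expect_equal(bic(fit), -2 * loglik_oracle + 3 * log(n),
               tolerance = 1e-8)
})

test_that("subset enumeration is ordered by size then lexicographically", {
  subs <- enumerate_subsets(c("TG", "HDL", "LDL"))
  expect_length(subs, 7)
  expect_equal(vapply(subs, paste, "", collapse = "+"),
               c("TG", "HDL", "LDL", "TG+HDL", "TG+LDL", "HDL+LDL",
                 "TG+HDL+LDL"))
  expect_equal(enumerate_subsets("TG"), list("TG"))
  expect_error(enumerate_subsets(paste0("P", 1:11)), "cap")
})

test_that("nested fits never fit worse and LRT statistics are nonnegative", {
  set.seed(77)
  for (rep in 1:10) {
    y <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
    w <- runif(20, 0.4, 1)
    fx <- bd_pm_fixture(runif(20), y, w = w)
    null <- fit_weighted_lm(fx$bd, fx$pm, character(0))
    subs <- enumerate_subsets(c("A", "B", "C"))
    rss <- setNames(vapply(subs, function(s)
      fit_weighted_lm(fx$bd, fx$pm, s)$rss_w, 0),
      vapply(subs, paste, "", collapse = "+"))
    for (s in subs)
      for (t in subs)
        if (all(s %in% t))
          expect_lte(rss[paste(t, collapse = "+")],
                     rss[paste(s, collapse = "+")] + 1e-12)
    full <- fit_weighted_lm(fx$bd, fx$pm, c("A", "B", "C"))
    expect_gte(lrt_pvalue(full, null)$statistic, 0)
  }
})

test_that("with unit weights and one phenotype the LRT is symmetric in
           outcome and predictor", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    y <- rnorm(n)
    p <- 0.2 + 0.02 * y + rnorm(n, sd = 0.05)
    fx <- bd_pm_fixture(p, cbind(A = y))
    null <- fit_weighted_lm(fx$bd, fx$pm, character(0))
    full <- fit_weighted_lm(fx$bd, fx$pm, "A")
    reverse_stat <- lrt_pvalue(full, null)$statistic
    forward_p <- univariate_burden_test(fx$bd, fx$pm, "A")
    expect_equal(attr(forward_p, "statistic"), reverse_stat,
                 tolerance = 1e-10)
    expect_equal(as.numeric(forward_p),
                 as.numeric(lrt_pvalue(full, null)$p), tolerance = 1e-10)
  }
})

test_that("rescaling a phenotype rescales its coefficient only", {
  set.seed(55)
  y <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("A", "B")))
  p <- 0.3 + 0.04 * y[, 1] + rnorm(40, sd = 0.05)
  w <- runif(40, 0.5, 1)
  fx <- bd_pm_fixture(p, y, w = w)
  f1 <- marv(fx$bd, fx$pm)

  y2 <- y; y2[, "A"] <- y2[, "A"] * 100
  fx2 <- bd_pm_fixture(p, y2, w = w)
  f2 <- marv(fx2$bd, fx2$pm)
  expect_equal(coef(f2)[["A"]], coef(f1)[["A"]] / 100, tolerance = 1e-10)
  expect_equal(as.numeric(f2$p_value), as.numeric(f1$p_value),
               tolerance = 1e-10)
})

test_that("marv selects a provably minimal-BIC singleton on a strong
           single-phenotype effect", {
  set.seed(21)
  n <- 400
  y <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("A", "B", "C")))
  p <- plogis(-2 + 1.5 * y[, 1]) / 4 + rnorm(n, sd = 0.01)
  p <- pmin(pmax(p, 0), 1)
  fx <- bd_pm_fixture(p, y)
  fit <- marv(fx$bd, fx$pm, all_subsets = TRUE)
  # oracle: recompute all 7 BICs independently and locate the minimum
  bics <- vapply(enumerate_subsets(c("A", "B", "C")), function(s)
    bic(fit_weighted_lm(fx$bd, fx$pm, s)), 0)
  expect_equal(fit$subset_fits$bic, unname(bics), tolerance = 1e-10)
  expect_equal(fit$best_subset,
               c("A", "B", "C", "A+B", "A+C", "B+C",
                 "A+B+C")[which.min(bics)])
  expect_equal(fit$best_subset, "A")
})

test_that("adding a pure-noise phenotype increases BIC at large N", {
  set.seed(33)
  n <- 5000
  y1 <- rnorm(n)
  p <- 0.2 + 0.01 * y1 + rnorm(n, sd = 0.05)
  y <- cbind(A = y1, NOISE = rnorm(n))
  fx <- bd_pm_fixture(p, y)
  expect_lt(bic(fit_weighted_lm(fx$bd, fx$pm, "A")),
            bic(fit_weighted_lm(fx$bd, fx$pm, c("A", "NOISE"))))
})

test_that("a constant burden yields a skip record without a p-value", {
  fx <- bd_pm_fixture(rep(0.2, 10), cbind(A = rnorm(10)))
  fit <- marv(fx$bd, fx$pm)
  expect_true(fit$skipped)
  expect_null(fit$p_value)
  expect_null(coef(fit))
  expect_output(print(fit), "SKIPPED")
})

test_that("marv model methods are coherent with the full fit", {
  set.seed(61)
  y <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("A", "B")))
  p <- 0.2 + 0.05 * y[, 1] + rnorm(50, sd = 0.03)
  fx <- bd_pm_fixture(p, y)
  fit <- marv(fx$bd, fx$pm, all_subsets = TRUE)
  expect_equal(fit$df, 2)
  expect_equal(length(fitted(fit)), fit$n_used)
  expect_equal(fitted(fit) + residuals(fit), p, ignore_attr = TRUE)
  expect_equal(unname(predict(fit, data.frame(A = 0, B = 0))),
               unname(coef(fit)[1]))
  expect_equal(nrow(fit$subset_fits), 3)
  expect_output(summary(fit), "combinations")
})

test_that("inverse-normal transform reproduces Blom scores", {
  out <- inverse_normal_transform(c(1, 2, 3))
  expect_equal(out[2], 0)
  expect_equal(out[1], -out[3])

  # closed-form rank scores for n = 5
  x <- c(5, 1, 3, 2, 4)
  expect_equal(inverse_normal_transform(x),
               qnorm((c(5, 1, 3, 2, 4) - 3 / 8) / (5 + 1 - 2 * 3 / 8)))

  # rank-based: invariant under monotone transforms, near-zero mean
  set.seed(3)
  z <- rexp(101)
  t1 <- inverse_normal_transform(z)
  expect_equal(t1, inverse_normal_transform(log(z)))
  expect_lt(abs(mean(t1)), 1e-10)

  # missing entries are preserved in place
  z[5] <- NA
  expect_true(is.na(inverse_normal_transform(z)[5]))
  expect_error(inverse_normal_transform(c(NA, NA)), "non-missing")
})

test_that("covariate adjustment equals the explicit projection", {
  set.seed(14)
  n <- 30
  covs <- cbind(sex = rbinom(n, 1, 0.5), bmi = rnorm(n, 25, 3),
                pc1 = rnorm(n))
  ph <- 1 + 0.5 * covs[, "bmi"] + rnorm(n)
  res <- adjust_covariates(ph, covs)
  x <- cbind(1, covs)
  h <- x %*% solve(t(x) %*% x) %*% t(x)
  expect_equal(res, drop((diag(n) - h) %*% ph), tolerance = 1e-10)

  # orthogonal covariate -> centred phenotype
  cov0 <- matrix(rep(c(-1, 1), 15), ncol = 1)
  ph0 <- rep(c(2, 2, 6, 6), length.out = 30)
  ph0 <- ph0 - (cov0[, 1] * sum(ph0 * cov0[, 1]) / 30)  # force orthogonality
  expect_equal(adjust_covariates(ph0, cov0), ph0 - mean(ph0),
               tolerance = 1e-10)

  # phenotype exactly linear in covariates -> zero residuals
  expect_equal(adjust_covariates(2 + 3 * covs[, "bmi"],
                                 covs[, "bmi", drop = FALSE]),
               rep(0, n), tolerance = 1e-10)
  expect_error(adjust_covariates(ph, cbind(covs, bmi2 = covs[, "bmi"])),
               "bmi2")
})
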