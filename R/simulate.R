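#' Locus model for simulated gene regions
#'
#' An "average" protein-coding gene is laid out as alternating exons and
#' introns (starting and ending with an exon) plus neutral flanks on both
#' sides.  The defaults — 8 exons of 300 bp and 7 introns of 3 kb — give a
#' coding length of 2.4 kb and a transcript length of 23.4 kb.
#'
#' @param n_exons,exon_len,n_introns,intron_len,flank layout parameters in
#'   base pairs.
#' @return an object of class \code{marv_locus} with the feature table and
#'   derived lengths \code{coding_len}, \code{transcript_len},
#'   \code{total_len}.
#' @examples
#' build_locus()  # coding 2400 bp, transcript 23400 bp
#' @export
build_locus <- function(n_exons = 8, exon_len = 300, n_introns = 7,
                        intron_len = 3000, flank = 100000) {
  if (n_introns != n_exons - 1)
    stop("non-alternating layout: need n_introns = n_exons - 1")
  lens <- integer(0); types <- character(0)
  for (i in seq_len(n_exons)) {
    lens <- c(lens, exon_len); types <- c(types, "exon")
    if (i < n_exons) { lens <- c(lens, intron_len); types <- c(types, "intron") }
  }
  lens <- c(flank, lens, flank)
  types <- c("flank", types, "flank")
  end <- cumsum(lens)
  features <- data.frame(type = types, start = c(1L, head(end, -1) + 1L),
                         end = end, stringsAsFactors = FALSE)
  structure(list(n_exons = n_exons, exon_len = exon_len,
                 n_introns = n_introns, intron_len = intron_len,
                 flank_len = flank, features = features,
                 coding_len = n_exons * exon_len,
                 transcript_len = n_exons * exon_len +
                   n_introns * intron_len,
                 total_len = sum(lens)),
            class = "marv_locus")
}

#' @export
print.marv_locus <- function(x, ...) {
  cat("Simulated locus:", x$n_exons, "exons x", x$exon_len, "bp,",
      x$n_introns, "introns x", x$intron_len, "bp,",
      "flanks", x$flank_len, "bp\n")
  cat("  coding:", x$coding_len, "bp  transcript:", x$transcript_len,
      "bp  total span:", x$total_len, "bp\n")
  invisible(x)
}

#' Draw minor allele frequencies from a calibrated rare-shifted spectrum
#'
#' MAFs are drawn from a Beta distribution truncated to (0, 0.5], with a
#' small first shape parameter so the density rises steeply toward zero —
#' a parametric stand-in for the neutral site-frequency spectrum — and the
#' second shape parameter solved numerically so that the expected fraction
#' of variants with MAF below 5\% equals \code{rare_fraction_target}
#' (default 0.96).  A target of 1 truncates the distribution at 0.05
#' instead, so every draw is rare.
#'
#' @param m number of variants.
#' @param rare_fraction_target expected P(MAF < 0.05); in (0, 1].
#' @param shape1 first Beta shape; default 0.1.
#' @param seed optional RNG seed (caller's RNG state is restored).
#' @return numeric vector of m MAFs in (0, 0.5].
#' @export
sample_maf_spectrum <- function(m, rare_fraction_target = 0.96,
                                shape1 = 0.1, seed = NULL) {
  stopifnot(m >= 1, rare_fraction_target > 0, rare_fraction_target <= 1)
  local_seed(seed)
  if (rare_fraction_target >= 1) {
    upper <- 0.05
    shape2 <- spectrum_shape2(0.96, shape1)  # rare-range shape unchanged
  } else {
    upper <- 0.5
    shape2 <- spectrum_shape2(rare_fraction_target, shape1)
  }
  u <- runif(m)
  qbeta(u * pbeta(upper, shape1, shape2), shape1, shape2)
}

spectrum_shape2 <- function(target, shape1) {
  f <- function(b) pbeta(0.05, shape1, b) / pbeta(0.5, shape1, b) - target
  if (f(1e-4) > 0 && f(1e4) > 0 || f(1e-4) < 0 && f(1e4) < 0)
    stop("spectrum calibration failed: target ", target,
         " unattainable with shape1 = ", shape1)
  uniroot(f, c(1e-4, 1e4), tol = 1e-10)$root
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Allele counts are drawn independently per variant as Binomial(2, MAF).
#'
#' @param mafs per-variant minor allele frequencies in (0, 0.5].
#' @param n number of individuals.
#' @param seed optional RNG seed.
#' @param causal_idx optional causal-variant indices carried in the result.
#' @return an object of class \code{marv_genotypes}: list with
#'   \code{allele_counts} (n x m integer matrix), \code{mafs},
#'   \code{causal_idx} and \code{sample_ids}.
#' @export
simulate_genotypes <- function(mafs, n, seed = NULL, causal_idx = integer(0)) {
  stopifnot(all(mafs > 0), all(mafs <= 0.5))
  local_seed(seed)
  m <- length(mafs)
  g <- matrix(rbinom(n * m, 2L, rep(mafs, each = n)), nrow = n, ncol = m)
  colnames(g) <- paste0("v", seq_len(m))
  structure(list(allele_counts = g, mafs = mafs, causal_idx = causal_idx,
                 sample_ids = paste0("id", seq_len(n))),
            class = "marv_genotypes")
}

#' Convert simulated genotypes to a carrier matrix
#'
#' Applies the rare-variant filter on the sample's computed MAF (variants
#' must be polymorphic in the sample and below \code{maf_max}) and maps
#' allele counts to the 0/1 carrier indicator.
#'
#' @param gs a \code{marv_genotypes} object.
#' @param maf_max exclusive MAF bound, default 0.05; \code{NULL} keeps all
#'   polymorphic variants.
#' @return a \code{\link{carrier_matrix}}.
#' @export
genotype_carriers <- function(gs, maf_max = 0.05) {
  stopifnot(inherits(gs, "marv_genotypes"))
  g <- gs$allele_counts
  n <- nrow(g)
  maf <- colMeans(g) / 2
  maf <- pmin(maf, 1 - maf)
  keep <- maf > 0
  if (!is.null(maf_max)) keep <- keep & maf < maf_max
  g <- g[, keep, drop = FALSE]
  carrier_matrix(pmin(g, 1L), gs$sample_ids,
                 data.frame(id = colnames(g), chrom = "1",
                            pos = which(keep), maf = maf[keep],
                            stringsAsFactors = FALSE))
}

#' Select causal variants under MAF constraints
#'
#' Draws variants at random, without replacement, among those with MAF
#' below \code{maf_cap} (default 2\%), accumulating while the sum of the
#' selected MAFs stays at or below \code{sum_cap} (default 5\%); selection
#' stops at the first candidate that would breach the cap.  At least one
#' variant is always selected.
#'
#' @param mafs per-variant MAFs.
#' @param maf_cap individual-MAF eligibility bound.
#' @param sum_cap bound on the summed MAF of the selected set.
#' @param seed optional RNG seed.
#' @return integer vector of causal indices.
#' @export
select_causal <- function(mafs, maf_cap = 0.02, sum_cap = 0.05,
                          seed = NULL) {
  eligible <- which(mafs < maf_cap)
  if (!length(eligible))
    stop("no variants with MAF below ", maf_cap, " to select from")
  local_seed(seed)
  ord <- eligible[sample.int(length(eligible))]
  total <- 0; out <- integer(0)
  for (i in ord) {
    if (length(out) && total + mafs[i] > sum_cap) break
    out <- c(out, i)
    total <- total + mafs[i]
  }
  sort(out)
}

#' Describe one simulation scenario
#'
#' A scenario fixes everything needed to regenerate a replicate stream:
#' sample size, number of rare variants, causal-effect size and pattern,
#' phenotype correlation, replicate count and master seed.  Two continuous
#' phenotypes are simulated as
#' \deqn{y_j = \sum_k \beta_{kj} g_k + \epsilon_j,}{y_j = sum_k b_kj g_k + e_j,}
#' with \eqn{(\epsilon_1, \epsilon_2)} bivariate normal with unit
#' variances and correlation \code{rho}, and \eqn{g_k} the causal allele
#' counts.  Effect patterns for the second phenotype relative to the
#' first: \code{"a"} same direction and magnitude, \code{"b"} opposite
#' direction, \code{"c"} same direction at half magnitude, \code{"d"} no
#' effect.  \code{direction_mix = "half"} flips the sign of
#' \eqn{\beta_{k1}} for every second causal variant (half trait-increasing,
#' half trait-decreasing).
#'
#' @param n_individuals N per replicate.
#' @param n_variants number of rare variants in the simulated region.
#' @param beta causal effect magnitude per minor allele (0 = null).
#' @param effect_pattern one of "a", "b", "c", "d".
#' @param direction_mix "increasing" (all effects +beta) or "half".
#' @param rho phenotype correlation in [-0.9, 0.9].
#' @param n_replicates replicate count.
#' @param maf_cap,sum_cap causal-selection constraints
#'   (\code{\link{select_causal}}).
#' @param rare_fraction_target spectrum calibration target
#'   (\code{\link{sample_maf_spectrum}}).
#' @param seed master seed; all randomness in the stream derives from it.
#' @return an object of class \code{marv_scenario}.
#' @export
sim_scenario <- function(n_individuals = 1000, n_variants = 150,
                         beta = 0, effect_pattern = c("a", "b", "c", "d"),
                         direction_mix = c("increasing", "half"),
                         rho = 0, n_replicates = 100,
                         maf_cap = 0.02, sum_cap = 0.05,
                         rare_fraction_target = 0.96, seed = 42) {
  effect_pattern <- match.arg(effect_pattern)
  direction_mix <- match.arg(direction_mix)
  if (abs(rho) > 0.9)
    stop("rho must lie in [-0.9, 0.9]")
  stopifnot(n_individuals >= 10, n_variants >= 1, n_replicates >= 1)
  structure(list(n_individuals = n_individuals, n_variants = n_variants,
                 beta = beta, effect_pattern = effect_pattern,
                 direction_mix = direction_mix, rho = rho,
                 n_replicates = n_replicates, maf_cap = maf_cap,
                 sum_cap = sum_cap,
                 rare_fraction_target = rare_fraction_target,
                 seed = as.integer(seed)),
            class = "marv_scenario")
}

#' @export
print.marv_scenario <- function(x, ...) {
  cat("Simulation scenario: N =", x$n_individuals, ", M =", x$n_variants,
      ", beta =", x$beta, "\n")
  cat("  pattern", x$effect_pattern, "/", x$direction_mix,
      " rho =", x$rho, " replicates =", x$n_replicates,
      " seed =", x$seed, "\n")
  invisible(x)
}

# per-phenotype effect vectors implied by the scenario
scenario_betas <- function(scenario, n_causal) {
  b1 <- rep(scenario$beta, n_causal)
  if (scenario$direction_mix == "half")
    b1 <- b1 * rep_len(c(1, -1), n_causal)
  b2 <- switch(scenario$effect_pattern,
               a = b1, b = -b1, c = b1 / 2, d = rep(0, n_causal))
  cbind(y1 = b1, y2 = b2)
}

#' Simulate two correlated phenotypes from causal genotypes
#'
#' @param gs a \code{marv_genotypes} with \code{causal_idx} set (may be
#'   empty for a pure-noise draw).
#' @param scenario a \code{marv_scenario}.
#' @param seed optional RNG seed for the error draw.
#' @return a \code{\link{phenotype_matrix}} with phenotypes y1, y2.
#' @export
simulate_phenotypes <- function(gs, scenario, seed = NULL) {
  stopifnot(inherits(gs, "marv_genotypes"),
            inherits(scenario, "marv_scenario"))
  if (abs(scenario$rho) >= 1) stop("|rho| must be < 1")
  local_seed(seed)
  n <- nrow(gs$allele_counts)
  sigma <- matrix(c(1, scenario$rho, scenario$rho, 1), 2)
  eps <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = sigma)
  y <- eps
  k <- length(gs$causal_idx)
  if (k && scenario$beta != 0) {
    b <- scenario_betas(scenario, k)
    y <- y + gs$allele_counts[, gs$causal_idx, drop = FALSE] %*% b
  }
  colnames(y) <- c("y1", "y2")
  phenotype_matrix(y, gs$sample_ids)
}

#' Deterministic replicate stream for a scenario
#'
#' Draws the MAF spectrum and the causal-variant set once per scenario —
#' the causal set is held fixed across all replicates — and regenerates
#' genotypes and phenotypes per replicate from seeds derived from the
#' scenario's master seed, so replicate \code{i} is reproducible in
#' isolation.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @return a list with the frozen \code{mafs} and \code{causal_idx} and a
#'   function \code{draw(i)} returning
#'   \code{list(genotypes, phenotypes)} for replicate i.
#' @export
replicate_stream <- function(scenario) {
  stopifnot(inherits(scenario, "marv_scenario"))
  seeds <- derive_seeds(scenario$seed, 3)
  mafs <- sample_maf_spectrum(scenario$n_variants,
                              scenario$rare_fraction_target,
                              seed = seeds[1])
  causal_idx <- select_causal(mafs, scenario$maf_cap, scenario$sum_cap,
                              seed = seeds[2])
  rep_seeds <- derive_seeds(seeds[3], 2 * scenario$n_replicates)
  draw <- function(i) {
    stopifnot(i >= 1, i <= scenario$n_replicates)
    gs <- simulate_genotypes(mafs, scenario$n_individuals,
                             seed = rep_seeds[2 * i - 1],
                             causal_idx = causal_idx)
    pm <- simulate_phenotypes(gs, scenario, seed = rep_seeds[2 * i])
    list(genotypes = gs, phenotypes = pm)
  }
  list(scenario = scenario, mafs = mafs, causal_idx = causal_idx,
       draw = draw)
}

#' Write simulated genotypes as GEN/SAMPLE and phenotype files
#'
#' Materialises one replicate as IMPUTE2-style fixture files so the full
#' file-based analysis path can be exercised without external data: hard
#' allele counts become degenerate probability triplets.
#'
#' @param gs a \code{marv_genotypes}.
#' @param pm a \code{marv_phenotypes} for the same individuals.
#' @param prefix output path prefix; writes \code{<prefix>.gen},
#'   \code{<prefix>.sample} and \code{<prefix>.pheno}.
#' @return invisibly, the three file paths.
#' @export
write_gen_sample <- function(gs, pm, prefix) {
  g <- gs$allele_counts
  n <- nrow(g); m <- ncol(g)
  trip <- matrix(0, nrow = m, ncol = 3 * n)
  for (code in 0:2) {
    hit <- t(g) == code
    trip[, seq(code + 1, 3 * n, by = 3)][hit] <- 1
  }
  gen <- data.frame(snp = paste0("snp", seq_len(m)), rsid = colnames(g),
                    pos = seq_len(m), a = "A", b = "G",
                    stringsAsFactors = FALSE)
  gen_path <- paste0(prefix, ".gen")
  write.table(cbind(gen, trip), gen_path, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  sample_path <- paste0(prefix, ".sample")
  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               paste(gs$sample_ids, gs$sample_ids, 0)), sample_path)
  pheno_path <- paste0(prefix, ".pheno")
  write.table(data.frame(ID = pm$sample_ids, pm$values,
                         check.names = FALSE),
              pheno_path, row.names = FALSE, quote = FALSE)
  invisible(c(gen = gen_path, sample = sample_path, pheno = pheno_path))
}
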