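#' Read region definitions
#'
#' Reads a tab- or whitespace-delimited file with four columns
#' (name, chrom, start, end) into a data frame of regions.  Coordinates are
#' 1-based and inclusive, matching VCF \code{POS}; files exported from UCSC
#' (0-based half-open starts) can be converted with \code{ucsc = TRUE},
#' which adds 1 to every start.
#'
#' @param path path to the region file (no header; comment lines starting
#'   with \code{#} are ignored).
#' @param ucsc logical; treat starts as 0-based half-open and convert.
#' @return a data frame with columns \code{name}, \code{chrom},
#'   \code{start}, \code{end}, one row per region in file order, of class
#'   \code{c("marv_regions", "data.frame")}.
#' @examples
#' tf <- tempfile()
#' writeLines("GENE1\t1\t100\t200", tf)
#' read_regions(tf)
#' @export
read_regions <- function(path, ucsc = FALSE) {
  if (!file.exists(path)) stop("region file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  out <- data.frame(name = character(0), chrom = character(0),
                    start = integer(0), end = integer(0),
                    stringsAsFactors = FALSE)
  idx <- which(keep)
  if (length(idx)) {
    fields <- strsplit(trimws(lines[idx]), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 4))
      stop("malformed region row at line ", idx[which(nf < 4)[1]],
           ": expected 4 columns (name, chrom, start, end)")
    start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
    end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4)))
    if (anyNA(start) || anyNA(end))
      stop("malformed region row at line ",
           idx[which(is.na(start) | is.na(end))[1]],
           ": non-integer start/end")
    if (ucsc) start <- start + 1L
    bad <- start > end
    if (any(bad))
      stop("invalid region at line ", idx[which(bad)[1]], ": start > end")
    out <- data.frame(name = vapply(fields, `[`, "", 1),
                      chrom = vapply(fields, `[`, "", 2),
                      start = start, end = end, stringsAsFactors = FALSE)
  }
  class(out) <- c("marv_regions", "data.frame")
  out
}

#' Construct a single region
#'
#' @param name region/gene label.
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive bounds, \code{start <= end}.
#' @return a one-row region data frame as from \code{\link{read_regions}}.
#' @export
region <- function(name, chrom, start, end) {
  stopifnot(start <= end)
  structure(data.frame(name = name, chrom = as.character(chrom),
                       start = as.integer(start), end = as.integer(end),
                       stringsAsFactors = FALSE),
            class = c("marv_regions", "data.frame"))
}

#' Construct a carrier matrix
#'
#' A carrier matrix holds, for N individuals by M variants, the probability
#' that the individual carries at least one minor allele at the variant:
#' 0/1 for hard genotype calls, the posterior probability of being
#' heterozygous or minor-homozygous for imputed dosages, \code{NA} for
#' missing genotypes.
#'
#' @param values N x M numeric matrix in [0, 1] (or NA).
#' @param sample_ids length-N character vector.
#' @param variants data frame with one row per variant, columns \code{id},
#'   \code{chrom}, \code{pos}, \code{maf} and optionally \code{info}.
#' @return an object of class \code{marv_carriers}.
#' @export
carrier_matrix <- function(values, sample_ids, variants) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(sample_ids),
            ncol(values) == nrow(variants))
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop("carrier values must lie in [0, 1]")
  if (!is.null(variants$maf) &&
      any(variants$maf < 0 | variants$maf > 0.5, na.rm = TRUE))
    stop("variant MAF must lie in [0, 0.5]")
  rownames(values) <- sample_ids
  colnames(values) <- variants$id
  structure(list(values = values, sample_ids = as.character(sample_ids),
                 variants = as.data.frame(variants)),
            class = "marv_carriers")
}

#' @export
print.marv_carriers <- function(x, ...) {
  cat("Carrier matrix:", length(x$sample_ids), "individuals x",
      nrow(x$variants), "variants\n")
  cat("  missing entries:", sum(is.na(x$values)), "\n")
  invisible(x)
}

#' @export
dim.marv_carriers <- function(x) dim(x$values)

#' Minor allele frequency from dosages
#'
#' Computes the folded allele frequency \code{min(f, 1 - f)} where
#' \code{f = sum(dosages) / (2 * number of non-missing individuals)}.
#'
#' @param dosages per-individual allele-count dosages in [0, 2]; NA allowed.
#' @return the minor allele frequency in [0, 0.5].
#' @examples
#' compute_maf(c(0, 0, 1, 1))  # 0.25
#' @export
compute_maf <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("MAF undefined: all dosages missing")
  f <- sum(dosages[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

# carrier probability and expected dosage from a genotype-probability
# triplet matrix (N x 3: hom-a, het, hom-b), given which allele is minor
triplet_to_carrier <- function(p, minor_is_b, tol = 0.02) {
  mass <- rowSums(p)
  bad <- is.na(mass) | abs(mass - 1) > tol
  carrier <- if (minor_is_b) p[, 2] + p[, 3] else p[, 2] + p[, 1]
  carrier[bad] <- NA_real_
  carrier <- pmin(pmax(carrier, 0), 1)
  list(carrier = carrier, n_bad = sum(bad))
}

#' Read a region's rare variants from a VCF file
#'
#' Extracts variants within a region from a VCF 4.x file, applies the
#' standard rare-variant filters (computed MAF below \code{maf_max},
#' imputation info at least \code{info_min}), and converts genotypes to a
#' carrier matrix.  Hard calls (\code{GT}) map to the 0/1 indicator of
#' carrying at least one minor allele; genotype probabilities (\code{GP},
#' biallelic sites only) map to P(het) + P(minor hom).  Which allele is
#' "minor" is decided from the sample's computed allele frequency, not from
#' the REF/ALT labels.  Multi-allelic sites are decomposed so that each
#' alternate allele is filtered and collapsed as an independent variant.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param region a one-row region data frame, e.g. from
#'   \code{\link{read_regions}}.
#' @param maf_max exclusive upper MAF bound; default 0.05.
#' @param info_min inclusive lower info-score bound; default 0.4.  Variants
#'   without an info score (directly genotyped) pass.
#' @param info_key INFO-field key carrying the imputation quality
#'   (default \code{"INFO"}; \code{"R2"} is also common).
#' @param use_gp if TRUE (default) prefer GP dosage probabilities over GT
#'   when both are present at biallelic sites.
#' @return a \code{\link{carrier_matrix}}; zero variants surviving the
#'   filters yields an empty matrix with attribute \code{skip = TRUE}.
#' @export
read_vcf_region <- function(path, region, maf_max = 0.05, info_min = 0.4,
                            info_key = "INFO", use_gp = TRUE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  stopifnot(maf_max > 0, maf_max <= 0.5, info_min >= 0, info_min <= 1)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  pos <- as.integer(fix[, "POS"])
  in_region <- fix[, "CHROM"] == as.character(region$chrom) &
    pos >= region$start & pos <= region$end
  sample_ids <- colnames(v@gt)[-1]
  n <- length(sample_ids)

  cols <- list(); meta <- list()
  for (i in which(in_region)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    info_val <- vcf_info_value(fix[i, "INFO"], info_key)
    gt <- vcf_field(v, i, "GT")
    gp <- if (use_gp && length(alts) == 1) vcf_field(v, i, "GP") else NULL
    for (a in seq_along(alts)) {
      if (!is.null(gp)) {
        p <- do.call(rbind, lapply(strsplit(gp, ","), function(x)
          suppressWarnings(as.numeric(x[1:3]))))
        dos <- p[, 2] + 2 * p[, 3]
        f_alt <- if (all(is.na(dos))) NA else
          sum(dos, na.rm = TRUE) / (2 * sum(!is.na(dos)))
        if (is.na(f_alt)) next
        carrier <- triplet_to_carrier(p, minor_is_b = f_alt <= 0.5)$carrier
        maf <- min(f_alt, 1 - f_alt)
      } else {
        counts <- gt_allele_count(gt, a)
        if (all(is.na(counts))) next
        f_alt <- sum(counts, na.rm = TRUE) / (2 * sum(!is.na(counts)))
        maf <- min(f_alt, 1 - f_alt)
        carrier <- if (f_alt <= 0.5) pmin(counts, 1) else
          pmin(2 - counts, 1)
      }
      if (!(maf > 0 && maf < maf_max)) next
      if (!is.na(info_val) && info_val < info_min) next
      id <- fix[i, "ID"]
      if (is.na(id) || id == ".")
        id <- paste0(fix[i, "CHROM"], ":", pos[i])
      if (length(alts) > 1) id <- paste0(id, "_", alts[a])
      cols[[length(cols) + 1L]] <- carrier
      meta[[length(meta) + 1L]] <- data.frame(
        id = id, chrom = fix[i, "CHROM"], pos = pos[i], maf = maf,
        info = info_val, stringsAsFactors = FALSE)
    }
  }
  if (!length(cols)) {
    cm <- carrier_matrix(matrix(numeric(0), nrow = n, ncol = 0),
                         sample_ids,
                         data.frame(id = character(0), chrom = character(0),
                                    pos = integer(0), maf = numeric(0),
                                    info = numeric(0)))
    attr(cm, "skip") <- TRUE
    return(cm)
  }
  carrier_matrix(do.call(cbind, cols), sample_ids, do.call(rbind, meta))
}

# extract one FORMAT sub-field for one variant row as a character vector
vcf_field <- function(v, i, key) {
  fmt <- strsplit(v@gt[i, 1], ":", fixed = TRUE)[[1]]
  k <- match(key, fmt)
  if (is.na(k)) return(NULL)
  entries <- strsplit(v@gt[i, -1], ":", fixed = TRUE)
  vapply(entries, function(x) if (length(x) >= k) x[k] else NA_character_,
         "")
}

vcf_info_value <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))[[1]]
  if (length(m) < 2) NA_real_ else suppressWarnings(as.numeric(m[2]))
}

# count of allele `a` (1-based ALT index) in a GT string vector;
# half-missing calls like ./1 are treated as missing
gt_allele_count <- function(gt, a) {
  vapply(gt, function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al == as.character(a))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a region from IMPUTE2 GEN/SAMPLE files
#'
#' Parses the GEN dosage format (five leading columns: SNP id, rsid,
#' position, allele A, allele B, then three genotype probabilities per
#' individual ordered AA, AB, BB) together with its SAMPLE file, restricts
#' to a region, applies MAF and info filters, and emits a carrier matrix
#' with carrier value P(AB) + P(minor hom).  The minor allele is decided
#' from the computed sample allele frequency.  Probability triplets whose
#' mass differs from 1 by more than \code{mass_tol} are set missing, with
#' one summary warning.
#'
#' @param gen_path path to the GEN file.
#' @param sample_path path to the SAMPLE file (two header lines).
#' @param region one-row region data frame; chromosome is taken from the
#'   region (GEN files carry no chromosome column in this dialect).
#' @param maf_max,info_min filters as in \code{\link{read_vcf_region}}.
#' @param info_score optional per-variant info vector aligned to GEN rows;
#'   GEN files carry no quality metric, so absent scores pass the filter.
#' @param mass_tol tolerance on |sum(triplet) - 1|; default 0.02.
#' @return a \code{\link{carrier_matrix}}.
#' @export
read_gen_sample <- function(gen_path, sample_path, region, maf_max = 0.05,
                            info_min = 0.4, info_score = NULL,
                            mass_tol = 0.02) {
  if (!file.exists(gen_path)) stop("GEN file not found: ", gen_path)
  if (!file.exists(sample_path)) stop("SAMPLE file not found: ", sample_path)
  smp <- read.table(sample_path, header = TRUE, stringsAsFactors = FALSE)
  smp <- smp[-1, , drop = FALSE]  # drop the type row (0/D/C/P codes)
  sample_ids <- as.character(if ("ID_2" %in% names(smp)) smp$ID_2
                             else smp[[1]])
  n <- length(sample_ids)
  gen <- read.table(gen_path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(gen) && ncol(gen) != 5 + 3 * n)
    stop("GEN/SAMPLE mismatch: expected ", 5 + 3 * n, " columns for ", n,
         " individuals, found ", ncol(gen))
  pos <- as.integer(gen[[3]])
  keep_pos <- which(pos >= region$start & pos <= region$end)
  cols <- list(); meta <- list(); n_bad <- 0L
  for (j in keep_pos) {
    p <- matrix(as.numeric(gen[j, -(1:5)]), ncol = 3, byrow = TRUE)
    mass <- rowSums(p)
    bad <- is.na(mass) | abs(mass - 1) > mass_tol
    n_bad <- n_bad + sum(bad)
    dos <- p[, 2] + 2 * p[, 3]
    dos[bad] <- NA
    if (all(is.na(dos))) next
    f_b <- sum(dos, na.rm = TRUE) / (2 * sum(!is.na(dos)))
    maf <- min(f_b, 1 - f_b)
    if (!(maf > 0 && maf < maf_max)) next
    info <- if (is.null(info_score)) NA_real_ else info_score[j]
    if (!is.na(info) && info < info_min) next
    tc <- triplet_to_carrier(p, minor_is_b = f_b <= 0.5, tol = mass_tol)
    cols[[length(cols) + 1L]] <- tc$carrier
    meta[[length(meta) + 1L]] <- data.frame(
      id = as.character(gen[j, 2]), chrom = as.character(region$chrom),
      pos = pos[j], maf = maf, info = info, stringsAsFactors = FALSE)
  }
  if (n_bad > 0)
    warning(n_bad, " genotype probability triplet(s) with |mass - 1| > ",
            mass_tol, " set to missing")
  if (!length(cols)) {
    cm <- carrier_matrix(matrix(numeric(0), nrow = n, ncol = 0), sample_ids,
                         data.frame(id = character(0), chrom = character(0),
                                    pos = integer(0), maf = numeric(0),
                                    info = numeric(0)))
    attr(cm, "skip") <- TRUE
    return(cm)
  }
  carrier_matrix(do.call(cbind, cols), sample_ids, do.call(rbind, meta))
}

#' Read a phenotype table
#'
#' Reads a whitespace-delimited phenotype file with a header row whose
#' first column is the sample identifier, extracts the requested phenotype
#' columns, and flags binary columns (values within \{0, 1\} plus missing).
#'
#' @param path path to the phenotype file.
#' @param names character vector of phenotype column names to extract;
#'   default all columns after the first.
#' @param missing_code string coding missing values; default \code{"NA"}.
#' @return an object of class \code{marv_phenotypes}: a list with
#'   \code{values} (N x K numeric matrix), \code{sample_ids},
#'   \code{phenotype_names} and \code{types} ("continuous" or "binary").
#' @export
read_phenotypes <- function(path, names = NULL, missing_code = "NA") {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    na.strings = missing_code, check.names = FALSE)
  if (is.null(names)) names <- colnames(tab)[-1]
  miss <- setdiff(names, colnames(tab))
  if (length(miss))
    stop("phenotype(s) not found in header: ", paste(miss, collapse = ", "))
  vals <- as.matrix(tab[, names, drop = FALSE])
  storage.mode(vals) <- "double"
  phenotype_matrix(vals, sample_ids = as.character(tab[[1]]))
}

#' Construct a phenotype matrix
#'
#' @param values N x K numeric matrix (colnames are the phenotype names).
#' @param sample_ids length-N identifiers.
#' @param types optional per-phenotype "continuous"/"binary"; auto-detected
#'   when omitted (a column is binary iff its non-missing values are all
#'   0 or 1).
#' @return an object of class \code{marv_phenotypes}.
#' @export
phenotype_matrix <- function(values, sample_ids, types = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(sample_ids))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("P", seq_len(ncol(values)))
  if (is.null(types)) {
    types <- apply(values, 2, function(x)
      if (all(x[!is.na(x)] %in% c(0, 1))) "binary" else "continuous")
  }
  types <- as.character(types)
  for (k in seq_len(ncol(values)))
    if (types[k] == "binary" &&
        !all(values[!is.na(values[, k]), k] %in% c(0, 1)))
      stop("binary phenotype '", colnames(values)[k],
           "' takes values outside {0, 1}")
  rownames(values) <- sample_ids
  structure(list(values = values, sample_ids = as.character(sample_ids),
                 phenotype_names = colnames(values),
                 types = setNames(types, colnames(values))),
            class = "marv_phenotypes")
}

#' @export
print.marv_phenotypes <- function(x, ...) {
  cat("Phenotype matrix:", length(x$sample_ids), "individuals x",
      length(x$phenotype_names), "phenotypes\n")
  cat(" ", paste0(x$phenotype_names, " (", x$types, ")", collapse = ", "),
      "\n")
  invisible(x)
}

#' Write / read a carrier matrix as a plain-text fixture
#'
#' Tab-delimited interchange format used for debugging and round-trip
#' tests: a variant header block followed by one row per individual.
#'
#' @param cm a \code{\link{carrier_matrix}}.
#' @param path output / input path.
#' @return \code{read_carrier_fixture} returns the reconstructed
#'   \code{marv_carriers} object.
#' @export
write_carrier_fixture <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#variants\t", nrow(cm$variants)), con)
  write.table(cm$variants, con, sep = "\t", row.names = FALSE,
              quote = FALSE)
  df <- data.frame(sample_id = cm$sample_ids, cm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_carrier_fixture
#' @export
read_carrier_fixture <- function(path) {
  lines <- readLines(path)
  m <- as.integer(sub("#variants\t", "", lines[1], fixed = TRUE))
  variants <- read.table(text = lines[2:(2 + m)], header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  body <- read.table(text = lines[-(1:(2 + m))], header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, check.names = FALSE)
  carrier_matrix(as.matrix(body[, -1, drop = FALSE]),
                 as.character(body[[1]]), variants)
}
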