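# Programmatic fixtures shared across test files.

# Minimal VCF with 4 samples covering hard calls, missing genotypes,
# a GP-dosage variant, an INFO-filtered variant, a common variant and a
# multi-allelic site.
write_test_vcf <- function(path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"info score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype probs\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", "S4", "S5", "S6", sep = "\t"))
  rows <- c(
    # hard-call variant, alt freq 0.3: carriers 0,1,1,NA,0,0
    paste("1", 110, "rs1", "A", "G", ".", ".", ".", "GT",
          "0/0", "0/1", "1/1", "./.", "0/0", "0/0", sep = "\t"),
    # GP variant, alt minor: carriers 0.8, 0, 0, 0, 0, 0 (S1 het-ish)
    paste("1", 120, "rs2", "C", "T", ".", ".", "INFO=0.9", "GT:GP",
          "0/1:0.2,0.5,0.3", "0/0:1,0,0", "0/0:1,0,0", "0/0:1,0,0",
          "0/0:1,0,0", "0/0:1,0,0", sep = "\t"),
    # fails the info filter
    paste("1", 130, "rs3", "A", "C", ".", ".", "INFO=0.2", "GT",
          "0/1", "0/0", "0/0", "0/0", "0/0", "0/0", sep = "\t"),
    # folded MAF exactly 0.5: never passes a strict MAF bound
    paste("1", 140, "rs4", "G", "T", ".", ".", ".", "GT",
          "0/1", "0/1", "0/1", "0/1", "0/1", "0/1", sep = "\t"),
    # multi-allelic: each alternate decomposed independently
    paste("1", 150, "rs5", "A", "G,T", ".", ".", ".", "GT",
          "0/1", "0/2", "0/0", "0/0", "0/0", "0/0", sep = "\t"),
    # outside any test region
    paste("1", 900, "rs6", "A", "G", ".", ".", ".", "GT",
          "0/1", "0/0", "0/0", "0/0", "0/0", "0/0", sep = "\t"))
  writeLines(c(header, rows), path)
  path
}

write_test_gen <- function(prefix = tempfile()) {
  gen <- c(
    # triplets per sample: (AA, AB, BB); B is the minor allele here
    "snp1 rs1 100 A G 1,0,0 0,1,0 0,0,1 1,0,0",
    "snp2 rs2 200 A G 0,0.5,0.5 1,0,0 1,0,0 1,0,0",
    # invalid probability mass for sample 1
    "snp3 rs3 300 A G 0.4,0.4,0.4 1,0,0 0,1,0 1,0,0")
  gen <- gsub(",", " ", gen, fixed = TRUE)
  gen_path <- paste0(prefix, ".gen")
  writeLines(gen, gen_path)
  sample_path <- paste0(prefix, ".sample")
  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               paste0("F", 1:4, " S", 1:4, " 0")), sample_path)
  list(gen = gen_path, sample = sample_path)
}

# carrier matrix straight from a values matrix with auto metadata
cm_fixture <- function(values, sample_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  m <- ncol(values)
  carrier_matrix(values, sample_ids,
                 data.frame(id = paste0("v", seq_len(m), recycle0 = TRUE),
                            chrom = rep("1", m), pos = seq_len(m),
                            maf = rep(0.01, m), stringsAsFactors = FALSE))
}

# burden + phenotype pair with unit weights from explicit vectors
bd_pm_fixture <- function(p, y, w = NULL) {
  y <- as.matrix(y)
  n <- length(p)
  m <- 10L
  bd <- structure(list(sample_ids = paste0("s", seq_len(n)),
                       proportion = p,
                       weight = w %||% rep(1, n),
                       n_variants = m,
                       n_observed = as.integer(round((w %||% rep(1, n)) * m)),
                       excluded = rep(FALSE, n)),
                  class = "marv_burden")
  if (is.null(colnames(y))) colnames(y) <- paste0("P", seq_len(ncol(y)))
  pm <- phenotype_matrix(y, bd$sample_ids)
  list(bd = bd, pm = pm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
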