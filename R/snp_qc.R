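#' SNP genotype quality control
#'
#' Two-pass QC for biallelic SNP-array genotypes: (1) per-SNP filters on
#' call rate, minor allele frequency and an exact Hardy-Weinberg test,
#' computed over all samples; (2) per-sample call rate computed over the
#' SNPs that survive pass 1. All exclusions are strict inequalities
#' (call rate < threshold, MAF < threshold, HWE p < threshold); boundary
#' values are retained.
#'
#' @name snp_qc
NULL

#' Default QC thresholds
#'
#' @param snp_call_rate_min minimum SNP call rate (default 0.90; SNPs with
#'   call rate strictly below are dropped).
#' @param maf_min minimum minor allele frequency (default 0.03).
#' @param hwe_p_min minimum exact HWE p-value (default 1e-6).
#' @param sample_call_rate_min minimum per-sample call rate (default 0.90).
#' @return a list of thresholds, validated to lie in (0, 1].
#' @export
qc_thresholds <- function(snp_call_rate_min = 0.90, maf_min = 0.03,
                          hwe_p_min = 1e-6, sample_call_rate_min = 0.90) {
  th <- list(snp_call_rate_min = snp_call_rate_min, maf_min = maf_min,
             hwe_p_min = hwe_p_min,
             sample_call_rate_min = sample_call_rate_min)
  if (any(unlist(th) <= 0 | unlist(th) > 1))
    stop("qc_thresholds: all thresholds must lie in (0, 1]")
  th
}

#' Genotype counts at one SNP
#'
#' @param n_AA,n_AB,n_BB,n_missing non-negative integer counts.
#' @export
genotype_counts <- function(n_AA, n_AB, n_BB, n_missing = 0) {
  v <- c(n_AA = n_AA, n_AB = n_AB, n_BB = n_BB, n_missing = n_missing)
  if (any(v < 0) || any(v != floor(v)))
    stop("genotype_counts: counts must be non-negative integers")
  as.list(v)
}

.count_geno <- function(g) {
  # g: character vector AA/AB/BB/NA for one SNP
  genotype_counts(sum(g == "AA", na.rm = TRUE),
                  sum(g == "AB", na.rm = TRUE),
                  sum(g == "BB", na.rm = TRUE),
                  sum(is.na(g)))
}

#' SNP call rate
#'
#' @param counts a [genotype_counts()] list.
#' @return fraction of non-missing genotypes in [0, 1].
#' @export
snp_call_rate <- function(counts) {
  typed <- counts$n_AA + counts$n_AB + counts$n_BB
  total <- typed + counts$n_missing
  if (total == 0) stop("snp_call_rate: no samples typed at this SNP")
  typed / total
}

#' Minor allele frequency
#'
#' B-allele frequency `(2 n_BB + n_AB) / (2 n_typed)` folded to `[0, 0.5]`.
#' Missing genotypes are excluded from the denominator.
#'
#' @param counts a [genotype_counts()] list.
#' @export
minor_allele_frequency <- function(counts) {
  typed <- counts$n_AA + counts$n_AB + counts$n_BB
  if (typed == 0) stop("minor_allele_frequency: no typed genotypes")
  p_b <- (2 * counts$n_BB + counts$n_AB) / (2 * typed)
  min(p_b, 1 - p_b)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the sum, over all heterozygote counts compatible with the
#' allele totals, of the conditional probabilities not exceeding that of
#' the observed configuration. Preferred over the chi-square test because
#' tail probabilities far below 1e-6 are needed at QC thresholds.
#'
#' @param counts a [genotype_counts()] list; missing genotypes ignored.
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(counts) {
  nAA <- counts$n_AA; nAB <- counts$n_AB; nBB <- counts$n_BB
  if (any(c(nAA, nAB, nBB) < 0)) stop("hwe_exact_p: negative counts")
  n <- nAA + nAB + nBB
  if (n < 1) stop("hwe_exact_p: no typed genotypes")
  nA <- 2 * nAA + nAB
  nr <- min(nA, 2 * n - nA)             # rare-allele count
  if (nr == 0) return(1.0)
  # log conditional probability of each possible het count (same parity
  # as nr), computed in one vectorized pass via log-factorials
  hets <- seq(nr %% 2, nr, by = 2)
  rare_hom <- (nr - hets) / 2
  com_hom <- n - hets - rare_hom
  logp <- lfactorial(n) -
    (lfactorial(rare_hom) + lfactorial(hets) + lfactorial(com_hom)) +
    hets * log(2) +
    lfactorial(nr) + lfactorial(2 * n - nr) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(nAB, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

#' Run the full QC procedure
#'
#' @param genotypes character matrix, rows = SNPs, cols = samples, entries
#'   `AA`/`AB`/`BB`/NA (see [read_genotypes()]).
#' @param thresholds a [qc_thresholds()] list.
#' @param snp_test_samples optional character vector of sample ids over
#'   which the SNP-level filters (call rate, MAF, HWE) are computed;
#'   default all samples. The sample-level filter always applies to all
#'   samples.
#' @param iterate if TRUE, re-apply SNP filters after sample removal until
#'   a fixed point (default FALSE: the two-pass order).
#' @return an object of class `cnvr_qc_report`: list with `snp_table`
#'   (snp_id, call_rate, maf, hwe_p, pass, failed), `sample_table`
#'   (sample_id, call_rate, pass), `genotypes` (filtered matrix), `counts`
#'   (survivors per stage), `thresholds`, and `warning_empty` /
#'   `snps_unstable` flags.
#' @export
run_qc <- function(genotypes, thresholds = qc_thresholds(),
                   snp_test_samples = NULL, iterate = FALSE) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) > 0, ncol(genotypes) > 0)
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- paste0("snp", seq_len(nrow(genotypes)))
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("s", seq_len(ncol(genotypes)))
  test_cols <- if (is.null(snp_test_samples)) seq_len(ncol(genotypes))
               else match(snp_test_samples, colnames(genotypes))

  snp_stats <- function(m) {
    t(apply(m, 1, function(g) {
      cc <- .count_geno(g)
      typed <- cc$n_AA + cc$n_AB + cc$n_BB
      c(call_rate = snp_call_rate(cc),
        maf = if (typed > 0) minor_allele_frequency(cc) else 0,
        hwe_p = if (typed > 0) hwe_exact_p(cc) else 1)
    }))
  }

  st <- snp_stats(genotypes[, test_cols, drop = FALSE])
  fail_cr <- st[, "call_rate"] < thresholds$snp_call_rate_min
  fail_maf <- st[, "maf"] < thresholds$maf_min
  fail_hwe <- st[, "hwe_p"] < thresholds$hwe_p_min
  snp_pass <- !(fail_cr | fail_maf | fail_hwe)
  failed <- apply(cbind(call_rate = fail_cr, maf = fail_maf,
                        hwe = fail_hwe), 1,
                  function(f) paste(names(f)[f], collapse = ";"))
  snp_table <- data.frame(snp_id = rownames(genotypes),
                          call_rate = st[, "call_rate"],
                          maf = st[, "maf"], hwe_p = st[, "hwe_p"],
                          pass = snp_pass, failed = failed,
                          row.names = NULL, stringsAsFactors = FALSE)

  g1 <- genotypes[snp_pass, , drop = FALSE]
  if (nrow(g1) > 0) {
    samp_cr <- colMeans(!is.na(g1))
  } else {
    samp_cr <- stats::setNames(rep(NA_real_, ncol(genotypes)),
                               colnames(genotypes))
  }
  samp_pass <- !is.na(samp_cr) & samp_cr >= thresholds$sample_call_rate_min
  sample_table <- data.frame(sample_id = colnames(genotypes),
                             call_rate = samp_cr, pass = samp_pass,
                             row.names = NULL, stringsAsFactors = FALSE)
  g2 <- g1[, samp_pass, drop = FALSE]

  # stability check: would any surviving SNP's verdict change if the SNP
  # filters were recomputed on the surviving samples?
  snps_unstable <- character(0)
  if (nrow(g2) > 0 && ncol(g2) > 0 && any(!samp_pass)) {
    st2 <- snp_stats(g2[, intersect(colnames(g2),
                                    colnames(genotypes)[test_cols]),
                        drop = FALSE])
    pass2 <- st2[, "call_rate"] >= thresholds$snp_call_rate_min &
      st2[, "maf"] >= thresholds$maf_min &
      st2[, "hwe_p"] >= thresholds$hwe_p_min
    snps_unstable <- rownames(g2)[!pass2]
    if (iterate && length(snps_unstable)) {
      sub <- run_qc(g2[pass2, , drop = FALSE], thresholds,
                    snp_test_samples = snp_test_samples, iterate = TRUE)
      g2 <- sub$genotypes
      snps_unstable <- character(0)
    }
  }

  out <- list(snp_table = snp_table, sample_table = sample_table,
              genotypes = g2,
              counts = c(snps_in = nrow(genotypes),
                         snps_pass = sum(snp_pass),
                         samples_in = ncol(genotypes),
                         samples_pass = sum(samp_pass)),
              thresholds = thresholds,
              warning_empty = nrow(g2) == 0 || ncol(g2) == 0,
              snps_unstable = snps_unstable)
  class(out) <- "cnvr_qc_report"
  out
}

#' @export
print.cnvr_qc_report <- function(x, ...) {
  cat("SNP QC report\n")
  cat(sprintf("  SNPs:    %d in, %d pass (call rate >= %.2f, MAF >= %.2f, HWE p >= %g)\n",
              x$counts["snps_in"], x$counts["snps_pass"],
              x$thresholds$snp_call_rate_min, x$thresholds$maf_min,
              x$thresholds$hwe_p_min))
  cat(sprintf("  Samples: %d in, %d pass (call rate >= %.2f)\n",
              x$counts["samples_in"], x$counts["samples_pass"],
              x$thresholds$sample_call_rate_min))
  if (length(x$snps_unstable))
    cat(sprintf("  note: %d SNP verdict(s) would change on iteration\n",
                length(x$snps_unstable)))
  if (x$warning_empty) cat("  WARNING: empty matrix after filtering\n")
  invisible(x)
}
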