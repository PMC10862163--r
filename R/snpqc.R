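#' Exact Hardy-Weinberg equilibrium test p-value
#'
#' Two-sided conditional exact test for a biallelic locus: with the allele
#' counts fixed, the probability of each possible heterozygote count (same
#' parity as the minor-allele count) follows the standard hypergeometric-form
#' distribution; the p-value sums the probabilities of all outcomes no more
#' probable than the observed one. Probabilities are computed in log space,
#' so large samples are handled stably. A monomorphic locus returns 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectorised).
#' @return p-values in (0, 1].
#' @export
hwe_exact_pvalue <- function(n_AA, n_Aa, n_aa) {
  mapply(function(a, h, b) {
    if (a < 0 || h < 0 || b < 0) stop("genotype counts must be non-negative")
    n <- a + h + b
    if (n < 1) stop("need at least one genotype")
    nA <- 2 * a + h
    na <- 2 * b + h
    rare <- min(nA, na)
    if (rare == 0) return(1)
    common <- max(nA, na)
    hets <- seq(rare %% 2, rare, by = 2)
    # log P(h | allele counts) up to the normalising constant:
    # P(h) proportional to 2^h / (h! * ((rare-h)/2)! * ((common-h)/2)!)
    lp <- hets * log(2) - lfactorial(hets) -
      lfactorial((rare - hets) / 2) - lfactorial((common - hets) / 2)
    lp <- lp - max(lp)
    pr <- exp(lp)
    pr <- pr / sum(pr)
    obs <- pr[match(h, hets)]
    if (is.na(obs)) stop("heterozygote count has wrong parity for allele counts")
    min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
  }, n_AA, n_Aa, n_aa)
}

#' Marker and individual quality control
#'
#' Applies the standard PLINK-style filters in a fixed, logged order:
#' (1) drop loci on excluded (sex) chromosomes; (2) drop loci whose missing
#' rate exceeds `snp_missing_max`; (3) drop individuals whose missing rate
#' exceeds `indiv_missing_max`; (4) recompute per-locus statistics on the
#' remaining individuals, then drop loci with minor-allele frequency strictly
#' below `maf_min` and loci with exact Hardy-Weinberg p-value strictly below
#' `hwe_alpha`. Missing-rate bounds are inclusive ("maximum missing rate"),
#' MAF and HWE bounds strict, matching the usual reporting conventions.
#' MAF is computed from non-missing calls only.
#'
#' @param genotypes a `"genotype_matrix"`.
#' @param hwe_alpha HWE exact-test threshold (drop if p < `hwe_alpha`).
#' @param maf_min minimum minor-allele frequency (drop if maf < `maf_min`).
#' @param snp_missing_max maximum per-locus missing rate (drop if >).
#' @param indiv_missing_max maximum per-individual missing rate (drop if >).
#' @param excluded_chromosomes chromosome labels to drop entirely.
#' @return An object of class `"snp_qc_result"`: list with the filtered
#'   `genotypes`, a per-locus `locus_report` (id, chrom, maf, missing_rate,
#'   hwe_p, pass, reason), an `individual_report`, and a per-stage
#'   `attrition` table.
#' @export
apply_qc <- function(genotypes, hwe_alpha = 0.001, maf_min = 0.05,
                     snp_missing_max = 0.1, indiv_missing_max = 0.05,
                     excluded_chromosomes = c("X", "Y", "Z", "W")) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  G <- unclass(genotypes)
  chrom <- attr(genotypes, "chrom")
  locus <- colnames(G)
  reason <- stats::setNames(rep(NA_character_, length(locus)), locus)

  # stage 1: chromosome exclusion
  drop_chrom <- chrom %in% excluded_chromosomes
  reason[drop_chrom] <- "excluded_chromosome"

  # stage 2: per-SNP missingness (on all individuals)
  miss_rate_full <- colMeans(is.na(G))
  drop_miss <- !drop_chrom & miss_rate_full > snp_missing_max
  reason[drop_miss] <- "snp_missingness"
  keep1 <- !drop_chrom & !drop_miss

  # stage 3: per-individual missingness on surviving loci
  if (any(keep1)) {
    ind_miss <- rowMeans(is.na(G[, keep1, drop = FALSE]))
  } else {
    ind_miss <- rowMeans(is.na(G))
  }
  ind_keep <- ind_miss <= indiv_missing_max
  individual_report <- data.frame(id = rownames(G), missing_rate = ind_miss,
                                  pass = ind_keep, row.names = NULL)
  # stage 4: recompute per-locus statistics on retained individuals
  H <- G[ind_keep, , drop = FALSE]
  nm <- colSums(!is.na(H))
  p_alt <- colSums(H, na.rm = TRUE) / (2 * pmax(nm, 1L))
  maf <- pmin(p_alt, 1 - p_alt)
  miss_rate <- colMeans(is.na(H))
  n_het <- colSums(H == 1, na.rm = TRUE)
  n_hom2 <- colSums(H == 2, na.rm = TRUE)
  n_hom0 <- nm - n_het - n_hom2
  hwe_p <- rep(NA_real_, length(locus))
  hwe_p[nm > 0] <- hwe_exact_pvalue(n_hom0[nm > 0], n_het[nm > 0],
                                    n_hom2[nm > 0])
  drop_maf <- keep1 & (maf < maf_min)
  reason[drop_maf] <- "maf"
  drop_hwe <- keep1 & !drop_maf & !is.na(hwe_p) & hwe_p < hwe_alpha
  reason[drop_hwe] <- "hwe"
  keep_locus <- keep1 & !drop_maf & !drop_hwe

  locus_report <- data.frame(locus = locus, chrom = chrom, maf = maf,
                             missing_rate = miss_rate, hwe_p = hwe_p,
                             pass = keep_locus, reason = unname(reason),
                             row.names = NULL)
  if (!any(keep_locus) || !any(ind_keep)) {
    stage <- if (!any(ind_keep)) "individual_missingness" else {
      last <- c("excluded_chromosome", "snp_missingness", "maf", "hwe")
      last[max(match(stats::na.omit(unname(reason)), last))]
    }
    stop("empty-result error: no data survive QC (last removals at stage: ",
         stage, ")")
  }
  attrition <- data.frame(
    stage = c("input", "excluded_chromosome", "snp_missingness",
              "individual_missingness", "maf", "hwe", "output"),
    loci = c(length(locus), sum(drop_chrom), sum(drop_miss), 0,
             sum(drop_maf), sum(drop_hwe), sum(keep_locus)),
    individuals = c(nrow(G), 0, 0, sum(!ind_keep), 0, 0, sum(ind_keep)))
  out <- genotype_matrix(G[ind_keep, keep_locus, drop = FALSE],
                         chrom = chrom[keep_locus])
  structure(list(genotypes = out, locus_report = locus_report,
                 individual_report = individual_report,
                 attrition = attrition,
                 thresholds = list(hwe_alpha = hwe_alpha, maf_min = maf_min,
                                   snp_missing_max = snp_missing_max,
                                   indiv_missing_max = indiv_missing_max,
                                   excluded_chromosomes = excluded_chromosomes)),
            class = "snp_qc_result")
}

#' @export
print.snp_qc_result <- function(x, ...) {
  cat("SNP quality control\n")
  print(x$attrition, row.names = FALSE)
  invisible(x)
}
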