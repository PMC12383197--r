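#' Exact Hardy-Weinberg test p-value
#'
#' Two-sided exact test conditional on the allele counts: the p-value
#' sums the conditional probabilities of every heterozygote count whose
#' probability does not exceed that of the observed table.
#'
#' @param n_AA,n_Aa,n_aa genotype counts at one biallelic locus.
#' @return the exact p-value (1 for a monomorphic locus).
#' @export
hwe_exact_pvalue <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotypes observed")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  # heterozygote counts share the parity of the minor-allele count
  rare <- min(nA, na)
  h <- seq(rare %% 2, rare, by = 2)
  logp <- lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((na - h) / 2) + h * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, h)]
  sum(pr[pr <= p_obs * (1 + 1e-10)])
}

# Vectorized HWE over the columns of a dosage matrix (NA tolerated).
hwe_pvalues <- function(genotypes) {
  apply(genotypes, 2, function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0) return(NA_real_)
    hwe_exact_pvalue(sum(g == 0), sum(g == 1), sum(g == 2))
  })
}

#' Marker and individual quality control
#'
#' PLINK-like filter cascade: individuals with too much missingness
#' first, then markers by missingness, minor allele frequency, and exact
#' Hardy-Weinberg test, in that order.
#'
#' @param genotypes dosage matrix, animals x markers, codes 0/1/2 and NA
#'   for missing; dimnames identify animals and markers.
#' @param maf_min minimum minor allele frequency.
#' @param locus_missing_max maximum marker missing fraction.
#' @param individual_missing_max maximum per-animal missing fraction.
#' @param hwe_p_min minimum exact HWE p-value.
#' @return list with `kept_markers`, `kept_individuals` (names, or
#'   indices when unnamed) and a `report` data frame counting removals
#'   per criterion in application order.
#' @export
apply_qc_filters <- function(genotypes, maf_min = 0.05,
                             locus_missing_max = 0.10,
                             individual_missing_max = 0.10,
                             hwe_p_min = 1e-5) {
  if (length(genotypes) == 0L) stop("empty genotype table")
  if (is.null(rownames(genotypes))) rownames(genotypes) <- seq_len(nrow(genotypes))
  if (is.null(colnames(genotypes))) colnames(genotypes) <- seq_len(ncol(genotypes))

  ind_miss <- rowMeans(is.na(genotypes))
  keep_ind <- ind_miss <= individual_missing_max
  g <- genotypes[keep_ind, , drop = FALSE]

  loc_miss <- colMeans(is.na(g))
  keep_miss <- loc_miss <= locus_missing_max
  n_miss <- sum(!keep_miss)
  g <- g[, keep_miss, drop = FALSE]

  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep_maf <- maf >= maf_min & !is.nan(maf)
  n_maf <- sum(!keep_maf)
  g <- g[, keep_maf, drop = FALSE]

  hwe <- hwe_pvalues(g)
  keep_hwe <- hwe >= hwe_p_min
  n_hwe <- sum(!keep_hwe)
  g <- g[, keep_hwe, drop = FALSE]

  list(
    kept_markers = colnames(g),
    kept_individuals = rownames(genotypes)[keep_ind],
    report = data.frame(
      criterion = c("individual_missingness", "locus_missingness",
                    "maf", "hwe"),
      removed = c(sum(!keep_ind), n_miss, n_maf, n_hwe)
    )
  )
}
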