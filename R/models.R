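#' Pedigree BLUP (PBLUP)
#'
#' Animal model with an overall mean as the only fixed effect and the
#' sparse `A^{-1}` built by Henderson's rules (with inbreeding); solved
#' by conjugate gradients. EBVs are returned for every pedigree animal,
#' phenotyped or not.
#'
#' @param ped pedigree data frame (`id`, `sire`, `dam`, parents first).
#' @param record_ids animal id per phenotype record.
#' @param y phenotype per record (no NA).
#' @param lambda variance ratio `sigma_e^2 / sigma_a^2`.
#' @param ... passed to [solve_mme()].
#' @return an evaluation result: list with `gebv` (named), `b`,
#'   `converged`, `iterations`.
#' @export
run_pblup <- function(ped, record_ids, y, lambda = 0.58 / 0.42, ...) {
  stopifnot(!anyNA(y))
  Ainv <- a_inverse(ped)
  Z <- incidence_matrix(record_ids, ped$id)
  fit <- solve_mme(y, Z, Ainv, lambda, ...)
  list(gebv = stats::setNames(fit$g, ped$id), b = fit$b,
       converged = fit$converged, iterations = fit$iterations)
}

# evaluator hook used inside run_recent()
pblup_evaluator <- function(ped, rec_ids, y, lambda) {
  run_pblup(ped, rec_ids, y, lambda, tol = 1e-8)$gebv
}

# Shared genotype preparation for the genomic models: stack reference and
# candidate genotypes, drop markers monomorphic in the joint set.
prep_joint_genotypes <- function(reference_genotypes, candidate_genotypes,
                                 allele_freqs = NULL) {
  stopifnot(ncol(reference_genotypes) == ncol(candidate_genotypes))
  M <- rbind(reference_genotypes, candidate_genotypes)
  if (is.null(rownames(M))) rownames(M) <- seq_len(nrow(M))
  obs <- colMeans(M) / 2
  p <- if (is.null(allele_freqs)) obs else allele_freqs
  mono <- p <= 0 | p >= 1 | obs <= 0 | obs >= 1
  if (any(mono)) {
    warning(sum(mono), " markers monomorphic in reference+candidates; excluded")
    M <- M[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  if (ncol(M) == 0L) stop("no polymorphic markers left")
  list(M = M, p = p, n_ref = nrow(reference_genotypes), kept = !mono)
}

#' Genomic BLUP (GBLUP)
#'
#' G is built over reference and candidate animals jointly (observed
#' allele frequencies), conditioned by a small identity blend for
#' invertibility, and the mixed-model equations are solved with
#' `K^{-1} = G*^{-1}`. Candidates carry no records; their GEBVs come
#' from the genomic covariance with the reference.
#'
#' @param reference_genotypes dosage matrix of reference animals (rows
#'   named by animal id).
#' @param reference_y phenotypes of the reference animals (NA allowed;
#'   NA records are dropped).
#' @param candidate_genotypes dosage matrix of (unphenotyped) candidates.
#' @param lambda variance ratio `sigma_e^2 / sigma_g^2`; the default is
#'   the simulated `0.58 / 0.42`.
#' @param blend_weight weight on G in the identity blend.
#' @param weights optional per-marker weights (then this is wGBLUP's
#'   second pass).
#' @param allele_freqs optional external (base-population) frequencies
#'   for centering; observed joint frequencies by default, which make G
#'   singular by construction (rows sum to zero) and therefore require
#'   `blend_weight < 1`.
#' @param ... passed to [solve_mme()].
#' @return evaluation result with `gebv` for reference then candidates.
#' @export
run_gblup <- function(reference_genotypes, reference_y, candidate_genotypes,
                      lambda = 0.58 / 0.42, blend_weight = 0.95,
                      weights = NULL, allele_freqs = NULL, ...) {
  jp <- prep_joint_genotypes(reference_genotypes, candidate_genotypes,
                             allele_freqs)
  G <- if (is.null(weights)) {
    genomic_relationship(jp$M, jp$p)
  } else {
    if (inherits(weights, "snp_weights")) weights <- weights$w
    stopifnot(length(weights) == length(jp$kept))
    weighted_genomic_relationship(jp$M, weights[jp$kept], jp$p)
  }
  Gs <- blend_and_align_G(G, diag(nrow(G)), blend_weight)
  dimnames(Gs) <- dimnames(G)
  Ginv <- solve(Gs)
  ok <- !is.na(reference_y)
  ref_ids <- rownames(jp$M)[seq_len(jp$n_ref)]
  Z <- incidence_matrix(ref_ids[ok], rownames(jp$M))
  fit <- solve_mme(reference_y[ok], Z, Ginv, lambda, ...)
  list(gebv = stats::setNames(fit$g, rownames(jp$M)), b = fit$b,
       converged = fit$converged, iterations = fit$iterations)
}

#' Single-step GBLUP (ssGBLUP)
#'
#' All pedigree animals enter through `H^{-1}`, combining the sparse
#' `A^{-1}` with the genomic information of the genotyped subset
#' (`G*^{-1} - A22^{-1}` correction). Phenotypes of non-genotyped
#' animals therefore contribute to genotyped animals' GEBVs.
#'
#' @param ped pedigree covering all animals (records and genotyped).
#' @param record_ids,y phenotype records (no NA in `y`).
#' @param genotypes dosage matrix of the genotyped subset, rows named by
#'   pedigree id.
#' @param lambda variance ratio.
#' @param blend_weight G blending weight against A22.
#' @param ... passed to [solve_mme()].
#' @return evaluation result with `gebv` named by pedigree id.
#' @export
run_ssgblup <- function(ped, record_ids, y, genotypes,
                        lambda = 0.58 / 0.42, blend_weight = 0.95, ...) {
  stopifnot(!anyNA(y))
  geno_ids <- rownames(genotypes)
  if (nrow(genotypes) > 0L && is.null(geno_ids))
    stop("genotype rows must be named by pedigree id")
  if (anyNA(match(geno_ids, ped$id)))
    stop("genotyped animals missing from pedigree")
  Ainv <- a_inverse(ped)
  if (nrow(genotypes) > 0L) {
    p <- colMeans(genotypes) / 2
    poly <- p > 0 & p < 1
    A22 <- a22_matrix(ped, geno_ids)
    G <- genomic_relationship(genotypes[, poly, drop = FALSE], p[poly])
    Gs <- blend_and_align_G(G, A22, blend_weight)
    Kinv <- h_inverse(Ainv, solve(A22), solve(Gs), geno_ids)
  } else {
    Kinv <- Ainv
  }
  Z <- incidence_matrix(record_ids, ped$id)
  fit <- solve_mme(y, Z, Kinv, lambda, ...)
  list(gebv = stats::setNames(fit$g, ped$id), b = fit$b,
       converged = fit$converged, iterations = fit$iterations)
}

#' Ridge (SNP-BLUP) estimates of marker effects
#'
#' Model `y = 1 b + Z alpha + e` with `alpha ~ N(0, W sigma_alpha^2)`
#' on frequency-centered genotypes, solved exactly in its dual (n x n)
#' form. With `sigma_alpha^2 = sigma_g^2 / sum(2 p (1 - p))` and identity
#' weights this is the SNP-space equivalent of GBLUP.
#'
#' @param genotypes reference dosage matrix.
#' @param y phenotypes (no NA).
#' @param weights per-marker prior-variance weights (identity default).
#' @param sigma_g2,sigma_e2 genetic and residual variances.
#' @param allele_freqs centering frequencies (observed by default).
#' @return list with `alpha` (per retained marker, named by column),
#'   `b`, `marker_kept` (logical over input columns).
#' @export
estimate_snp_effects <- function(genotypes, y, weights = NULL,
                                 sigma_g2 = 0.42, sigma_e2 = 0.58,
                                 allele_freqs = colMeans(genotypes) / 2) {
  stopifnot(!anyNA(y), nrow(genotypes) == length(y))
  kept <- allele_freqs > 0 & allele_freqs < 1
  if (!any(kept)) stop("all marker columns have zero variance")
  Z <- sweep(genotypes[, kept, drop = FALSE], 2, 2 * allele_freqs[kept])
  m <- ncol(Z)
  w <- if (is.null(weights)) rep(1, m) else {
    if (inherits(weights, "snp_weights")) weights <- weights$w
    stopifnot(length(weights) == length(kept))
    weights[kept]
  }
  sigma_a2 <- sigma_g2 / sum(2 * allele_freqs[kept] * (1 - allele_freqs[kept]))
  Zw <- sweep(Z, 2, w, `*`)
  V <- tcrossprod(Zw, Z) * sigma_a2 + diag(sigma_e2, nrow(Z))
  Vi_y1 <- solve(V, cbind(y, 1))
  b <- sum(Vi_y1[, 1]) / sum(Vi_y1[, 2])
  Vi_r <- Vi_y1[, 1] - b * Vi_y1[, 2]
  alpha <- sigma_a2 * w * as.vector(crossprod(Z, Vi_r))
  names(alpha) <- colnames(Z)
  list(alpha = alpha, b = b, marker_kept = kept)
}

#' Window-averaged SNP weights
#'
#' `W_jj = C * mean(alpha_hat^2)` over the window `[j - S, j + S]`
#' clipped to the marker array, with `C` chosen so the mean weight is 1.
#'
#' @param alpha_hat estimated SNP effects (first-pass, identity prior).
#' @param S window half-width in markers (`2S + 1` SNPs per window).
#' @return an object of class `snp_weights`: list with `w` (mean 1),
#'   `window_halfwidth`, `scaling_constant`.
#' @export
window_weights <- function(alpha_hat, S = 20L) {
  m <- length(alpha_hat)
  if (m == 0L) stop("empty effect vector")
  stopifnot(S >= 0)
  a2 <- alpha_hat^2
  cs <- cumsum(c(0, a2))
  lo <- pmax(seq_len(m) - S, 1L)
  hi <- pmin(seq_len(m) + S, m)
  raw <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  C <- if (sum(raw) > 0) m / sum(raw) else 1
  out <- list(w = raw * C, window_halfwidth = as.integer(S),
              scaling_constant = C)
  class(out) <- "snp_weights"
  out
}

#' Window-weighted GBLUP (wGBLUP)
#'
#' Two passes: (1) SNP effects estimated on the training records with
#' identity weights; (2) a window-weighted G built from those effects
#' and refit. Candidates never enter the weight estimation.
#'
#' @inheritParams run_gblup
#' @param S window half-width for the weights.
#' @param sigma_g2,sigma_e2 variance components (also define `lambda`).
#' @param weights optional precomputed weights; skips pass 1.
#' @return evaluation result with `gebv`, plus the `weights` used.
#' @export
run_wgblup <- function(reference_genotypes, reference_y, candidate_genotypes,
                       S = 20L, sigma_g2 = 0.42, sigma_e2 = 0.58,
                       blend_weight = 0.95, weights = NULL, ...) {
  if (is.null(weights)) {
    ok <- !is.na(reference_y)
    fit1 <- estimate_snp_effects(reference_genotypes[ok, , drop = FALSE],
                                 reference_y[ok], weights = NULL,
                                 sigma_g2 = sigma_g2, sigma_e2 = sigma_e2)
    alpha_full <- numeric(ncol(reference_genotypes))
    alpha_full[fit1$marker_kept] <- fit1$alpha
    weights <- window_weights(alpha_full, S)
  }
  fit <- run_gblup(reference_genotypes, reference_y, candidate_genotypes,
                   lambda = sigma_e2 / sigma_g2, blend_weight = blend_weight,
                   weights = weights, ...)
  fit$weights <- weights
  fit
}

#' Prediction accuracy
#'
#' Pearson correlation between predicted and true breeding values on a
#' validation subset.
#'
#' @param gebv named predictions.
#' @param tbv named true values (or same order as `gebv`).
#' @param subset optional ids restricting the comparison.
#' @return a single correlation.
#' @export
accuracy <- function(gebv, tbv, subset = NULL) {
  if (!is.null(subset)) {
    gebv <- gebv[as.character(subset)]
    tbv <- tbv[as.character(subset)]
  } else if (!is.null(names(gebv)) && !is.null(names(tbv))) {
    tbv <- tbv[names(gebv)]
  }
  if (length(gebv) == 0L || anyNA(gebv) || anyNA(tbv))
    stop("predictions and true values must cover the subset")
  if (sd(gebv) == 0 || sd(tbv) == 0)
    stop("zero variance in predictions or true values")
  cor(gebv, tbv)
}
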