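#' Genomic relationship matrix
#'
#' The frequency-centered form: `Z = M - 2p` column-wise, and
#' `G = Z Z' / sum(2 p_i (1 - p_i))`. Centering makes G invariant to
#' which allele is labeled as reference at any marker and gives a mean
#' diagonal near 1 in an unstructured population.
#'
#' @param genotype_matrix complete post-QC dosage matrix, animals x
#'   markers, codes 0/1/2.
#' @param allele_freqs per-marker frequency of the counted allele;
#'   defaults to the observed frequencies in `genotype_matrix`. All must
#'   lie strictly in (0, 1).
#' @return dense symmetric G with animal dimnames.
#' @export
genomic_relationship <- function(genotype_matrix,
                                 allele_freqs = colMeans(genotype_matrix) / 2) {
  if (anyNA(genotype_matrix)) stop("genotypes must be complete (post-QC)")
  if (any(allele_freqs <= 0 | allele_freqs >= 1))
    stop("monomorphic marker: allele frequencies must be in (0, 1)")
  Z <- sweep(genotype_matrix, 2, 2 * allele_freqs)
  G <- tcrossprod(Z) / sum(2 * allele_freqs * (1 - allele_freqs))
  dimnames(G) <- list(rownames(genotype_matrix), rownames(genotype_matrix))
  G
}

#' Window-weighted genomic relationship matrix
#'
#' `G_w = Z W Z' / (sum(2 p (1 - p)) * mean(w))`, so identity weights
#' recover the plain G exactly and any rescaling of the weights cancels.
#'
#' @inheritParams genomic_relationship
#' @param weights per-marker nonnegative weights (diagonal of W).
#' @return dense symmetric weighted G.
#' @export
weighted_genomic_relationship <- function(genotype_matrix, weights,
                                          allele_freqs = colMeans(genotype_matrix) / 2) {
  stopifnot(length(weights) == ncol(genotype_matrix))
  if (any(weights < 0)) stop("weights must be non-negative")
  if (any(allele_freqs <= 0 | allele_freqs >= 1))
    stop("monomorphic marker: allele frequencies must be in (0, 1)")
  Z <- sweep(genotype_matrix, 2, 2 * allele_freqs)
  Zw <- sweep(Z, 2, sqrt(weights), `*`)
  G <- tcrossprod(Zw) /
    (sum(2 * allele_freqs * (1 - allele_freqs)) * mean(weights))
  dimnames(G) <- list(rownames(genotype_matrix), rownames(genotype_matrix))
  G
}

#' Blend and align G against its pedigree counterpart
#'
#' Standard single-step conditioning: G is first rescaled so its mean
#' diagonal matches that of `A22`, then blended,
#' `G* = w G + (1 - w) A22`, which guarantees an invertible G* even with
#' duplicate genotypes.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationship block for the same animals (identity
#'   for a purely genomic model).
#' @param blend_weight weight on G, in (0, 1].
#' @return dense symmetric conditioned matrix G*.
#' @export
blend_and_align_G <- function(G, A22 = diag(nrow(G)), blend_weight = 0.95) {
  stopifnot(blend_weight > 0, blend_weight <= 1)
  if (!all(dim(G) == dim(A22))) stop("dimension mismatch between G and A22")
  G <- G * (mean(diag(A22)) / mean(diag(G)))
  blend_weight * G + (1 - blend_weight) * A22
}

#' Single-step H-inverse
#'
#' `H^{-1} = A^{-1}` plus `(G*^{-1} - A22^{-1})` added into the block of
#' genotyped animals.
#'
#' @param A_inv sparse inverse numerator relationship matrix over the
#'   full pedigree (dimnames = ids).
#' @param A22_inv dense inverse of the genotyped pedigree block.
#' @param G_star_inv dense inverse of the conditioned genomic matrix,
#'   same animal order as `A22_inv`.
#' @param genotyped_index positions (or ids) of the genotyped animals in
#'   the ordering of `A_inv`.
#' @return sparse symmetric H-inverse.
#' @export
h_inverse <- function(A_inv, A22_inv, G_star_inv, genotyped_index) {
  if (is.character(genotyped_index))
    genotyped_index <- match(genotyped_index, rownames(A_inv))
  ng <- length(genotyped_index)
  if (anyNA(genotyped_index) || any(genotyped_index < 1) ||
      any(genotyped_index > nrow(A_inv)))
    stop("genotyped index out of range")
  if (ng == 0L) return(A_inv)
  if (!all(dim(G_star_inv) == c(ng, ng)) || !all(dim(A22_inv) == c(ng, ng)))
    stop("non-conformable genomic blocks")
  D <- G_star_inv - A22_inv
  n <- nrow(A_inv)
  corr <- sparseMatrix(i = rep(genotyped_index, ng),
                       j = rep(genotyped_index, each = ng),
                       x = as.vector(D), dims = c(n, n),
                       dimnames = dimnames(A_inv))
  Matrix::forceSymmetric(A_inv + corr)
}
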