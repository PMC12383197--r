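#' @importFrom Matrix sparseMatrix Diagonal Cholesky solve crossprod t diag
NULL

# Normalize a pedigree data.frame (id, sire, dam; 0/NA = unknown) into
# 1..n recoded integer vectors ordered parents-before-offspring, erroring
# if the given order violates that.
check_pedigree <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  n <- nrow(ped)
  sire <- match(ped$sire, ped$id)
  dam <- match(ped$dam, ped$id)
  unk_s <- is.na(ped$sire) | ped$sire == 0
  unk_d <- is.na(ped$dam) | ped$dam == 0
  if (any(is.na(sire) & !unk_s) || any(is.na(dam) & !unk_d))
    stop("pedigree refers to parents that are not listed")
  sire[unk_s] <- 0L
  dam[unk_d] <- 0L
  sire <- as.integer(sire)
  dam <- as.integer(dam)
  if (any(sire >= seq_len(n)) || any(dam >= seq_len(n)))
    stop("an animal is listed before its parents")
  list(sire = sire, dam = dam, ids = ped$id, n = n)
}

#' Numerator relationship matrix (tabular method)
#'
#' `A_kk = 1 + A(s,d)/2`, `A_kj = (A_js + A_jd)/2`, unknown parents
#' contributing zero. Dense; meant for moderate pedigrees such as the
#' genotyped subset.
#'
#' @param ped data frame with columns `id`, `sire`, `dam` (0 or NA for
#'   unknown), parents listed before offspring.
#' @return dense symmetric matrix with dimnames = ids.
#' @export
numerator_relationship <- function(ped) {
  p <- check_pedigree(ped)
  A <- cpp_tabular_A(p$sire, p$dam)
  dimnames(A) <- list(p$ids, p$ids)
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' Exact coefficients (`F_i = A(sire, dam) / 2`), computed without a
#' dense relationship matrix via an indirect (gene-flow) evaluation of
#' the needed relationship entries, so deep multi-thousand-animal
#' pedigrees are cheap.
#'
#' @inheritParams numerator_relationship
#' @return numeric vector named by id.
#' @export
pedigree_inbreeding <- function(ped) {
  p <- check_pedigree(ped)
  stats::setNames(cpp_inbreeding(p$sire, p$dam), p$ids)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: contributions `alpha_i = 1 / d_i`
#' where `d_i` is the Mendelian-sampling variance computed from parental
#' inbreeding.
#'
#' @inheritParams numerator_relationship
#' @return a sparse symmetric `dgCMatrix` with dimnames = ids.
#' @export
a_inverse <- function(ped) {
  p <- check_pedigree(ped)
  n <- p$n
  F <- cpp_inbreeding(p$sire, p$dam)
  Fs <- ifelse(p$sire > 0, F[pmax(p$sire, 1L)], 0)
  Fd <- ifelse(p$dam > 0, F[pmax(p$dam, 1L)], 0)
  ks <- p$sire > 0
  kd <- p$dam > 0
  d <- 1 - 0.25 * (ks * (1 + Fs)) - 0.25 * (kd * (1 + Fd))
  alpha <- 1 / d

  i <- seq_len(n)
  ii <- c(i, i[ks], i[kd], p$sire[ks], p$dam[kd],
          p$sire[ks & kd], p$dam[ks & kd])
  jj <- c(i, p$sire[ks], p$dam[kd], i[ks], i[kd],
          p$dam[ks & kd], p$sire[ks & kd])
  xx <- c(alpha,
          -0.5 * alpha[ks], -0.5 * alpha[kd],
          -0.5 * alpha[ks], -0.5 * alpha[kd],
          0.25 * alpha[ks & kd], 0.25 * alpha[ks & kd])
  # parent self-blocks
  ii <- c(ii, p$sire[ks], p$dam[kd])
  jj <- c(jj, p$sire[ks], p$dam[kd])
  xx <- c(xx, 0.25 * alpha[ks], 0.25 * alpha[kd])
  M <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                    dimnames = list(p$ids, p$ids))
  Matrix::forceSymmetric(M)
}

#' Pedigree block of A for a set of animals
#'
#' `A22`, the numerator-relationship sub-matrix for (typically genotyped)
#' animals, extracted from the sparse `A^{-1}` of the full pedigree by
#' solving `A^{-1} X = E` with a cached Cholesky factor, in column
#' chunks. Exactly equals the corresponding block of the tabular A.
#'
#' @param ped full pedigree data frame.
#' @param ids animals whose block is wanted.
#' @param chunk columns solved per pass (memory/time trade-off).
#' @return dense symmetric matrix over `ids`.
#' @export
a22_matrix <- function(ped, ids, chunk = 400L) {
  Ainv <- a_inverse(ped)
  pos <- match(ids, ped$id)
  if (anyNA(pos)) stop("ids missing from pedigree")
  ch <- Cholesky(methods::as(Ainv, "CsparseMatrix"), LDL = FALSE)
  n <- nrow(Ainv)
  out <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (s in split(seq_along(pos), ceiling(seq_along(pos) / chunk))) {
    E <- sparseMatrix(i = pos[s], j = seq_along(s), x = 1,
                      dims = c(n, length(s)))
    X <- solve(ch, E, system = "A")
    out[, s] <- as.matrix(X[pos, , drop = FALSE])
  }
  (out + t(out)) / 2
}

#' Prune a pedigree to a set of animals and their ancestors
#'
#' @param ped pedigree data frame.
#' @param keep ids whose ancestry must be retained.
#' @return the pruned pedigree, original order preserved.
#' @export
prune_pedigree <- function(ped, keep) {
  wanted <- logical(nrow(ped))
  wanted[match(keep, ped$id)] <- TRUE
  # ids are ordered parents-first, so one reverse sweep suffices
  sire_pos <- match(ped$sire, ped$id)
  dam_pos <- match(ped$dam, ped$id)
  for (i in rev(seq_len(nrow(ped)))) {
    if (wanted[i]) {
      if (!is.na(sire_pos[i])) wanted[sire_pos[i]] <- TRUE
      if (!is.na(dam_pos[i])) wanted[dam_pos[i]] <- TRUE
    }
  }
  ped[wanted, , drop = FALSE]
}
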