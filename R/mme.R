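# Jacobi-preconditioned conjugate gradients for a symmetric positive
# (semi)definite system. Works for base matrices and Matrix classes.
pcg_solve <- function(C, b, tol = 1e-8, max_iter = 10000L) {
  d <- Matrix::diag(C)
  d[d <= 0] <- 1
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) return(list(x = x, converged = TRUE, iterations = 0L))
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    Cp <- as.vector(C %*% p)
    alpha <- rz / sum(p * Cp)
    x <- x + alpha * p
    r <- r - alpha * Cp
    if (sqrt(sum(r * r)) / bnorm <= tol) {
      converged <- TRUE
      break
    }
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, converged = converged, iterations = it)
}

# Record-to-animal incidence matrix (sparse).
incidence_matrix <- function(record_ids, animal_ids) {
  j <- match(record_ids, animal_ids)
  if (anyNA(j)) stop("a record maps to no animal")
  sparseMatrix(i = seq_along(record_ids), j = j, x = 1,
               dims = c(length(record_ids), length(animal_ids)))
}

#' Solve Henderson's mixed model equations
#'
#' Builds the system
#' `[X'X, X'Z; Z'X, Z'Z + lambda K^{-1}] [b; g] = [X'y; Z'y]`
#' and solves it by Jacobi-preconditioned conjugate gradients to a
#' relative residual `tol`.
#'
#' @param y phenotype vector (non-missing records only).
#' @param Z record-to-animal incidence matrix (rows = records).
#' @param K_inv inverse relationship structure over the animals (sparse
#'   or dense).
#' @param lambda variance ratio `sigma_e^2 / sigma_g^2`.
#' @param X fixed-effect incidence; defaults to an intercept.
#' @param tol relative-residual convergence tolerance.
#' @param max_iter iteration cap; non-convergence is flagged, not fatal.
#' @return list with `b` (fixed effects), `g` (genetic values, named by
#'   the animal dimnames of `K_inv` when present), `converged`,
#'   `iterations`.
#' @export
solve_mme <- function(y, Z, K_inv, lambda, X = matrix(1, length(y), 1),
                      tol = 1e-8, max_iter = 10000L) {
  stopifnot(lambda > 0, nrow(Z) == length(y), nrow(X) == length(y),
            ncol(Z) == nrow(K_inv))
  Xs <- methods::as(X, "CsparseMatrix")
  C <- rbind(
    cbind(Matrix::crossprod(Xs), Matrix::crossprod(Xs, Z)),
    cbind(Matrix::crossprod(Z, Xs), Matrix::crossprod(Z) + lambda * K_inv)
  )
  rhs <- c(as.vector(Matrix::crossprod(Xs, y)),
           as.vector(Matrix::crossprod(Z, y)))
  sol <- pcg_solve(C, rhs, tol = tol, max_iter = max_iter)
  if (!sol$converged)
    warning("mixed-model equations: conjugate gradients did not converge in ",
            sol$iterations, " iterations")
  nf <- ncol(X)
  g <- sol$x[-seq_len(nf)]
  if (!is.null(rownames(K_inv))) names(g) <- rownames(K_inv)
  list(b = sol$x[seq_len(nf)], g = g,
       converged = sol$converged, iterations = sol$iterations)
}
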