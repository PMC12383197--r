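# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: dense direct solves, recursive kinship, and
# naive enumeration.

# Dense direct solve of Henderson's MME (the CG oracle).
dense_mme_oracle <- function(y, X, Z, Kinv, lambda) {
  X <- as.matrix(X); Z <- as.matrix(Z); Kinv <- as.matrix(Kinv)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * Kinv))
  sol <- solve(C, c(crossprod(X, y), crossprod(Z, y)))
  list(b = sol[seq_len(ncol(X))], g = sol[-seq_len(ncol(X))])
}

# Recursive kinship (coefficient of coancestry) with memoisation;
# A = 2 * kinship. Pedigree rows ordered parents-first, 0 = unknown.
kinship_oracle <- function(sire, dam) {
  n <- length(sire)
  phi <- matrix(NA_real_, n, n)
  get <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (!is.na(phi[i, j])) return(phi[i, j])
    v <- if (i == j) {
      0.5 * (1 + get(sire[i], dam[i]))
    } else {
      a <- max(i, j); b <- min(i, j)
      0.5 * (get(sire[a], b) + get(dam[a], b))
    }
    phi[i, j] <<- v; phi[j, i] <<- v
    v
  }
  for (i in seq_len(n)) for (j in seq_len(i)) get(i, j)
  2 * phi
}

# Random generational pedigree for property tests.
random_pedigree <- function(n_founders = 6, n_gen = 3, per_gen = 10) {
  id <- seq_len(n_founders)
  sire <- dam <- rep(0L, n_founders)
  sex <- rep(c("M", "F"), length.out = n_founders)
  for (g in seq_len(n_gen)) {
    males <- id[sex == "M"]
    females <- id[sex == "F"]
    for (k in seq_len(per_gen)) {
      id <- c(id, length(id) + 1L)
      sire <- c(sire, sample(males, 1))
      dam <- c(dam, sample(females, 1))
      sex <- c(sex, sample(c("M", "F"), 1))
    }
  }
  data.frame(id = id, sire = sire, dam = dam, sex = sex)
}

# Dense H built from its closed form, for the H-inverse oracle:
# H = A + [A12 A22^-1; I] (G - A22) [A22^-1 A21, I] on the genotyped block.
dense_H_oracle <- function(A, G, geno) {
  n <- nrow(A)
  non <- setdiff(seq_len(n), geno)
  H <- A
  A22i <- solve(A[geno, geno])
  D <- G - A[geno, geno]
  T12 <- A[non, geno, drop = FALSE] %*% A22i
  H[non, non] <- A[non, non] + T12 %*% D %*% t(T12)
  H[non, geno] <- A[non, geno] + T12 %*% D
  H[geno, non] <- t(H[non, geno])
  H[geno, geno] <- G
  H
}

# Independent HWE enumeration with plain factorials (small counts only).
hwe_enum_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * n - nA
  hs <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  pr <- sapply(hs, function(h) {
    factorial(n) / (factorial((nA - h) / 2) * factorial(h) *
                      factorial((na - h) / 2)) * 2^h
  })
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nAa, hs)] * (1 + 1e-10)])
}

# Independent genotypes at chosen allele frequencies (HWE sampling).
sim_geno <- function(n, freqs, ids = seq_len(n)) {
  m <- length(freqs)
  g <- sapply(freqs, function(p) rbinom(n, 2, p))
  rownames(g) <- ids
  colnames(g) <- paste0("L", seq_len(m))
  g
}

# Small single-chromosome map for meiosis tests.
toy_map <- function(len_cM = 100, n_markers = 50, n_qtl = 0,
                    mutation_rate = 0) {
  build_genome(1L, len_cM, n_markers, n_qtl, mutation_rate)
}
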