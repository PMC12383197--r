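test_that("G matches the hand-evaluated centered form", {
  M <- rbind(a = c(2, 2, 2), b = c(0, 0, 0))
  G <- genomic_relationship(M, allele_freqs = c(0.5, 0.5, 0.5))
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2))
  # duplicate individuals: off-diagonal equals the diagonal
  M2 <- rbind(a = c(2, 1, 0, 1), b = c(2, 1, 0, 1), c = c(0, 1, 2, 1))
  G2 <- genomic_relationship(M2, rep(0.5, 4))
  expect_equal(G2["a", "b"], G2["a", "a"])
  expect_error(genomic_relationship(rbind(c(0, 2), c(0, 0))), "monomorphic")
})

test_that("G is invariant to allele relabelling", {
  set.seed(801)
  M <- sim_geno(40, runif(100, 0.1, 0.9))
  flip <- sample(100, 30)
  M2 <- M
  M2[, flip] <- 2 - M2[, flip]
  expect_equal(genomic_relationship(M), genomic_relationship(M2),
               tolerance = 1e-12)
})

test_that("mean diagonal of G is near 1 under HWE sampling", {
  set.seed(802)
  M <- sim_geno(300, runif(3000, 0.1, 0.9))
  G <- genomic_relationship(M)
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
})

test_that("weighted G reduces to G at identity weights and scales per column", {
  set.seed(803)
  M <- sim_geno(30, runif(50, 0.2, 0.8))
  expect_equal(weighted_genomic_relationship(M, rep(1, 50)),
               genomic_relationship(M), tolerance = 1e-12)
  # weight concentrated on one SNP: hand oracle on that single column
  w <- c(2, rep(0, 49))
  p <- colMeans(M) / 2
  z <- M[, 1] - 2 * p[1]
  oracle <- (2 * tcrossprod(z)) / (sum(2 * p * (1 - p)) * mean(w))
  expect_equal(unname(weighted_genomic_relationship(M, w, p)), oracle,
               tolerance = 1e-12)
  # any nonnegative weight vector keeps G_w positive semidefinite
  w2 <- runif(50, 0, 3)
  ev <- eigen(weighted_genomic_relationship(M, w2), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  expect_error(weighted_genomic_relationship(M, c(-1, rep(1, 49))),
               "non-negative")
})

test_that("blending aligns scale and repairs rank", {
  set.seed(804)
  M <- sim_geno(20, runif(60, 0.2, 0.8))
  A22 <- diag(20)
  G <- genomic_relationship(M)
  G1 <- blend_and_align_G(G, A22, 1)
  expect_equal(mean(diag(G1)), mean(diag(A22)), tolerance = 1e-12)
  # duplicated animals make G singular; blending restores invertibility
  Md <- rbind(M, M[1:3, ])
  Gd <- genomic_relationship(Md)
  expect_error(solve(Gd), "singular|exactly singular|computationally")
  Gs <- blend_and_align_G(Gd, diag(23), 0.95)
  expect_silent(solve(Gs))
  expect_equal(mean(diag(Gs)), 1, tolerance = 1e-12)
})

test_that("H-inverse equals the dense closed-form oracle", {
  set.seed(805)
  ped <- random_pedigree(4, 2, 8)
  n <- nrow(ped)
  geno_pos <- sort(sample(seq_len(n), 6))
  A <- numerator_relationship(ped)
  M <- sim_geno(6, runif(40, 0.2, 0.8), ids = ped$id[geno_pos])
  A22 <- A[geno_pos, geno_pos]
  Gs <- blend_and_align_G(genomic_relationship(M), A22, 0.95)
  Hinv <- h_inverse(a_inverse(ped), solve(A22), solve(Gs), geno_pos)
  H_oracle <- dense_H_oracle(A, Gs, geno_pos)
  expect_equal(as.matrix(Hinv), solve(H_oracle), tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_true(Matrix::isSymmetric(Hinv))
})

test_that("H-inverse degenerates to A-inverse", {
  set.seed(806)
  ped <- random_pedigree(4, 2, 6)
  Ainv <- a_inverse(ped)
  geno_pos <- 3:8
  A22 <- numerator_relationship(ped)[geno_pos, geno_pos]
  H1 <- h_inverse(Ainv, solve(A22), solve(A22), geno_pos)
  expect_equal(as.matrix(H1), as.matrix(Ainv), tolerance = 1e-10)
  expect_equal(h_inverse(Ainv, matrix(0, 0, 0), matrix(0, 0, 0), integer(0)),
               Ainv)
  expect_error(h_inverse(Ainv, solve(A22), solve(A22), c(1, 999)),
               "out of range")
})
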