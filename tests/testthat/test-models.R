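test_that("PBLUP matches the dense oracle on toy pedigrees", {
  # founders only: A = I, so PBLUP is ridge regression
  set.seed(1001)
  ped <- data.frame(id = 1:6, sire = 0, dam = 0)
  y <- rnorm(6)
  fit <- run_pblup(ped, ped$id, y, lambda = 1.4, tol = 1e-10)
  oracle <- dense_mme_oracle(y, matrix(1, 6, 1), diag(6), diag(6), 1.4)
  expect_equal(unname(fit$gebv), unname(oracle$g), tolerance = 1e-8)

  # a sire with many phenotyped progeny, checked against the dense solve
  set.seed(1002)
  ped2 <- data.frame(id = 1:22, sire = c(0, 0, rep(1, 20)),
                     dam = c(0, 0, rep(2, 20)))
  rec <- 3:22
  y2 <- rnorm(20, mean = 2)
  fit2 <- run_pblup(ped2, rec, y2, lambda = 1.4, tol = 1e-10)
  A <- numerator_relationship(ped2)
  Z <- matrix(0, 20, 22)
  Z[cbind(1:20, rec)] <- 1
  oracle2 <- dense_mme_oracle(y2, matrix(1, 20, 1), Z, solve(A), 1.4)
  expect_equal(unname(fit2$gebv), unname(oracle2$g), tolerance = 1e-7)
  # the unphenotyped sire inherits half the progeny-mean signal
  expect_gt(unname(fit2$gebv["1"]) * sign(mean(y2) - fit2$b), 0)
})

test_that("GBLUP agrees with the dense direct solve", {
  set.seed(1003)
  Mr <- sim_geno(20, runif(50, 0.2, 0.8), ids = paste0("r", 1:20))
  Mc <- sim_geno(8, runif(50, 0.2, 0.8), ids = paste0("c", 1:8))
  # same frequencies so the joint panel stays polymorphic
  y <- rnorm(20)
  fit <- run_gblup(Mr, y, Mc, lambda = 1.4, blend_weight = 0.95, tol = 1e-10)
  M <- rbind(Mr, Mc)
  G <- genomic_relationship(M)
  Gs <- blend_and_align_G(G, diag(28), 0.95)
  Z <- cbind(diag(20), matrix(0, 20, 8))
  oracle <- dense_mme_oracle(y, matrix(1, 20, 1), Z, solve(Gs), 1.4)
  expect_equal(unname(fit$gebv), unname(oracle$g), tolerance = 1e-6)
})

test_that("a candidate with a reference twin gets the twin's GEBV", {
  set.seed(1004)
  Mr <- sim_geno(15, runif(60, 0.2, 0.8), ids = paste0("r", 1:15))
  Mc <- rbind(Mr[3, , drop = FALSE], sim_geno(5, runif(60, 0.2, 0.8)))
  rownames(Mc) <- paste0("c", 1:6)
  y <- rnorm(15)
  # near-unblended G keeps the duplicate rows effectively exchangeable
  fit <- run_gblup(Mr, y, Mc, blend_weight = 1 - 1e-8, tol = 1e-12)
  expect_equal(unname(fit$gebv["c1"]), unname(fit$gebv["r3"]),
               tolerance = 1e-4)
})

test_that("ssGBLUP collapses to PBLUP without genomic information", {
  set.seed(1005)
  ped <- random_pedigree(4, 2, 8)
  rec <- sample(ped$id, 12)
  y <- rnorm(12)
  pb <- run_pblup(ped, rec, y, lambda = 1.4, tol = 1e-10)

  # no genotyped animals at all
  geno0 <- matrix(0, 0, 10)
  rownames(geno0) <- character(0)
  ss0 <- run_ssgblup(ped, rec, y, geno0, lambda = 1.4, tol = 1e-10)
  expect_equal(ss0$gebv, pb$gebv, tolerance = 1e-8)

  # blend weight pushed to zero forces G* towards A22
  M <- sim_geno(6, runif(40, 0.2, 0.8), ids = sample(ped$id, 6))
  ss_eps <- run_ssgblup(ped, rec, y, M, lambda = 1.4, blend_weight = 1e-9,
                        tol = 1e-10)
  expect_equal(ss_eps$gebv, pb$gebv, tolerance = 1e-5)
})

test_that("ssGBLUP matches a dense H oracle on a part-genotyped toy", {
  set.seed(1006)
  ped <- random_pedigree(4, 2, 6)
  n <- nrow(ped)
  geno_pos <- sort(sample(seq_len(n), 6))
  M <- sim_geno(6, runif(50, 0.2, 0.8), ids = ped$id[geno_pos])
  rec <- sample(ped$id, 10)
  y <- rnorm(10)
  fit <- run_ssgblup(ped, rec, y, M, lambda = 1.4, blend_weight = 0.95,
                     tol = 1e-11)
  A <- numerator_relationship(ped)
  p <- colMeans(M) / 2
  keep <- p > 0 & p < 1
  Gs <- blend_and_align_G(genomic_relationship(M[, keep], p[keep]),
                          A[geno_pos, geno_pos], 0.95)
  H <- dense_H_oracle(A, Gs, geno_pos)
  Z <- matrix(0, 10, n)
  Z[cbind(1:10, match(rec, ped$id))] <- 1
  oracle <- dense_mme_oracle(y, matrix(1, 10, 1), Z, solve(H), 1.4)
  expect_equal(unname(fit$gebv), unname(oracle$g), tolerance = 1e-6)
})

test_that("ssGBLUP with everyone genotyped equals GBLUP", {
  set.seed(1007)
  ped <- data.frame(id = paste0("a", 1:25), sire = 0, dam = 0)
  M <- sim_geno(25, runif(80, 0.2, 0.8), ids = ped$id)
  y <- rnorm(18)
  rec <- ped$id[1:18]
  gb <- run_gblup(M[1:18, ], y, M[19:25, ], lambda = 1.4, tol = 1e-10)
  ss <- run_ssgblup(ped, rec, y, M, lambda = 1.4, tol = 1e-10)
  expect_equal(unname(ss$gebv[names(gb$gebv)]), unname(gb$gebv),
               tolerance = 1e-5)
})

test_that("SNP-BLUP matches a dense ridge oracle and flags the causal SNP", {
  set.seed(1008)
  M <- sim_geno(40, runif(10, 0.2, 0.8))
  y_noise <- rnorm(40)
  est <- estimate_snp_effects(M, y_noise, sigma_g2 = 0.42, sigma_e2 = 0.58)
  # dense primal oracle: [n, 1'Z; Z'1, Z'Z + lambda_snp I]
  p <- colMeans(M) / 2
  Z <- sweep(M, 2, 2 * p)
  s2a <- 0.42 / sum(2 * p * (1 - p))
  lam <- 0.58 / s2a
  C <- rbind(cbind(40, t(rep(1, 40)) %*% Z),
             cbind(crossprod(Z, rep(1, 40)), crossprod(Z) + lam * diag(10)))
  sol <- solve(C, c(sum(y_noise), crossprod(Z, y_noise)))
  expect_equal(unname(est$alpha), unname(sol[-1]), tolerance = 1e-8)
  expect_equal(est$b, unname(sol[1]), tolerance = 1e-8)

  # noiseless single-causal-SNP signal concentrates on that SNP
  y_causal <- M[, 4] * 2
  est2 <- estimate_snp_effects(M, y_causal)
  expect_equal(which.max(abs(est2$alpha)), 4L, ignore_attr = TRUE)
})

test_that("SNP-BLUP and GBLUP are the same model at identity weights", {
  set.seed(1009)
  # external base frequencies keep G nonsingular (observed-frequency
  # centering zeroes all column sums, so that G always has 1 in its null
  # space); the equivalence needs sigma_alpha^2 = sigma_g^2 / sum 2pq.
  freqs <- runif(60, 0.2, 0.8)
  Mr <- sim_geno(25, freqs, ids = paste0("r", 1:25))
  Mc <- sim_geno(10, freqs, ids = paste0("c", 1:10))
  y <- rnorm(25)
  est <- estimate_snp_effects(Mr, y, allele_freqs = freqs,
                              sigma_g2 = 0.42, sigma_e2 = 0.58)
  gebv_snp <- sweep(Mc, 2, 2 * freqs) %*% est$alpha
  # GRM form, unconditioned, on the same frequencies
  G <- genomic_relationship(rbind(Mr, Mc), freqs)
  Z <- cbind(diag(25), matrix(0, 25, 10))
  fit <- solve_mme(y, methods::as(Z, "CsparseMatrix"), solve(G),
                   lambda = 0.58 / 0.42, tol = 1e-12)
  expect_equal(unname(drop(gebv_snp)), unname(fit$g[26:35]),
               tolerance = 1e-6)
})

test_that("window weights match the hand oracle and its limits", {
  w_flat <- window_weights(rep(0.3, 7), S = 2)
  expect_equal(w_flat$w, rep(1, 7))

  a <- c(1, 0, 0, 0, 2)
  raw <- c(mean(c(1, 0)), mean(c(1, 0, 0)), mean(c(0, 0, 0)),
           mean(c(0, 0, 4)), mean(c(0, 4)))
  expect_equal(raw, c(0.5, 1 / 3, 0, 4 / 3, 2))
  ww <- window_weights(a, S = 1)
  expect_equal(ww$w, raw * 5 / sum(raw))
  expect_equal(mean(ww$w), 1)

  w0 <- window_weights(a, S = 0)
  expect_equal(w0$w, a^2 * 5 / sum(a^2))
  expect_error(window_weights(numeric(0), 1), "empty")
})

test_that("wGBLUP with flat weights is exactly GBLUP", {
  set.seed(1010)
  Mr <- sim_geno(20, runif(40, 0.2, 0.8), ids = paste0("r", 1:20))
  Mc <- sim_geno(8, runif(40, 0.2, 0.8), ids = paste0("c", 1:8))
  y <- rnorm(20)
  gb <- run_gblup(Mr, y, Mc, lambda = 0.58 / 0.42, tol = 1e-10)
  wg <- run_wgblup(Mr, y, Mc, weights = rep(1, 40), tol = 1e-10)
  expect_equal(wg$gebv, gb$gebv, tolerance = 1e-8)
  # computed weights always have mean one
  wg2 <- run_wgblup(Mr, y, Mc, S = 3, tol = 1e-8)
  expect_equal(mean(wg2$weights$w), 1, tolerance = 1e-12)
})

test_that("accuracy is the Pearson correlation with affine invariance", {
  tbv <- c(2, 4, 5, 9)
  gebv <- c(1, 2, 3, 4)
  # closed-form Pearson oracle
  oracle <- sum((gebv - mean(gebv)) * (tbv - mean(tbv))) /
    sqrt(sum((gebv - mean(gebv))^2) * sum((tbv - mean(tbv))^2))
  expect_equal(accuracy(gebv, tbv), oracle)
  expect_equal(accuracy(tbv, tbv), 1)
  expect_equal(accuracy(-tbv, tbv), -1)
  expect_equal(accuracy(3 * gebv + 7, tbv), oracle)
  expect_error(accuracy(rep(1, 4), tbv), "zero variance")
  named_g <- stats::setNames(gebv, letters[1:4])
  named_t <- stats::setNames(tbv, letters[1:4])
  expect_equal(accuracy(named_g, named_t, subset = c("a", "c", "d")),
               accuracy(gebv[c(1, 3, 4)], tbv[c(1, 3, 4)]))
})
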