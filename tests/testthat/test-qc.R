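test_that("HWE exact p-values match direct enumeration", {
  expect_equal(hwe_exact_pvalue(25, 50, 25), 1, tolerance = 1e-12)
  expect_equal(hwe_exact_pvalue(10, 0, 10), hwe_enum_oracle(10, 0, 10),
               tolerance = 1e-12)
  for (cnt in list(c(3, 5, 9), c(0, 10, 5), c(7, 1, 2), c(12, 12, 1))) {
    expect_equal(hwe_exact_pvalue(cnt[1], cnt[2], cnt[3]),
                 hwe_enum_oracle(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-12, label = paste(cnt, collapse = "/"))
  }
  expect_equal(hwe_exact_pvalue(40, 0, 0), 1)
  expect_error(hwe_exact_pvalue(0, 0, 0), "no genotypes")
})

test_that("clean equilibrium data pass every filter", {
  set.seed(601)
  g <- sim_geno(200, rep(0.5, 30))
  qc <- apply_qc_filters(g)
  expect_equal(length(qc$kept_markers), 30L)
  expect_equal(length(qc$kept_individuals), 200L)
  expect_true(all(qc$report$removed == 0))
})

test_that("MAF filtering matches hand-computed frequencies", {
  # deterministic columns with allele frequencies
  # {0.5, 0.04, 0.2, 0.0, 0.5, 0.06} over 50 diploids
  n <- 50
  col <- function(nAA, nAa) c(rep(2, nAA), rep(1, nAa), rep(0, n - nAA - nAa))
  g <- cbind(col(12, 26), col(0, 4), col(2, 16), col(0, 0), col(13, 24),
             col(0, 6))
  colnames(g) <- paste0("m", 1:6)
  rownames(g) <- seq_len(n)
  expect_equal(unname(colMeans(g) / 2), c(0.5, 0.04, 0.2, 0, 0.5, 0.06))
  qc <- apply_qc_filters(g, maf_min = 0.05, hwe_p_min = 0)
  expect_setequal(qc$kept_markers, c("m1", "m3", "m5", "m6"))
  expect_equal(qc$report$removed[qc$report$criterion == "maf"], 2)
})

test_that("QC is idempotent and order-independent", {
  set.seed(602)
  g <- sim_geno(150, runif(60, 0.01, 0.5))
  # missingness concentrated in a few bad samples and light elsewhere
  g[1:5, sample(60, 15)] <- NA
  g[cbind(sample(6:150, 100, TRUE), sample(60, 100, TRUE))] <- NA
  qc1 <- apply_qc_filters(g)
  g2 <- g[qc1$kept_individuals, qc1$kept_markers, drop = FALSE]
  qc2 <- apply_qc_filters(g2)
  expect_true(all(qc2$report$removed == 0))
  expect_setequal(qc2$kept_markers, qc1$kept_markers)
  # column permutation leaves the retained set unchanged
  perm <- sample(ncol(g))
  qc3 <- apply_qc_filters(g[, perm])
  expect_setequal(qc3$kept_markers, qc1$kept_markers)
})

test_that("fully permissive thresholds remove nothing", {
  set.seed(603)
  g <- sim_geno(80, runif(40, 0, 1))
  g[sample(length(g), 200)] <- NA
  qc <- apply_qc_filters(g, maf_min = 0, locus_missing_max = 1,
                         individual_missing_max = 1, hwe_p_min = 0)
  expect_equal(length(qc$kept_markers), 40L)
  expect_equal(length(qc$kept_individuals), 80L)
})

test_that("PED/MAP round-trip preserves dosages and pedigree fields", {
  set.seed(604)
  map <- build_genome(2, c(40, 60), 25, 5)
  g <- sim_geno(12, runif(25, 0.1, 0.9))
  g[2, 3] <- NA
  ped <- data.frame(id = 1:12, sire = c(0, 0, rep(1, 10)),
                    dam = c(0, 0, rep(2, 10)),
                    sex = rep(c("M", "F"), 6))
  prefix <- file.path(tempdir(), "qc_roundtrip")
  write_plink(prefix, g, map, ped)
  back <- read_plink(prefix)
  expect_equal(unname(back$genotypes), unname(g))
  expect_equal(back$fam$id, as.character(1:12))
  expect_equal(back$fam$sex, rep(c(1L, 2L), 6))
  expect_equal(nrow(back$map), 25L)
  expect_equal(back$map$cM, map$loci$pos_cM[map$marker_idx])
})

test_that("trait-model and relationship-matrix exports round-trip", {
  set.seed(605)
  map <- build_genome(2, c(40, 60), 20, 6)
  Q <- sim_geno(40, runif(6, 0.2, 0.8))
  tm <- draw_qtl_effects(6, Q)
  p1 <- file.path(tempdir(), "trait.csv")
  d <- write_trait_model_csv(tm, map, p1)
  back <- read.csv(p1)
  expect_equal(back$effect, tm$qtl_effects, tolerance = 1e-12)
  expect_equal(back$chrom, map$loci$chrom[map$qtl_idx])

  A <- numerator_relationship(
    data.frame(id = 1:5, sire = c(0, 0, 1, 1, 3), dam = c(0, 0, 2, 2, 4)))
  p2 <- file.path(tempdir(), "A.csv")
  write_relationship_matrix(A, p2, "dense")
  expect_equal(read_relationship_matrix(p2, "dense"), A, tolerance = 1e-12)
  p3 <- file.path(tempdir(), "A.txt")
  write_relationship_matrix(A, p3, "triplet")
  expect_equal(read_relationship_matrix(p3, "triplet"), A, tolerance = 1e-12)
})
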