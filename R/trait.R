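#' Draw QTL effects and calibrate the additive variance
#'
#' Absolute effects are gamma draws (shape 0.4 by default, the classic
#' leptokurtic architecture for production traits), signs are fair coins,
#' and one multiplicative constant rescales all effects so the variance
#' of the true breeding values in the supplied base population equals
#' `target_sigma_a2` exactly.
#'
#' @param n_qtl number of QTL.
#' @param base_qtl_genotypes base-population QTL dosage matrix
#'   (animals x QTL, codes 0/1/2) used for the variance calibration.
#' @param gamma_shape shape of the gamma effect-size distribution.
#' @param target_sigma_a2 additive genetic variance after rescaling.
#' @param var_phenotypic total phenotypic variance; the residual variance
#'   is `var_phenotypic - target_sigma_a2`.
#' @param mu overall trait mean (the only fixed effect).
#' @return a `trait_model`: list with `qtl_effects`, `sigma_a2`,
#'   `sigma_e2`, `mu`.
#' @export
draw_qtl_effects <- function(n_qtl, base_qtl_genotypes, gamma_shape = 0.4,
                             target_sigma_a2 = 0.42, var_phenotypic = 1.0,
                             mu = 0) {
  stopifnot(n_qtl >= 1, ncol(base_qtl_genotypes) == n_qtl,
            target_sigma_a2 >= 0, var_phenotypic >= target_sigma_a2)
  beta <- rgamma(n_qtl, shape = gamma_shape, scale = 1) *
    sample(c(-1, 1), n_qtl, replace = TRUE)
  if (target_sigma_a2 == 0) {
    beta <- rep(0, n_qtl)
  } else {
    v <- var(as.vector(base_qtl_genotypes %*% beta))
    if (v <= 0) stop("base-population TBV variance is zero (all QTL fixed)")
    beta <- beta * sqrt(target_sigma_a2 / v)
  }
  tm <- list(qtl_effects = beta, sigma_a2 = target_sigma_a2,
             sigma_e2 = var_phenotypic - target_sigma_a2, mu = mu)
  class(tm) <- "trait_model"
  tm
}

#' True breeding values
#'
#' `TBV_k = sum_j beta_j Q_kj` with `Q_kj` the count (0/1/2) of the
#' effect allele at QTL `j` in animal `k`.
#'
#' @param qtl_genotypes dosage matrix animals x QTL, codes 0/1/2.
#' @param qtl_effects per-QTL additive effects (or a `trait_model`).
#' @return numeric vector of TBVs.
#' @export
true_breeding_value <- function(qtl_genotypes, qtl_effects) {
  if (inherits(qtl_effects, "trait_model")) qtl_effects <- qtl_effects$qtl_effects
  if (!all(qtl_genotypes %in% c(0, 1, 2)))
    stop("QTL genotype codes must be 0, 1 or 2")
  drop(qtl_genotypes %*% qtl_effects)
}

#' Simulate phenotypes
#'
#' `y = mu + TBV + e`, `e ~ N(0, sigma_e2)`; each record is then missing
#' (NA) independently with probability `missing_rate`.
#'
#' @param tbv true breeding values.
#' @param mu overall mean.
#' @param sigma_e2 residual variance.
#' @param missing_rate probability a record is not observed.
#' @return numeric vector with NA for missing records.
#' @export
simulate_phenotype <- function(tbv, mu = 0, sigma_e2 = 0.58, missing_rate = 0) {
  if (sigma_e2 < 0) stop("sigma_e2 must be non-negative")
  stopifnot(missing_rate >= 0, missing_rate <= 1)
  y <- mu + tbv + rnorm(length(tbv), 0, sqrt(sigma_e2))
  if (missing_rate > 0)
    y[runif(length(y)) < missing_rate] <- NA_real_
  y
}
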