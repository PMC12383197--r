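#' Founder haplotypes at allele frequency one half
#'
#' Every locus starts with the two alleles at equal frequency: each
#' founder haplotype allele is an independent fair Bernoulli draw.
#'
#' @param map a `genome_map`.
#' @param n_ind number of diploid founders.
#' @return integer matrix with one row per locus and `2 * n_ind` columns;
#'   columns `2i - 1`, `2i` are the two haplotypes of individual `i`.
#' @export
founder_haplotypes <- function(map, n_ind) {
  L <- n_loci(map)
  matrix(sample(0:1, L * 2 * n_ind, replace = TRUE),
         nrow = L, ncol = 2 * n_ind)
}

#' Sample one gamete from a parent
#'
#' Per chromosome the crossover count is Poisson with mean equal to the
#' map length in Morgans, breakpoints are uniform, and the starting
#' haplotype is a fair coin; the gamete copies alternating parental
#' segments. Afterwards each locus mutates (allele flip, recurrent model)
#' independently with the map's mutation rate.
#'
#' @param parent_haplotypes integer matrix, loci x 2 (the parent's pair).
#' @param map a `genome_map`.
#' @param mutation_rate overrides the map's rate when not `NULL`.
#' @return integer vector of length `n_loci(map)`.
#' @export
sample_gamete <- function(parent_haplotypes, map, mutation_rate = NULL) {
  stopifnot(ncol(parent_haplotypes) == 2L,
            nrow(parent_haplotypes) == n_loci(map))
  mu <- if (is.null(mutation_rate)) map$mutation_rate else mutation_rate
  cb <- chrom_blocks(map)
  drop(cpp_make_gametes(parent_haplotypes, 1L, map$loci$pos_cM,
                        cb$first, cb$nloci, map$chrom_lengths_cM, mu))
}

# Batch gamete sampling: one gamete per entry of `parents` (1-based
# individual indices into the loci x 2n haplotype store).
make_gametes <- function(haplo, parents, map, mutation_rate = NULL) {
  mu <- if (is.null(mutation_rate)) map$mutation_rate else mutation_rate
  cb <- chrom_blocks(map)
  cpp_make_gametes(haplo, as.integer(parents), map$loci$pos_cM,
                   cb$first, cb$nloci, map$chrom_lengths_cM, mu)
}

# Offspring haplotypes: paternal gamete in odd columns, maternal in even.
mate <- function(haplo, sire_cols_idx, dam_cols_idx, map) {
  pat <- make_gametes(haplo, sire_cols_idx, map)
  mat <- make_gametes(haplo, dam_cols_idx, map)
  n <- length(sire_cols_idx)
  out <- matrix(0L, nrow = nrow(haplo), ncol = 2L * n)
  out[, seq(1L, 2L * n, by = 2L)] <- pat
  out[, seq(2L, 2L * n, by = 2L)] <- mat
  out
}

# Dosage (0/1/2) matrix, animals x loci, for selected individuals
# (1-based indices into the haplotype store) and selected locus rows.
dosage_from_haplo <- function(haplo, ind_idx, locus_idx) {
  h1 <- haplo[locus_idx, 2L * ind_idx - 1L, drop = FALSE]
  h2 <- haplo[locus_idx, 2L * ind_idx, drop = FALSE]
  t(h1 + h2)
}
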