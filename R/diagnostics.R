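#' Linkage-disequilibrium decay curve
#'
#' Mean squared genotypic correlation (`r^2`) between intra-chromosome
#' marker pairs, binned by map distance (1 cM is reported as 1 Mb, the
#' cattle-scale equivalence). Pairs are subsampled for speed.
#'
#' @param genotypes dosage matrix animals x markers (columns in map
#'   order).
#' @param marker_map data frame with `chrom`, `pos_cM` per marker column.
#' @param breaks_cM bin edges in centimorgans.
#' @param max_pairs cap on sampled pairs.
#' @return data frame with bin edges/midpoint, mean `r2` and pair count;
#'   bins with no pairs are absent.
#' @export
ld_decay_curve <- function(genotypes, marker_map,
                           breaks_cM = seq(0, 1, by = 0.1),
                           max_pairs = 50000L) {
  stopifnot(nrow(marker_map) == ncol(genotypes))
  max_d <- max(breaks_cM)
  # sample pairs within chromosomes at offsets likely within range
  pairs <- NULL
  for (c in unique(marker_map$chrom)) {
    idx <- which(marker_map$chrom == c)
    if (length(idx) < 2) next
    if (choose(length(idx), 2) <= max_pairs) {
      cmb <- t(utils::combn(idx, 2L))
      pairs <- rbind(pairs, cmb)
    } else {
      i <- sample(idx, min(length(idx) * 20L, max_pairs), replace = TRUE)
      j <- sample(idx, length(i), replace = TRUE)
      keep <- i < j
      pairs <- rbind(pairs, cbind(i[keep], j[keep]))
    }
  }
  if (is.null(pairs) || nrow(pairs) == 0L) stop("no intra-chromosome pairs")
  d <- abs(marker_map$pos_cM[pairs[, 1]] - marker_map$pos_cM[pairs[, 2]])
  keep <- d <= max_d
  pairs <- pairs[keep, , drop = FALSE]
  d <- d[keep]
  if (nrow(pairs) > max_pairs) {
    s <- sample(nrow(pairs), max_pairs)
    pairs <- pairs[s, , drop = FALSE]
    d <- d[s]
  }
  sd_col <- apply(genotypes, 2, sd)
  ok <- sd_col[pairs[, 1]] > 0 & sd_col[pairs[, 2]] > 0
  pairs <- pairs[ok, , drop = FALSE]
  d <- d[ok]
  gc <- scale(genotypes)
  n <- nrow(genotypes)
  r <- colSums(gc[, pairs[, 1], drop = FALSE] *
                 gc[, pairs[, 2], drop = FALSE]) / (n - 1)
  bin <- cut(d, breaks_cM, include.lowest = TRUE)
  out <- aggregate(r^2, by = list(bin = bin), FUN = mean)
  names(out)[2] <- "mean_r2"
  out$n_pairs <- as.vector(table(bin)[as.character(out$bin)])
  mids <- (breaks_cM[-1] + breaks_cM[-length(breaks_cM)]) / 2
  out$mid_cM <- mids[match(out$bin, levels(bin))]
  out
}

#' Principal components of a genotype matrix
#'
#' Eigen-analysis of the centered genotype covariance (equivalently of
#' the genomic relationship matrix).
#'
#' @param genotypes dosage matrix animals x markers.
#' @param n_components number of components to return.
#' @return list with `projection` (animals x components) and
#'   `variance_fraction` per component.
#' @export
pca_populations <- function(genotypes, n_components = 2L) {
  if (nrow(genotypes) < n_components)
    stop("fewer animals than requested components")
  pc <- prcomp(genotypes, center = TRUE, scale. = FALSE, rank. = n_components)
  tot <- sum(pc$sdev^2)
  vf <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  proj <- pc$x
  rownames(proj) <- rownames(genotypes)
  list(projection = proj, variance_fraction = vf[seq_len(n_components)])
}
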