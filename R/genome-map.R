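#' @useDynLib mbgpsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats var cor rnorm rbinom rgamma runif cmdscale prcomp
#'   kmeans sd aggregate
#' @importFrom utils write.table read.table head
NULL

#' Largest-remainder proportional allocation
#'
#' Splits `total` items over bins proportionally to `weights`, rounding by
#' the largest-remainder rule so bin counts differ from the exact
#' proportional share by less than 1 and sum exactly to `total`.
#'
#' @param total integer number of items.
#' @param weights positive bin weights.
#' @return integer vector of bin counts.
#' @export
allocate_proportional <- function(total, weights) {
  stopifnot(total >= 0, all(weights > 0))
  q <- total * weights / sum(weights)
  base <- floor(q)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0) {
    add <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Build a simulated genome map
#'
#' Lays out biallelic marker and QTL loci on a multi-chromosome linkage
#' map. Marker and QTL counts per chromosome are proportional to map
#' length (largest-remainder rounding); positions are uniform within the
#' chromosome. Marker and QTL position lists are disjoint with
#' probability one (continuous positions).
#'
#' @param n_chromosomes number of autosomes.
#' @param chrom_lengths_cM per-chromosome map length in centimorgans.
#' @param n_markers total marker count.
#' @param n_qtl total QTL count.
#' @param mutation_rate per-locus, per-meiosis recurrent mutation
#'   probability.
#' @return an object of class `genome_map`: a list with the chromosome
#'   lengths, a `loci` data frame (chrom, pos_cM, type) sorted by
#'   chromosome and position, and index vectors for marker and QTL loci.
#' @export
build_genome <- function(n_chromosomes, chrom_lengths_cM, n_markers, n_qtl,
                         mutation_rate = 2.5e-5) {
  stopifnot(length(chrom_lengths_cM) == n_chromosomes)
  if (any(chrom_lengths_cM <= 0)) stop("chromosome lengths must be positive")
  if (n_qtl < 0) stop("n_qtl must be non-negative")
  if (n_markers < n_chromosomes) stop("need at least one marker per chromosome")

  m_per <- allocate_proportional(n_markers, chrom_lengths_cM)
  q_per <- if (n_qtl > 0) allocate_proportional(n_qtl, chrom_lengths_cM) else
    integer(n_chromosomes)

  loci <- do.call(rbind, lapply(seq_len(n_chromosomes), function(c) {
    pos_m <- sort(runif(m_per[c], 0, chrom_lengths_cM[c]))
    pos_q <- sort(runif(q_per[c], 0, chrom_lengths_cM[c]))
    d <- data.frame(
      chrom = rep(c, m_per[c] + q_per[c]),
      pos_cM = c(pos_m, pos_q),
      type = rep(c("marker", "qtl"), c(m_per[c], q_per[c]))
    )
    d[order(d$pos_cM), , drop = FALSE]
  }))
  rownames(loci) <- NULL

  map <- list(
    n_chromosomes = n_chromosomes,
    chrom_lengths_cM = chrom_lengths_cM,
    loci = loci,
    marker_idx = which(loci$type == "marker"),
    qtl_idx = which(loci$type == "qtl"),
    mutation_rate = mutation_rate
  )
  class(map) <- "genome_map"
  map
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", x$n_chromosomes, "chromosomes,",
      sprintf("%.2f cM,", sum(x$chrom_lengths_cM)),
      length(x$marker_idx), "markers,",
      length(x$qtl_idx), "QTL, mutation rate", x$mutation_rate, "\n")
  invisible(x)
}

n_loci <- function(map) nrow(map$loci)

# First locus index and locus count per chromosome (loci are sorted).
chrom_blocks <- function(map) {
  nl <- tabulate(map$loci$chrom, nbins = map$n_chromosomes)
  list(first = as.integer(cumsum(c(1L, nl[-length(nl)]))),
       nloci = as.integer(nl))
}
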