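#' Ascertain the marker panel and QTL set from a locus pool
#'
#' Emulates SNP-chip design the way QMSim-style simulators do: the
#' genome is first simulated with a pool of candidate loci (all starting
#' at frequency 0.5), and at the end of the historical phase the marker
#' panel is drawn uniformly from the candidate markers still segregating
#' in *every* supplied population, while the QTL set is drawn from the
#' candidate QTL segregating in the first (base) population.
#' Conditional on having survived a long drift phase, allele frequencies
#' are near-uniform, which is what makes most panel markers pass a
#' MAF > 0.05 filter later, as on a real chip.
#'
#' @param map the pool `genome_map` the populations were simulated on.
#' @param populations list of `population` objects (historical output);
#'   the first is the base population for QTL ascertainment.
#' @param n_markers,n_qtl panel sizes; truncated with a warning when
#'   fewer segregating candidates exist.
#' @return list with `map` (the panel `genome_map`) and `locus_rows`
#'   (pool row indices of the panel loci, in map order), to be applied
#'   to each population with [apply_panel()].
#' @export
ascertain_panel <- function(map, populations, n_markers, n_qtl) {
  if (!is.list(populations) || inherits(populations, "population"))
    populations <- list(populations)
  seg <- function(pop, rows) {
    f <- rowMeans(pop$haplo[rows, , drop = FALSE])
    f > 0 & f < 1
  }
  seg_mk <- Reduce(`&`, lapply(populations, seg, rows = map$marker_idx))
  seg_qtl <- seg(populations[[1]], map$qtl_idx)

  pick <- function(cand, n, what) {
    if (sum(cand) < n) {
      warning("only ", sum(cand), " segregating ", what,
              " candidates for a panel of ", n)
      n <- sum(cand)
    }
    sort(sample(which(cand), n))
  }
  mk <- map$marker_idx[pick(seg_mk, n_markers, "marker")]
  qt <- if (n_qtl > 0) map$qtl_idx[pick(seg_qtl, n_qtl, "QTL")] else integer(0)

  rows <- sort(c(mk, qt))
  new_map <- map
  new_map$loci <- map$loci[rows, , drop = FALSE]
  rownames(new_map$loci) <- NULL
  new_map$marker_idx <- which(rows %in% mk)
  new_map$qtl_idx <- which(rows %in% qt)
  list(map = new_map, locus_rows = rows)
}

#' Restrict a population to an ascertained panel
#'
#' @param pop a `population` simulated on the pool map.
#' @param panel result of [ascertain_panel()].
#' @return the population with haplotypes and map subset to the panel.
#' @export
apply_panel <- function(pop, panel) {
  stopifnot(max(panel$locus_rows) <= nrow(pop$haplo))
  pop$haplo <- pop$haplo[panel$locus_rows, , drop = FALSE]
  pop$map <- panel$map
  pop
}
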