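#' Describe a demographic phase
#'
#' A phase spans `n_gen` generations over which the census moves linearly
#' from `start` to `end` individuals (the usual way to encode histories
#' given only as endpoints, e.g. "gradually expanded").
#'
#' @param n_gen number of generations in the phase (may be 0 for the
#'   initial founder phase).
#' @param start census at the first generation of the phase.
#' @param end census at the last generation of the phase.
#' @return a one-row data frame usable in a phase table.
#' @export
demography_phase <- function(n_gen, start, end = start) {
  stopifnot(n_gen >= 0, start >= 2, end >= 2)
  data.frame(n_gen = as.integer(n_gen), start = as.integer(start),
             end = as.integer(end))
}

#' Census per generation implied by a phase table
#'
#' Generation 0 is the founder generation at the first phase's start
#' size; each phase then contributes `n_gen` generations interpolated
#' linearly from its start to its end census.
#'
#' @param phases phase table built from [demography_phase()] rows.
#' @return integer census vector, one entry per generation.
#' @export
census_schedule <- function(phases) {
  stopifnot(nrow(phases) >= 1)
  sizes <- phases$start[1]
  for (i in seq_len(nrow(phases))) {
    ng <- phases$n_gen[i]
    if (ng == 0) next
    sizes <- c(sizes,
               round(seq(phases$start[i], phases$end[i], length.out = ng + 1))[-1])
  }
  as.integer(sizes)
}

#' Run the historical (drift) phase of a population
#'
#' Non-overlapping generations, equal sex ratio, random mating, no
#' selection or migration. Each generation's census follows the
#' piecewise-linear phase schedule; dams are used as evenly as possible
#' (without replacement until the dam pool is exhausted), sires are drawn
#' uniformly with replacement. Only the final generation is returned,
#' with full haplotypes.
#'
#' @param map a `genome_map`.
#' @param phases phase table from [demography_phase()] rows.
#' @param final_males male count in the final generation (defaults to an
#'   equal split); lets a history end on a skewed herd structure such as
#'   100 bulls / 900 cows.
#' @return a `population` object holding the final historical generation
#'   (founder pedigree: unknown parents).
#' @export
run_historical <- function(map, phases, final_males = NULL) {
  sizes <- census_schedule(phases)
  n_gen <- length(sizes) - 1L

  split_sexes <- function(n, males = NULL) {
    nm <- if (is.null(males)) n %/% 2L else as.integer(males)
    if (nm < 1L || n - nm < 1L) stop("a generation has zero males or zero females")
    # M first, F after; order within a generation is arbitrary
    rep(c("M", "F"), c(nm, n - nm))
  }

  sex <- split_sexes(sizes[1])
  haplo <- founder_haplotypes(map, sizes[1])

  if (n_gen > 0) {
    for (t in seq_len(n_gen)) {
      n_new <- sizes[t + 1L]
      males <- which(sex == "M")
      females <- which(sex == "F")
      if (length(males) == 0L || length(females) == 0L)
        stop("a generation has zero males or zero females")
      dams <- sample(rep_len(sample(females), n_new))
      sires <- sample(males, n_new, replace = TRUE)
      haplo <- mate(haplo, sires, dams, map)
      sex <- split_sexes(n_new, if (t == n_gen) final_males else NULL)
    }
  }

  n <- sizes[length(sizes)]
  pop <- list(
    map = map,
    ped = data.frame(id = seq_len(n), sire = 0L, dam = 0L, sex = sex,
                     gen = 0L, phase = "founder"),
    haplo = haplo,
    haplo_ids = seq_len(n),
    records = NULL,
    gen_summary = NULL
  )
  class(pop) <- "population"
  pop
}

#' @export
print.population <- function(x, ...) {
  cat("population:", nrow(x$ped), "pedigree animals,",
      length(x$haplo_ids), "with haplotypes over", nrow(x$haplo), "loci\n")
  if (!is.null(x$records))
    cat("  records:", nrow(x$records), "animals in retained generations\n")
  invisible(x)
}

#' Genotype dosages for a population
#'
#' @param pop a `population`.
#' @param ids animal ids (must have retained haplotypes); defaults to all.
#' @param loci `"marker"`, `"qtl"` or `"all"`.
#' @return integer matrix animals x loci, rows named by id.
#' @export
genotypes <- function(pop, ids = pop$haplo_ids, loci = c("marker", "qtl", "all")) {
  loci <- match.arg(loci)
  idx <- match(ids, pop$haplo_ids)
  if (anyNA(idx)) stop("some ids have no retained haplotypes")
  rows <- switch(loci, marker = pop$map$marker_idx, qtl = pop$map$qtl_idx,
                 all = seq_len(n_loci(pop$map)))
  g <- dosage_from_haplo(pop$haplo, idx, rows)
  rownames(g) <- ids
  colnames(g) <- paste0("L", rows)
  g
}
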