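#' Study configurations at three scales
#'
#' Returns the full configuration of the three-population simulation
#' study: genome layout, the three demographic histories (stable/expand;
#' shrink/stable/expand; stable/shrink), recent breeding schemes with
#' their replacement rates, trait parameters (h2 = 0.42, phenotypic
#' variance 1), QC thresholds, mixing fractions and model list.
#'
#' Scales:
#' * `"full"` — 29 autosomes totalling 2715.85 cM, 58,990 markers, 725
#'   QTL, 1095 historical generations, full censuses. Hours of compute.
#' * `"desk"` — 3 chromosomes (280.95 cM), 3,000 markers, 75 QTL, 200
#'   historical generations, censuses divided by 5. Minutes; the scale
#'   used by the package's own test suite and acceptance runs.
#' * `"micro"` — a tiny smoke-test scale (seconds).
#'
#' @param scale one of `"full"`, `"desk"`, `"micro"`.
#' @return a nested configuration list.
#' @export
simulation_preset <- function(scale = c("desk", "full", "micro")) {
  scale <- match.arg(scale)

  if (scale == "full") {
    # chromosome lengths taper like the bovine karyotype, summing to the
    # configured genome length
    lens <- seq(1.8, 0.55, length.out = 29)
    genome <- list(n_chromosomes = 29L,
                   chrom_lengths_cM = lens / sum(lens) * 2715.85,
                   n_markers = 58990L, n_qtl = 725L, mutation_rate = 2.5e-5,
                   pool_factor = 8)
    hist_g <- c(const = 1000L, ramp = 95L)
    div <- 1
  } else if (scale == "desk") {
    genome <- list(n_chromosomes = 3L,
                   chrom_lengths_cM = c(100, 95, 85.95),
                   n_markers = 3000L, n_qtl = 75L, mutation_rate = 2.5e-5,
                   pool_factor = 8)
    hist_g <- c(const = 160L, ramp = 40L)
    div <- 5
  } else {
    genome <- list(n_chromosomes = 2L,
                   chrom_lengths_cM = c(60, 40),
                   n_markers = 400L, n_qtl = 30L, mutation_rate = 2.5e-5,
                   pool_factor = 8)
    hist_g <- c(const = 30L, ramp = 10L)
    div <- 10
  }

  sc <- function(n) as.integer(pmax(2, round(n / div)))
  exp_g <- if (scale == "micro") 4L else 10L
  sel_g <- if (scale == "micro") 4L else 10L

  scheme <- function(s1m, s1f, s2m, s2f, rs, rd) {
    breeding_scheme(n_founder_males = sc(s1m), n_founder_females = sc(s1f),
                    n_breeding_males = sc(s2m), n_breeding_females = sc(s2f),
                    sire_replacement = rs, dam_replacement = rd,
                    expansion_generations = exp_g,
                    selected_generations = sel_g)
  }

  populations <- list(
    A = list(  # stable, then continuous expansion
      phases = rbind(demography_phase(0, sc(200)),
                     demography_phase(hist_g["const"], sc(200), sc(200)),
                     demography_phase(hist_g["ramp"], sc(200), sc(1000))),
      final_males = sc(100),
      scheme = scheme(250, 3000, 200, 2800, 0.6, 0.3)
    ),
    B = list(  # shrink to stable, then expansion
      phases = rbind(demography_phase(0, sc(500)),
                     demography_phase(hist_g["const"], sc(500), sc(200)),
                     demography_phase(hist_g["ramp"], sc(200), sc(1000))),
      final_males = sc(100),
      scheme = scheme(250, 2550, 220, 2335, 0.5, 0.3)
    ),
    C = list(  # large and stable, then contraction
      phases = rbind(demography_phase(0, sc(1000)),
                     demography_phase(hist_g["const"], sc(1000), sc(1000)),
                     demography_phase(hist_g["ramp"], sc(1000), sc(200))),
      final_males = sc(100),
      scheme = scheme(250, 3000, 200, 2800, 0.5, 0.2)
    )
  )

  list(scale = scale,
       genome = genome,
       populations = populations,
       trait = list(h2 = 0.42, var_phenotypic = 1.0, gamma_shape = 0.4),
       qc = list(maf_min = 0.05, locus_missing_max = 0.10,
                 individual_missing_max = 0.10, hwe_p_min = 1e-5),
       fractions = c(0.10, 0.15, 0.20),
       models = c("gblup", "ssgblup", "wgblup"),
       mds_dims = 2L,
       window_S = 20L,
       blend_weight = 0.95)
}

#' Build the candidate locus pool genome for a configuration
#'
#' The genome is simulated with `pool_factor` times the target marker
#' and QTL counts; the panel is ascertained among segregating loci at
#' the end of the historical phase ([ascertain_panel()]).
#'
#' @param genome the `genome` entry of a [simulation_preset()].
#' @return a `genome_map` over the locus pool.
#' @export
build_pool_genome <- function(genome) {
  build_genome(genome$n_chromosomes, genome$chrom_lengths_cM,
               n_markers = as.integer(genome$n_markers * genome$pool_factor),
               n_qtl = as.integer(genome$n_qtl * genome$pool_factor),
               mutation_rate = genome$mutation_rate)
}

#' Simulate one population end to end
#'
#' Historical drift phases, optional marker-panel ascertainment, then
#' the recent expansion/selection scheme.
#'
#' @param map a `genome_map` (a locus pool when `panel_sizes` is given).
#' @param pop_config one entry of `simulation_preset()$populations`.
#' @param trait_model a shared `trait_model`, or `NULL` to draw one from
#'   this population's historical base (QTL effects are identical across
#'   breeds, so draw once on the main population and pass it to the
#'   others).
#' @param trait trait configuration (used when drawing).
#' @param panel_sizes optional `list(n_markers, n_qtl)`: ascertain the
#'   panel within this population before the recent phase.
#' @return a `population`; the trait model used is attached as
#'   `$trait_model`.
#' @export
simulate_population <- function(map, pop_config, trait_model = NULL,
                                trait = simulation_preset("desk")$trait,
                                panel_sizes = NULL) {
  founders <- run_historical(map, pop_config$phases, pop_config$final_males)
  if (!is.null(panel_sizes)) {
    panel <- ascertain_panel(map, founders, panel_sizes$n_markers,
                             panel_sizes$n_qtl)
    founders <- apply_panel(founders, panel)
  }
  if (is.null(trait_model)) {
    qg <- genotypes(founders, loci = "qtl")
    trait_model <- draw_qtl_effects(
      n_qtl = length(founders$map$qtl_idx), base_qtl_genotypes = qg,
      gamma_shape = trait$gamma_shape,
      target_sigma_a2 = trait$h2 * trait$var_phenotypic,
      var_phenotypic = trait$var_phenotypic)
  }
  run_recent(founders, pop_config$scheme, trait_model)
}
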