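#' Assemble a mixed or single-breed reference scenario
#'
#' Donors are screened by MDS distance to the base population on the
#' shared post-QC markers of generation-9 animals. In mixed mode the
#' reference is all phenotyped generation-9 base animals plus the
#' selected donors; in single mode it is the selected donors alone. The
#' validation set is the donor population's generation-10 animals, whose
#' phenotypes are never used.
#'
#' @param base_pop,donor_pop `population` objects from
#'   [simulate_population()] (records and genotypes retained for the
#'   last two selected generations).
#' @param fraction donor fraction of the donor population's
#'   generation-9 animals.
#' @param shared_markers marker column names usable in both populations
#'   (post-QC intersection).
#' @param mode `"mixed"` or `"single"`.
#' @param base_label,donor_label population labels used to build unique
#'   animal ids (e.g. `"A"` and `"B"`).
#' @param mds_dims MDS embedding dimension for the screening.
#' @return a `scenario` list with reference/validation definitions and
#'   prefixed genotype matrices, phenotypes and true breeding values.
#' @export
build_scenario <- function(base_pop, donor_pop, fraction, shared_markers,
                           mode = c("mixed", "single"),
                           base_label = "A", donor_label = "B",
                           mds_dims = 2L) {
  mode <- match.arg(mode)
  gens <- sort(unique(donor_pop$records$gen))
  g9 <- gens[length(gens) - 1L]
  g10 <- gens[length(gens)]

  tag <- function(lab, ids) paste0(lab, ".", ids)

  base_rec <- base_pop$records
  base9 <- base_rec$id[base_rec$gen == g9]
  donor_rec <- donor_pop$records
  donor9 <- donor_rec$id[donor_rec$gen == g9]
  valid10 <- donor_rec$id[donor_rec$gen == g10]

  gb <- genotypes(base_pop, base9)[, shared_markers, drop = FALSE]
  gd9 <- genotypes(donor_pop, donor9)[, shared_markers, drop = FALSE]
  gd10 <- genotypes(donor_pop, valid10)[, shared_markers, drop = FALSE]
  rownames(gb) <- tag(base_label, base9)
  rownames(gd9) <- tag(donor_label, donor9)
  rownames(gd10) <- tag(donor_label, valid10)

  D <- ibs_distance_matrix(rbind(gb, gd9))
  mds <- classical_mds(D, mds_dims)
  sel <- select_donors(mds$points, rownames(gb), rownames(gd9), fraction)

  phen <- c(stats::setNames(base_rec$phenotype, tag(base_label, base_rec$id)),
            stats::setNames(donor_rec$phenotype, tag(donor_label, donor_rec$id)))
  tbv <- c(stats::setNames(base_rec$tbv, tag(base_label, base_rec$id)),
           stats::setNames(donor_rec$tbv, tag(donor_label, donor_rec$id)))

  ref_ids <- if (mode == "mixed") {
    c(rownames(gb)[!is.na(phen[rownames(gb)])], sel)
  } else {
    sel
  }
  val_ids <- rownames(gd10)
  if (length(val_ids) == 0L) stop("validation set is empty")
  stopifnot(length(intersect(ref_ids, val_ids)) == 0L)

  ref_geno <- rbind(gb, gd9)[ref_ids, , drop = FALSE]

  name <- sprintf("%s+%d%%%s%s", base_label, round(fraction * 100),
                  donor_label, if (mode == "single") " (single)" else "")
  structure(list(
    name = name, mode = mode, fraction = fraction,
    base_label = base_label, donor_label = donor_label,
    reference_ids = ref_ids, validation_ids = val_ids,
    donor_selected = sel,
    reference_genotypes = ref_geno,
    reference_y = unname(phen[ref_ids]),
    candidate_genotypes = gd10,
    validation_tbv = tbv[val_ids],
    mds = list(points = mds$points,
               centroid_distance = mds_centroid_distance(
                 mds$points, rownames(gb), sel))
  ), class = "scenario")
}

# Combined two-population pedigree with prefixed ids, restricted to the
# ancestors of the animals that matter (records + genotyped).
combine_pedigrees <- function(pops, labels, keep_tagged) {
  ped <- do.call(rbind, lapply(seq_along(pops), function(i) {
    p <- pops[[i]]$ped
    tag <- function(x) ifelse(x == 0, "0", paste0(labels[i], ".", x))
    data.frame(id = tag(p$id), sire = tag(p$sire), dam = tag(p$dam),
               sex = p$sex, gen = p$gen, phase = p$phase)
  }))
  ped$sire[ped$sire == "0"] <- NA
  ped$dam[ped$dam == "0"] <- NA
  prune_pedigree(ped, keep_tagged)
}

#' Fit the requested models on a scenario
#'
#' @param scenario a `scenario` from [build_scenario()].
#' @param pops named list of the `population` objects involved (by
#'   label), needed for the single-step pedigree.
#' @param models subset of `c("gblup", "ssgblup", "wgblup")`.
#' @param sigma_g2,sigma_e2 variance components.
#' @param window_S wGBLUP window half-width.
#' @param blend_weight G conditioning weight.
#' @return data frame: one row per model with validation accuracy.
#' @export
evaluate_scenario <- function(scenario, pops,
                              models = c("gblup", "ssgblup", "wgblup"),
                              sigma_g2 = 0.42, sigma_e2 = 0.58,
                              window_S = 20L, blend_weight = 0.95) {
  lambda <- sigma_e2 / sigma_g2
  out <- NULL
  for (model in models) {
    fit <- switch(
      model,
      gblup = run_gblup(scenario$reference_genotypes, scenario$reference_y,
                        scenario$candidate_genotypes, lambda = lambda,
                        blend_weight = blend_weight),
      wgblup = run_wgblup(scenario$reference_genotypes, scenario$reference_y,
                          scenario$candidate_genotypes, S = window_S,
                          sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                          blend_weight = blend_weight),
      ssgblup = {
        labels <- if (scenario$mode == "mixed")
          c(scenario$base_label, scenario$donor_label) else scenario$donor_label
        use_pops <- pops[labels]
        geno <- rbind(scenario$reference_genotypes, scenario$candidate_genotypes)
        geno <- geno[intersect(rownames(geno),
                               unlist(lapply(labels, function(l)
                                 paste0(l, ".", pops[[l]]$ped$id)))), ,
                     drop = FALSE]
        ok <- !is.na(scenario$reference_y)
        ped <- combine_pedigrees(use_pops, labels,
                                 unique(c(scenario$reference_ids[ok],
                                          rownames(geno))))
        run_ssgblup(ped, scenario$reference_ids[ok],
                    scenario$reference_y[ok], geno,
                    lambda = lambda, blend_weight = blend_weight)
      },
      stop("unknown model ", model)
    )
    acc <- accuracy(fit$gebv, scenario$validation_tbv,
                    subset = scenario$validation_ids)
    out <- rbind(out, data.frame(
      scenario = scenario$name, mode = scenario$mode,
      donor = scenario$donor_label, fraction = scenario$fraction,
      model = model, accuracy = acc,
      n_reference = length(scenario$reference_ids),
      n_validation = length(scenario$validation_ids),
      converged = fit$converged))
  }
  out
}

#' Run the full multi-breed prediction experiment
#'
#' Per replicate: build a genome, simulate the three populations (QTL
#' effects drawn once, on the main population's historical base), apply
#' per-population marker QC, screen donors by MDS, assemble all mixed
#' and single-breed scenarios at the configured fractions, fit all
#' models and score validation accuracy against true breeding values.
#'
#' @param config a [simulation_preset()] configuration.
#' @param n_replicates number of independent replicates.
#' @param master_seed master seed; every stage derives a named
#'   substream, so the whole run is a pure function of
#'   `(config, master_seed)`.
#' @param modes scenario modes to run.
#' @param diagnostics also compute LD-decay curves, PCA projections and
#'   MDS centroid distances per replicate.
#' @return list with `results` (long data frame), `summary` (mean
#'   accuracy per scenario x model, Table-2 layout in long form) and
#'   `diagnostics`.
#' @export
run_experiment <- function(config, n_replicates = 2L, master_seed = 1L,
                           modes = c("mixed", "single"),
                           diagnostics = TRUE) {
  results <- NULL
  diags <- list()
  qc_log <- NULL

  for (rep in seq_len(n_replicates)) {
    set.seed(substream_seed(master_seed, "genome", rep))
    map <- build_pool_genome(config$genome)

    # historical phase of each population on the shared locus pool
    founders <- list()
    for (lab in names(config$populations)) {
      set.seed(substream_seed(master_seed, paste0("hist", lab), rep))
      founders[[lab]] <- run_historical(map,
                                        config$populations[[lab]]$phases,
                                        config$populations[[lab]]$final_males)
    }

    # one shared chip: markers segregating in every population; QTL
    # ascertained (and effects calibrated) on the main population's base
    set.seed(substream_seed(master_seed, "panel", rep))
    panel <- ascertain_panel(map, founders, config$genome$n_markers,
                             config$genome$n_qtl)
    founders <- lapply(founders, apply_panel, panel = panel)

    set.seed(substream_seed(master_seed, "trait", rep))
    trait_model <- draw_qtl_effects(
      n_qtl = length(panel$map$qtl_idx),
      base_qtl_genotypes = genotypes(founders[["A"]], loci = "qtl"),
      gamma_shape = config$trait$gamma_shape,
      target_sigma_a2 = config$trait$h2 * config$trait$var_phenotypic,
      var_phenotypic = config$trait$var_phenotypic)

    pops <- list()
    for (lab in names(config$populations)) {
      set.seed(substream_seed(master_seed, paste0("pop", lab), rep))
      pops[[lab]] <- run_recent(founders[[lab]],
                                config$populations[[lab]]$scheme, trait_model)
      pops[[lab]]$trait_model <- trait_model
    }
    founders <- NULL

    # per-population marker QC on the genotyped (last two) generations
    kept <- lapply(pops, function(p) {
      qc <- apply_qc_filters(genotypes(p),
                             maf_min = config$qc$maf_min,
                             locus_missing_max = config$qc$locus_missing_max,
                             individual_missing_max = config$qc$individual_missing_max,
                             hwe_p_min = config$qc$hwe_p_min)
      qc$kept_markers
    })
    qc_log <- rbind(qc_log, data.frame(
      replicate = rep, pop = names(kept),
      markers_kept = vapply(kept, length, 0L),
      markers_total = length(pops[[1]]$map$marker_idx)))

    for (donor in setdiff(names(pops), "A")) {
      shared <- intersect(kept[["A"]], kept[[donor]])
      for (fraction in config$fractions) {
        for (mode in modes) {
          set.seed(substream_seed(master_seed,
                                  paste0("scen", donor, fraction, mode), rep))
          scen <- build_scenario(pops[["A"]], pops[[donor]], fraction, shared,
                                 mode = mode, base_label = "A",
                                 donor_label = donor,
                                 mds_dims = config$mds_dims)
          res <- evaluate_scenario(scen, pops, models = config$models,
                                   sigma_g2 = config$trait$h2 * config$trait$var_phenotypic,
                                   sigma_e2 = (1 - config$trait$h2) * config$trait$var_phenotypic,
                                   window_S = config$window_S,
                                   blend_weight = config$blend_weight)
          res$replicate <- rep
          res$mds_centroid_distance <- scen$mds$centroid_distance
          results <- rbind(results, res)
        }
      }
    }

    if (diagnostics) {
      set.seed(substream_seed(master_seed, "diagnostics", rep))
      shared_all <- Reduce(intersect, kept)
      mk <- panel$map$loci[panel$map$marker_idx, ]
      rownames(mk) <- paste0("L", panel$map$marker_idx)
      ld <- lapply(names(pops), function(lab) {
        p <- pops[[lab]]
        g10 <- p$records$id[p$records$gen == max(p$records$gen)]
        g <- genotypes(p, g10)[, kept[[lab]], drop = FALSE]
        cbind(pop = lab, replicate = rep,
              ld_decay_curve(g, mk[kept[[lab]], ]))
      })
      gall <- do.call(rbind, lapply(names(pops), function(lab) {
        p <- pops[[lab]]
        g10 <- p$records$id[p$records$gen == max(p$records$gen)]
        g <- genotypes(p, g10)[, shared_all, drop = FALSE]
        rownames(g) <- paste0(lab, ".", g10)
        g
      }))
      pca <- pca_populations(gall, 2L)
      diags[[rep]] <- list(ld = do.call(rbind, ld), pca = pca)
    }
  }

  summary <- aggregate(accuracy ~ donor + fraction + mode + model,
                       data = results, FUN = mean)
  list(results = results, summary = summary, qc = qc_log,
       diagnostics = if (diagnostics) diags else NULL)
}
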