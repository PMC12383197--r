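# One micro-scale pair of populations shared by the scenario tests.
scenario_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(1301)
    cfg <- simulation_preset("micro")
    map <- build_pool_genome(cfg$genome)
    fA <- run_historical(map, cfg$populations$A$phases,
                         cfg$populations$A$final_males)
    fB <- run_historical(map, cfg$populations$B$phases,
                         cfg$populations$B$final_males)
    panel <- ascertain_panel(map, list(fA, fB), cfg$genome$n_markers,
                             cfg$genome$n_qtl)
    fA <- apply_panel(fA, panel)
    fB <- apply_panel(fB, panel)
    tm <- draw_qtl_effects(length(panel$map$qtl_idx),
                           genotypes(fA, loci = "qtl"))
    popA <- run_recent(fA, cfg$populations$A$scheme, tm)
    popB <- run_recent(fB, cfg$populations$B$scheme, tm)
    kA <- apply_qc_filters(genotypes(popA))$kept_markers
    kB <- apply_qc_filters(genotypes(popB))$kept_markers
    cache <<- list(cfg = cfg, popA = popA, popB = popB,
                   shared = intersect(kA, kB))
    cache
  }
})

test_that("mixed scenarios assemble the contracted reference and validation", {
  fx <- scenario_fixture()
  scen <- build_scenario(fx$popA, fx$popB, 0.15, fx$shared, mode = "mixed",
                         base_label = "A", donor_label = "B")
  expect_equal(scen$name, "A+15%B")
  expect_length(intersect(scen$reference_ids, scen$validation_ids), 0)
  g9 <- sort(unique(fx$popB$records$gen))[1]
  n_donors9 <- sum(fx$popB$records$gen == g9)
  expect_length(scen$donor_selected, round(0.15 * n_donors9))
  # validation is the donor population's final generation, fully covered
  g10 <- max(fx$popB$records$gen)
  expect_length(scen$validation_ids,
                sum(fx$popB$records$gen == g10))
  expect_true(all(startsWith(scen$validation_ids, "B.")))
  # reference phenotypes exist for the base contingent
  base_refs <- scen$reference_ids[startsWith(scen$reference_ids, "A.")]
  expect_false(anyNA(scen$reference_y[match(base_refs, scen$reference_ids)]))
  expect_gt(scen$mds$centroid_distance, 0)
})

test_that("single-breed scenarios use the screened donors alone", {
  fx <- scenario_fixture()
  scen <- build_scenario(fx$popA, fx$popB, 0.20, fx$shared, mode = "single",
                         base_label = "A", donor_label = "B")
  expect_setequal(scen$reference_ids, scen$donor_selected)
  expect_true(all(startsWith(scen$reference_ids, "B.")))
  expect_length(intersect(scen$reference_ids, scen$validation_ids), 0)
  # full inclusion at fraction 1
  scen_all <- build_scenario(fx$popA, fx$popB, 1, fx$shared, mode = "single")
  g9 <- sort(unique(fx$popB$records$gen))[1]
  expect_length(scen_all$reference_ids, sum(fx$popB$records$gen == g9))
})

test_that("scenario evaluation scores every requested model", {
  fx <- scenario_fixture()
  scen <- build_scenario(fx$popA, fx$popB, 0.15, fx$shared, mode = "mixed")
  res <- evaluate_scenario(scen, list(A = fx$popA, B = fx$popB),
                           models = c("gblup", "wgblup"))
  expect_equal(res$model, c("gblup", "wgblup"))
  expect_true(all(res$accuracy >= -1 & res$accuracy <= 1))
  expect_true(all(res$converged))
})

test_that("the experiment is a pure function of configuration and seed", {
  cfg <- simulation_preset("micro")
  cfg$populations <- cfg$populations[c("A", "B")]
  cfg$fractions <- 0.15
  cfg$models <- "gblup"
  r1 <- run_experiment(cfg, n_replicates = 1, master_seed = 42,
                       modes = "mixed", diagnostics = FALSE)
  r2 <- run_experiment(cfg, n_replicates = 1, master_seed = 42,
                       modes = "mixed", diagnostics = FALSE)
  expect_identical(r1$results, r2$results)
  r3 <- run_experiment(cfg, n_replicates = 1, master_seed = 43,
                       modes = "mixed", diagnostics = FALSE)
  expect_false(isTRUE(all.equal(r1$results$accuracy, r3$results$accuracy)))
})

test_that("a two-replicate smoke run yields the contracted result grid", {
  cfg <- simulation_preset("micro")
  cfg$populations <- cfg$populations[c("A", "B")]
  cfg$fractions <- 0.10
  cfg$models <- "ssgblup"
  res <- run_experiment(cfg, n_replicates = 2, master_seed = 7,
                        diagnostics = FALSE)
  # 2 replicates x (mixed, single) = 4 result rows
  expect_equal(nrow(res$results), 4L)
  expect_setequal(res$results$mode, c("mixed", "single"))
  expect_equal(nrow(res$summary), 2L)
  expect_true(all(abs(res$results$accuracy) <= 1))
})
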