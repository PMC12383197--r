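#' Describe a recent-generation breeding scheme
#'
#' Stage 1 expands the herd by random mating: `n_founder_males` sires and
#' `n_founder_females` dams (drawn from the historical population) breed
#' for `expansion_generations` generations with litter size 1; each
#' generation the breeding set is refreshed at random from the new
#' offspring, topped up with current breeders where a sex is short.
#' Stage 2 keeps `n_breeding_males` sires and `n_breeding_females` dams
#' under selection for `selected_generations` generations: each
#' generation the given replacement fraction of breeders is culled
#' (lowest EBV first, older animals first on ties, then id) and replaced
#' by the top-EBV young animals of that generation.
#'
#' @param n_founder_males,n_founder_females stage-1 breeding counts.
#' @param n_breeding_males,n_breeding_females stage-2 breeding counts.
#' @param sire_replacement,dam_replacement per-generation replacement
#'   fractions in (0, 1].
#' @param expansion_generations,selected_generations stage lengths.
#' @param litter_size offspring per dam per generation (fixed at 1).
#' @param selection_criterion `"ebv"` (pedigree BLUP) or `"phenotype"`.
#' @param missing_record_rate probability a phenotype record is missing.
#' @param retain_generations how many final selected generations keep
#'   genotypes and phenotype records in the returned population.
#' @return a `breeding_scheme` list.
#' @export
breeding_scheme <- function(n_founder_males, n_founder_females,
                            n_breeding_males, n_breeding_females,
                            sire_replacement, dam_replacement,
                            expansion_generations = 10L,
                            selected_generations = 10L,
                            litter_size = 1L,
                            selection_criterion = c("ebv", "phenotype"),
                            missing_record_rate = 0.05,
                            retain_generations = 2L) {
  stopifnot(litter_size == 1L,
            sire_replacement >= 0, sire_replacement <= 1,
            dam_replacement >= 0, dam_replacement <= 1,
            missing_record_rate >= 0, missing_record_rate <= 1)
  s <- list(n_founder_males = as.integer(n_founder_males),
            n_founder_females = as.integer(n_founder_females),
            n_breeding_males = as.integer(n_breeding_males),
            n_breeding_females = as.integer(n_breeding_females),
            sire_replacement = sire_replacement,
            dam_replacement = dam_replacement,
            expansion_generations = as.integer(expansion_generations),
            selected_generations = as.integer(selected_generations),
            litter_size = 1L,
            selection_criterion = match.arg(selection_criterion),
            missing_record_rate = missing_record_rate,
            retain_generations = as.integer(retain_generations))
  class(s) <- "breeding_scheme"
  s
}

# draw `n` ids from `pool`; with replacement only if the pool is smaller
# (duplicated draws become separate pedigree founders sharing haplotypes)
draw_founders <- function(pool, n) {
  if (length(pool) == 0L) stop("empty founder pool")
  if (length(pool) >= n) sample(pool, n) else sample(pool, n, replace = TRUE)
}

#' Run the recent generations: expansion then EBV-based selection
#'
#' @param founders a `population` from [run_historical()].
#' @param scheme a [breeding_scheme()].
#' @param trait_model a `trait_model` (shared across populations so QTL
#'   effects are identical across breeds).
#' @param evaluator function `(ped, rec_ids, y, lambda) -> named EBV
#'   vector over all pedigree ids`; defaults to pedigree BLUP solved by
#'   conjugate gradients. Only used when the selection criterion is EBV.
#' @param lambda variance ratio used by the evaluator; defaults to
#'   `sigma_e2 / sigma_a2` of the trait model.
#' @return a `population` with the full recent pedigree, genotypes and
#'   records for the last `retain_generations` selected generations, a
#'   per-generation summary (`gen_summary`) and a `breeding_log`.
#' @export
run_recent <- function(founders, scheme, trait_model, evaluator = NULL,
                       lambda = trait_model$sigma_e2 / trait_model$sigma_a2) {
  map <- founders$map
  if (is.null(evaluator)) evaluator <- pblup_evaluator

  hp_m <- founders$ped$id[founders$ped$sex == "M"]
  hp_f <- founders$ped$id[founders$ped$sex == "F"]

  src_m <- draw_founders(hp_m, scheme$n_founder_males)
  src_f <- draw_founders(hp_f, scheme$n_founder_females)
  n0 <- length(src_m) + length(src_f)

  ped <- data.frame(id = seq_len(n0), sire = 0L, dam = 0L,
                    sex = rep(c("M", "F"), c(length(src_m), length(src_f))),
                    gen = 0L, phase = "base")
  src_idx <- match(c(src_m, src_f), founders$haplo_ids)
  live_ids <- seq_len(n0)
  live_haplo <- founders$haplo[, as.vector(rbind(2L * src_idx - 1L, 2L * src_idx)),
                               drop = FALSE]

  cur_sires <- ped$id[ped$sex == "M"]
  cur_dams <- ped$id[ped$sex == "F"]
  next_id <- n0 + 1L

  born <- function(dams, gen, phase) {
    n_off <- length(dams)
    sires <- sample(cur_sires, n_off, replace = TRUE)
    off_h <- mate(live_haplo, match(sires, live_ids), match(dams, live_ids), map)
    off_ids <- seq.int(next_id, length.out = n_off)
    off_sex <- ifelse(runif(n_off) < 0.5, "M", "F")
    list(ped = data.frame(id = off_ids, sire = sires, dam = dams,
                          sex = off_sex, gen = gen, phase = phase),
         haplo = off_h, ids = off_ids)
  }

  ## Stage 1: expansion by random mating, no selection -----------------
  for (g in seq_len(scheme$expansion_generations)) {
    off <- born(cur_dams, g, "expansion")
    ped <- rbind(ped, off$ped)
    next_id <- next_id + length(off$ids)

    keep <- c(cur_sires, cur_dams)
    live_haplo <- cbind(
      live_haplo[, as.vector(rbind(2L * match(keep, live_ids) - 1L,
                                   2L * match(keep, live_ids))), drop = FALSE],
      off$haplo)
    live_ids <- c(keep, off$ids)

    off_m <- off$ids[off$ped$sex == "M"]
    off_f <- off$ids[off$ped$sex == "F"]
    refresh <- function(new, old, n) {
      if (length(new) >= n) sample(new, n)
      else c(new, sample(old, n - length(new)))
    }
    cur_sires <- refresh(off_m, cur_sires, scheme$n_founder_males)
    cur_dams <- refresh(off_f, cur_dams, scheme$n_founder_females)
  }

  ## Stage 2 founders: drawn from the expanded base --------------------
  pool <- live_ids
  pool_sex <- ped$sex[match(pool, ped$id)]
  pool_m <- pool[pool_sex == "M"]
  pool_f <- pool[pool_sex == "F"]
  if (length(pool_m) < scheme$n_breeding_males ||
      length(pool_f) < scheme$n_breeding_females)
    stop("expanded base too small for the stage-2 breeding set")
  cur_sires <- sample(pool_m, scheme$n_breeding_males)
  cur_dams <- sample(pool_f, scheme$n_breeding_females)
  breeders <- c(cur_sires, cur_dams)

  # phenotype the stage-2 breeders (selection-phase records start here)
  qg <- dosage_from_haplo(live_haplo, match(breeders, live_ids), map$qtl_idx)
  tbv <- true_breeding_value(qg, trait_model)
  phe <- simulate_phenotype(tbv, trait_model$mu, trait_model$sigma_e2,
                            scheme$missing_record_rate)
  records <- data.frame(id = breeders, gen = 0L,
                        sex = ped$sex[match(breeders, ped$id)],
                        phenotype = phe, tbv = tbv, ebv = NA_real_)

  # drop non-breeder haplotypes
  ki <- match(breeders, live_ids)
  live_haplo <- live_haplo[, as.vector(rbind(2L * ki - 1L, 2L * ki)), drop = FALSE]
  live_ids <- breeders

  n_cull_m <- round(scheme$sire_replacement * scheme$n_breeding_males)
  n_cull_f <- round(scheme$dam_replacement * scheme$n_breeding_females)
  breeding_log <- NULL
  retained_haplo <- list()

  ## Stage 2: selection -------------------------------------------------
  for (g in seq_len(scheme$selected_generations)) {
    off <- born(cur_dams, g, "selection")
    off$ped$phase <- "selection"
    ped <- rbind(ped, off$ped)
    next_id <- next_id + length(off$ids)

    qg <- dosage_from_haplo(off$haplo, seq_along(off$ids), map$qtl_idx)
    tbv <- true_breeding_value(qg, trait_model)
    phe <- simulate_phenotype(tbv, trait_model$mu, trait_model$sigma_e2,
                              scheme$missing_record_rate)
    records <- rbind(records,
                     data.frame(id = off$ids, gen = g, sex = off$ped$sex,
                                phenotype = phe, tbv = tbv, ebv = NA_real_))

    keep <- unique(c(cur_sires, cur_dams,
                     unlist(lapply(retained_haplo, `[[`, "ids"))))
    ki <- match(keep, live_ids)
    live_haplo <- cbind(live_haplo[, as.vector(rbind(2L * ki - 1L, 2L * ki)),
                                   drop = FALSE], off$haplo)
    live_ids <- c(keep, off$ids)
    if (g > scheme$selected_generations - scheme$retain_generations)
      retained_haplo[[as.character(g)]] <- list(ids = off$ids, haplo = off$haplo)

    # breeding values for culling/selection
    if (scheme$selection_criterion == "ebv") {
      ok <- !is.na(records$phenotype)
      ebv <- evaluator(ped, records$id[ok], records$phenotype[ok], lambda)
    } else {
      ebv <- stats::setNames(records$phenotype, records$id)
      ebv[is.na(ebv)] <- -Inf
    }
    records$ebv <- unname(ebv[as.character(records$id)])

    cull_replace <- function(cur, cand, n_cull) {
      if (n_cull == 0L) return(list(cur = cur, n = 0L))
      if (length(cand) < n_cull)
        stop("replacement demand exceeds available candidates")
      e_cur <- ebv[as.character(cur)]
      # cull lowest EBV; ties: older first then id order, and ids are
      # assigned in birth order, so ascending id covers both
      out <- cur[order(e_cur, cur)][seq_len(n_cull)]
      e_cand <- ebv[as.character(cand)]
      inn <- cand[order(-e_cand, cand)][seq_len(n_cull)]
      list(cur = c(setdiff(cur, out), inn), n = n_cull)
    }
    off_m <- off$ids[off$ped$sex == "M"]
    off_f <- off$ids[off$ped$sex == "F"]
    rm_ <- cull_replace(cur_sires, off_m, n_cull_m)
    rf_ <- cull_replace(cur_dams, off_f, n_cull_f)
    breeding_log <- rbind(breeding_log,
                          data.frame(gen = g, n_sires = length(cur_sires),
                                     n_dams = length(cur_dams),
                                     sires_replaced = rm_$n,
                                     dams_replaced = rf_$n))
    cur_sires <- rm_$cur
    cur_dams <- rf_$cur
    # keep live haplotypes: breeders + retained generations
    keep <- unique(c(cur_sires, cur_dams,
                     unlist(lapply(retained_haplo, `[[`, "ids"))))
    ki <- match(keep, live_ids)
    live_haplo <- live_haplo[, as.vector(rbind(2L * ki - 1L, 2L * ki)),
                             drop = FALSE]
    live_ids <- keep
  }

  gen_summary <- aggregate(cbind(tbv, phenotype) ~ gen, data = records,
                           FUN = mean, na.action = stats::na.pass,
                           na.rm = TRUE)
  gen_summary$n <- as.vector(table(records$gen))

  keep_gens <- seq(scheme$selected_generations - scheme$retain_generations + 1L,
                   scheme$selected_generations)
  out_rec <- records[records$gen %in% keep_gens, , drop = FALSE]
  out_ids <- unlist(lapply(retained_haplo, `[[`, "ids"))
  ki <- match(out_ids, live_ids)
  out_haplo <- live_haplo[, as.vector(rbind(2L * ki - 1L, 2L * ki)), drop = FALSE]

  pop <- list(map = map, ped = ped, haplo = out_haplo, haplo_ids = out_ids,
              records = out_rec, gen_summary = gen_summary,
              breeding_log = breeding_log, trait_model = trait_model)
  class(pop) <- "population"
  pop
}
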