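round_half_up <- function(x) floor(x + 0.5)

# sample() without the length-1 surprise: always samples from the vector x.
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Breed configuration for the recent (expanded) generations
#'
#' Founder counts, replacement and growth rates, and the selection criterion
#' for one breed's 10 recent generations.  Mating and culling are random;
#' each dam has exactly one progeny.
#'
#' @param breed_label Breed tag (e.g. `"A"`, `"B"`, `"C"`).
#' @param n_founder_males,n_founder_females Founders drawn from the last
#'   historical generation.
#' @param n_generations Number of recent generations (10).
#' @param selection_criterion `"phenotype"` or `"ebv"` (EBV selection runs a
#'   pedigree BLUP on the data recorded so far at every generation).
#' @param sire_replacement,sire_growth,dam_replacement,dam_growth Per-sex
#'   replacement proportion and compound per-generation growth rate of the
#'   breeding pools.
#' @param offspring_per_dam Progeny per dam per generation (1).
#' @param mutation_rate Per-locus per-gamete mutation rate in the recent
#'   generations (default 0: negligible over 10 generations and keeps every
#'   recent allele founder-derived).
#' @return An object of class `breed_config`.
#' @export
breed_config <- function(breed_label,
                         n_founder_males, n_founder_females,
                         n_generations = 10L,
                         selection_criterion = c("phenotype", "ebv"),
                         sire_replacement = 0.5, sire_growth = 0,
                         dam_replacement = 0.3, dam_growth = 0,
                         offspring_per_dam = 1L,
                         mutation_rate = 0) {
  selection_criterion <- match.arg(selection_criterion)
  rates <- c(sire_replacement, dam_replacement)
  if (any(rates < 0 | rates > 1)) stop("replacement rates must be in [0, 1]")
  if (sire_growth < 0 || dam_growth < 0) stop("growth rates must be >= 0")
  structure(list(breed_label = breed_label,
                 n_founder_males = as.integer(n_founder_males),
                 n_founder_females = as.integer(n_founder_females),
                 n_generations = as.integer(n_generations),
                 selection_criterion = selection_criterion,
                 sire_replacement = sire_replacement,
                 sire_growth = sire_growth,
                 dam_replacement = dam_replacement,
                 dam_growth = dam_growth,
                 offspring_per_dam = as.integer(offspring_per_dam),
                 mutation_rate = mutation_rate),
            class = "breed_config")
}

#' Breed configurations of the three simulated beef-cattle breeds
#'
#' Founder counts, replacement and growth rates for breeds A, B and C,
#' optionally shrunk by a scale factor (founder counts multiplied by
#' `scale`, rates unchanged).
#'
#' @param scale Factor in (0, 1] applied to founder counts.
#' @param selection_criterion Passed to [breed_config()].
#' @return Named list of `breed_config` objects.
#' @export
cattle_breed_configs <- function(scale = 1,
                                 selection_criterion = c("phenotype", "ebv")) {
  selection_criterion <- match.arg(selection_criterion)
  mk <- function(label, nm, nf, sr, sg, dr, dg)
    breed_config(label,
                 n_founder_males = max(2, round_half_up(nm * scale)),
                 n_founder_females = max(2, round_half_up(nf * scale)),
                 selection_criterion = selection_criterion,
                 sire_replacement = sr, sire_growth = sg,
                 dam_replacement = dr, dam_growth = dg)
  list(A = mk("A", 620, 5800, 0.5065, 0.072, 0.30, 0.098),
       B = mk("B", 350, 5100, 0.1851, 0.1038, 0.3015, 0.1629),
       C = mk("C", 300, 5000, 0.063, 0.123, 0.105, 0.355))
}

#' Historical plans of the three simulated breeds
#'
#' Population-size trajectories (bottleneck at the midpoint breakpoint,
#' expansion to a common final size) optionally shrunk by `scale`; the
#' generation axis is shrunk by the same factor so drift time in units of
#' population size is preserved.
#'
#' @param scale Factor in (0, 1] applied to sizes and generation counts.
#' @return Named list of [historical_plan()] objects.
#' @export
cattle_historical_plans <- function(scale = 1) {
  mk <- function(sizes) {
    g <- round_half_up(c(0, 500, 1000) * scale)
    g[2] <- max(g[2], 1)
    g[3] <- max(g[3], g[2] + 1)
    historical_plan(g, pmax(4, round_half_up(sizes * scale)))
  }
  list(A = mk(c(10000, 1000, 7120)),
       B = mk(c(5000, 3000, 7120)),
       C = mk(c(1000, 4000, 7120)))
}

#' Found a breed from the last historical generation
#'
#' Draws founders at random without replacement from the historical
#' population and resets the generation counter to 0.  By default the sex of
#' a founder is assigned at the draw (the configured counts are then always
#' satisfiable); with `respect_sex = TRUE` the draw honours the historical
#' sexes and errors when either sex runs short.
#'
#' @param historical A `population_state` (last historical generation).
#' @param cfg A [breed_config()].
#' @param seed Integer seed.
#' @param respect_sex Honour historical sexes when drawing founders.
#' @return A `breed_state`: list with `ped` (id, sire, dam, sex, generation,
#'   tbv, phenotype), `haps`, `pool_sires`, `pool_dams`, `candidates`, `map`,
#'   `generation`.
#' @export
found_breed <- function(historical, cfg, seed = 1L, respect_sex = FALSE) {
  set.seed(as.integer(seed))
  nm <- cfg$n_founder_males
  nf <- cfg$n_founder_females
  n_hist <- nrow(historical$ped)
  if (respect_sex) {
    males <- which(historical$ped$sex == 1L)
    females <- which(historical$ped$sex == 2L)
    if (length(males) < nm)
      stop("founding error: insufficient males in the historical population (",
           length(males), " < ", nm, ")")
    if (length(females) < nf)
      stop("founding error: insufficient females in the historical population (",
           length(females), " < ", nf, ")")
    pick_m <- resample(males, nm)
    pick_f <- resample(females, nf)
  } else {
    if (n_hist < nm + nf)
      stop("founding error: historical population (", n_hist,
           ") smaller than requested founder count (", nm + nf, ")")
    pick <- sample(n_hist, nm + nf)
    pick_m <- pick[seq_len(nm)]
    pick_f <- pick[nm + seq_len(nf)]
  }
  rows <- c(pick_m, pick_f)
  n <- length(rows)
  hap_rows <- as.vector(rbind(2L * rows - 1L, 2L * rows))
  ped <- data.frame(id = seq_len(n), sire = 0L, dam = 0L,
                    sex = rep(c(1L, 2L), c(nm, nf)),
                    generation = 0L, tbv = NA_real_, phenotype = NA_real_)
  structure(list(ped = ped,
                 haps = historical$haps[hap_rows, , drop = FALSE],
                 pool_sires = seq_len(nm),
                 pool_dams = nm + seq_len(nf),
                 candidates = integer(0),
                 map = historical$map,
                 generation = 0L),
            class = "breed_state")
}

#' @export
print.breed_state <- function(x, ...) {
  cat(sprintf("breed_state: generation %d, %d animals (%d sires / %d dams in pool)\n",
              x$generation, nrow(x$ped), length(x$pool_sires), length(x$pool_dams)))
  invisible(x)
}

# Update one sex's breeding pool: cull `replacement * size` members at random,
# grow the pool to round(n0 * (1+growth)^t), and fill vacancies with the
# top-ranked young candidates of that sex.
update_pool <- function(pool, target_size, replacement, candidates, ranking) {
  n_cull <- min(round_half_up(replacement * length(pool)), length(pool))
  keep <- if (n_cull > 0) resample(pool, length(pool) - n_cull) else pool
  culled <- setdiff(pool, keep)
  n_recruit <- target_size - length(keep)
  ranked <- candidates[order(ranking, decreasing = TRUE)]
  recruits <- ranked[seq_len(min(n_recruit, length(ranked)))]
  short <- n_recruit - length(recruits)
  if (short > 0 && length(culled))  # re-retain culled animals if young stock runs out
    keep <- c(keep, culled[seq_len(min(short, length(culled)))])
  out <- c(keep, recruits)
  if (!length(out)) stop("generation error: breeding pool is empty")
  out
}

# Recruit the current candidate cohort into the breeding pools.  The pool of
# each sex grows along the compound path round(n0 * (1 + growth)^t), where t
# counts pool updates (one per candidate cohort); a replacement-rate fraction
# of the old pool is culled at random and the vacancies go to the top-ranked
# young candidates of that sex.
select_pools <- function(state, cfg, ranking) {
  if (!length(state$candidates)) return(state)
  if (is.null(ranking) || length(ranking) != length(state$candidates))
    stop("ranking must cover all current candidates")
  t <- state$generation  # candidates were born at this generation
  cand_sex <- state$ped$sex[state$candidates]
  target_s <- max(1L, round_half_up(cfg$n_founder_males *
                                      (1 + cfg$sire_growth)^t))
  target_d <- max(1L, round_half_up(cfg$n_founder_females *
                                      (1 + cfg$dam_growth)^t))
  state$pool_sires <- update_pool(state$pool_sires, target_s,
                                  cfg$sire_replacement,
                                  state$candidates[cand_sex == 1L],
                                  ranking[cand_sex == 1L])
  state$pool_dams <- update_pool(state$pool_dams, target_d,
                                 cfg$dam_replacement,
                                 state$candidates[cand_sex == 2L],
                                 ranking[cand_sex == 2L])
  state
}

#' Advance a breed by one generation
#'
#' Replaces a fraction of each sex's breeding pool with the top-ranked young
#' candidates (pool sizes follow the compound growth path
#' `round(n0 * (1 + growth)^t)`), mates every dam to a randomly assigned
#' sire, and produces exactly one offspring per dam with sex Bernoulli(1/2).
#' Gametes use the same recombination model as the historical phase, with
#' mutation at `cfg$mutation_rate` (0 by default).
#'
#' @param state A `breed_state`.
#' @param cfg The [breed_config()].
#' @param ranking Numeric selection score for each current candidate (same
#'   order as `state$candidates`); ignored when there are no candidates yet.
#' @param seed Optional integer seed; `NULL` continues the current RNG stream.
#' @return The advanced `breed_state`; the new cohort is in `candidates`.
#' @export
advance_breed_generation <- function(state, cfg, ranking = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  t_next <- state$generation + 1L
  state <- select_pools(state, cfg, ranking)
  if (!length(state$pool_sires) || !length(state$pool_dams))
    stop("generation error: empty breeding pool")
  dams <- state$pool_dams
  n_off <- length(dams) * cfg$offspring_per_dam
  dam_of <- rep(dams, each = cfg$offspring_per_dam)
  sire_of <- resample(state$pool_sires, n_off, replace = TRUE)
  chrinfo <- chromosome_index(state$map)
  pat <- make_gametes(state$haps, 2L * sire_of - 1L, 2L * sire_of, chrinfo)
  mat <- make_gametes(state$haps, 2L * dam_of - 1L, 2L * dam_of, chrinfo)
  if (cfg$mutation_rate > 0) {
    pat <- apply_recurrent_mutation(pat, cfg$mutation_rate)
    mat <- apply_recurrent_mutation(mat, cfg$mutation_rate)
  }
  new_haps <- matrix(0L, 2L * n_off, ncol(state$haps))
  new_haps[seq(1L, 2L * n_off, by = 2L), ] <- pat
  new_haps[seq(2L, 2L * n_off, by = 2L), ] <- mat
  first_id <- nrow(state$ped) + 1L
  ids <- first_id:(first_id + n_off - 1L)
  state$ped <- rbind(state$ped, data.frame(
    id = ids, sire = sire_of, dam = dam_of,
    sex = sample(c(1L, 2L), n_off, replace = TRUE),
    generation = t_next, tbv = NA_real_, phenotype = NA_real_))
  state$haps <- rbind(state$haps, new_haps)
  state$candidates <- ids
  state$generation <- t_next
  state
}

# PBLUP EBVs of the candidate cohort from all phenotypes recorded so far.
ebv_ranking <- function(state, arch, candidates) {
  ped <- state$ped[, c("id", "sire", "dam")]
  rec <- which(!is.na(state$ped$phenotype))
  lambda <- arch$sigma_e2 / max(arch$sigma_a2, 1e-8)
  fit <- solve_pblup(y = state$ped$phenotype[rec], animal = rec,
                     pedigree = ped, lambda = lambda)
  fit$u[candidates]
}

#' Run a breed's recent generations
#'
#' Founds the breed, simulates `cfg$n_generations` generations of selection
#' and mating, and emits pedigree, genotypes and phenotypes.  True breeding
#' values and phenotypes are generated for every recent animal (selection
#' needs them); genotype and phenotype tables are emitted for the last two
#' generations only, which are the genotyped cohorts.
#'
#' @param historical A `population_state` (last historical generation).
#' @param cfg A [breed_config()].
#' @param arch A `trait_architecture` (effects scaled in the historical base).
#' @param seed Integer seed.
#' @param respect_sex Passed to [found_breed()].
#' @return List with `pedigree` (data.frame id, sire, dam, sex, generation,
#'   breed), `genotypes` (a [genotype_matrix()] over marker loci for the last
#'   two generations), `phenotypes` (a `phenotype_table` for the same
#'   animals), and `state` (the final `breed_state`).
#' @export
run_breed <- function(historical, cfg, arch, seed = 1L, respect_sex = FALSE) {
  state <- found_breed(historical, cfg, seed = seed, respect_sex = respect_sex)
  qtl <- qtl_loci(state$map)
  score_tbv <- function(ids)
    drop((state$haps[2L * ids - 1L, qtl, drop = FALSE] +
          state$haps[2L * ids, qtl, drop = FALSE]) %*% arch$beta)
  # founders are phenotyped too (their records seed EBV selection)
  f_ids <- state$ped$id
  state$ped$tbv[f_ids] <- score_tbv(f_ids)
  state$ped$phenotype[f_ids] <- arch$mu + state$ped$tbv[f_ids] +
    stats::rnorm(length(f_ids), 0, sqrt(arch$sigma_e2))
  cohort_ranking <- function() {
    if (!length(state$candidates)) return(NULL)
    if (cfg$selection_criterion == "phenotype")
      state$ped$phenotype[state$candidates]
    else ebv_ranking(state, arch, state$candidates)
  }
  for (g in seq_len(cfg$n_generations)) {
    state <- advance_breed_generation(state, cfg, ranking = cohort_ranking())
    ids <- state$candidates
    state$ped$tbv[ids] <- score_tbv(ids)
    state$ped$phenotype[ids] <- arch$mu + state$ped$tbv[ids] +
      stats::rnorm(length(ids), 0, sqrt(arch$sigma_e2))
  }
  # the last cohort is itself selected into the pools (the breeding pool a
  # generation-11 mating would use), completing the compound growth path
  state <- select_pools(state, cfg, cohort_ranking())
  g_keep <- c(cfg$n_generations - 1L, cfg$n_generations)
  sel <- which(state$ped$generation %in% g_keep)
  geno <- dosages_of(state, sel, marker_loci(state$map))
  gm <- genotype_matrix(geno,
                        animal_ids = state$ped$id[sel],
                        locus_ids = state$map$id[marker_loci(state$map)])
  ped_out <- state$ped[, c("id", "sire", "dam", "sex", "generation")]
  ped_out$breed <- cfg$breed_label
  phen <- state$ped[sel, c("id", "sex", "generation", "tbv", "phenotype")]
  rownames(phen) <- NULL
  class(phen) <- c("phenotype_table", "data.frame")
  list(pedigree = ped_out, genotypes = gm, phenotypes = phen, state = state)
}

# Dosage matrix of a subset of breed animals.
dosages_of <- function(state, animal_rows, loci) {
  h1 <- state$haps[2L * animal_rows - 1L, loci, drop = FALSE]
  h2 <- state$haps[2L * animal_rows, loci, drop = FALSE]
  h1 + h2
}

#' Export a pedigree as a whitespace-delimited file
#'
#' Three columns (id, sire, dam) with 0 as the missing-parent code, plus
#' optional sex/generation columns (PLINK .fam compatible dialect).
#'
#' @param ped data.frame with at least id, sire, dam.
#' @param path Output path.
#' @param extra_cols Additional columns to keep (e.g. `c("sex", "generation")`).
#' @export
write_pedigree <- function(ped, path, extra_cols = character(0)) {
  cols <- c("id", "sire", "dam", extra_cols)
  utils::write.table(ped[, cols], path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
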