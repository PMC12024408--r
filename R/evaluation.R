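#' Prediction accuracy as the TBV-EBV correlation
#'
#' Pearson correlation between true and estimated breeding values of the
#' same animals.
#'
#' @param tbv,ebv Numeric vectors of equal length >= 3.
#' @return The correlation (a number in `[-1, 1]`).
#' @export
accuracy <- function(tbv, ebv) {
  if (length(tbv) != length(ebv)) stop("tbv and ebv lengths differ")
  if (length(tbv) < 3L) stop("need at least 3 animals for an accuracy")
  if (stats::sd(tbv) == 0 || stats::sd(ebv) == 0)
    stop("undefined accuracy: zero variance in TBV or EBV")
  stats::cor(tbv, ebv)
}

#' Reference/validation split of the genotyped candidates
#'
#' Validation animals are drawn at random from the last genotyped
#' generation; the reference (training) set is drawn from the remaining
#' candidates by a common random ordering, so reference sets of increasing
#' size at the same seed are nested.
#'
#' @param candidates A `phenotype_table` (or data.frame) with columns `id`
#'   and `generation` for all genotyped animals.
#' @param rp_size Reference-population size.
#' @param n_validation Validation-set size.
#' @param seed Integer seed.
#' @return List with `reference` and `validation` ID vectors (disjoint).
#' @export
split_reference_validation <- function(candidates, rp_size, n_validation,
                                       seed = 1L) {
  set.seed(as.integer(seed))
  last_gen <- max(candidates$generation)
  g10 <- candidates$id[candidates$generation == last_gen]
  if (length(g10) < n_validation)
    stop("sizing error: validation set (", n_validation,
         ") exceeds the last genotyped generation (", length(g10), ")")
  validation <- resample(g10, n_validation)
  rest <- setdiff(candidates$id, validation)
  if (rp_size > length(rest))
    stop("sizing error: reference size ", rp_size, " exceeds the ",
         length(rest), " available candidates (short by ",
         rp_size - length(rest), ")")
  reference <- rest[sample.int(length(rest))][seq_len(rp_size)]
  list(reference = reference, validation = validation)
}

#' Simulate one breed's evaluation dataset
#'
#' End-to-end data generation for one (breed, heritability, marker density)
#' scenario: genome map, historical population (drift + recurrent mutation
#' through the bottleneck/expansion), trait architecture scaled in the last
#' historical generation, 10 recent generations under selection, and
#' PLINK-style quality control of the genotyped generations.
#'
#' @param breed `"A"`, `"B"` or `"C"`.
#' @param h2 Heritability of the simulated trait.
#' @param density Panel tag (`"50k"` or `"770k"`).
#' @param scale Scale factor in (0, 1] applied to population sizes, founder
#'   counts and historical generation counts.
#' @param panel_scale Scale factor for the marker-panel sizes (default
#'   `scale`).  Marker density can be kept closer to full scale than the
#'   populations: tagging of local LD collapses if the panel is thinned as
#'   aggressively as the population is shrunk.
#' @param seed Integer seed for the whole dataset.
#' @param selection_criterion `"phenotype"` (fast) or `"ebv"`.
#' @param genome Optional [genome_spec()] override.
#' @param qc [qc_thresholds()].
#' @param mutation_rate Historical per-locus per-gamete mutation rate.
#' @return List of class `breed_dataset`: `map`, `pedigree`, `genotypes`
#'   (post-QC [genotype_matrix()]), `qc_report`, `phenotypes` (generations
#'   9-10 with `tbv`), `marker_chr` (chromosome per retained marker),
#'   `arch`, plus the scenario descriptors.
#' @export
simulate_breed_dataset <- function(breed = "A", h2 = 0.5, density = "50k",
                                   scale = 1, seed = 1L,
                                   selection_criterion = c("phenotype", "ebv"),
                                   genome = NULL, qc = qc_thresholds(),
                                   mutation_rate = 2.5e-5,
                                   panel_scale = scale) {
  selection_criterion <- match.arg(selection_criterion)
  sub_seed <- function(k) as.integer((as.numeric(seed) * 113 + k) %% 2147483647)
  if (is.null(genome)) {
    panels <- c("50k" = 58990, "770k" = 777962)
    genome <- genome_spec(panel_sizes = stats::setNames(
      pmax(29L, round_half_up(panels * panel_scale)), names(panels)))
  }
  map <- build_genome_map(genome, density, seed = sub_seed(1L))
  plan <- cattle_historical_plans(scale)[[breed]]
  hist <- simulate_historical(map, plan, mutation_rate = mutation_rate,
                              seed = sub_seed(2L))
  qfreq <- allele_freqs(hist, qtl_loci(map))
  arch <- sample_qtl_effects(map, qfreq, h2 = h2, seed = sub_seed(3L))
  cfg <- cattle_breed_configs(scale, selection_criterion)[[breed]]
  br <- run_breed(hist, cfg, arch, seed = sub_seed(4L))
  qcres <- apply_qc(br$genotypes, qc)
  marker_chr <- map$chr[match(qcres$genotypes$locus_ids, map$id)]
  structure(list(map = map, pedigree = br$pedigree,
                 genotypes = qcres$genotypes, qc_report = qcres$report,
                 phenotypes = br$phenotypes, marker_chr = marker_chr,
                 arch = arch, breed = breed, h2 = h2, density = density,
                 scale = scale, panel_scale = panel_scale, seed = seed),
            class = "breed_dataset")
}

#' @export
print.breed_dataset <- function(x, ...) {
  cat(sprintf(
    "breed_dataset: breed %s, h2 %.2f, density %s, scale %g\n  %d genotyped animals x %d QC-passing markers; pedigree of %d\n",
    x$breed, x$h2, x$density, x$scale, nrow(x$genotypes$dosage),
    ncol(x$genotypes$dosage), nrow(x$pedigree)))
  invisible(x)
}

#' Run one prediction scenario
#'
#' Splits the dataset's genotyped candidates into reference and validation
#' sets, fits the requested method with the reference phenotypes only
#' (validation phenotypes are masked at the split and never enter any
#' training computation), and returns the validation-set accuracy
#' (correlation of TBV with the predicted breeding values).
#'
#' @param dataset A [simulate_breed_dataset()] result.
#' @param method `"PBLUP"`, `"GBLUP"` or `"wGBLUP"`.
#' @param rp_size Reference-population size.
#' @param n_validation Validation-set size (drawn from the last generation).
#' @param seed Split seed (keep constant across methods to pair contrasts).
#' @param S wGBLUP window half-width.
#' @param blend GRM stabilization weight for GBLUP (see [stabilize_grm()]).
#' @return One-row data.frame (`breed`, `h2`, `density`, `rp_size`,
#'   `method`, `seed`, `accuracy`, `n_reference`, `n_validation`,
#'   `converged`).
#' @export
run_scenario <- function(dataset, method = c("PBLUP", "GBLUP", "wGBLUP"),
                         rp_size, n_validation, seed = 1L, S = 10L,
                         blend = 0.99) {
  method <- match.arg(method)
  ph <- dataset$phenotypes
  split <- split_reference_validation(ph, rp_size, n_validation, seed = seed)
  ref <- split$reference
  val <- split$validation
  y <- ph$phenotype[match(ref, ph$id)]
  lambda <- (1 - dataset$h2) / dataset$h2
  converged <- TRUE
  if (method == "PBLUP") {
    fit <- solve_pblup(y, animal = ref, pedigree = dataset$pedigree,
                       lambda = lambda)
    ebv <- fit$u[as.character(val)]
    converged <- fit$diagnostics$converged
  } else if (method == "GBLUP") {
    G <- stabilize_grm(grm(dataset$genotypes), blend = blend)
    fit <- solve_gblup(y, animal = ref, G = G, lambda = lambda)
    ebv <- fit$u[as.character(val)]
    converged <- fit$diagnostics$converged
  } else {
    fit <- wgblup_predict(y, animal = ref, genotypes = dataset$genotypes,
                          lambda = lambda,
                          cfg = window_weight_config(S = S),
                          chr = dataset$marker_chr)
    ebv <- fit$gebv[as.character(val)]
  }
  tbv <- ph$tbv[match(val, ph$id)]
  data.frame(breed = dataset$breed, h2 = dataset$h2,
             density = dataset$density, rp_size = rp_size,
             method = method, seed = seed,
             accuracy = accuracy(tbv, ebv),
             n_reference = length(ref), n_validation = length(val),
             converged = converged, stringsAsFactors = FALSE)
}

#' Run a factorial scenario grid
#'
#' Full factorial over breeds, heritabilities, densities, reference sizes
#' and methods, with `replicates` independent simulated datasets per
#' (breed, h2, density) cell.  Within a replicate the split seed is shared
#' across methods and reference sizes, so method contrasts are paired and
#' reference sets are nested.  When `results_path` is given, completed rows
#' found there are skipped and the file is extended (resumable).
#'
#' @param breeds,h2s,densities,rp_sizes,methods Grid axes.
#' @param replicates Replicates per cell (the study convention is 4).
#' @param panel_scale Marker-panel scale factor (default `scale`); see
#'   [simulate_breed_dataset()].
#' @param n_validation Validation animals per replicate.
#' @param scale Scale factor for [simulate_breed_dataset()].
#' @param seed Base seed; replicate r of a cell uses a seed derived from
#'   (seed, breed, h2, density, r).
#' @param selection_criterion,S,blend Passed through.
#' @param results_path Optional CSV for incremental/resumable results.
#' @return data.frame of [run_scenario()] rows plus `replicate`.
#' @export
run_grid <- function(breeds = "A", h2s = c(0.3, 0.5, 0.7),
                     densities = "50k", rp_sizes, methods = c("PBLUP", "GBLUP", "wGBLUP"),
                     replicates = 4L, n_validation, scale = 1,
                     seed = 1L, selection_criterion = "phenotype",
                     S = 10L, blend = 0.99, results_path = NULL,
                     panel_scale = scale) {
  done <- NULL
  if (!is.null(results_path) && file.exists(results_path))
    done <- utils::read.csv(results_path, stringsAsFactors = FALSE)
  rows <- list()
  cell_id <- 0L
  for (breed in breeds) for (density in densities) {
    cell_id <- cell_id + 1L
    for (r in seq_len(replicates)) {
      # one seed per (breed, density, replicate): heritability levels share
      # the genome, historical population, founder draw and raw QTL effects,
      # so h2 contrasts are paired like method contrasts
      ds_seed <- as.integer((as.numeric(seed) * 1009 + cell_id * 131 + r) %% 2147483647)
      for (h2 in h2s) {
      ds <- NULL
      for (rp in rp_sizes) for (method in methods) {
        if (!is.null(done) &&
            any(done$breed == breed & done$h2 == h2 & done$density == density &
                done$rp_size == rp & done$method == method & done$replicate == r)) next
        if (is.null(ds))
          ds <- simulate_breed_dataset(breed, h2, density, scale = scale,
                                       seed = ds_seed,
                                       selection_criterion = selection_criterion,
                                       panel_scale = panel_scale)
        row <- tryCatch(
          run_scenario(ds, method, rp_size = rp, n_validation = n_validation,
                       seed = ds_seed, S = S, blend = blend),
          error = function(e) {
            warning(sprintf("cell (%s, %.1f, %s, %d, %s, rep %d) failed: %s",
                            breed, h2, density, rp, method, r,
                            conditionMessage(e)))
            NULL
          })
        if (is.null(row)) next
        row$replicate <- r
        rows[[length(rows) + 1L]] <- row
        if (!is.null(results_path)) {
          utils::write.table(row, results_path, sep = ",",
                             append = file.exists(results_path),
                             col.names = !file.exists(results_path),
                             row.names = FALSE, qmethod = "double")
        }
      }
      }
    }
  }
  new <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(done) && nrow(done)) {
    if (is.null(new)) return(done)
    return(rbind(done[, names(new), drop = FALSE], new))
  }
  if (is.null(new))
    new <- data.frame(breed = character(0), h2 = numeric(0),
                      density = character(0), rp_size = numeric(0),
                      method = character(0), seed = integer(0),
                      accuracy = numeric(0), n_reference = integer(0),
                      n_validation = integer(0), converged = logical(0),
                      replicate = integer(0))
  new
}

#' Per-cell replicate means and standard errors
#'
#' @param results A [run_grid()] result.
#' @return data.frame with one row per (breed, h2, density, rp_size, method)
#'   cell: `mean_accuracy`, `se`, `n_replicates`.
#' @export
summarize_grid <- function(results) {
  key <- interaction(results$breed, results$h2, results$density,
                     results$rp_size, results$method, drop = TRUE)
  agg <- lapply(split(results, key), function(d) {
    data.frame(breed = d$breed[1], h2 = d$h2[1], density = d$density[1],
               rp_size = d$rp_size[1], method = d$method[1],
               mean_accuracy = mean(d$accuracy),
               se = stats::sd(d$accuracy) / sqrt(nrow(d)),
               n_replicates = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$breed, out$h2, out$density, out$rp_size, out$method), ]
}

lookup_cell <- function(table, rp_size, h2, method, density, breed = NULL) {
  sel <- table$rp_size == rp_size & table$h2 == h2 &
    table$method == method & table$density == density
  if (!is.null(breed) && "breed" %in% names(table))
    sel <- sel & table$breed == breed
  acc_col <- if ("accuracy" %in% names(table)) "accuracy" else "mean_accuracy"
  v <- table[[acc_col]][sel]
  if (length(v) != 1L)
    stop("lookup error: ", length(v), " cells match (breed=",
         if (is.null(breed)) "*" else breed, ", rp=", rp_size, ", h2=", h2,
         ", ", method, ", ", density, ")")
  v
}

#' Density gain in percentage points
#'
#' `(accuracy at the high density - accuracy at the low density) * 100`,
#' the study's convention for quoting density improvements.
#'
#' @param table Results table with columns `rp_size`, `h2`, `method`,
#'   `density` and `accuracy` (or `mean_accuracy`), e.g. a fixture from
#'   [published_example_cells()] or a [run_grid()] summary.
#' @param rp_size,h2,method Cell selector.
#' @param breed Breed selector when the table carries one.
#' @param densities Low and high density tags, default `c("50k", "770k")`.
#' @return Percentage-point difference (a single number).
#' @export
density_gain <- function(table, rp_size, h2, method, breed = NULL,
                         densities = c("50k", "770k")) {
  lo <- lookup_cell(table, rp_size, h2, method, densities[1], breed)
  hi <- lookup_cell(table, rp_size, h2, method, densities[2], breed)
  (hi - lo) * 100
}

#' Method contrast in percentage points
#'
#' `(accuracy of method 1 - accuracy of method 2) * 100` in one cell.
#'
#' @inheritParams density_gain
#' @param methods The two methods, contrast = first minus second.
#' @param density Density of the cell.
#' @export
method_gain <- function(table, rp_size, h2, density,
                        methods = c("GBLUP", "PBLUP"), breed = NULL) {
  a1 <- lookup_cell(table, rp_size, h2, methods[1], density, breed)
  a2 <- lookup_cell(table, rp_size, h2, methods[2], density, breed)
  (a1 - a2) * 100
}

#' Published accuracy grid for breed A
#'
#' The full-precision accuracy table for breed A (population size x
#' heritability x method x marker density), packaged verbatim as data for
#' the summary operations.
#'
#' @return data.frame with columns `breed`, `rp_size`, `h2`, `method`,
#'   `density`, `accuracy`.
#' @export
published_accuracy_grid <- function() {
  path <- system.file("extdata", "table2_breed_a.csv", package = "gblupsim",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published example accuracy cells for all three breeds
#'
#' The rounded accuracy pairs quoted in the study's results narrative for
#' selected (breed, reference size, heritability, method) cells at both
#' marker densities; the inputs to the quoted density-gain percentages.
#'
#' @return data.frame with columns `breed`, `rp_size`, `h2`, `method`,
#'   `density`, `accuracy`.
#' @export
published_example_cells <- function() {
  path <- system.file("extdata", "printed_example_cells.csv",
                      package = "gblupsim", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Accuracy-versus-reference-size plot
#'
#' Line plot of per-cell mean accuracy against reference-population size,
#' one panel per heritability, coloured by density, line type by method.
#' Requires ggplot2.
#'
#' @param summary A [summarize_grid()] result.
#' @return A ggplot object.
#' @export
plot_accuracy_grid <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = rp_size, y = mean_accuracy,
                               colour = density, linetype = method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(breed ~ h2) +
    ggplot2::labs(x = "reference population size", y = "accuracy")
}

#' Read a study configuration from YAML
#'
#' The configuration tree mirrors [run_grid()]'s arguments (`breeds`,
#' `h2s`, `densities`, `rp_sizes`, `methods`, `replicates`,
#' `n_validation`, `scale`, `seed`, ...); unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return Named list suitable for `do.call(run_grid, ...)`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(run_grid)), "results_path")
  bad <- setdiff(names(cfg), c(allowed, "results_path"))
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  cfg
}
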