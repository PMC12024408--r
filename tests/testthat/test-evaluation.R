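test_that("accuracy is the Pearson correlation with guarded inputs", {
  expect_equal(accuracy(1:5, 1:5), 1)
  expect_equal(accuracy(1:5, -(1:5)), -1)
  expect_equal(accuracy(c(1, 2, 3, 4), c(1, 2, 3, 5)), 0.9827076,
               tolerance = 1e-6)
  expect_error(accuracy(1:4, rep(1, 4)), "zero variance")
  expect_error(accuracy(1:2, 1:2), "at least 3")
})

candidate_table <- function(n9 = 60L, n10 = 80L) {
  data.frame(id = seq_len(n9 + n10),
             generation = rep(c(9L, 10L), c(n9, n10)))
}

test_that("splits are deterministic, disjoint and nested across sizes", {
  cand <- candidate_table()
  s1 <- split_reference_validation(cand, 50, 20, seed = 3)
  s2 <- split_reference_validation(cand, 50, 20, seed = 3)
  expect_identical(s1, s2)
  expect_length(intersect(s1$reference, s1$validation), 0L)
  expect_true(all(cand$generation[match(s1$validation, cand$id)] == 10L))
  # nested under a common seed
  s_small <- split_reference_validation(cand, 40, 20, seed = 3)
  expect_true(all(s_small$reference %in% s1$reference))
  # taking everything leaves the exact complement
  s_all <- split_reference_validation(cand, 120, 20, seed = 3)
  expect_setequal(s_all$reference, setdiff(cand$id, s_all$validation))
  expect_error(split_reference_validation(cand, 130, 20, seed = 3),
               "sizing error")
})

test_that("density and method gains reproduce the published percentages", {
  cells <- published_example_cells()
  expect_equal(density_gain(cells, 8000, 0.5, "PBLUP", breed = "A"), 4.29,
               tolerance = 1e-9)
  expect_equal(density_gain(cells, 12000, 0.7, "PBLUP", breed = "B"), 8.25,
               tolerance = 1e-9)
  expect_equal(density_gain(cells, 15000, 0.3, "PBLUP", breed = "C"), 4.25,
               tolerance = 1e-9)
  expect_equal(density_gain(cells, 8000, 0.5, "wGBLUP", breed = "A"), 4.41,
               tolerance = 1e-9)
  expect_equal(round(density_gain(cells, 8000, 0.5, "GBLUP", breed = "A"), 2),
               -0.10)
  expect_error(density_gain(cells, 9999, 0.5, "PBLUP", breed = "A"),
               "lookup error")
  t2 <- published_accuracy_grid()
  expect_equal(nrow(t2), 72L)
  # full-precision grid: the same cell computed from the verbatim table
  expect_equal(density_gain(t2, 8000, 0.5, "PBLUP", breed = "A"),
               (0.6338298 - 0.590504) * 100, tolerance = 1e-9)
  expect_equal(method_gain(t2, 15000, 0.7, "50k", breed = "A"),
               (0.7941701 - 0.6052722) * 100, tolerance = 1e-9)
})

test_that("equal accuracies give a zero gain", {
  tab <- data.frame(breed = "X", rp_size = 1, h2 = 0.5,
                    method = "PBLUP", density = c("50k", "770k"),
                    accuracy = c(0.6, 0.6))
  expect_equal(density_gain(tab, 1, 0.5, "PBLUP"), 0)
})

small_dataset <- function(h2 = 0.5, seed = 1L) {
  gen <- genome_spec(n_chromosomes = 3L, chr_lengths = rep(100, 3),
                     panel_sizes = c("50k" = 90L, "770k" = 240L),
                     n_qtl_per_chr = 8L)
  simulate_breed_dataset(breed = "A", h2 = h2, density = "50k",
                         scale = 0.01, seed = seed, genome = gen)
}

test_that("a simulated dataset is internally consistent", {
  ds <- small_dataset()
  expect_s3_class(ds$genotypes, "genotype_matrix")
  expect_false(anyNA(ds$genotypes$dosage))
  expect_setequal(as.character(ds$phenotypes$id), ds$genotypes$animal_ids)
  expect_true(all(ds$marker_chr %in% 1:3))
  # missingness filters are no-ops on simulated data
  rep <- ds$qc_report
  expect_equal(rep$removed[rep$filter %in% c("animal_missing", "locus_missing")],
               c(0L, 0L))
})

test_that("run_scenario masks validation phenotypes and tags results", {
  ds <- small_dataset()
  row <- run_scenario(ds, "GBLUP", rp_size = 60, n_validation = 20, seed = 5)
  expect_equal(row$n_reference, 60L)
  expect_equal(row$n_validation, 20L)
  expect_true(abs(row$accuracy) <= 1)
  # data-flow taint check: corrupting the masked validation phenotypes
  # changes nothing in any method's predictions
  s <- split_reference_validation(ds$phenotypes, 60, 20, seed = 5)
  ds2 <- ds
  ds2$phenotypes$phenotype[match(s$validation, ds2$phenotypes$id)] <- 999
  for (m in c("PBLUP", "GBLUP", "wGBLUP")) {
    a1 <- run_scenario(ds, m, rp_size = 60, n_validation = 20, seed = 5)$accuracy
    a2 <- run_scenario(ds2, m, rp_size = 60, n_validation = 20, seed = 5)$accuracy
    expect_identical(a1, a2)
  }
})

test_that("the noiseless limit with QTL on the panel approaches accuracy 1", {
  sim <- sparse_trait_sim(n = 180L, m = 50L, n_qtl = 50L, h2 = 0.999,
                          seed = 77)
  y <- sim$tbv[1:150]                       # sigma_e^2 = 0: phenotype = TBV
  tr <- sim$g$animal_ids[1:150]
  val <- sim$g$animal_ids[151:180]
  fw <- wgblup_predict(y, tr, sim$g, lambda = 1e-8, freqs = sim$p,
                       cfg = window_weight_config(n_passes = 1L))
  expect_gt(accuracy(sim$tbv[151:180], fw$gebv[val]), 0.999)
})

test_that("run_grid is factorial, resumable and summarizable", {
  path <- file.path(withr::local_tempdir(), "grid.csv")
  res <- run_grid(breeds = "A", h2s = c(0.3, 0.7), densities = "50k",
                  rp_sizes = c(40, 60), methods = c("PBLUP", "GBLUP"),
                  replicates = 2L, n_validation = 20L, scale = 0.01,
                  seed = 9L, results_path = path)
  expect_equal(nrow(res), 2 * 2 * 2 * 2)
  expect_true(file.exists(path))
  # resuming re-reads completed rows and adds nothing
  res2 <- run_grid(breeds = "A", h2s = c(0.3, 0.7), densities = "50k",
                   rp_sizes = c(40, 60), methods = c("PBLUP", "GBLUP"),
                   replicates = 2L, n_validation = 20L, scale = 0.01,
                   seed = 9L, results_path = path)
  expect_equal(nrow(res2), nrow(res))
  expect_equal(sort(res2$accuracy), sort(res$accuracy), tolerance = 1e-12)
  summ <- summarize_grid(res)
  expect_equal(nrow(summ), 8L)
  expect_equal(unique(summ$n_replicates), 2L)
})

test_that("YAML study configurations round-trip into run_grid arguments", {
  path <- file.path(withr::local_tempdir(), "study.yaml")
  writeLines(c("breeds: [A]", "h2s: [0.3, 0.5]", "densities: [50k]",
               "rp_sizes: [40, 60]", "replicates: 2",
               "n_validation: 20", "scale: 0.01", "seed: 3"), path)
  cfg <- read_study_config(path)
  expect_equal(cfg$h2s, c(0.3, 0.5))
  writeLines("bogus_key: 1", path)
  expect_error(read_study_config(path), "unknown configuration keys")
})
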