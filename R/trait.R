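#' Sample QTL effects and scale them to a target heritability
#'
#' Absolute effects are drawn from a gamma distribution (shape 0.4 by
#' default), signs are assigned + or - with probability 1/2 each, and the
#' whole vector is rescaled by one common constant so that the additive
#' variance expected in the scaling population,
#' `sum_j 2 p_j (1 - p_j) beta_j^2`, equals `h2` times the phenotypic
#' variance of 1.0.
#'
#' @param map A `marker_map` (its QTL rows define the effect vector length),
#'   or an integer number of QTL.
#' @param founder_freqs Allele frequencies of the QTL in the scaling (base)
#'   population, one per QTL.
#' @param h2 Target heritability in `[0, 1)`.
#' @param shape Gamma shape parameter for the raw effect magnitudes.
#' @param seed Integer seed.
#' @param signs `"random"` (default) or `"positive"`.
#' @return A `trait_architecture`: list with `beta`, `h2`, `sigma_a2`,
#'   `sigma_e2`, `mu`, `qtl_freqs`.
#' @examples
#' arch <- sample_qtl_effects(10L, rep(0.5, 10), h2 = 0.5, seed = 1)
#' sum(2 * arch$qtl_freqs * (1 - arch$qtl_freqs) * arch$beta^2)  # 0.5
#' @export
sample_qtl_effects <- function(map, founder_freqs, h2, shape = 0.4,
                               seed = 1L, signs = c("random", "positive")) {
  signs <- match.arg(signs)
  n_qtl <- if (inherits(map, "marker_map")) sum(map$kind == "qtl")
           else as.integer(map)
  if (shape <= 0) stop("gamma shape must be > 0")
  if (h2 < 0 || h2 >= 1) stop("h2 must be in [0, 1)")
  if (length(founder_freqs) != n_qtl)
    stop("founder_freqs must have one entry per QTL (", n_qtl, ")")
  set.seed(as.integer(seed))
  raw <- stats::rgamma(n_qtl, shape = shape, rate = 1)
  if (signs == "random")
    raw <- raw * sample(c(-1, 1), n_qtl, replace = TRUE)
  het <- 2 * founder_freqs * (1 - founder_freqs)
  denom <- sum(het * raw^2)
  if (h2 == 0) {
    beta <- rep(0, n_qtl)
  } else {
    if (denom <= 0)
      stop("architecture error: all QTL monomorphic in the scaling population; ",
           "cannot scale effects to the target heritability")
    beta <- raw * sqrt(h2 / denom)
  }
  structure(list(beta = beta, h2 = h2, sigma_a2 = h2, sigma_e2 = 1 - h2,
                 mu = 0, qtl_freqs = founder_freqs, shape = shape),
            class = "trait_architecture")
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf("trait_architecture: %d QTL, h2 = %.3g (sigma_a2 = %.3g, sigma_e2 = %.3g)\n",
              length(x$beta), x$h2, x$sigma_a2, x$sigma_e2))
  invisible(x)
}

#' True breeding values from QTL dosages
#'
#' `TBV_k = sum_j beta_j * Q_kj` with dosages coded 0/1/2.
#'
#' @param genotypes Animals x QTL dosage matrix (entries 0, 1 or 2).
#' @param arch A `trait_architecture`.
#' @return Numeric vector of TBVs, one per animal.
#' @export
compute_tbv <- function(genotypes, arch) {
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != length(arch$beta))
    stop("validation error: dosage columns (", ncol(genotypes),
         ") do not match the number of QTL effects (", length(arch$beta), ")")
  drop(genotypes %*% arch$beta)
}

#' Per-QTL variance contributions
#'
#' Reports `2 p (1 - p) beta^2` per QTL at the supplied allele frequencies and
#' flags loci whose contribution exceeds `cap` (the simulated trait is
#' polygenic: no single QTL should dominate).
#'
#' @param arch A `trait_architecture`.
#' @param freqs QTL allele frequencies in the population of interest
#'   (default: the architecture's scaling frequencies).
#' @param cap Flag threshold for a single QTL's variance contribution.
#' @return data.frame with columns `qtl`, `freq`, `beta`, `variance`,
#'   `exceeds_cap`.
#' @export
qtl_variance_report <- function(arch, freqs = arch$qtl_freqs, cap = 0.02) {
  v <- 2 * freqs * (1 - freqs) * arch$beta^2
  data.frame(qtl = seq_along(arch$beta), freq = freqs, beta = arch$beta,
             variance = v, exceeds_cap = v > cap)
}

#' Simulate phenotypes from true breeding values
#'
#' `y = mu + TBV + e` with `e ~ N(0, sigma_e2)` i.i.d.; the overall mean `mu`
#' is the only fixed effect.
#'
#' @param tbv Numeric vector of true breeding values.
#' @param arch A `trait_architecture` (supplies `mu` and `sigma_e2`).
#' @param seed Integer seed; same seed gives bit-identical phenotypes.
#' @param info Optional data.frame with one row per animal (e.g. id, sex,
#'   generation) copied into the output.
#' @return A `phenotype_table`: data.frame with columns from `info` (or `id`)
#'   plus `tbv` and `phenotype`.
#' @export
simulate_phenotypes <- function(tbv, arch, seed = 1L, info = NULL) {
  force(tbv); force(info)
  if (arch$sigma_e2 < 0) stop("validation error: sigma_e2 must be >= 0")
  set.seed(as.integer(seed))
  e <- stats::rnorm(length(tbv), 0, sqrt(arch$sigma_e2))
  out <- if (is.null(info)) data.frame(id = seq_along(tbv)) else as.data.frame(info)
  if (nrow(out) != length(tbv))
    stop("info must have one row per animal")
  out$tbv <- tbv
  out$phenotype <- arch$mu + tbv + e
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Simulate a base (unselected, equilibrium) cohort
#'
#' Draws QTL dosages for `n` unrelated animals at the supplied base allele
#' frequencies (Hardy-Weinberg binomial sampling), samples a trait
#' architecture scaled to `h2` at those frequencies, and simulates
#' phenotypes with residual variance `1 - h2`.  The direct route to a large
#' cohort for variance checks, without the forward simulation machinery.
#'
#' @param n Number of animals.
#' @param h2 Heritability.
#' @param n_qtl Number of QTL (725 in the cattle genome).
#' @param freqs QTL allele frequencies (default all 0.5).
#' @param shape Gamma shape for effect magnitudes.
#' @param seed Integer seed.
#' @return A `phenotype_table` with the `trait_architecture` attached as
#'   attribute `arch`.
#' @export
simulate_base_cohort <- function(n, h2, n_qtl = 725L, freqs = NULL,
                                 shape = 0.4, seed = 1L) {
  if (is.null(freqs)) freqs <- rep(0.5, n_qtl)
  arch <- sample_qtl_effects(as.integer(n_qtl), freqs, h2 = h2,
                             shape = shape, seed = seed)
  set.seed(as.integer(seed) + 1L)
  q <- matrix(stats::rbinom(n * n_qtl, 2L, rep(freqs, each = n)), nrow = n)
  tbv <- compute_tbv(q, arch)
  out <- simulate_phenotypes(tbv, arch, seed = as.integer(seed) + 2L)
  attr(out, "arch") <- arch
  out
}

#' Export a phenotype table as a whitespace/CSV file
#'
#' @param pt A `phenotype_table`.
#' @param path Output file path.
#' @param include_tbv Keep the `tbv` column (never feed it to estimators).
#' @param sep Field separator (default whitespace).
#' @export
write_phenotypes <- function(pt, path, include_tbv = FALSE, sep = " ") {
  df <- as.data.frame(pt)
  if (!include_tbv) df$tbv <- NULL
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
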