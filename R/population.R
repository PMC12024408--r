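#' @importFrom stats rpois runif rbinom setNames var cor sd rnorm rgamma
NULL

# Per-chromosome locus bookkeeping used by the meiosis code.
chromosome_index <- function(map) {
  chrs <- sort(unique(map$chr))
  spec <- attr(map, "spec")
  list(
    chr = chrs,
    idx = lapply(chrs, function(ch) which(map$chr == ch)),
    pos = lapply(chrs, function(ch) map$pos_cm[map$chr == ch]),
    len = vapply(chrs, function(ch) {
      if (!is.null(spec)) spec$chr_lengths[[ch]] else max(map$pos_cm[map$chr == ch])
    }, numeric(1)))
}

#' Create a founder population
#'
#' Founders carry phased haplotypes with every allele drawn independently as
#' Bernoulli(0.5) ("equal" starting allele frequencies), the null parent ID 0,
#' and an exactly balanced sex ratio.
#'
#' @param map A `marker_map`.
#' @param n Number of founder animals (>= 2).
#' @param seed Integer seed.
#' @param generation Generation label for the founders.
#' @return A `population_state`: list with `ped` (id, sire, dam, sex,
#'   generation), `haps` (integer matrix, two rows per animal in `ped` order),
#'   `map`, and `generation`.
#' @export
new_founder_population <- function(map, n, seed = 1L, generation = 0L) {
  n <- as.integer(n)
  if (n < 2L) stop("simulation error: population size must be >= 2")
  set.seed(as.integer(seed))
  L <- nrow(map)
  haps <- matrix(sample(c(0L, 1L), 2L * n * L, replace = TRUE), nrow = 2L * n)
  ped <- data.frame(id = seq_len(n), sire = 0L, dam = 0L,
                    sex = sample(rep(1:2, length.out = n)),
                    generation = as.integer(generation))
  structure(list(ped = ped, haps = haps, map = map,
                 generation = as.integer(generation)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("population_state: %d animals at generation %d, %d loci\n",
              nrow(x$ped), x$generation, ncol(x$haps)))
  invisible(x)
}

# Form gametes by meiosis.  haps: haplotype matrix; hap_a/hap_b: row indices of
# the two parental haplotypes for each gamete.  Crossover count per chromosome
# is Poisson(length/100) (Haldane, no interference), crossover positions
# uniform; the starting haplotype of each chromosome is chosen at random.
make_gametes <- function(haps, hap_a, hap_b, chrinfo) {
  n_g <- length(hap_a)
  out <- matrix(0L, n_g, ncol(haps))
  nchr <- length(chrinfo$idx)
  for (ch in seq_len(nchr)) {
    idx <- chrinfo$idx[[ch]]
    pos <- chrinfo$pos[[ch]]
    len <- chrinfo$len[ch]
    k <- stats::rpois(n_g, len / 100)
    s <- sample(c(0L, 1L), n_g, replace = TRUE)
    # no-crossover gametes copy a whole parental chromosome (vectorized)
    plain <- which(k == 0L)
    if (length(plain)) {
      src <- ifelse(s[plain] == 0L, hap_a[plain], hap_b[plain])
      out[plain, idx] <- haps[src, idx]
    }
    for (g in which(k > 0L)) {
      xo <- sort(stats::runif(k[g], 0, len))
      use_b <- (s[g] + findInterval(pos, xo)) %% 2L == 1L
      v <- haps[hap_a[g], idx]
      if (any(use_b)) v[use_b] <- haps[hap_b[g], idx][use_b]
      out[g, idx] <- v
    }
  }
  out
}

# Recurrent allele-flip mutation: each allele copy flips 0<->1 with the given
# per-locus per-gamete probability (no new allelic states).
apply_recurrent_mutation <- function(gametes, rate) {
  if (rate <= 0) return(gametes)
  n <- length(gametes)
  n_mut <- stats::rbinom(1L, n, rate)
  if (n_mut > 0L) {
    at <- sample.int(n, n_mut)
    gametes[at] <- 1L - gametes[at]
  }
  gametes
}

#' Historical phase plan
#'
#' Population-size trajectory as (generation, size) breakpoints with linear
#' interpolation of size between breakpoints (so a bottleneck at an
#' intermediate breakpoint produces a gradual contraction and re-expansion).
#'
#' @param generations Strictly increasing integer breakpoints starting at 0.
#' @param sizes Population size at each breakpoint (all >= 2).
#' @return An object of class `historical_plan` with per-generation sizes.
#' @examples
#' plan <- historical_plan(c(0, 500, 1000), c(10000, 1000, 7120))
#' @export
historical_plan <- function(generations, sizes) {
  generations <- as.integer(generations)
  if (length(generations) != length(sizes) || length(generations) < 1L)
    stop("generations and sizes must have equal positive length")
  if (generations[1] != 0L || any(diff(generations) <= 0L))
    stop("generation breakpoints must be strictly increasing and start at 0")
  if (any(sizes < 2))
    stop("simulation error: plan sizes must be >= 2")
  gens <- 0:max(generations)
  per_gen <- as.integer(round(stats::approx(generations, sizes, xout = gens)$y))
  structure(list(breakpoints = data.frame(generation = generations,
                                          size = as.integer(sizes)),
                 size_by_generation = per_gen),
            class = "historical_plan")
}

#' @export
print.historical_plan <- function(x, ...) {
  b <- x$breakpoints
  cat("historical_plan:",
      paste(sprintf("%d(%d)", b$generation, b$size), collapse = " -> "), "\n")
  invisible(x)
}

#' Evolve a historical population under drift and recurrent mutation
#'
#' Starting from founders with all allele frequencies at 0.5, each generation
#' is formed by random union of gametes (random mating, discrete generations,
#' exactly balanced sex ratio, no selection, no migration).  Gametes are
#' formed by Poisson-crossover recombination and allele-flip mutation at
#' `mutation_rate` per locus per gamete.  Returns the final generation.
#'
#' @param map A `marker_map`.
#' @param plan A [historical_plan()].
#' @param mutation_rate Per-locus per-gamete flip probability in `[0, 1)`.
#' @param seed Integer seed; identical inputs give bit-identical output.
#' @return A `population_state` for the final generation (ancestors are not
#'   retained; final-generation animals carry the null parent ID).
#' @export
simulate_historical <- function(map, plan, mutation_rate = 2.5e-5, seed = 1L) {
  stopifnot(inherits(plan, "historical_plan"))
  if (!is.finite(mutation_rate) || mutation_rate < 0 || mutation_rate >= 1)
    stop("validation error: mutation_rate must be in [0, 1)")
  sizes <- plan$size_by_generation
  pop <- new_founder_population(map, sizes[1], seed = seed, generation = 0L)
  chrinfo <- chromosome_index(map)
  n_gen <- length(sizes) - 1L
  if (n_gen < 1L) return(pop)
  for (t in seq_len(n_gen)) {
    n_next <- sizes[t + 1L]
    males <- which(pop$ped$sex == 1L)
    females <- which(pop$ped$sex == 2L)
    sire <- males[sample.int(length(males), n_next, replace = TRUE)]
    dam <- females[sample.int(length(females), n_next, replace = TRUE)]
    pat <- make_gametes(pop$haps, 2L * sire - 1L, 2L * sire, chrinfo)
    mat <- make_gametes(pop$haps, 2L * dam - 1L, 2L * dam, chrinfo)
    pat <- apply_recurrent_mutation(pat, mutation_rate)
    mat <- apply_recurrent_mutation(mat, mutation_rate)
    haps <- matrix(0L, 2L * n_next, ncol(pop$haps))
    haps[seq(1L, 2L * n_next, by = 2L), ] <- pat
    haps[seq(2L, 2L * n_next, by = 2L), ] <- mat
    pop$haps <- haps
    pop$ped <- data.frame(id = seq_len(n_next), sire = 0L, dam = 0L,
                          sex = sample(rep(1:2, length.out = n_next)),
                          generation = t)
    pop$generation <- t
  }
  pop
}

#' Additive genotype dosages of a population
#'
#' @param pop A `population_state`.
#' @param loci Optional integer vector of locus indices (default all).
#' @return Integer matrix animals x loci of allele-1 counts (0/1/2).
#' @export
dosages <- function(pop, loci = NULL) {
  n <- nrow(pop$ped)
  odd <- seq(1L, 2L * n, by = 2L)
  h1 <- pop$haps[odd, , drop = FALSE]
  h2 <- pop$haps[odd + 1L, , drop = FALSE]
  d <- h1 + h2
  if (!is.null(loci)) d <- d[, loci, drop = FALSE]
  rownames(d) <- pop$ped$id
  d
}

#' Allele frequencies of a population
#'
#' @inheritParams dosages
#' @return Numeric vector of allele-1 frequencies per locus.
#' @export
allele_freqs <- function(pop, loci = NULL) {
  h <- pop$haps
  if (!is.null(loci)) h <- h[, loci, drop = FALSE]
  colMeans(h)
}

#' Mean expected heterozygosity
#'
#' Mean over loci of `2p(1-p)` from the phased haplotypes; the drift statistic
#' that decays as `(1 - 1/(2N))^t` in an ideal population.
#'
#' @inheritParams dosages
#' @return A single number.
#' @export
expected_heterozygosity <- function(pop, loci = NULL) {
  p <- allele_freqs(pop, loci)
  mean(2 * p * (1 - p))
}

# r^2 between two loci from phased haplotype frequencies.
r2_from_haplotypes <- function(ha, hb) {
  pa <- mean(ha); pb <- mean(hb)
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) return(NA_real_)
  D <- mean(ha == 1L & hb == 1L) - pa * pb
  D * D / (pa * (1 - pa) * pb * (1 - pb))
}

#' Linkage-disequilibrium summary
#'
#' Computes `r^2` from phased haplotype frequencies for all within-chromosome
#' marker pairs closer than `max_dist` cM and bins by pairwise distance.
#' Monomorphic loci are excluded.
#'
#' @param pop A `population_state`.
#' @param map The `marker_map` the population was simulated on.
#' @param max_dist Maximum pairwise distance (cM) to include.
#' @param n_bins Number of equal-width distance bins.
#' @param loci Locus indices to consider (default: marker loci).
#' @return data.frame with columns `dist_lo`, `dist_hi`, `n_pairs`, `mean_r2`.
#'   Empty (with a warning) when fewer than two polymorphic loci remain.
#' @export
ld_summary <- function(pop, map, max_dist = 10, n_bins = 10L, loci = NULL) {
  if (is.null(loci)) loci <- marker_loci(map)
  p <- allele_freqs(pop, loci)
  poly <- loci[p > 0 & p < 1]
  empty <- data.frame(dist_lo = numeric(0), dist_hi = numeric(0),
                      n_pairs = integer(0), mean_r2 = numeric(0))
  if (length(poly) < 2L) {
    warning("fewer than two polymorphic loci; empty LD table")
    return(empty)
  }
  H <- pop$haps[, poly, drop = FALSE]
  pv <- colMeans(H)
  dists <- numeric(0); r2s <- numeric(0)
  for (ch in unique(map$chr[poly])) {
    sel <- which(map$chr[poly] == ch)
    if (length(sel) < 2L) next
    pos <- map$pos_cm[poly[sel]]
    Hc <- H[, sel, drop = FALSE]
    # joint 1-1 haplotype frequencies for all pairs on this chromosome
    P11 <- crossprod(Hc) / nrow(Hc)
    pc <- pv[sel]
    for (i in seq_len(length(sel) - 1L)) {
      j <- which(pos > pos[i] & pos - pos[i] <= max_dist)
      j <- j[j > i]
      if (!length(j)) next
      D <- P11[i, j] - pc[i] * pc[j]
      r2 <- D^2 / (pc[i] * (1 - pc[i]) * pc[j] * (1 - pc[j]))
      dists <- c(dists, pos[j] - pos[i])
      r2s <- c(r2s, r2)
    }
  }
  if (!length(r2s)) {
    warning("no marker pairs within max_dist; empty LD table")
    return(empty)
  }
  breaks <- seq(0, max_dist, length.out = n_bins + 1L)
  bin <- cut(dists, breaks, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(
    dist_lo = breaks[seq_len(n_bins)],
    dist_hi = breaks[-1L],
    n_pairs = as.integer(tabulate(bin, n_bins)),
    mean_r2 = vapply(seq_len(n_bins), function(b) {
      v <- r2s[bin == b]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)))
  out[out$n_pairs > 0L, , drop = FALSE]
}
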