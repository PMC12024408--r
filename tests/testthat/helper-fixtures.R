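# Shared builders for small in-code fixtures.

# A small multi-chromosome genome for fast simulations.
toy_genome <- function(n_chr = 3L, len = 100, n_markers = 120L, n_qtl = 10L) {
  genome_spec(n_chromosomes = n_chr, chr_lengths = rep(len, n_chr),
              panel_sizes = c(toy = as.integer(n_markers)),
              n_qtl_per_chr = n_qtl)
}

toy_map <- function(seed = 1L, ...) build_genome_map(toy_genome(...), "toy", seed = seed)

# Population whose haplotype pool is given explicitly (rows = haplotypes).
population_from_haplotypes <- function(haps, map) {
  n <- nrow(haps) / 2L
  structure(list(
    ped = data.frame(id = seq_len(n), sire = 0L, dam = 0L,
                     sex = rep(c(1L, 2L), length.out = n), generation = 0L),
    haps = haps, map = map, generation = 0L),
    class = "population_state")
}

# Two-locus map for LD hand computations.
two_locus_map <- function(dist = 1) {
  gs <- genome_spec(n_chromosomes = 1L, chr_lengths = 100,
                    panel_sizes = c(none = 0L), n_qtl_per_chr = 0L)
  map <- data.frame(locus = 1:2, id = c("M1_1", "M1_2"), chr = 1L,
                    pos_cm = c(10, 10 + dist), kind = "marker")
  attr(map, "spec") <- gs
  class(map) <- c("marker_map", "data.frame")
  map
}

# Random valid pedigree: founders plus animals with parents drawn from
# earlier animals of the right sex.
random_pedigree <- function(n, n_founders = max(4L, n %/% 5L), seed = 1L) {
  set.seed(seed)
  sex <- c(rep(1:2, length.out = n_founders),
           sample(c(1L, 2L), n - n_founders, replace = TRUE))
  sire <- integer(n); dam <- integer(n)
  for (i in (n_founders + 1L):n) {
    prev <- seq_len(i - 1L)
    males <- prev[sex[prev] == 1L]
    females <- prev[sex[prev] == 2L]
    sire[i] <- males[sample.int(length(males), 1L)]
    dam[i] <- females[sample.int(length(females), 1L)]
  }
  data.frame(id = seq_len(n), sire = sire, dam = dam, sex = sex)
}

# Unlinked binomial genotypes (independent animals).
random_genotypes <- function(n, m, seed = 1L, p = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- stats::runif(m, 0.1, 0.9)
  d <- vapply(p, function(pp) stats::rbinom(n, 2L, pp), integer(n))
  list(g = genotype_matrix(d, animal_ids = paste0("a", seq_len(n))), p = p)
}

# Sparse large-effect architecture on unlinked markers: the wGBLUP-friendly
# regime (few QTL among many neutral markers).
sparse_trait_sim <- function(n = 500L, m = 500L, n_qtl = 5L, h2 = 0.3,
                             seed = 1L) {
  rg <- random_genotypes(n, m, seed = seed)
  set.seed(seed + 1000L)
  qtl <- sample.int(m, n_qtl)
  beta <- stats::rnorm(n_qtl)
  het <- 2 * rg$p[qtl] * (1 - rg$p[qtl])
  beta <- beta * sqrt(h2 / sum(het * beta^2))
  tbv <- drop(rg$g$dosage[, qtl, drop = FALSE] %*% beta)
  y <- tbv + stats::rnorm(n, 0, sqrt(1 - h2))
  list(g = rg$g, p = rg$p, qtl = qtl, tbv = tbv, y = y, h2 = h2)
}
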