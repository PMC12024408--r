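test_that("tabular A reproduces the classic hand cases", {
  # unrelated founders
  ped <- data.frame(id = 1:4, sire = 0L, dam = 0L)
  expect_equal(unname(numerator_relationship(ped)), diag(4), ignore_attr = TRUE)
  # two full sibs of unrelated parents
  ped <- data.frame(id = 1:4, sire = c(0, 0, 1, 1), dam = c(0, 0, 2, 2))
  A <- numerator_relationship(ped)
  expect_equal(A["3", "4"], 0.5)
  expect_equal(diag(A), rep(1, 4), ignore_attr = TRUE)
  # sire-daughter mating: offspring diagonal 1.25
  ped <- data.frame(id = 1:4, sire = c(0, 0, 1, 1), dam = c(0, 0, 2, 3))
  A <- numerator_relationship(ped)
  expect_equal(A["4", "4"], 1.25)
  expect_equal(unname(inbreeding(ped)), c(0, 0, 0, 0.25))
})

test_that("Henderson A-inverse matches the hand trio and founder identity", {
  ped <- data.frame(id = 1:3, sire = 0L, dam = 0L)
  expect_equal(as.matrix(a_inverse(ped)), diag(3), ignore_attr = TRUE)
  ped <- data.frame(id = c("s", "d", "o"), sire = c(0, 0, "s"),
                    dam = c(0, 0, "d"))
  Ai <- as.matrix(a_inverse(ped))
  expect_equal(Ai["s", "s"], 1.5)
  expect_equal(Ai["s", "d"], 0.5)
  expect_equal(Ai["s", "o"], -1)
  expect_equal(Ai["o", "o"], 2)
})

test_that("A-inverse inverts tabular A on random pedigrees with inbreeding", {
  for (seed in 1:5) {
    ped <- random_pedigree(200L, seed = seed)
    A <- numerator_relationship(ped)
    Ai <- as.matrix(a_inverse(ped))
    expect_lt(max(abs(A %*% Ai - diag(nrow(ped)))), 1e-8)
  }
})

test_that("pedigree validation rejects cycles and unknown parents", {
  ped <- data.frame(id = 1:2, sire = c(2, 1), dam = 0L)
  expect_error(numerator_relationship(ped), "cycle")
  ped <- data.frame(id = 1:2, sire = c(0, 9), dam = 0L)
  expect_error(a_inverse(ped), "unknown parent")
})

test_that("VanRaden G matches a brute-force two-loop computation", {
  rg <- random_genotypes(4L, 6L, seed = 3)
  M <- rg$g$dosage
  p <- colMeans(M) / 2
  G <- grm(rg$g)
  denom <- sum(2 * p * (1 - p))
  Gb <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    Gb[i, j] <- sum((M[i, ] - 2 * p) * (M[j, ] - 2 * p)) / denom
  expect_equal(unname(G), Gb, tolerance = 1e-12, ignore_attr = TRUE)
  # uncentered form as printed
  Gu <- grm(rg$g, centered = FALSE)
  expect_equal(unname(Gu), M %*% t(M) / denom, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("G degenerate cases: all-het animal and duplicated genomes", {
  d <- matrix(1L, 1, 8)
  g <- genotype_matrix(d)
  G <- grm(g, freqs = rep(0.5, 8))
  expect_equal(G[1, 1], 0)
  d2 <- rbind(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L), c(2L, 1L, 0L, 1L))
  g2 <- genotype_matrix(d2)
  G2 <- grm(g2)
  expect_equal(G2[1, 2], G2[1, 1])
  expect_error(grm(genotype_matrix(matrix(2L, 3, 4))), "monomorphic")
})

test_that("centered G is invariant to allele-label swaps and sums to zero", {
  rg <- random_genotypes(10L, 30L, seed = 5)
  G <- grm(rg$g)
  # sum-to-zero property of centered scores: G rows sum to zero, so the
  # average off-diagonal offsets the average diagonal
  expect_equal(sum(G), 0, tolerance = 1e-9)
  expect_equal(mean(G[row(G) != col(G)]),
               -mean(diag(G)) / (nrow(G) - 1), tolerance = 1e-9)
  d2 <- rg$g$dosage
  d2[, 3] <- 2L - d2[, 3]
  expect_equal(unname(grm(genotype_matrix(d2))), unname(G), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("weighted G reduces to G for unit weights and localizes support", {
  rg <- random_genotypes(4L, 6L, seed = 7)
  G <- grm(rg$g)
  Gw <- weighted_grm(rg$g, rep(1, 6))
  expect_lt(max(abs(Gw - G)), 1e-12)
  # all weight on one segregating locus equals that single-locus GRM
  M <- rg$g$dosage; p <- colMeans(M) / 2
  j <- which(p > 0 & p < 1)[1]
  w <- numeric(6); w[j] <- 6
  G3 <- weighted_grm(rg$g, w)
  z <- M[, j] - 2 * p[j]
  expect_equal(unname(G3), outer(z, z) / (2 * p[j] * (1 - p[j])),
               tolerance = 1e-12, ignore_attr = TRUE)
  # brute-force weighted oracle, weights (2,1,1,1,1,0) normalized to mean 1
  w2 <- c(2, 1, 1, 1, 1, 0); w2 <- w2 / mean(w2)
  Gw2 <- weighted_grm(rg$g, w2)
  Gb <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    Gb[i, j] <- sum(w2 * (M[i, ] - 2 * p) * (M[j, ] - 2 * p)) /
      sum(2 * p * (1 - p) * w2)
  expect_equal(unname(Gw2), Gb, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(weighted_grm(rg$g, c(-1, rep(1, 5))), "validation error")
})

test_that("full sibs' genomic relationship matches the pedigree expectation", {
  # many unlinked loci, sib pairs share half their genome in expectation
  map <- toy_map(n_chr = 10L, len = 100, n_markers = 600L, n_qtl = 0L)
  set.seed(11)
  n_fam <- 80L
  haps <- matrix(sample(c(0L, 1L), 4L * n_fam * nrow(map), replace = TRUE),
                 nrow = 4L * n_fam)
  chrinfo <- gblupsim:::chromosome_index(map)
  sib_g <- numeric(0)
  rows <- function(a) c(2L * a - 1L, 2L * a)
  gam <- function(par) gblupsim:::make_gametes(haps, rep(2L * par - 1L, 2),
                                               rep(2L * par, 2), chrinfo)
  dos <- NULL
  for (f in seq_len(n_fam)) {
    s <- 2L * f - 1L; d <- 2L * f
    gs <- gam(s); gd <- gam(d)
    dos <- rbind(dos, gs + gd)   # two full sibs
  }
  g <- genotype_matrix(dos)
  G <- grm(g, freqs = rep(0.5, nrow(map)))
  for (f in seq_len(n_fam)) sib_g <- c(sib_g, G[2L * f - 1L, 2L * f])
  expect_equal(mean(sib_g), 0.5, tolerance = 3 * sd(sib_g) / sqrt(n_fam))
})

test_that("stabilized G is invertible and records its blend", {
  rg <- random_genotypes(30L, 10L, seed = 13)   # n > m: singular G
  G <- grm(rg$g)
  expect_error(chol(G), "positive definite|not positive")
  Gs <- stabilize_grm(G)
  expect_silent(chol(Gs))
  expect_equal(attr(Gs, "blend"), 0.99)
})
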