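test_that("conjugate gradients matches dense direct solves on random MMEs", {
  for (seed in 1:5) {
    ped <- random_pedigree(120L, seed = seed)          # ~240 equations w/ mean
    set.seed(seed + 100)
    rec <- sample(ped$id, 90L)
    y <- rnorm(90)
    f_cg <- solve_pblup(y, rec, pedigree = ped, lambda = 1.7, tol = 1e-10)
    f_dir <- solve_pblup(y, rec, pedigree = ped, lambda = 1.7, method = "direct")
    expect_lt(max(abs(f_cg$u - f_dir$u)), 1e-6)
    expect_lt(max(abs(f_cg$b - f_dir$b)), 1e-6)
    expect_true(f_cg$diagnostics$converged)
  }
})

test_that("a lone record confounded with the mean gives a zero EBV", {
  ped <- data.frame(id = 1, sire = 0, dam = 0)
  fit <- solve_pblup(3.2, 1, pedigree = ped, lambda = 1)
  expect_equal(unname(fit$u), 0, tolerance = 1e-10)
  expect_equal(unname(fit$b), 3.2, tolerance = 1e-10)
})

test_that("extreme shrinkage drives all EBVs to zero", {
  ped <- random_pedigree(40L, seed = 2)
  set.seed(3); y <- rnorm(30)
  fit <- solve_pblup(y, sample(ped$id, 30), pedigree = ped, lambda = 1e12,
                     method = "direct")
  expect_lt(max(abs(fit$u)), 1e-6)
})

test_that("EBVs are invariant to a constant phenotype shift", {
  ped <- random_pedigree(50L, seed = 4)
  set.seed(5); rec <- sample(ped$id, 35); y <- rnorm(35)
  f1 <- solve_pblup(y, rec, pedigree = ped, lambda = 2, method = "direct")
  f2 <- solve_pblup(y + 7.5, rec, pedigree = ped, lambda = 2, method = "direct")
  expect_equal(f1$u, f2$u, tolerance = 1e-9)
  expect_equal(unname(f2$b - f1$b), 7.5, tolerance = 1e-9)
})

test_that("animals without records get EBVs through pedigree ties", {
  # sire with many recorded progeny: EBV pulled towards progeny mean
  n_prog <- 20L
  ped <- data.frame(id = 1:(2 + n_prog),
                    sire = c(0, 0, rep(1, n_prog)),
                    dam = c(0, 0, rep(2, n_prog)))
  set.seed(6)
  y <- 2 + rnorm(n_prog, 0, 0.3)
  fit <- solve_pblup(y, 3:(2 + n_prog), pedigree = ped, lambda = 1,
                     method = "direct")
  expect_gt(unname(fit$u["1"]), 0)
})

test_that("GBLUP equals PBLUP when G is the pedigree A", {
  ped <- random_pedigree(40L, seed = 7)
  A <- numerator_relationship(ped)
  set.seed(8); rec <- sample(ped$id, 30); y <- rnorm(30)
  fp <- solve_pblup(y, rec, pedigree = ped, lambda = 1.3, method = "direct")
  fg <- solve_gblup(y, rec, G = A, lambda = 1.3, method = "direct")
  expect_lt(max(abs(fp$u - fg$u[names(fp$u)])), 1e-8)
})

test_that("duplicate genotyped animals receive equal GEBVs", {
  rg <- random_genotypes(20L, 60L, seed = 9)
  d <- rg$g$dosage
  d[2, ] <- d[1, ]
  g <- genotype_matrix(d, animal_ids = paste0("b", 1:20))
  # duplicated rows make G exactly singular; the identity blend preserves
  # the symmetry between the duplicates
  G <- stabilize_grm(weighted_grm(g, rep(1, 60), freqs = rg$p,
                                  scaling = "standardized"))
  set.seed(10); y <- rnorm(12)
  fit <- solve_gblup(y, paste0("b", 5:16), G, lambda = 1, method = "direct")
  expect_equal(fit$u[["b1"]], fit$u[["b2"]], tolerance = 1e-8)
})

test_that("GBLUP GEBVs equal the SNP-BLUP backsolve", {
  rg <- random_genotypes(30L, 100L, seed = 11)
  std <- standardize_genotypes(rg$g, freqs = rg$p)
  m <- ncol(std$Z)
  G <- weighted_grm(rg$g, rep(1, 100), freqs = rg$p, scaling = "standardized")
  set.seed(12); y <- rnorm(30)
  fg <- solve_gblup(y, rg$g$animal_ids, G, lambda = 2, method = "direct")
  fs <- snp_blup(y, std$Z, lambda = 2 * m)
  expect_lt(max(abs(fg$u - drop(std$Z %*% fs$alpha))), 1e-6)
})

test_that("SNP-BLUP matches hand-assembled normal equations on a toy", {
  set.seed(13)
  Z <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  lambda <- 2.5
  fit <- snp_blup(y, Z, lambda = lambda)
  X <- matrix(1, 10, 1)
  LHS <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + diag(lambda, 3)))
  sol <- solve(LHS, c(crossprod(X, y), crossprod(Z, y)))
  expect_equal(unname(fit$b), sol[1], tolerance = 1e-10)
  expect_equal(unname(fit$alpha), sol[2:4], tolerance = 1e-10)
})

test_that("primal and dual SNP-BLUP forms agree", {
  set.seed(14)
  Z <- matrix(rnorm(20 * 50), 20, 50)   # m > n: dual
  y <- rnorm(20)
  w <- runif(50, 0.2, 2)
  f_dual <- snp_blup(y, Z, lambda = 3, weights = w)
  expect_equal(f_dual$diagnostics$form, "dual")
  # same system through the primal path on an m <= n subproblem
  Z2 <- Z[, 1:15]
  f_pri <- snp_blup(y, Z2, lambda = 3, weights = w[1:15])
  K <- tcrossprod(sweep(Z2, 2, w[1:15], `*`), Z2) + diag(3, 20)
  X <- matrix(1, 20, 1)
  b <- solve(crossprod(X, solve(K, X)), crossprod(X, solve(K, y)))
  alpha <- w[1:15] * drop(crossprod(Z2, solve(K, y - X %*% b)))
  expect_equal(unname(f_pri$alpha), alpha, tolerance = 1e-8)
})

test_that("SNP-BLUP limits: OLS at lambda 0 and monotone shrinkage", {
  set.seed(15)
  x <- rnorm(25)
  y <- 2 * x + rnorm(25, 0, 1e-6)
  fit <- snp_blup(y, cbind(x), lambda = 0)
  ols <- coef(lm(y ~ x))
  expect_equal(unname(fit$alpha), unname(ols[2]), tolerance = 1e-6)
  # null trait: mean |alpha| decreases in lambda
  Z <- matrix(rnorm(40 * 10), 40, 10)
  y0 <- rnorm(40)
  sizes <- vapply(c(1, 10, 100, 1000), function(l)
    mean(abs(snp_blup(y0, Z, lambda = l)$alpha)), numeric(1))
  expect_true(all(diff(sizes) < 0))
})

test_that("zero-weight and zero-variance markers are excluded cleanly", {
  set.seed(16)
  Z <- cbind(matrix(rnorm(60), 20, 3), 0)
  y <- rnorm(20)
  expect_warning(fit <- snp_blup(y, Z, lambda = 1), "zero-variance")
  expect_equal(unname(fit$alpha[4]), 0)
  fit2 <- snp_blup(y, Z[, 1:3], lambda = 1, weights = c(1, 0, 1))
  expect_equal(unname(fit2$alpha[2]), 0)
})

test_that("non-convergence is reported, never silent", {
  ped <- random_pedigree(60L, seed = 17)
  set.seed(18); rec <- sample(ped$id, 40); y <- rnorm(40)
  expect_warning(
    fit <- solve_pblup(y, rec, pedigree = ped, lambda = 1, maxit = 2L),
    "did not converge")
  expect_false(fit$diagnostics$converged)
})
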