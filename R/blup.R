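# Preconditioned conjugate gradients (Jacobi preconditioner) for a symmetric
# positive-definite system.  `A` may be a base or Matrix matrix.
pcg_solve <- function(A, b, tol = 1e-8, maxit = NULL, x0 = NULL) {
  n <- length(b)
  if (is.null(maxit)) maxit <- 10L * n
  Minv <- 1 / Matrix::diag(A)
  Minv[!is.finite(Minv)] <- 1
  x <- if (is.null(x0)) numeric(n) else x0
  r <- b - as.numeric(A %*% x)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) bnorm <- 1
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  iters <- 0L
  repeat {
    res <- sqrt(sum(r^2)) / bnorm
    if (res <= tol || iters >= maxit) break
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
    iters <- iters + 1L
  }
  res <- sqrt(sum((b - as.numeric(A %*% x))^2)) / bnorm
  list(x = x, iterations = iters, residual = res, converged = res <= tol)
}

# Drop linearly dependent columns of X (logged constraint).
full_rank_design <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    message("dropping ", ncol(X) - qrX$rank,
            " dependent fixed-effect column(s)")
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

# Assemble and solve Henderson's mixed-model equations
#   [X'X  X'Z ; Z'X  Z'Z + lambda * Kinv] [b; u] = [X'y; Z'y]
# by PCG (default) or a dense direct solve.
solve_mme <- function(y, X, Z, Kinv, lambda,
                      method = c("pcg", "direct"),
                      tol = 1e-8, maxit = NULL) {
  method <- match.arg(method)
  if (lambda <= 0) stop("validation error: lambda must be > 0")
  X <- full_rank_design(as.matrix(X))
  nb <- ncol(X)
  nu <- ncol(Z)
  XtX <- crossprod(X)
  XtZ <- as.matrix(crossprod(X, Z))
  ZtZ <- Matrix::crossprod(Z)
  lhs_uu <- ZtZ + lambda * Kinv
  LHS <- rbind(cbind(XtX, XtZ),
               cbind(t(XtZ), as.matrix(lhs_uu)))
  rhs <- c(crossprod(X, y), as.numeric(Matrix::crossprod(Z, y)))
  if (method == "pcg") {
    sol <- pcg_solve(LHS, rhs, tol = tol, maxit = maxit)
    if (!sol$converged)
      warning(sprintf(
        "conjugate gradients did not converge (iter %d, rel. residual %.3g)",
        sol$iterations, sol$residual))
    x <- sol$x
    diag_info <- sol[c("iterations", "residual", "converged")]
  } else {
    x <- solve(LHS, rhs)
    diag_info <- list(iterations = 0L, residual = 0, converged = TRUE)
  }
  list(b = x[seq_len(nb)], u = x[nb + seq_len(nu)], diagnostics = diag_info)
}

# Sparse record-to-level incidence matrix.
incidence <- function(level_index, n_levels) {
  Matrix::sparseMatrix(i = seq_along(level_index), j = level_index,
                       x = 1, dims = c(length(level_index), n_levels))
}

#' Pedigree BLUP (PBLUP)
#'
#' Solves the mixed-model equations `y = Xb + Zu + e` with
#' `Var(u) = A sigma_a^2`, using the sparse `A^-1` built by Henderson's
#' rules.  Animals without records receive EBVs through their pedigree ties.
#'
#' @param y Phenotype vector (records).
#' @param animal Animal ID of each record (must appear in `pedigree`).
#' @param pedigree data.frame `id`, `sire`, `dam`; or pass a prebuilt
#'   `Ainv` (with ID dimnames) instead.
#' @param lambda Variance ratio `sigma_e^2 / sigma_a^2`.
#' @param X Fixed-effect design matrix (default: overall mean).
#' @param Ainv Optional precomputed inverse relationship matrix.
#' @param method `"pcg"` (Jacobi-preconditioned conjugate gradients,
#'   relative residual `tol`) or `"direct"` (dense solve).
#' @param tol,maxit PCG controls (defaults 1e-8 and 10 x system size).
#' @return List with `b` (fixed effects), `u` (EBVs named by animal ID) and
#'   `diagnostics` (`iterations`, `residual`, `converged`).
#' @export
solve_pblup <- function(y, animal, pedigree = NULL, lambda, X = NULL,
                        Ainv = NULL, method = c("pcg", "direct"),
                        tol = 1e-8, maxit = NULL) {
  method <- match.arg(method)
  if (is.null(Ainv)) {
    if (is.null(pedigree)) stop("either pedigree or Ainv is required")
    Ainv <- a_inverse(pedigree)
  }
  ids <- rownames(Ainv)
  j <- match(as.character(animal), ids)
  if (anyNA(j)) stop("records refer to animals missing from the pedigree")
  if (is.null(X)) X <- matrix(1, length(y), 1L)
  Z <- incidence(j, length(ids))
  fit <- solve_mme(y, X, Z, Ainv, lambda, method = method,
                   tol = tol, maxit = maxit)
  fit$u <- stats::setNames(fit$u, ids)
  fit
}

#' Genomic BLUP (GBLUP)
#'
#' As [solve_pblup()] with `G^-1` in the random block; GEBVs are returned for
#' every animal in `G`, including animals without records (e.g. validation
#' animals with masked phenotypes).
#'
#' @inheritParams solve_pblup
#' @param G Genomic relationship matrix with animal-ID dimnames (stabilize
#'   with [stabilize_grm()] if it is singular).
#' @param lambda Variance ratio `sigma_e^2 / sigma_g^2`.
#' @return List with `b`, `u` (GEBVs named by animal ID) and `diagnostics`.
#' @export
solve_gblup <- function(y, animal, G, lambda, X = NULL,
                        method = c("pcg", "direct"),
                        tol = 1e-8, maxit = NULL) {
  method <- match.arg(method)
  ids <- rownames(G)
  if (is.null(ids)) stop("G must carry animal IDs as dimnames")
  j <- match(as.character(animal), ids)
  if (anyNA(j)) stop("records refer to animals missing from G")
  Ginv <- tryCatch(chol2inv(chol(G)),
                   error = function(e)
                     stop("G is singular; stabilize it first (stabilize_grm)"))
  if (is.null(X)) X <- matrix(1, length(y), 1L)
  Z <- incidence(j, length(ids))
  fit <- solve_mme(y, X, Z, Ginv, lambda, method = method,
                   tol = tol, maxit = maxit)
  fit$u <- stats::setNames(fit$u, ids)
  fit
}

#' Standardize a genotype matrix for SNP-BLUP
#'
#' Columns are centered at `2p` and scaled by `sqrt(2 p (1 - p))`.
#' Zero-variance (monomorphic) columns are dropped with a warning.
#'
#' @param g A [genotype_matrix()] without missing entries.
#' @param freqs Optional allele frequencies (default observed).
#' @return List with `Z` (standardized design), `loci` (kept locus IDs),
#'   `freqs` (kept frequencies).
#' @export
standardize_genotypes <- function(g, freqs = NULL) {
  d <- g$dosage
  if (anyNA(d)) stop("missing dosages: run apply_qc() first")
  if (is.null(freqs)) freqs <- colMeans(d) / 2
  het <- 2 * freqs * (1 - freqs)
  keep <- het > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance marker column(s) excluded")
  Z <- sweep(sweep(d[, keep, drop = FALSE], 2L, 2 * freqs[keep]),
             2L, sqrt(het[keep]), `/`)
  rownames(Z) <- g$animal_ids
  list(Z = Z, loci = g$locus_ids[keep], freqs = freqs[keep])
}

#' SNP-BLUP (ridge regression on standardized genotypes)
#'
#' Fits `y = Xb + Z alpha + e` with `alpha ~ N(0, W sigma_alpha^2)`,
#' `e ~ N(0, I sigma_e^2)`, i.e. the ridge solution
#' `alpha_hat = (Z'Z + lambda W^-1)^-1 Z'(y - X b_hat)` with fixed effects
#' solved jointly.  Zero-weight markers get `alpha_hat = 0` and are excluded
#' from the `W^-1` inversion.  The number of equations never exceeds
#' `min(n, m)`: for `m > n` the equivalent dual (animal-dimension) form is
#' used.
#'
#' @param y Phenotype vector.
#' @param Z Standardized genotype design matrix (records x markers), e.g.
#'   from [standardize_genotypes()].
#' @param lambda Ridge parameter `sigma_e^2 / sigma_alpha^2`; `lambda = 0`
#'   gives ordinary least squares (requires `m <= n`).
#' @param weights Non-negative diagonal of `W` (default all 1).
#' @param X Fixed-effect design (default: overall mean).
#' @return List with `b`, `alpha` (named by `colnames(Z)` if present),
#'   `gebv` (`Z %*% alpha` for the supplied rows) and `diagnostics`.
#' @export
snp_blup <- function(y, Z, lambda, weights = NULL, X = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z); m <- ncol(Z)
  if (length(y) != n) stop("y and Z dimensions disagree")
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m) stop("weights must have one entry per marker")
  if (any(weights < 0)) stop("validation error: negative marker weight")
  if (is.null(X)) X <- matrix(1, n, 1L)
  X <- full_rank_design(as.matrix(X))
  sds <- apply(Z, 2L, stats::sd)
  dead <- sds == 0
  if (any(dead)) {
    warning(sum(dead), " zero-variance marker column(s) get alpha = 0")
    weights[dead] <- 0
  }
  active <- weights > 0
  Za <- Z[, active, drop = FALSE]
  wa <- weights[active]
  ma <- sum(active)
  alpha <- numeric(m)
  if (lambda < 0) stop("validation error: lambda must be >= 0")
  if (lambda == 0 || ma <= n) {
    # primal: joint normal equations in min(m, n) marker dimension
    if (lambda == 0 && ma > n)
      stop("lambda = 0 requires no more active markers than records")
    nb <- ncol(X)
    LHS <- rbind(cbind(crossprod(X), crossprod(X, Za)),
                 cbind(crossprod(Za, X), crossprod(Za) +
                         lambda * diag(1 / wa, ma)))
    rhs <- c(crossprod(X, y), crossprod(Za, y))
    sol <- solve(LHS, rhs)
    b <- sol[seq_len(nb)]
    alpha[active] <- sol[nb + seq_len(ma)]
  } else {
    # dual: K = Za W Za' + lambda I is n x n
    K <- tcrossprod(sweep(Za, 2L, wa, `*`), Za) + diag(lambda, n)
    Ky <- solve(K, cbind(y, X))
    XtKinvX <- crossprod(X, Ky[, -1L, drop = FALSE])
    b <- solve(XtKinvX, crossprod(X, Ky[, 1L]))
    resid <- drop(solve(K, y - X %*% b))
    alpha[active] <- wa * drop(crossprod(Za, resid))
  }
  names(alpha) <- colnames(Z)
  list(b = drop(b), alpha = alpha, gebv = drop(Z %*% alpha),
       diagnostics = list(iterations = 0L, residual = 0, converged = TRUE,
                          form = if (lambda == 0 || ma <= n) "primal" else "dual"))
}
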