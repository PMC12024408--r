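# Normalize a pedigree data.frame (id, sire, dam) to integer indices in
# topological order.  0 / NA are the null-parent codes.  Errors on cycles and
# duplicate animals.
normalize_pedigree <- function(ped) {
  ped <- as.data.frame(ped)
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  id <- as.character(ped$id)
  if (anyDuplicated(id)) stop("duplicate animals in pedigree")
  code <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "0"] <- NA
    m <- match(x, id)
    if (any(!is.na(x) & is.na(m)))
      stop("pedigree refers to unknown parent IDs")
    m
  }
  sire <- code(ped$sire)
  dam <- code(ped$dam)
  n <- length(id)
  ord <- integer(0)
  placed <- logical(n)
  remaining <- seq_len(n)
  repeat {
    ready <- remaining[(is.na(sire[remaining]) | placed[sire[remaining]]) &
                       (is.na(dam[remaining]) | placed[dam[remaining]])]
    if (!length(ready)) {
      if (length(remaining))
        stop("validation error: pedigree contains a cycle")
      break
    }
    ord <- c(ord, ready)
    placed[ready] <- TRUE
    remaining <- setdiff(remaining, ready)
  }
  pos <- match(seq_len(n), ord)
  list(id = id[ord],
       sire = ifelse(is.na(sire[ord]), 0L, pos[sire[ord]]),
       dam = ifelse(is.na(dam[ord]), 0L, pos[dam[ord]]),
       order = ord)
}

#' Pedigree numerator relationship matrix (A)
#'
#' Tabular (recursive) method: `a(i,i) = 1 + a(s,d)/2` and
#' `a(i,j) = (a(j,s) + a(j,d))/2` for `j` older than `i`; a missing parent
#' contributes 0.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam` (0/NA = unknown).
#' @return Dense symmetric matrix with animal IDs as dimnames and attribute
#'   `kind = "A"`, rows/columns in the input animal order.
#' @export
numerator_relationship <- function(ped) {
  np <- normalize_pedigree(ped)
  n <- length(np$id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- np$sire[i]; d <- np$dam[i]
    asd <- if (s > 0L && d > 0L) A[s, d] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      av <- numeric(i - 1L)
      if (s > 0L) av <- av + A[j, s]
      if (d > 0L) av <- av + A[j, d]
      A[j, i] <- A[i, j] <- 0.5 * av
    }
  }
  inv <- order(np$order)
  A <- A[inv, inv, drop = FALSE]
  dimnames(A) <- list(np$id[inv], np$id[inv])
  attr(A, "kind") <- "A"
  A
}

# Inbreeding coefficients and Mendelian-sampling variances by the
# Meuwissen-Luo tracing algorithm on a topologically ordered pedigree
# (indices: parents precede offspring, 0 = unknown).
ml_inbreeding <- function(sire, dam) {
  n <- length(sire)
  F <- numeric(n)
  D <- numeric(n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    Fs <- if (s > 0L) F[s] else 0
    Fd <- if (d > 0L) F[d] else 0
    D[i] <- if (s > 0L && d > 0L) 0.5 - 0.25 * (Fs + Fd)
            else if (s > 0L || d > 0L) 0.75 - 0.25 * (Fs + Fd)
            else 1
    if (s > 0L && d > 0L) {
      # a(i,i) = sum_j v_j^2 D_j over ancestors (A = L D L')
      v <- numeric(i)
      v[i] <- 1
      aii <- 0
      for (j in i:1) {
        if (v[j] != 0) {
          aii <- aii + v[j]^2 * D[j]
          if (sire[j] > 0L) v[sire[j]] <- v[sire[j]] + 0.5 * v[j]
          if (dam[j] > 0L) v[dam[j]] <- v[dam[j]] + 0.5 * v[j]
        }
      }
      F[i] <- aii - 1
    }
  }
  list(F = F, D = D)
}

#' Inverse numerator relationship matrix by Henderson's rules
#'
#' Builds `A^-1` directly (never forming A) with inbreeding accounted for via
#' the Meuwissen-Luo computation of Mendelian-sampling variances.
#'
#' @inheritParams numerator_relationship
#' @return Sparse symmetric `Matrix::dsCMatrix` with animal IDs as dimnames,
#'   attribute `kind = "A_inverse"`, rows/columns in the input animal order.
#' @export
a_inverse <- function(ped) {
  np <- normalize_pedigree(ped)
  n <- length(np$id)
  ml <- ml_inbreeding(np$sire, np$dam)
  alpha <- 1 / ml$D
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    s <- np$sire[i]; d <- np$dam[i]; a <- alpha[i]
    add(i, i, a)
    if (s > 0L) { add(s, s, a / 4); add(min(i, s), max(i, s), -a / 2) }
    if (d > 0L) { add(d, d, a / 4); add(min(i, d), max(i, d), -a / 2) }
    if (s > 0L && d > 0L) add(min(s, d), max(s, d), a / 4)
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               symmetric = TRUE)
  inv <- order(np$order)
  Ainv <- Ainv[inv, inv, drop = FALSE]
  dimnames(Ainv) <- list(np$id[inv], np$id[inv])
  attr(Ainv, "kind") <- "A_inverse"
  Ainv
}

#' Inbreeding coefficients from a pedigree
#'
#' @inheritParams numerator_relationship
#' @return Named numeric vector of inbreeding coefficients, input order.
#' @export
inbreeding <- function(ped) {
  np <- normalize_pedigree(ped)
  F <- ml_inbreeding(np$sire, np$dam)$F
  inv <- order(np$order)
  stats::setNames(F[inv], np$id[inv])
}

#' Genomic relationship matrix (VanRaden)
#'
#' Default (`centered = TRUE`) is VanRaden method 1:
#' `G = Z Z' / sum_i 2 p_i (1 - p_i)` with `Z = M - 2p` column-wise.
#' `centered = FALSE` uses the raw dosage matrix `M` in place of `Z`
#' (the uncentered cross-product form; not a relationship matrix in the
#' variance-interpretation sense, provided for completeness).
#'
#' @param g A [genotype_matrix()] with no missing entries (post-QC).
#' @param freqs Optional allele frequencies for centering/scaling; defaults
#'   to the observed frequencies of `g`.
#' @param centered Center dosages by twice the allele frequency.
#' @return Dense symmetric matrix, animal IDs as dimnames, attribute
#'   `kind = "G"`.
#' @export
grm <- function(g, freqs = NULL, centered = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  if (anyNA(d)) stop("missing dosages: run apply_qc()/imputation first")
  if (is.null(freqs)) freqs <- colMeans(d) / 2
  denom <- sum(2 * freqs * (1 - freqs))
  if (denom <= 0)
    stop("all loci monomorphic at the supplied frequencies: ",
         "the VanRaden denominator is zero; filter the panel (apply_qc) ",
         "or supply polymorphic frequencies")
  Z <- if (centered) sweep(d, 2L, 2 * freqs) else d
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(g$animal_ids, g$animal_ids)
  attr(G, "kind") <- "G"
  G
}

#' SNP-weighted genomic relationship matrix
#'
#' With `scaling = "vanraden"` (default):
#' `G_w = Z diag(W) Z' / sum_i 2 p_i (1 - p_i) W_i` with `Z = M - 2p`; with
#' `W` identically 1 this reproduces [grm()].  With
#' `scaling = "standardized"` the columns of `Z` are additionally divided by
#' `sqrt(2 p (1 - p))` and the denominator is `sum_i W_i`; this is the form
#' under which GBLUP with `G_w` is exactly equivalent to SNP-BLUP on
#' standardized genotypes with effect covariance `diag(W)`.
#'
#' @inheritParams grm
#' @param weights Non-negative per-marker weights (length = loci).
#' @param scaling `"vanraden"` or `"standardized"`.
#' @return Dense symmetric matrix, attribute `kind = "G_weighted"`.
#' @export
weighted_grm <- function(g, weights, freqs = NULL,
                         scaling = c("vanraden", "standardized")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  if (anyNA(d)) stop("missing dosages: run apply_qc()/imputation first")
  if (length(weights) != ncol(d))
    stop("weights must have one entry per locus")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("validation error: weights must be finite and non-negative")
  if (is.null(freqs)) freqs <- colMeans(d) / 2
  het <- 2 * freqs * (1 - freqs)
  Z <- sweep(d, 2L, 2 * freqs)
  if (scaling == "vanraden") {
    denom <- sum(het * weights)
    if (denom <= 0) stop("zero denominator: no weighted polymorphic loci")
    G <- tcrossprod(sweep(Z, 2L, weights, `*`), Z) / denom
  } else {
    keep <- het > 0
    Zs <- sweep(Z[, keep, drop = FALSE], 2L, sqrt(het[keep]), `/`)
    w <- weights[keep]
    denom <- sum(w)
    if (denom <= 0) stop("zero denominator: all weights zero")
    G <- tcrossprod(sweep(Zs, 2L, w, `*`), Zs) / denom
  }
  G <- (G + t(G)) / 2
  dimnames(G) <- list(g$animal_ids, g$animal_ids)
  attr(G, "kind") <- "G_weighted"
  G
}

#' Blend a genomic relationship matrix towards the identity
#'
#' `G* = blend * G + (1 - blend) * I`, the standard ridge stabilization that
#' guarantees invertibility of G inside the mixed-model equations.
#'
#' @param G A genomic relationship matrix.
#' @param blend Weight on G (default 0.99).
#' @return The blended matrix (attribute `blend` records the weight).
#' @export
stabilize_grm <- function(G, blend = 0.99) {
  stopifnot(blend > 0, blend <= 1)
  Gs <- blend * G + (1 - blend) * diag(nrow(G))
  dimnames(Gs) <- dimnames(G)
  attr(Gs, "kind") <- attr(G, "kind")
  attr(Gs, "blend") <- blend
  Gs
}

#' Export a relationship matrix as plain-text lower triangle
#'
#' @param K Relationship matrix with ID dimnames.
#' @param path Output path.
#' @export
write_relationship <- function(K, path) {
  ids <- rownames(K)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ids, collapse = " "), con)
  for (i in seq_len(nrow(K)))
    writeLines(paste(signif(K[i, seq_len(i)], 10), collapse = " "), con)
  invisible(path)
}
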