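#' Genotype matrix container
#'
#' Additive dosages (0/1/2, `NA` for missing) with animal and locus
#' identifiers.
#'
#' @param dosage Animals x loci matrix with entries in `{0, 1, 2, NA}`.
#' @param animal_ids,locus_ids Identifier vectors matching the dimensions.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, animal_ids = rownames(dosage),
                            locus_ids = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(animal_ids)) animal_ids <- seq_len(nrow(dosage))
  if (is.null(locus_ids)) locus_ids <- paste0("snp", seq_len(ncol(dosage)))
  if (length(animal_ids) != nrow(dosage) || length(locus_ids) != ncol(dosage))
    stop("identifier lengths do not match the dosage matrix")
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(animal_ids, locus_ids)
  structure(list(dosage = dosage,
                 animal_ids = as.character(animal_ids),
                 locus_ids = as.character(locus_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d animals x %d loci (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Observed allele frequencies of a genotype matrix
#'
#' @param g A `genotype_matrix`.
#' @return Counted-allele frequency per locus (missing entries excluded).
#' @export
genotype_freqs <- function(g) colMeans(g$dosage, na.rm = TRUE) / 2

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test for one biallelic locus: the p-value is the summed
#' probability, under the conditional distribution of heterozygote count
#' given allele counts, of all genotype configurations no more probable
#' than the observed one (full enumeration; mid-p off).
#'
#' @param n_aa,n_ab,n_bb Genotype counts (minor hom, het, major hom in any
#'   consistent orientation).
#' @return The exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(1)
  n_a <- 2L * n_aa + n_ab            # minor-allele count
  if (n_a > n) return(hwe_exact_test(n_bb, n_ab, n_aa))
  hets <- seq(n_a %% 2L, n_a, by = 2L)
  # log-probability of each possible het count given allele counts
  lp <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2
    bb <- n - aa - h
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) + lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- which(hets == n_ab)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Quality-control thresholds
#'
#' @param maf_min Minimum minor-allele frequency (loci below are removed).
#' @param locus_missing_max Maximum per-locus missing fraction.
#' @param animal_missing_max Maximum per-animal missing fraction.
#' @param hwe_p_min Minimum Hardy-Weinberg exact-test p-value.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.05, locus_missing_max = 0.10,
                          animal_missing_max = 0.10, hwe_p_min = 1e-5) {
  v <- c(maf_min, locus_missing_max, animal_missing_max, hwe_p_min)
  if (any(v < 0 | v > 1)) stop("thresholds must be in [0, 1]")
  structure(list(maf_min = maf_min, locus_missing_max = locus_missing_max,
                 animal_missing_max = animal_missing_max,
                 hwe_p_min = hwe_p_min),
            class = "qc_thresholds")
}

#' Apply marker and animal quality control
#'
#' Filters are applied in a fixed order so removal counts are deterministic:
#' animals by missing fraction, then loci by missing fraction, then loci by
#' minor-allele frequency, then loci by the Hardy-Weinberg exact test.
#'
#' @param g A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @return List with `genotypes` (filtered matrix), and `report` (data.frame
#'   of removal counts per filter).  When every locus is removed the
#'   `genotypes` element is an empty matrix and a warning is raised.
#' @export
apply_qc <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (nrow(g$dosage) == 0L || ncol(g$dosage) == 0L)
    stop("empty genotype matrix")
  d <- g$dosage

  miss_animal <- rowMeans(is.na(d))
  drop_animal <- miss_animal > thresholds$animal_missing_max
  d <- d[!drop_animal, , drop = FALSE]

  miss_locus <- colMeans(is.na(d))
  drop_miss <- miss_locus > thresholds$locus_missing_max
  d <- d[, !drop_miss, drop = FALSE]

  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  drop_maf <- maf < thresholds$maf_min
  d <- d[, !drop_maf, drop = FALSE]

  drop_hwe <- logical(ncol(d))
  if (ncol(d) > 0L) {
    for (j in seq_len(ncol(d))) {
      x <- d[, j]
      n2 <- sum(x == 2L, na.rm = TRUE)
      n1 <- sum(x == 1L, na.rm = TRUE)
      n0 <- sum(x == 0L, na.rm = TRUE)
      drop_hwe[j] <- hwe_exact_test(n2, n1, n0) < thresholds$hwe_p_min
    }
    d <- d[, !drop_hwe, drop = FALSE]
  }

  report <- data.frame(
    filter = c("animal_missing", "locus_missing", "maf", "hwe"),
    removed = c(sum(drop_animal), sum(drop_miss), sum(drop_maf), sum(drop_hwe)),
    unit = c("animals", "loci", "loci", "loci"))
  if (ncol(d) == 0L)
    warning("empty panel: all loci removed by quality control")
  out <- structure(list(dosage = d,
                        animal_ids = rownames(d),
                        locus_ids = colnames(d)),
                   class = "genotype_matrix")
  list(genotypes = out, report = report)
}

#' Write a QC report as CSV
#'
#' @param report The `report` element of [apply_qc()]'s result.
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
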