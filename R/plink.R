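# PLINK 1.9-dialect genotype files.  Binary .bed is SNP-major: three magic
# bytes 0x6c 0x1b 0x01, then per SNP ceil(n/4) bytes, two bits per sample
# starting at the least significant pair: 00 = hom A1 (dosage 2),
# 01 = missing, 10 = het, 11 = hom A2 (dosage 0).  A1 is the counted allele.

plink_map_frame <- function(g, map) {
  m <- length(g$locus_ids)
  if (is.null(map)) {
    return(data.frame(chr = 1L, id = g$locus_ids, cm = 0,
                      bp = seq_len(m), stringsAsFactors = FALSE))
  }
  if (inherits(map, "marker_map")) {
    pm <- map_to_plink(map, markers_only = FALSE)
    pm <- pm[match(g$locus_ids, pm$id), , drop = FALSE]
    if (anyNA(pm$id)) stop("map does not cover all genotype loci")
    return(pm)
  }
  map <- as.data.frame(map)
  stopifnot(all(c("chr", "id", "cm", "bp") %in% names(map)))
  map[match(g$locus_ids, map$id), , drop = FALSE]
}

plink_fam_frame <- function(g, pedigree) {
  if (is.null(pedigree)) {
    return(data.frame(fid = g$animal_ids, iid = g$animal_ids,
                      pat = 0L, mat = 0L, sex = 0L, pheno = -9,
                      stringsAsFactors = FALSE))
  }
  pedigree <- as.data.frame(pedigree)
  idx <- match(g$animal_ids, as.character(pedigree$id))
  if (anyNA(idx)) stop("pedigree does not cover all genotyped animals")
  data.frame(fid = g$animal_ids, iid = g$animal_ids,
             pat = pedigree$sire[idx], mat = pedigree$dam[idx],
             sex = if ("sex" %in% names(pedigree)) pedigree$sex[idx] else 0L,
             pheno = if ("phenotype" %in% names(pedigree))
               pedigree$phenotype[idx] else -9,
             stringsAsFactors = FALSE)
}

#' Write genotypes in PLINK format
#'
#' Writes either the text pair `.ped`/`.map` or the binary triple
#' `.bed`/`.bim`/`.fam` (v1.9 dialect, SNP-major).  The counted (A1) allele
#' is written as `A`, the other as `B`; additive coding is preserved on a
#' round trip through [read_plink()].
#'
#' @param g A [genotype_matrix()].
#' @param prefix Output path prefix (extensions are appended).
#' @param map Optional `marker_map` or data.frame with columns
#'   `chr`, `id`, `cm`, `bp` covering the genotyped loci.
#' @param pedigree Optional data.frame with `id`, `sire`, `dam` (and
#'   optionally `sex`) used for the family file.
#' @param binary Write `.bed`/`.bim`/`.fam` (default) instead of `.ped`/`.map`.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(g, prefix, map = NULL, pedigree = NULL, binary = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  pm <- plink_map_frame(g, map)
  fam <- plink_fam_frame(g, pedigree)
  d <- g$dosage
  n <- nrow(d); m <- ncol(d)
  if (binary) {
    utils::write.table(data.frame(pm$chr, pm$id, pm$cm, pm$bp, "A", "B"),
                       paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    # 2-bit codes indexed by dosage (0,1,2) -> 3,2,0; missing -> 1
    code <- matrix(3L, n, m)
    code[d == 1L] <- 2L
    code[d == 2L] <- 0L
    code[is.na(d)] <- 1L
    bytes_per_snp <- ceiling(n / 4)
    pad <- 4L * bytes_per_snp - n
    if (pad > 0L) code <- rbind(code, matrix(0L, pad, m))
    shift <- rep(c(1L, 4L, 16L, 64L), bytes_per_snp)
    packed <- code * shift
    idx <- rep(seq_len(bytes_per_snp), each = 4L)
    raw_mat <- vapply(seq_len(m), function(j)
      as.raw(rowsum(packed[, j], idx)), raw(bytes_per_snp))
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    writeBin(as.vector(raw_mat), con)
  } else {
    utils::write.table(data.frame(pm$chr, pm$id, pm$cm, pm$bp),
                       paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    al1 <- matrix("0", n, m); al2 <- matrix("0", n, m)
    al1[d == 2L] <- "A"; al2[d == 2L] <- "A"
    al1[d == 1L] <- "A"; al2[d == 1L] <- "B"
    al1[d == 0L] <- "B"; al2[d == 0L] <- "B"
    inter <- matrix("", n, 2L * m)
    inter[, seq(1L, 2L * m, by = 2L)] <- al1
    inter[, seq(2L, 2L * m, by = 2L)] <- al2
    out <- cbind(as.matrix(format(fam, trim = TRUE)), inter)
    utils::write.table(out, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(prefix)
}

#' Read genotypes from PLINK files
#'
#' Reads `.bed`/`.bim`/`.fam` when present at the prefix, otherwise
#' `.ped`/`.map`.  Dosages count the A1 allele of the `.bim`/`.ped` coding.
#'
#' @param prefix Path prefix of the file set.
#' @return List with `genotypes` (a [genotype_matrix()]), `map` (data.frame
#'   `chr`, `id`, `cm`, `bp`, and for binary input `a1`, `a2`) and `fam`
#'   (data.frame `fid`, `iid`, `pat`, `mat`, `sex`, `pheno`).
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  if (file.exists(bed)) read_plink_binary(prefix) else read_plink_text(prefix)
}

read_plink_binary <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chr", "id", "cm", "bp", "a1", "a2"),
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "numeric"))
  if (anyDuplicated(fam$iid))
    stop("format error: duplicate animal IDs in ", prefix, ".fam")
  if (anyDuplicated(bim$id))
    stop("format error: duplicate locus IDs in ", prefix, ".bim")
  n <- nrow(fam); m <- nrow(bim)
  bed_path <- paste0(prefix, ".bed")
  bytes <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(bytes) < 3L || bytes[1] != as.raw(0x6c) || bytes[2] != as.raw(0x1b))
    stop("format error: ", bed_path, " does not start with the PLINK magic bytes")
  if (bytes[3] != as.raw(0x01))
    stop("format error: ", bed_path, " is not in SNP-major orientation")
  body <- bytes[-(1:3)]
  bytes_per_snp <- ceiling(n / 4)
  if (length(body) != bytes_per_snp * m)
    stop("format error: ", bed_path, " is truncated (", length(body),
         " body bytes, expected ", bytes_per_snp * m, ")")
  iv <- as.integer(body)
  # unpack 4 two-bit codes per byte, low pair first
  codes <- rbind(iv %% 4L, (iv %/% 4L) %% 4L,
                 (iv %/% 16L) %% 4L, (iv %/% 64L) %% 4L)
  codes <- matrix(as.vector(codes), nrow = 4L * bytes_per_snp)[seq_len(n), ,
                                                               drop = FALSE]
  lut <- c(2L, NA_integer_, 1L, 0L)   # code 0,1,2,3 -> A1 dosage
  d <- matrix(lut[codes + 1L], n, m)
  g <- genotype_matrix(d, animal_ids = fam$iid, locus_ids = bim$id)
  list(genotypes = g, map = bim, fam = fam)
}

read_plink_text <- function(prefix) {
  pmap <- utils::read.table(paste0(prefix, ".map"),
                            col.names = c("chr", "id", "cm", "bp"))
  raw <- utils::read.table(paste0(prefix, ".ped"), colClasses = "character")
  m <- nrow(pmap)
  if (ncol(raw) != 6L + 2L * m)
    stop("format error: ", prefix, ".ped has ", ncol(raw),
         " columns, expected ", 6L + 2L * m)
  fam <- stats::setNames(raw[, 1:6], c("fid", "iid", "pat", "mat", "sex", "pheno"))
  fam$sex <- as.integer(fam$sex)
  fam$pheno <- as.numeric(fam$pheno)
  if (anyDuplicated(fam$iid))
    stop("format error: duplicate animal IDs in ", prefix, ".ped")
  a1 <- as.matrix(raw[, 6L + seq(1L, 2L * m, by = 2L), drop = FALSE])
  a2 <- as.matrix(raw[, 6L + seq(2L, 2L * m, by = 2L), drop = FALSE])
  d <- (a1 == "A") + (a2 == "A")
  d[a1 == "0" | a2 == "0"] <- NA
  g <- genotype_matrix(d, animal_ids = fam$iid, locus_ids = pmap$id)
  list(genotypes = g, map = pmap, fam = fam)
}
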