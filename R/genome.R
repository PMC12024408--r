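#' Physical sizes of the 29 bovine autosomes
#'
#' Autosome lengths (base pairs) of the ARS-UCD1.2 cattle assembly, used to
#' apportion genetic map length across chromosomes when only a genome total
#' is configured.
#'
#' @return Named numeric vector of length 29 (names `"1"`..`"29"`), in bp.
#' @export
bovine_autosome_bp <- function() {
  c(`1` = 158534110, `2` = 136231102, `3` = 121005158, `4` = 120000601,
    `5` = 120089316, `6` = 117806340, `7` = 110682743, `8` = 113319770,
    `9` = 105454467, `10` = 103308737, `11` = 106982474, `12` = 87216183,
    `13` = 83472345, `14` = 82403003, `15` = 85007780, `16` = 81013979,
    `17` = 73167244, `18` = 65820629, `19` = 63449741, `20` = 71974595,
    `21` = 69862954, `22` = 60773035, `23` = 52498615, `24` = 62317253,
    `25` = 42350435, `26` = 51992305, `27` = 45612108, `28` = 45940150,
    `29` = 51098607)
}

#' Genome specification
#'
#' Defines the coordinate frame for the simulated cattle genome: number of
#' autosomes, per-chromosome genetic lengths, target marker-panel sizes and
#' the number of QTL per chromosome.
#'
#' By default the 29 autosomes carry genetic lengths proportional to their
#' ARS-UCD1.2 physical sizes, rescaled so the genome totals `total_cm`
#' (2715.85 cM).  Pass `total_cm = 2486` for the alternative genome total,
#' or supply `chr_lengths` directly for reduced desk-scale genomes.
#'
#' @param n_chromosomes Number of autosomes (29 for the cattle genome).
#' @param total_cm Total genetic length in centimorgans; ignored when
#'   `chr_lengths` is given.
#' @param chr_lengths Optional numeric vector of per-chromosome lengths (cM).
#' @param panel_sizes Named integer vector of marker counts per density tag,
#'   e.g. `c("50k" = 58990, "770k" = 777962)`.
#' @param n_qtl_per_chr Number of evenly spaced QTL per chromosome.
#' @return An object of class `genome_spec`.
#' @examples
#' gs <- genome_spec()
#' sum(gs$chr_lengths)  # 2715.85
#' @export
genome_spec <- function(n_chromosomes = 29L,
                        total_cm = 2715.85,
                        chr_lengths = NULL,
                        panel_sizes = c("50k" = 58990L, "770k" = 777962L),
                        n_qtl_per_chr = 25L) {
  n_chromosomes <- as.integer(n_chromosomes)
  if (n_chromosomes < 1L) stop("n_chromosomes must be >= 1")
  if (is.null(chr_lengths)) {
    bp <- bovine_autosome_bp()
    if (n_chromosomes == 29L) {
      chr_lengths <- unname(bp) / sum(bp) * total_cm
    } else {
      chr_lengths <- rep(total_cm / n_chromosomes, n_chromosomes)
    }
  }
  chr_lengths <- as.numeric(chr_lengths)
  if (length(chr_lengths) != n_chromosomes)
    stop("chr_lengths must have one entry per chromosome")
  if (any(!is.finite(chr_lengths)) || any(chr_lengths <= 0))
    stop("invalid genome spec: chromosome lengths must be strictly positive")
  if (is.null(names(panel_sizes)))
    stop("panel_sizes must be a named vector of marker counts")
  structure(
    list(n_chromosomes = n_chromosomes,
         chr_lengths = stats::setNames(chr_lengths, seq_len(n_chromosomes)),
         total_length = sum(chr_lengths),
         panel_sizes = vapply(panel_sizes, as.integer, integer(1)),
         n_qtl_per_chr = as.integer(n_qtl_per_chr)),
    class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome_spec: %d chromosomes, %.2f cM total, %d QTL/chr\n",
              x$n_chromosomes, x$total_length, x$n_qtl_per_chr))
  cat("panels:", paste(sprintf("%s=%d", names(x$panel_sizes), x$panel_sizes),
                       collapse = ", "), "\n")
  invisible(x)
}

# Largest-remainder apportionment of `total` items proportional to `weights`.
# Guarantees the counts sum exactly to `total` and no count deviates from
# exact proportionality by more than 1.
apportion_largest_remainder <- function(total, weights) {
  total <- as.integer(total)
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Build a marker/QTL map
#'
#' Places the configured number of markers uniformly at random along each
#' chromosome (marker counts apportioned to chromosomes proportional to their
#' genetic length, largest-remainder rule) and `n_qtl_per_chr` QTL at evenly
#' spaced positions, then sorts all loci by (chromosome, position).
#'
#' @param spec A [genome_spec()].
#' @param density Panel tag naming an entry of `spec$panel_sizes`, or a single
#'   non-negative integer marker count.
#' @param seed Integer seed for the uniform marker placement.
#' @return A `marker_map`: data.frame with columns `locus` (index after
#'   sorting), `id`, `chr`, `pos_cm`, `kind` (`"marker"`/`"qtl"`), carrying the
#'   genome spec as attribute `spec`.
#' @examples
#' map <- build_genome_map(genome_spec(), "50k", seed = 1)
#' sum(map$kind == "qtl")     # 725
#' sum(map$kind == "marker")  # 58990
#' @export
build_genome_map <- function(spec, density = "50k", seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  if (is.character(density)) {
    if (!density %in% names(spec$panel_sizes))
      stop("unknown density tag '", density, "'; configured: ",
           paste(names(spec$panel_sizes), collapse = ", "))
    n_markers <- spec$panel_sizes[[density]]
  } else {
    n_markers <- as.integer(density)
    density <- as.character(n_markers)
  }
  if (n_markers < 0) stop("marker count must be non-negative")
  if (n_markers > 0 && n_markers < spec$n_chromosomes)
    stop("configuration error: panel size (", n_markers,
         ") smaller than the number of chromosomes (", spec$n_chromosomes, ")")

  per_chr <- if (n_markers > 0)
    apportion_largest_remainder(n_markers, spec$chr_lengths)
  else rep(0L, spec$n_chromosomes)

  set.seed(as.integer(seed))
  pieces <- vector("list", spec$n_chromosomes)
  for (ch in seq_len(spec$n_chromosomes)) {
    len <- spec$chr_lengths[[ch]]
    mpos <- sort(stats::runif(per_chr[ch], 0, len))
    q <- spec$n_qtl_per_chr
    # QTL at interval midpoints: evenly spaced, none on a chromosome edge
    qpos <- if (q > 0) (seq_len(q) - 0.5) * len / q else numeric(0)
    df <- data.frame(
      chr = ch,
      pos_cm = c(mpos, qpos),
      kind = c(rep("marker", length(mpos)), rep("qtl", length(qpos))),
      stringsAsFactors = FALSE)
    pieces[[ch]] <- df[order(df$pos_cm), , drop = FALSE]
  }
  map <- do.call(rbind, pieces)
  rownames(map) <- NULL
  map$locus <- seq_len(nrow(map))
  midx <- cumsum(map$kind == "marker")
  qidx <- cumsum(map$kind == "qtl")
  map$id <- ifelse(map$kind == "marker",
                   sprintf("M%d_%d", map$chr, midx),
                   sprintf("Q%d_%d", map$chr, qidx))
  # per-chromosome local numbering for ids
  for (ch in seq_len(spec$n_chromosomes)) {
    sel <- map$chr == ch & map$kind == "marker"
    map$id[sel] <- sprintf("M%d_%d", ch, seq_len(sum(sel)))
    sel <- map$chr == ch & map$kind == "qtl"
    map$id[sel] <- sprintf("Q%d_%d", ch, seq_len(sum(sel)))
  }
  map <- map[, c("locus", "id", "chr", "pos_cm", "kind")]
  attr(map, "spec") <- spec
  attr(map, "density") <- density
  class(map) <- c("marker_map", "data.frame")
  map
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("marker_map: %d loci (%d markers, %d QTL) on %d chromosomes\n",
              nrow(x), sum(x$kind == "marker"), sum(x$kind == "qtl"),
              length(unique(x$chr))))
  invisible(x)
}

#' Indices of marker and QTL loci in a map
#'
#' @param map A `marker_map`.
#' @return Integer vector of row indices.
#' @export
marker_loci <- function(map) which(map$kind == "marker")

#' @rdname marker_loci
#' @export
qtl_loci <- function(map) which(map$kind == "qtl")

#' Export a marker map in PLINK .map/.bim coordinates
#'
#' Base-pair positions are derived from genetic positions as
#' `round(pos_cm * 1e6 / bp_per_cm_scale)` and made 1-based.
#'
#' @param map A `marker_map`.
#' @param markers_only Drop QTL rows (the usual chip export).
#' @param bp_scale Divisor applied to cM*1e6 when deriving bp (default 1).
#' @return data.frame with columns `chr`, `id`, `cm`, `bp`.
#' @export
map_to_plink <- function(map, markers_only = TRUE, bp_scale = 1) {
  rows <- if (markers_only) marker_loci(map) else seq_len(nrow(map))
  data.frame(chr = map$chr[rows],
             id = map$id[rows],
             cm = map$pos_cm[rows],
             bp = pmax(1L, as.integer(round(map$pos_cm[rows] * 1e6 / bp_scale))),
             stringsAsFactors = FALSE)
}
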