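#' Binned Hi-C contact map
#'
#' A `contact_map` stores one symmetric cis matrix per chromosome together
#' with its bin table, a per-bin mask, and (after balancing) per-bin
#' correction weights. Trans contacts are kept only as a total count for QC
#' ratios; all analyses in this package are cis.
#'
#' @param bins Bin table (`chrom`, `start`, `end`), 0-based half-open.
#' @param matrices Named list (one per chromosome) of symmetric numeric
#'   matrices of raw counts (or derived values, see `unit`).
#' @param resolution Bin size in bp.
#' @param mask Logical vector, one per bin; masked bins carry no signal.
#' @param weights Optional per-bin balancing weights (`NA` for masked bins).
#' @param trans_total Total trans (inter-chromosomal) contact count.
#' @param unit `"counts"` for raw/balanceable counts, `"oe"` for
#'   observed-over-expected values.
#' @return Object of class `contact_map`.
#' @export
contact_map <- function(bins, matrices, resolution, mask = NULL,
                        weights = NULL, trans_total = 0, unit = "counts") {
  chroms <- unique(bins$chrom)
  check_that(setequal(names(matrices), chroms),
             "matrix names must match bin-table chromosomes")
  n_per <- table(factor(bins$chrom, levels = chroms))
  for (ch in chroms) {
    m <- matrices[[ch]]
    check_that(is.matrix(m) && nrow(m) == ncol(m) && nrow(m) == n_per[[ch]],
               "matrix for ", ch, " does not match its bin count")
  }
  mask <- mask %||% rep(FALSE, nrow(bins))
  structure(list(bins = bins, matrices = matrices[chroms],
                 resolution = resolution, mask = mask, weights = weights,
                 trans_total = trans_total, unit = unit),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map:", nrow(x$bins), "bins @", x$resolution, "bp,",
      length(x$matrices), "chromosome(s);",
      sum(x$mask), "masked;",
      if (is.null(x$weights)) "unbalanced" else "balanced",
      sprintf("[%s]\n", x$unit))
  invisible(x)
}

# global bin indices per chromosome, in bin-table order
cm_index <- function(map) {
  split(seq_len(nrow(map$bins)),
        factor(map$bins$chrom, levels = unique(map$bins$chrom)))
}

#' Balanced values for one chromosome
#'
#' Returns the corrected matrix `c_ij * w_i * w_j` with masked rows/columns
#' set to `NA`. For an O/E map the stored values are returned unchanged.
#'
#' @param map A [contact_map()].
#' @param chrom Chromosome name.
#' @return Symmetric numeric matrix.
#' @export
balanced_matrix <- function(map, chrom) {
  m <- map$matrices[[chrom]]
  check_that(!is.null(m), "unknown chromosome: ", chrom)
  idx <- cm_index(map)[[chrom]]
  if (map$unit == "oe") {
    out <- m
  } else {
    check_that(!is.null(map$weights),
               "map is not balanced; run ice_normalize() first")
    w <- map$weights[idx]
    wz <- ifelse(is.na(w), 0, w)
    out <- m * outer(wz, wz)
  }
  bad <- map$mask[idx]
  if (!is.null(map$weights)) bad <- bad | is.na(map$weights[idx])
  out[bad, ] <- NA_real_
  out[, bad] <- NA_real_
  out
}

#' Load a contact map from a sparse triplet file
#'
#' The triplet format is tab-separated text with columns
#' `chrom`, `bin_i_start`, `bin_j_start`, `count` (cis only). Duplicate
#' entries, including mirrored `(j, i)` pairs, are summed.
#'
#' @param triplet_file Path to the triplet TSV (no header).
#' @param genome A [genome_spec()] or path to a chrom.sizes file.
#' @param resolution Bin size in bp; triplet coordinates must be multiples.
#' @return A [contact_map()] of raw counts.
#' @export
load_matrix <- function(triplet_file, genome, resolution) {
  if (is.character(genome)) genome <- read_chrom_sizes(genome)
  bins <- genome_bins(genome, resolution)
  tab <- tryCatch(
    read.table(triplet_file, sep = "\t", header = FALSE,
               col.names = c("chrom", "start_i", "start_j", "count"),
               colClasses = c("character", "numeric", "numeric", "numeric")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL else stop(e)
    })
  idx <- cm_index0(bins)
  mats <- lapply(idx, function(i) {
    n <- length(i)
    matrix(0, n, n)
  })
  if (!is.null(tab) && nrow(tab) > 0) {
    lens <- stats::setNames(genome$chroms$length, genome$chroms$name)
    for (k in seq_len(nrow(tab))) {
      ch <- tab$chrom[k]
      si <- tab$start_i[k]; sj <- tab$start_j[k]
      if (!ch %in% names(lens))
        fail("line ", k, ": unknown chromosome '", ch, "'")
      if (si %% resolution != 0 || sj %% resolution != 0)
        fail("line ", k, ": coordinate not a multiple of ", resolution)
      if (si < 0 || sj < 0 || si >= lens[[ch]] || sj >= lens[[ch]])
        fail("line ", k, ": coordinate outside chromosome ", ch)
      i <- si %/% resolution + 1
      j <- sj %/% resolution + 1
      mats[[ch]][i, j] <- mats[[ch]][i, j] + tab$count[k]
      if (i != j) mats[[ch]][j, i] <- mats[[ch]][j, i] + tab$count[k]
    }
  }
  contact_map(bins, mats, resolution)
}

# index helper usable before a contact_map exists
cm_index0 <- function(bins) {
  split(seq_len(nrow(bins)),
        factor(bins$chrom, levels = unique(bins$chrom)))
}

#' Write a contact map as sparse triplets
#'
#' Upper-triangle (including diagonal) non-zero entries only, columns
#' `chrom`, `bin_i_start`, `bin_j_start`, `count`.
#'
#' @param map A [contact_map()].
#' @param path Output file.
#' @export
write_matrix <- function(map, path) {
  idx <- cm_index(map)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(map$matrices)) {
    m <- map$matrices[[ch]]
    starts <- map$bins$start[idx[[ch]]]
    keep <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    if (nrow(keep) == 0) next
    df <- data.frame(chrom = ch, i = starts[keep[, 1]], j = starts[keep[, 2]],
                     count = m[keep])
    df <- df[order(df$i, df$j), ]
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Mask blacklisted regions out of a contact map
#'
#' Any bin overlapping a blacklist region by at least 1 bp is added to the
#' mask and its matrix row and column are zeroed. Masking is idempotent.
#'
#' @param map A [contact_map()].
#' @param regions Blacklist intervals: data.frame (`chrom`, `start`, `end`,
#'   0-based half-open), a `GRanges`, or a path to a BED file.
#' @return The masked [contact_map()].
#' @export
apply_blacklist <- function(map, regions) {
  if (is.character(regions)) {
    gr <- rtracklayer::import(regions, format = "BED")
  } else if (is.data.frame(regions)) {
    if (nrow(regions) == 0) return(map)
    gr <- as_granges(regions)
  } else {
    gr <- regions
  }
  if (length(gr) == 0) return(map)
  hit <- IRanges::overlapsAny(as_granges(map$bins), gr)
  map$mask <- map$mask | hit
  idx <- cm_index(map)
  for (ch in names(map$matrices)) {
    local_bad <- which(map$mask[idx[[ch]]])
    if (length(local_bad)) {
      map$matrices[[ch]][local_bad, ] <- 0
      map$matrices[[ch]][, local_bad] <- 0
    }
  }
  if (!is.null(map$weights)) map$weights[map$mask] <- NA_real_
  map
}
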