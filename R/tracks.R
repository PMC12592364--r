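#' Binned genomic signal track
#'
#' A `binned_track` ties a per-bin numeric value (possibly missing) to a
#' fixed-resolution bin table, with a unit tag that enforces the
#' normalization order counts -> cpm -> log2_ratio -> zscore.
#'
#' @param bins Bin table (`chrom`, `start`, `end`), 0-based half-open.
#' @param value Numeric vector, one value per bin (`NA` = missing).
#' @param resolution Bin size in bp.
#' @param unit One of `"counts"`, `"cpm"`, `"log2_ratio"`, `"zscore"`,
#'   `"log2_cpm1"`, or a free-form tag (e.g. `"gc"`).
#' @return Object of class `binned_track`.
#' @export
binned_track <- function(bins, value, resolution, unit = "counts") {
  check_that(nrow(bins) == length(value),
             "value length must match the bin table")
  structure(list(bins = bins, value = as.numeric(value),
                 resolution = resolution, unit = unit),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat("binned_track:", nrow(x$bins), "bins @", x$resolution, "bp [",
      x$unit, "];", sum(is.na(x$value)), "missing\n")
  invisible(x)
}

#' @method as.data.frame binned_track
#' @export
as.data.frame.binned_track <- function(x, ...) {
  cbind(x$bins, value = x$value)
}

require_unit <- function(track, allowed, what) {
  check_that(track$unit %in% allowed,
             what, " needs a track with unit ",
             paste(allowed, collapse = "/"), ", got '", track$unit, "'")
}

same_bins <- function(a, b) {
  identical(a$bins$chrom, b$bins$chrom) &&
    identical(a$bins$start, b$bins$start)
}

track_chrom_split <- function(track) {
  split(seq_len(nrow(track$bins)),
        factor(track$bins$chrom, levels = unique(track$bins$chrom)))
}

#' Count fragments into fixed-size bins
#'
#' Each fragment is counted once, in the bin containing its midpoint
#' (`floor((start + end) / 2)`). Fragments whose midpoint falls outside a
#' known chromosome are skipped; the number of skips is attached as
#' attribute `skipped` and reported with a warning.
#'
#' @param fragments data.frame (`chrom`, `start`, `end`), 0-based half-open,
#'   or a path to a BED file.
#' @param genome A [genome_spec()].
#' @param resolution Bin size in bp (the study uses 100 bp or 1 kb).
#' @return A count [binned_track()].
#' @export
bin_fragments <- function(fragments, genome, resolution) {
  if (is.character(fragments)) {
    gr <- rtracklayer::import(fragments, format = "BED")
    fragments <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                            start = GenomicRanges::start(gr) - 1,
                            end = GenomicRanges::end(gr))
  }
  bins <- genome_bins(genome, resolution)
  counts <- numeric(nrow(bins))
  idx <- cm_index0(bins)
  lens <- stats::setNames(genome$chroms$length, genome$chroms$name)
  skipped <- 0L
  if (nrow(fragments) > 0) {
    mid <- (fragments$start + fragments$end) %/% 2
    known <- fragments$chrom %in% names(lens)
    inside <- known & mid >= 0 & mid < lens[fragments$chrom]
    skipped <- sum(!inside)
    if (skipped > 0)
      warning(skipped, " fragment(s) outside the genome were skipped")
    for (ch in unique(fragments$chrom[inside])) {
      sel <- inside & fragments$chrom == ch
      b <- mid[sel] %/% resolution + 1L
      tab <- tabulate(b, nbins = length(idx[[ch]]))
      counts[idx[[ch]]] <- counts[idx[[ch]]] + tab
    }
  }
  out <- binned_track(bins, counts, resolution, unit = "counts")
  attr(out, "skipped") <- skipped
  out
}

#' Aggregate a count track to a coarser resolution
#'
#' Counts are summed; a partial terminal bin sums whatever source bins
#' exist. Only count tracks may be re-binned (normalize after aggregating).
#'
#' @param track A count [binned_track()].
#' @param target Target resolution, a multiple of the source resolution.
#' @return A count [binned_track()] at `target` resolution.
#' @export
rebin <- function(track, target = 1e4) {
  require_unit(track, "counts", "rebin()")
  check_that(target %% track$resolution == 0,
             "`target` must be a multiple of the source resolution")
  if (target == track$resolution) return(track)
  idx <- track_chrom_split(track)
  pieces <- lapply(names(idx), function(ch) {
    gi <- idx[[ch]]
    g <- track$bins$start[gi] %/% target
    agg <- rowsum(track$value[gi], g)
    starts <- as.numeric(rownames(agg)) * target
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + target, max(track$bins$end[gi])),
               value = as.vector(agg))
  })
  df <- do.call(rbind, pieces)
  binned_track(df[c("chrom", "start", "end")], df$value, target,
               unit = "counts")
}

#' Counts-per-million normalization
#'
#' `value * 1e6 / total`, where `total` defaults to the track sum but can be
#' replaced by the library's total mapped-fragment count.
#'
#' @param track A count [binned_track()].
#' @param library_total Optional external total; default `sum(value)`.
#' @return A cpm [binned_track()].
#' @export
cpm_normalize <- function(track, library_total = NULL) {
  require_unit(track, "counts", "cpm_normalize()")
  total <- library_total %||% sum(track$value, na.rm = TRUE)
  check_that(total > 0, "library total is zero; cannot compute cpm")
  binned_track(track$bins, track$value * 1e6 / total, track$resolution,
               unit = "cpm")
}

#' Log2 IP-over-input ratio
#'
#' `log2(ip / input)` per bin; bins where either sample is zero or missing
#' become missing (zeros are treated as no-data, no pseudocount is added).
#'
#' @param ip,input cpm [binned_track()]s on identical bins.
#' @return A log2-ratio [binned_track()].
#' @export
log2_ip_over_input <- function(ip, input) {
  require_unit(ip, "cpm", "log2_ip_over_input()")
  require_unit(input, "cpm", "log2_ip_over_input()")
  check_that(same_bins(ip, input), "ip and input bins differ")
  r <- log2(ip$value / input$value)
  r[!is.finite(r)] <- NA_real_
  r[is.na(ip$value) | is.na(input$value) |
      ip$value == 0 | input$value == 0] <- NA_real_
  binned_track(ip$bins, r, ip$resolution, unit = "log2_ratio")
}

#' Per-chromosome z-score scaling
#'
#' Centers and scales each chromosome over its non-missing bins. Chromosomes
#' with fewer than two non-missing bins or zero variance become all-missing.
#' The transform is idempotent.
#'
#' @param track A [binned_track()] (cpm, log2-ratio, z-score or log2(cpm+1)).
#' @return A z-score [binned_track()].
#' @export
zscore_per_chromosome <- function(track) {
  require_unit(track, c("cpm", "log2_ratio", "zscore", "log2_cpm1"),
               "zscore_per_chromosome()")
  v <- track$value
  for (gi in track_chrom_split(track)) {
    x <- v[gi]
    ok <- !is.na(x)
    if (sum(ok) < 2 || stats::sd(x[ok]) == 0) {
      v[gi] <- NA_real_
    } else {
      v[gi] <- (x - mean(x[ok])) / stats::sd(x[ok])
    }
  }
  binned_track(track$bins, v, track$resolution, unit = "zscore")
}

#' Smooth over non-zero bins
#'
#' Considering only non-missing, non-zero bins in genomic order within each
#' chromosome, each such bin becomes the mean of itself and its
#' `(window-1)/2` non-zero neighbours on each side (truncated at chromosome
#' ends). Zero and missing bins are left untouched, so the zero set and the
#' number of non-zero bins are preserved.
#'
#' @param track A [binned_track()].
#' @param window Odd window length in non-zero bins (default 3).
#' @return A [binned_track()] with the same unit.
#' @export
smooth_nonzero <- function(track, window = 3) {
  check_that(is_count(window) && window %% 2 == 1, "`window` must be odd")
  half <- (window - 1) / 2
  v <- track$value
  for (gi in track_chrom_split(track)) {
    nz <- gi[!is.na(v[gi]) & v[gi] != 0]
    if (length(nz) == 0) next
    x <- v[nz]
    sm <- vapply(seq_along(x), function(j) {
      mean(x[max(1, j - half):min(length(x), j + half)])
    }, numeric(1))
    v[nz] <- sm
  }
  binned_track(track$bins, v, track$resolution, unit = track$unit)
}

#' RNA-seq display scale: log2(cpm + 1)
#'
#' @param track A count [binned_track()].
#' @param library_total Optional external total for the cpm step.
#' @return A [binned_track()] with unit `"log2_cpm1"`.
#' @export
rna_log_cpm <- function(track, library_total = NULL) {
  cpm <- cpm_normalize(track, library_total)
  binned_track(cpm$bins, log2(cpm$value + 1), cpm$resolution,
               unit = "log2_cpm1")
}

#' Read / write a track as bedGraph
#'
#' @param track A [binned_track()].
#' @param path File path.
#' @param drop_na Omit missing bins on export (bedGraph has no NA).
#' @return `read_bedgraph` returns a [binned_track()] on the genome's bins
#'   with missing values where the file has no interval.
#' @export
write_bedgraph <- function(track, path, drop_na = TRUE) {
  df <- as.data.frame(track)
  if (drop_na) df <- df[!is.na(df$value), ]
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end),
                               score = df$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @param genome A [genome_spec()] defining the bin frame.
#' @param resolution Bin size of the stored track.
#' @param unit Unit tag to attach.
#' @export
read_bedgraph <- function(path, genome, resolution, unit = "counts") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  bins <- genome_bins(genome, resolution)
  v <- rep(NA_real_, nrow(bins))
  key <- paste(bins$chrom, bins$start)
  got <- paste(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1)
  hit <- match(got, key)
  v[hit[!is.na(hit)]] <- gr$score[!is.na(hit)]
  binned_track(bins, v, resolution, unit = unit)
}
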