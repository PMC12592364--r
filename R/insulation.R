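#' Insulation score from a balanced contact map
#'
#' For bin `i`, the window mean is the mean balanced contact over all pairs
#' `(a, b)` with `i-w <= a < i < b <= i+w` (`w = window / resolution`), i.e.
#' the square of cells crossing the bin. The normalized score is
#' `log2(window mean / chromosome mean of window means)`. The score is
#' defined only where the full window fits inside the chromosome and at
#' least half of the window cells are unmasked; elsewhere it is `NA`.
#'
#' The log-ratio normalization makes the score invariant to global scaling
#' of the contact map.
#'
#' @param map A balanced [contact_map()], typically at 10 kb.
#' @param window Window size in bp (default 100 kb), a multiple of the
#'   resolution.
#' @param min_coverage Minimum fraction of unmasked window cells (default
#'   0.5).
#' @return Object of class `insulation_track`: `bins`, `window_mean`,
#'   `score`, `resolution`, `window`.
#' @export
insulation_score <- function(map, window = 1e5, min_coverage = 0.5) {
  check_that(window %% map$resolution == 0,
             "`window` must be a multiple of the map resolution")
  w <- window %/% map$resolution
  check_that(w >= 1, "`window` must be at least one bin")
  idx <- cm_index(map)
  raw <- rep(NA_real_, nrow(map$bins))
  for (ch in names(map$matrices)) {
    gi <- idx[[ch]]
    n <- length(gi)
    if (n < 2 * w + 1) next
    b <- balanced_matrix(map, ch)
    for (i in seq(w + 1, n - w)) {
      cells <- b[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
      ok <- !is.na(cells)
      if (mean(ok) < min_coverage) next
      raw[gi[i]] <- mean(cells[ok])
    }
    defined <- !is.na(raw[gi])
    if (any(defined)) {
      chrom_mean <- mean(raw[gi][defined])
      if (chrom_mean <= 0) raw[gi] <- NA_real_
    }
  }
  score <- rep(NA_real_, length(raw))
  for (ch in names(idx)) {
    gi <- idx[[ch]]
    defined <- !is.na(raw[gi])
    if (!any(defined)) next
    chrom_mean <- mean(raw[gi][defined])
    score[gi[defined]] <- log2(raw[gi][defined] / chrom_mean)
  }
  structure(list(bins = map$bins, window_mean = raw, score = score,
                 resolution = map$resolution, window = window),
            class = "insulation_track")
}

#' @export
print.insulation_track <- function(x, ...) {
  cat("insulation_track:", nrow(x$bins), "bins @", x$resolution,
      "bp, window", x$window, "bp;", sum(!is.na(x$score)), "scored\n")
  invisible(x)
}

# topographic prominence of local minima within one gap-free score vector;
# returns data.frame(pos, prominence) of candidate minima
local_minima_prominence <- function(x) {
  n <- length(x)
  if (n < 3) return(data.frame(pos = integer(), prominence = numeric()))
  is_min <- which(vapply(2:(n - 1), function(i) {
    x[i] < x[i - 1] && x[i] <= x[i + 1] ||
      x[i] <= x[i - 1] && x[i] < x[i + 1]
  }, logical(1))) + 1L
  # plateau handling: keep the first bin of any run of equal minima
  if (length(is_min) > 1)
    is_min <- is_min[c(TRUE, diff(is_min) > 1 |
                         x[is_min[-1]] != x[is_min[-length(is_min)]])]
  prom <- vapply(is_min, function(i) {
    side_col <- function(ids) {
      if (!length(ids)) return(Inf)
      deeper <- ids[x[ids] < x[i]]
      stretch <- if (length(deeper)) {
        d0 <- deeper[which.min(abs(deeper - i))]
        ids[(ids - i) * sign(d0 - i) > 0 & abs(ids - i) < abs(d0 - i)]
      } else ids
      if (!length(stretch)) return(0) else max(x[stretch]) - x[i]
    }
    left <- side_col(seq_len(i - 1))
    right <- side_col(if (i < n) (i + 1):n else integer())
    min(left, right)
  }, numeric(1))
  data.frame(pos = is_min, prominence = prom)
}

#' Call TAD borders from an insulation track
#'
#' Borders are local minima of the normalized insulation score whose
#' topographic prominence is at least `min_prominence` (log2 units).
#' Stretches of `NA` score split a chromosome into independent segments.
#' Output is ordered by genomic position.
#'
#' @param track An `insulation_track` from [insulation_score()].
#' @param min_prominence Minimum prominence in log2 units (default 0.2, a
#'   conservative level that yields no borders on flat maps).
#' @return data.frame with `chrom`, `start` (bp), `bin` (global bin index),
#'   `score`, `prominence`.
#' @export
call_borders <- function(track, min_prominence = 0.2) {
  idx <- cm_index0(track$bins)
  out <- list()
  for (ch in names(idx)) {
    gi <- idx[[ch]]
    s <- track$score[gi]
    runs <- rle(!is.na(s))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in seq_along(runs$values)) {
      if (!runs$values[k]) next
      seg <- starts[k]:ends[k]
      cand <- local_minima_prominence(s[seg])
      cand <- cand[cand$prominence >= min_prominence, , drop = FALSE]
      if (!nrow(cand)) next
      pos <- gi[seg[cand$pos]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = track$bins$start[pos], bin = pos,
        score = track$score[pos], prominence = cand$prominence)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      bin = integer(), score = numeric(),
                      prominence = numeric()))
  df <- do.call(rbind, out)
  df <- df[order(match(df$chrom, names(idx)), df$start), ]
  rownames(df) <- NULL
  df
}

#' Tolerance-based border overlap between two border sets
#'
#' A border in `borders_a` is matched if an unused border of `borders_b` on
#' the same chromosome lies within `tolerance` bp (inclusive, bin-start
#' distance). Matching is greedy nearest-first, each B border used at most
#' once, preventing double counting of clustered borders.
#'
#' @param borders_a,borders_b Border tables from [call_borders()] (any
#'   data.frame with `chrom` and `start` works).
#' @param tolerance Matching tolerance in bp (default 20 kb).
#' @return List with `fraction` (matched / |A|, `NA` if A is empty),
#'   `n_matched`, `n_a`, `n_b`, and `matches` (data.frame of paired
#'   positions).
#' @export
border_overlap <- function(borders_a, borders_b, tolerance = 2e4) {
  n_a <- nrow(borders_a); n_b <- nrow(borders_b)
  if (n_a == 0)
    return(list(fraction = NA_real_, n_matched = 0L, n_a = 0L, n_b = n_b,
                matches = data.frame(chrom = character(),
                                     start_a = numeric(),
                                     start_b = numeric())))
  used <- rep(FALSE, n_b)
  match_rows <- list()
  ord <- order(borders_a$chrom, borders_a$start)
  for (i in ord) {
    cand <- which(!used & borders_b$chrom == borders_a$chrom[i] &
                    abs(borders_b$start - borders_a$start[i]) <= tolerance)
    if (!length(cand)) next
    j <- cand[which.min(abs(borders_b$start[cand] - borders_a$start[i]))]
    used[j] <- TRUE
    match_rows[[length(match_rows) + 1L]] <- data.frame(
      chrom = borders_a$chrom[i], start_a = borders_a$start[i],
      start_b = borders_b$start[j])
  }
  matches <- if (length(match_rows)) do.call(rbind, match_rows) else
    data.frame(chrom = character(), start_a = numeric(),
               start_b = numeric())
  list(fraction = nrow(matches) / n_a, n_matched = nrow(matches),
       n_a = n_a, n_b = n_b, matches = matches)
}
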