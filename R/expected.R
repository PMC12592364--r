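#' Distance-decay expected profile per chromosome arm
#'
#' For every arm and bin distance `d`, the expected value `E(d)` is the mean
#' balanced contact over all pairs of non-masked bins at that distance within
#' the arm. If `arms` is `NULL` each chromosome is one arm.
#'
#' @param map A balanced [contact_map()].
#' @param arms Optional arm intervals (`chrom`, `start`, `end`), e.g. from
#'   [genome_arms()].
#' @return Object of class `expected_profile`: a table with columns `arm`,
#'   `chrom`, `d` (bin distance), `sum`, `count`, `expected`.
#' @export
expected_cis <- function(map, arms = NULL) {
  arms <- normalize_arms(map, arms)
  idx <- cm_index(map)
  rows <- list()
  for (a in seq_len(nrow(arms))) {
    ch <- arms$chrom[a]
    gi <- idx[[ch]]
    loc <- which(map$bins$start[gi] >= arms$start[a] &
                   map$bins$start[gi] < arms$end[a])
    if (length(loc) < 2) {
      warning("arm ", arms$arm[a], " shorter than 2 bins; skipped")
      next
    }
    b <- balanced_matrix(map, ch)[loc, loc, drop = FALSE]
    n <- length(loc)
    for (d in seq_len(n - 1)) {
      i <- seq_len(n - d)
      vals <- b[cbind(i, i + d)]
      ok <- !is.na(vals)
      rows[[length(rows) + 1L]] <-
        data.frame(arm = arms$arm[a], chrom = ch, d = d,
                   sum = sum(vals[ok]), count = sum(ok),
                   expected = if (any(ok)) mean(vals[ok]) else NA_real_)
    }
  }
  structure(list(table = do.call(rbind, rows), arms = arms,
                 resolution = map$resolution),
            class = "expected_profile")
}

normalize_arms <- function(map, arms) {
  if (is.null(arms)) {
    chroms <- unique(map$bins$chrom)
    arms <- data.frame(
      chrom = chroms,
      start = vapply(chroms, function(ch)
        min(map$bins$start[map$bins$chrom == ch]), numeric(1)),
      end = vapply(chroms, function(ch)
        max(map$bins$end[map$bins$chrom == ch]), numeric(1)))
  }
  if (is.null(arms$arm))
    arms$arm <- paste0(arms$chrom, "_", seq_len(nrow(arms)))
  arms
}

#' Observed-over-expected map
#'
#' Divides balanced contacts by the arm's expected value at the same bin
#' distance. Entries are `NA` on the diagonal, for masked bins, outside any
#' arm (including cross-arm pairs), and where `E(d) = 0`.
#'
#' @param map A balanced [contact_map()].
#' @param expected An `expected_profile` from [expected_cis()] computed on a
#'   compatible map.
#' @return A [contact_map()] with `unit = "oe"`.
#' @export
observed_over_expected <- function(map, expected) {
  check_that(inherits(expected, "expected_profile"),
             "`expected` must come from expected_cis()")
  check_that(expected$resolution == map$resolution,
             "expected profile resolution does not match the map")
  idx <- cm_index(map)
  arms <- expected$arms
  oe_mats <- lapply(map$matrices, function(m) {
    out <- m
    out[] <- NA_real_
    out
  })
  for (a in seq_len(nrow(arms))) {
    ch <- arms$chrom[a]
    gi <- idx[[ch]]
    loc <- which(map$bins$start[gi] >= arms$start[a] &
                   map$bins$start[gi] < arms$end[a])
    if (length(loc) < 2) next
    b <- balanced_matrix(map, ch)[loc, loc, drop = FALSE]
    etab <- expected$table[expected$table$arm == arms$arm[a], ]
    ed <- rep(NA_real_, max(etab$d))
    ed[etab$d] <- etab$expected
    n <- length(loc)
    for (d in seq_len(n - 1)) {
      e <- ed[d]
      if (is.na(e) || e == 0) next
      i <- seq_len(n - d)
      vals <- b[cbind(i, i + d)] / e
      oe_mats[[ch]][cbind(loc[i], loc[i + d])] <- vals
      oe_mats[[ch]][cbind(loc[i + d], loc[i])] <- vals
    }
  }
  contact_map(map$bins, oe_mats, map$resolution, mask = map$mask,
              weights = NULL, trans_total = map$trans_total, unit = "oe")
}

#' Contact-frequency decay curve P(s)
#'
#' Balanced contact frequency as a function of genomic separation, computed
#' per arm, aggregated across arms by pair-count weighting, and smoothed into
#' log-spaced distance bins.
#'
#' @param map A balanced [contact_map()].
#' @param arms Optional arm intervals as in [expected_cis()].
#' @param points_per_decade Number of log-spaced distance bins per decade.
#' @return Object of class `ps_curve`: data.frame with columns `s` (bp),
#'   `ps` (mean frequency), `count`.
#' @export
ps_curve <- function(map, arms = NULL, points_per_decade = 8) {
  exp_prof <- expected_cis(map, arms)
  tab <- exp_prof$table
  agg_sum <- tapply(tab$sum, tab$d, sum)
  agg_n <- tapply(tab$count, tab$d, sum)
  d <- as.numeric(names(agg_sum))
  s <- d * map$resolution
  lb <- floor(log10(s) * points_per_decade)
  out <- do.call(rbind, lapply(split(seq_along(s), lb), function(k) {
    n <- sum(agg_n[k])
    data.frame(
      s = exp(stats::weighted.mean(log(s[k]), pmax(agg_n[k], 1))),
      ps = if (n > 0) sum(agg_sum[k]) / n else NA_real_,
      count = n)
  }))
  out <- out[order(out$s), ]
  rownames(out) <- NULL
  class(out) <- c("ps_curve", "data.frame")
  out
}

#' Fit the log-log slope of a P(s) curve
#'
#' Ordinary least squares of `log(P)` on `log(s)` over a distance window,
#' used to recover the decay exponent.
#'
#' @param ps A [ps_curve()].
#' @param s_range Distance window in bp (inclusive).
#' @return Slope (dimensionless).
#' @export
ps_slope <- function(ps, s_range = c(2e5, 5e6)) {
  keep <- ps$s >= s_range[1] & ps$s <= s_range[2] &
    is.finite(ps$ps) & ps$ps > 0
  check_that(sum(keep) >= 3, "too few P(s) points in the fitting window")
  stats::coef(stats::lm(log(ps$ps[keep]) ~ log(ps$s[keep])))[[2]]
}

#' Short-range, long-range and trans contact totals
#'
#' Classifies cis contacts by the distance between bin start coordinates:
#' `<= threshold` is short-range (inclusive), otherwise long-range. Trans
#' contacts are the stored inter-chromosomal total. The cis/trans ratio is
#' flagged undefined when no trans contacts exist.
#'
#' @param map A [contact_map()] of raw counts.
#' @param threshold Short-range cutoff in bp (default 20 kb, inclusive).
#' @return List with `short_cis`, `long_cis`, `trans`, `cis_trans` and
#'   `undefined` (logical).
#' @export
cis_trans_ratio <- function(map, threshold = 2e4) {
  check_that(map$unit == "counts", "needs a counts map")
  short <- 0; long <- 0
  for (ch in names(map$matrices)) {
    m <- map$matrices[[ch]]
    n <- nrow(m)
    ut <- upper.tri(m, diag = TRUE)
    dmat <- (col(m) - row(m)) * map$resolution
    short <- short + sum(m[ut & dmat <= threshold])
    long <- long + sum(m[ut & dmat > threshold])
  }
  trans <- map$trans_total
  list(short_cis = short, long_cis = long, trans = trans,
       cis_trans = if (trans > 0) (short + long) / trans else Inf,
       undefined = trans == 0)
}

#' Differential (log2 ratio) contact map
#'
#' Coarsens the balanced values of two maps to `resolution` by summation and
#' returns the per-entry `log2(B/A)`. Entries zero or missing in either map
#' are `NA`; the result is antisymmetric under swapping the two maps.
#'
#' @param map_a,map_b Balanced [contact_map()]s on identical bins.
#' @param resolution Target resolution in bp (default 1 Mb).
#' @return List of class `diff_map` with coarse `bins`, per-chromosome
#'   `matrices` of log2 ratios, and `resolution`.
#' @export
differential_map <- function(map_a, map_b, resolution = 1e6) {
  check_that(identical(map_a$bins, map_b$bins), "bin tables differ")
  check_that(resolution %% map_a$resolution == 0,
             "`resolution` must be a multiple of the map resolution")
  idx <- cm_index(map_a)
  out_mats <- list()
  out_bins <- list()
  for (ch in names(map_a$matrices)) {
    gi <- idx[[ch]]
    g <- map_a$bins$start[gi] %/% resolution
    grp <- factor(g, levels = sort(unique(g)))
    coarsen <- function(map) {
      b <- balanced_matrix(map, ch)
      b[is.na(b)] <- 0
      t(rowsum(t(rowsum(b, grp)), grp))
    }
    ca <- coarsen(map_a)
    cb <- coarsen(map_b)
    r <- log2(cb / ca)
    r[ca == 0 | cb == 0] <- NA_real_
    out_mats[[ch]] <- r
    starts <- as.numeric(levels(grp)) * resolution
    out_bins[[ch]] <- data.frame(
      chrom = ch, start = starts,
      end = pmin(starts + resolution, max(map_a$bins$end[gi])))
  }
  structure(list(bins = do.call(rbind, out_bins), matrices = out_mats,
                 resolution = resolution),
            class = "diff_map")
}
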