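#' A/B compartment eigenvector track
#'
#' Per-bin first eigenvector (EV1) of the per-chromosome O/E correlation
#' matrix, scaled by the square root of its eigenvalue and sign-oriented by
#' GC content. Labels: `A` where EV1 > 0, `B` where EV1 < 0, `NA` where the
#' bin is masked or EV1 is undefined or exactly 0.
#'
#' @param oe_map An O/E [contact_map()] (see [observed_over_expected()]),
#'   typically at 50 kb.
#' @param gc GC-content [binned_track()] on the same bins, used only to
#'   orient the eigenvector sign (correlation with GC made non-negative).
#' @return Object of class `compartment_track` with `bins`, `ev1`,
#'   `resolution`.
#' @export
compute_ev1 <- function(oe_map, gc) {
  check_that(oe_map$unit == "oe", "`oe_map` must be an O/E map")
  check_that(identical(oe_map$bins$start, gc$bins$start) &&
               identical(oe_map$bins$chrom, gc$bins$chrom),
             "GC track bins do not match the map")
  idx <- cm_index(oe_map)
  ev <- rep(NA_real_, nrow(oe_map$bins))
  for (ch in names(oe_map$matrices)) {
    gi <- idx[[ch]]
    o <- oe_map$matrices[[ch]]
    usable <- !oe_map$mask[gi] & colSums(is.finite(o)) > 0
    if (sum(usable) < 10) {
      warning("chromosome ", ch, " has fewer than 10 usable bins; EV1 is NA")
      next
    }
    sub <- o[usable, usable, drop = FALSE]
    cc <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    cc[!is.finite(cc)] <- 0
    # double-centre before decomposition
    cc <- cc - rowMeans(cc)
    cc <- sweep(cc, 2, colMeans(cc))
    eg <- eigen(cc, symmetric = TRUE)
    k <- which.max(abs(eg$values))
    v <- eg$vectors[, k] * sqrt(abs(eg$values[k]))
    r <- suppressWarnings(stats::cor(v, gc$value[gi][usable],
                                     use = "complete.obs"))
    if (is.finite(r) && r < 0) v <- -v
    ev[gi[usable]] <- v
  }
  structure(list(bins = oe_map$bins, ev1 = ev,
                 resolution = oe_map$resolution),
            class = "compartment_track")
}

#' @export
print.compartment_track <- function(x, ...) {
  lab <- compartment_labels(x)
  cat("compartment_track:", nrow(x$bins), "bins @", x$resolution, "bp;",
      sum(lab == "A", na.rm = TRUE), "A,",
      sum(lab == "B", na.rm = TRUE), "B,", sum(is.na(lab)), "NA\n")
  invisible(x)
}

#' Per-bin compartment labels
#'
#' @param track A `compartment_track`.
#' @return Character vector: `"A"`, `"B"` or `NA` per bin.
#' @export
compartment_labels <- function(track) {
  ifelse(is.na(track$ev1) | track$ev1 == 0, NA_character_,
         ifelse(track$ev1 > 0, "A", "B"))
}

#' Segment a compartment track into A/B domains
#'
#' Domains are maximal runs of bins with the same EV1 sign; NA bins break
#' runs and never belong to a domain.
#'
#' @param track A `compartment_track`.
#' @return data.frame with `chrom`, `start`, `end`, `sign` (`"A"`/`"B"`),
#'   `size` (bp) and `n_bins`.
#' @export
call_domains <- function(track) {
  lab <- compartment_labels(track)
  idx <- cm_index0(track$bins)
  out <- list()
  for (ch in names(idx)) {
    gi <- idx[[ch]]
    l <- lab[gi]
    key <- ifelse(is.na(l), "NA", l)
    r <- rle(key)
    stop_at <- cumsum(r$lengths)
    start_at <- stop_at - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] == "NA") next
      b1 <- gi[start_at[k]]; b2 <- gi[stop_at[k]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = track$bins$start[b1], end = track$bins$end[b2],
        sign = r$values[k],
        size = track$bins$end[b2] - track$bins$start[b1],
        n_bins = r$lengths[k])
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), sign = character(), size = numeric(),
                      n_bins = integer()))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Concordant compartment-switch classification
#'
#' A bin is called `A-to-B` only if EV1 is positive in the baseline and
#' negative in the perturbed condition in *both* replicate cell lines
#' (`B-to-A` symmetrically). Any missing or exactly-zero EV1 among the four
#' tracks makes the bin `NA`; discordant changes count as `unchanged`. The
#' genome proportion switching is computed over non-NA bins.
#'
#' @param wt_line1,ko_line1,wt_line2,ko_line2 `compartment_track`s on
#'   identical bins (baseline/perturbed for each of the two lines).
#' @return Object of class `switch_call`: `labels` (per-bin character),
#'   `counts`, `proportion` (switching / non-NA), `n_informative`.
#' @export
classify_switch_bins <- function(wt_line1, ko_line1, wt_line2, ko_line2) {
  tracks <- list(wt_line1, ko_line1, wt_line2, ko_line2)
  for (t in tracks[-1])
    check_that(identical(t$bins$start, tracks[[1]]$bins$start) &&
                 identical(t$bins$chrom, tracks[[1]]$bins$chrom),
               "the four tracks must share one bin table")
  s <- vapply(tracks, function(t)
    ifelse(is.na(t$ev1) | t$ev1 == 0, NA_real_, sign(t$ev1)),
    numeric(nrow(tracks[[1]]$bins)))
  any_na <- apply(is.na(s), 1, any)
  ab <- !any_na & s[, 1] > 0 & s[, 2] < 0 & s[, 3] > 0 & s[, 4] < 0
  ba <- !any_na & s[, 1] < 0 & s[, 2] > 0 & s[, 3] < 0 & s[, 4] > 0
  labels <- ifelse(any_na, NA_character_,
                   ifelse(ab, "A-to-B", ifelse(ba, "B-to-A", "unchanged")))
  n_inf <- sum(!any_na)
  counts <- c(`A-to-B` = sum(ab), `B-to-A` = sum(ba),
              unchanged = n_inf - sum(ab) - sum(ba), `NA` = sum(any_na))
  structure(list(labels = labels, counts = counts,
                 proportion = if (n_inf > 0) (sum(ab) + sum(ba)) / n_inf
                 else NA_real_,
                 n_informative = n_inf),
            class = "switch_call")
}

#' @export
print.switch_call <- function(x, ...) {
  cat("switch_call:", paste(names(x$counts), x$counts, collapse = ", "),
      sprintf("; %.2f%% of informative bins switch\n", 100 * x$proportion))
  invisible(x)
}

#' Saddle analysis of compartmentalization strength
#'
#' Bins are ranked by EV1 and split into `n_quantiles` equal-count groups
#' (ties broken deterministically by genomic order). Per arm, the mean O/E
#' is accumulated for every group pair and aggregated genome-wide weighted
#' by pair counts. The grid runs from the lowest (most strongly B) to the
#' highest (most strongly A) EV1 percentile.
#'
#' @param oe_map An O/E [contact_map()].
#' @param track A `compartment_track` on the same bins.
#' @param n_quantiles Grid size (default 50).
#' @param arms Optional arm intervals as in [expected_cis()].
#' @param trim Optional EV1 quantile range `c(lo, hi)` to keep, e.g.
#'   `c(0.01, 0.99)`; default no trimming.
#' @return Object of class `saddle_matrix`: `mean`, `count` and `se`
#'   matrices plus `n_quantiles`.
#' @export
saddle <- function(oe_map, track, n_quantiles = 50, arms = NULL,
                   trim = NULL) {
  check_that(oe_map$unit == "oe", "`oe_map` must be an O/E map")
  check_that(identical(oe_map$bins$start, track$bins$start),
             "track bins do not match the map")
  ev <- track$ev1
  usable <- !is.na(ev) & !oe_map$mask
  if (!is.null(trim)) {
    qs <- stats::quantile(ev[usable], trim)
    usable <- usable & ev >= qs[1] & ev <= qs[2]
  }
  n <- sum(usable)
  check_that(n >= n_quantiles, "fewer usable bins (", n,
             ") than quantiles (", n_quantiles, ")")
  q <- rep(NA_integer_, length(ev))
  ord <- which(usable)[order(ev[usable], which(usable))]
  q[ord] <- as.integer(floor((seq_along(ord) - 1) * n_quantiles /
                               length(ord)) + 1)
  arms <- normalize_arms(oe_map, arms)
  idx <- cm_index(oe_map)
  nq <- n_quantiles
  acc_sum <- matrix(0, nq, nq)
  acc_sq <- matrix(0, nq, nq)
  acc_n <- matrix(0, nq, nq)
  for (a in seq_len(nrow(arms))) {
    ch <- arms$chrom[a]
    gi <- idx[[ch]]
    loc <- gi[oe_map$bins$start[gi] >= arms$start[a] &
                oe_map$bins$start[gi] < arms$end[a]]
    if (length(loc) < 2) next
    o <- oe_map$matrices[[ch]][loc - gi[1] + 1, loc - gi[1] + 1,
                               drop = FALSE]
    qv <- q[loc]
    ut <- which(upper.tri(o), arr.ind = TRUE)
    qi <- qv[ut[, 1]]; qj <- qv[ut[, 2]]
    vals <- o[ut]
    keep <- is.finite(vals) & !is.na(qi) & !is.na(qj)
    if (!any(keep)) next
    lo <- pmin(qi[keep], qj[keep])
    hi <- pmax(qi[keep], qj[keep])
    key <- (lo - 1) * nq + hi
    v <- vals[keep]
    scatter <- function(agg) {
      out <- numeric(nq * nq)
      out[as.integer(rownames(agg))] <- agg[, 1]
      matrix(out, nq, nq, byrow = TRUE)
    }
    acc_sum <- acc_sum + scatter(rowsum(v, key))
    acc_sq <- acc_sq + scatter(rowsum(v^2, key))
    acc_n <- acc_n + scatter(rowsum(rep(1, length(v)), key))
  }
  # accumulated into the upper triangle (lo, hi); symmetrize
  sym <- function(m) {
    lt <- lower.tri(m)
    m[lt] <- t(m)[lt]
    m
  }
  acc_sum <- sym(acc_sum); acc_sq <- sym(acc_sq); acc_n <- sym(acc_n)
  mean_m <- ifelse(acc_n > 0, acc_sum / acc_n, NA_real_)
  var_m <- ifelse(acc_n > 1, (acc_sq / acc_n - mean_m^2) * acc_n /
                    (acc_n - 1), NA_real_)
  se_m <- sqrt(var_m / acc_n)
  structure(list(mean = mean_m, count = acc_n, se = se_m,
                 n_quantiles = nq),
            class = "saddle_matrix")
}

#' Differential saddle: log2 ratio of two saddle grids
#'
#' @param saddle_a,saddle_b `saddle_matrix` objects with the same grid size
#'   (typically baseline and perturbed conditions).
#' @return Matrix of `log2(B/A)`; cells empty in either grid are `NA`.
#' @export
differential_saddle <- function(saddle_a, saddle_b) {
  check_that(saddle_a$n_quantiles == saddle_b$n_quantiles,
             "saddle grids differ in size")
  r <- log2(saddle_b$mean / saddle_a$mean)
  r[saddle_a$count == 0 | saddle_b$count == 0 |
      !is.finite(saddle_a$mean) | !is.finite(saddle_b$mean)] <- NA_real_
  r
}

#' Corner means of a saddle grid
#'
#' Count-weighted means of the k-by-k corners: `BB` (lowest percentiles),
#' `AA` (highest), and `AB` (off-diagonal corner), the standard summary of
#' compartmentalization strength.
#'
#' @param sdl A `saddle_matrix`.
#' @param k Corner size (default 5).
#' @return Named list `AA`, `BB`, `AB`.
#' @export
saddle_corners <- function(sdl, k = 5) {
  nq <- sdl$n_quantiles
  lo <- seq_len(k)
  hi <- seq(nq - k + 1, nq)
  wmean <- function(i, j) {
    m <- sdl$mean[i, j, drop = FALSE]
    w <- sdl$count[i, j, drop = FALSE]
    ok <- is.finite(m) & w > 0
    sum(m[ok] * w[ok]) / sum(w[ok])
  }
  list(AA = wmean(hi, hi), BB = wmean(lo, lo), AB = wmean(lo, hi))
}

#' Stack a signal track over compartment domains
#'
#' One row per domain, centred at the domain midpoint and extending
#' `flank` bp each side at the track's resolution; rows are sorted by
#' domain size, largest first. Cells outside the chromosome are missing.
#'
#' @param domains Domain table from [call_domains()].
#' @param track A [binned_track()] (typically 10 kb enrichment).
#' @param flank Flank in bp each side of the midpoint (default 2.5 Mb).
#' @param min_size Optional minimum domain size in bp.
#' @return A `stackup` object (see [stackup()]) with domain signs attached.
#' @export
domain_enrichment_stack <- function(domains, track, flank = 2.5e6,
                                    min_size = NULL) {
  if (!is.null(min_size)) domains <- domains[domains$size >= min_size, ]
  ids <- if (nrow(domains)) paste0(domains$sign, "_",
                                   seq_len(nrow(domains))) else character()
  centers <- data.frame(chrom = domains$chrom,
                        mid = (domains$start + domains$end) %/% 2,
                        size = domains$size, id = ids,
                        class = domains$sign)
  build_stackup(track, centers, flank)
}

# shared stack-up engine: centers has chrom, mid (bp), size, id, class
build_stackup <- function(track, centers, flank) {
  check_that(flank %% track$resolution == 0,
             "`flank` must be a multiple of the track resolution")
  idx <- track_chrom_split(track)
  known <- centers$chrom %in% names(idx)
  if (any(!known)) {
    warning(sum(!known), " site(s) on unknown chromosomes were skipped")
    centers <- centers[known, ]
  }
  f <- flank %/% track$resolution
  offs <- -f:f
  vals <- matrix(NA_real_, nrow(centers), length(offs))
  for (r in seq_len(nrow(centers))) {
    gi <- idx[[centers$chrom[r]]]
    cbin <- centers$mid[r] %/% track$resolution + 1L
    pos <- cbin + offs
    ok <- pos >= 1 & pos <= length(gi)
    vals[r, ok] <- track$value[gi[pos[ok]]]
  }
  ord <- order(-centers$size, centers$chrom, centers$mid)
  structure(list(values = vals[ord, , drop = FALSE],
                 sizes = centers$size[ord], ids = centers$id[ord],
                 class = centers$class[ord],
                 positions = offs * track$resolution,
                 resolution = track$resolution, flank = flank),
            class = "stackup")
}

#' @export
print.stackup <- function(x, ...) {
  cat("stackup:", nrow(x$values), "rows x", ncol(x$values),
      "positions (±", x$flank, "bp @", x$resolution, "bp)\n")
  invisible(x)
}
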