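#' Genomic site interval set
#'
#' Site sets hold the interval classes analysed at site level (e.g. blurred
#' and buried early-replication initiation zones, or their randomized
#' controls) as 0-based half-open intervals with unique ids and one class
#' label per set.
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally `id`.
#' @param class Class label for the whole set (e.g. `"blurred"`,
#'   `"buried"`, `"random"`, `"peak"`).
#' @return data.frame of class `site_set` with columns `chrom`, `start`,
#'   `end`, `id`, `class`.
#' @export
site_set <- function(df, class = "random") {
  check_that(all(c("chrom", "start", "end") %in% names(df)),
             "site table needs chrom/start/end")
  check_that(all(df$start < df$end), "site start must be < end")
  if (is.null(df$id))
    df$id <- if (nrow(df)) paste0(class, "_", seq_len(nrow(df))) else
      character()
  check_that(!anyDuplicated(df$id), "site ids must be unique")
  out <- data.frame(chrom = as.character(df$chrom), start = df$start,
                    end = df$end, id = as.character(df$id),
                    class = rep(class, nrow(df)), stringsAsFactors = FALSE)
  class(out) <- c("site_set", "data.frame")
  out
}

#' Read / write site intervals as BED-like text
#'
#' Tab-separated, no header: chrom, start, end, id (column 4), class
#' (column 5).
#'
#' @param path File path.
#' @return `read_sites` returns a [site_set()].
#' @export
read_sites <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "id", "class"),
                    colClasses = c("character", "numeric", "numeric",
                                   "character", "character"))
  cls <- unique(tab$class)
  check_that(length(cls) == 1, "site file mixes classes: ",
             paste(cls, collapse = ", "))
  site_set(tab[c("chrom", "start", "end", "id")], class = cls)
}

#' @rdname read_sites
#' @param sites A [site_set()].
#' @export
write_sites <- function(sites, path) {
  write.table(as.data.frame(sites)[c("chrom", "start", "end", "id",
                                     "class")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Stack a signal track over site midpoints
#'
#' One row per site, centred at the site midpoint (snapped to its
#' containing bin) and extending `flank` bp each side; rows sorted by site
#' size, largest first. Cells beyond the chromosome ends are missing; sites
#' on chromosomes absent from the track are skipped with a warning.
#'
#' @param track A [binned_track()] (typically 10 kb enrichment).
#' @param sites A [site_set()].
#' @param flank Flank in bp (default 0.5 Mb), a multiple of the track
#'   resolution.
#' @return A `stackup` object: `values` (site x position matrix), `sizes`,
#'   `ids`, `positions` (bp offsets from the midpoint).
#' @export
stackup <- function(track, sites, flank = 5e5) {
  centers <- data.frame(chrom = sites$chrom,
                        mid = (sites$start + sites$end) %/% 2,
                        size = sites$end - sites$start,
                        id = sites$id, class = sites$class)
  build_stackup(track, centers, flank)
}

#' Position-wise mean profile of a stack-up
#'
#' Mean over rows whose site size falls inside `size_window` (inclusive),
#' ignoring missing cells.
#'
#' @param stack A `stackup` from [stackup()] or
#'   [domain_enrichment_stack()].
#' @param size_window Size window in bp (default 60-160 kb); `NULL` keeps
#'   all rows.
#' @return data.frame with `position` (bp from centre) and `mean`; the
#'   number of contributing rows is attached as attribute `n_rows`.
#' @export
mean_profile <- function(stack, size_window = c(6e4, 1.6e5)) {
  keep <- if (is.null(size_window)) rep(TRUE, length(stack$sizes)) else
    stack$sizes >= size_window[1] & stack$sizes <= size_window[2]
  if (!any(keep)) {
    warning("no rows fall inside the size window")
    out <- data.frame(position = numeric(), mean = numeric())
    attr(out, "n_rows") <- 0L
    return(out)
  }
  m <- stack$values[keep, , drop = FALSE]
  out <- data.frame(position = stack$positions,
                    mean = colMeans(m, na.rm = TRUE))
  attr(out, "n_rows") <- sum(keep)
  rownames(out) <- NULL
  out
}

# EV1 replicated onto a finer bin grid (piecewise-constant)
rebin_ev1 <- function(ev, target = 1e4) {
  g <- truth_genome(list(bins = ev$bins))
  bins <- genome_bins(g, target)
  parent <- match(
    paste(bins$chrom, (bins$start %/% ev$resolution) * ev$resolution),
    paste(ev$bins$chrom, ev$bins$start))
  binned_track(bins, ev$ev1[parent], target, unit = "ev1")
}

#' Mean EV1 value per site
#'
#' The 50 kb EV1 signal is replicated onto 10 kb bins (piecewise-constant,
#' no interpolation) and averaged over each site's overlapping bins. Sites
#' whose defined-bin fraction falls below `min_defined_frac` are `NA`
#' (masked-region filter); a site with no defined bins is always `NA`.
#'
#' @param ev A `compartment_track` (typically 50 kb).
#' @param sites A [site_set()].
#' @param target Fine bin size for replication (default 10 kb).
#' @param min_defined_frac Minimum fraction of a site's bins with defined
#'   EV1 (default 0.5).
#' @return Numeric vector of per-site means, named by site id.
#' @export
site_mean_ev1 <- function(ev, sites, target = 1e4, min_defined_frac = 0.5) {
  fine <- rebin_ev1(ev, target)
  hits <- GenomicRanges::findOverlaps(as_granges(sites),
                                      as_granges(fine$bins))
  out <- stats::setNames(rep(NA_real_, nrow(sites)), sites$id)
  for (k in seq_len(nrow(sites))) {
    b <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == k]
    if (!length(b)) next
    v <- fine$value[b]
    frac <- mean(!is.na(v))
    if (frac == 0 || frac < min_defined_frac) next
    out[k] <- mean(v, na.rm = TRUE)
  }
  out
}

#' Quadrant classification of per-site compartment changes
#'
#' Classifies each site by the signs of its mean EV1 in two conditions:
#' `(+, -)` is `A-to-B` (the lower-right quadrant of a condition-1 vs
#' condition-2 scatter), `(-, +)` is `B-to-A` (upper left), `(+, +)`
#' `A-stable`, `(-, -)` `B-stable`; a zero or missing value in either
#' condition gives `NA`.
#'
#' @param mean_ev_cond1,mean_ev_cond2 Paired per-site mean EV1 values.
#' @return Object of class `quadrant_result`: `labels`, `proportions`
#'   (over non-NA sites, summing to 1), `switch_proportion`
#'   (A-to-B + B-to-A), `n_informative`.
#' @export
quadrant_classify <- function(mean_ev_cond1, mean_ev_cond2) {
  check_that(length(mean_ev_cond1) == length(mean_ev_cond2),
             "unpaired sites: condition vectors differ in length")
  s1 <- ifelse(is.na(mean_ev_cond1) | mean_ev_cond1 == 0, NA_real_,
               sign(mean_ev_cond1))
  s2 <- ifelse(is.na(mean_ev_cond2) | mean_ev_cond2 == 0, NA_real_,
               sign(mean_ev_cond2))
  lab <- rep(NA_character_, length(s1))
  ok <- !is.na(s1) & !is.na(s2)
  lab[ok & s1 > 0 & s2 < 0] <- "A-to-B"
  lab[ok & s1 < 0 & s2 > 0] <- "B-to-A"
  lab[ok & s1 > 0 & s2 > 0] <- "A-stable"
  lab[ok & s1 < 0 & s2 < 0] <- "B-stable"
  lev <- c("A-to-B", "B-to-A", "A-stable", "B-stable")
  cnt <- table(factor(lab, levels = lev))
  n <- sum(ok)
  props <- if (n > 0) as.numeric(cnt) / n else rep(NA_real_, 4)
  names(props) <- lev
  structure(list(labels = lab, proportions = props,
                 switch_proportion = unname(props["A-to-B"] +
                                              props["B-to-A"]),
                 n_informative = n),
            class = "quadrant_result")
}

#' @export
print.quadrant_result <- function(x, ...) {
  cat("quadrant_result:", x$n_informative, "informative sites;",
      paste(sprintf("%s %.1f%%", names(x$proportions),
                    100 * x$proportions), collapse = ", "), "\n")
  invisible(x)
}

#' Cross-line summary of quadrant proportions
#'
#' Mean and standard deviation of the quadrant proportions across replicate
#' cell lines.
#'
#' @param results List of `quadrant_result`s, one per cell line.
#' @return data.frame with `label`, `mean`, `sd`.
#' @export
cross_line_quadrants <- function(results) {
  mat <- vapply(results, function(r) r$proportions, numeric(4))
  data.frame(label = rownames(mat),
             mean = rowMeans(mat),
             sd = apply(mat, 1, stats::sd),
             row.names = NULL)
}

#' Size- (and compartment-) matched randomized control sites
#'
#' Generates a control set with exactly the same multiset of lengths as
#' `sites`, placed uniformly over the unmasked genome (chromosomes chosen
#' proportionally to length, so the control is matched for size only, not
#' for chromosome). With `match_compartment`, placements are additionally
#' rejection-sampled until the control's per-class compartment label counts
#' (A / B / undefined, by sign of mean EV1) equal those of the input set.
#'
#' @param sites A [site_set()] to match.
#' @param genome A [genome_spec()].
#' @param mask Optional excluded intervals (data.frame or `GRanges`);
#'   controls never overlap them.
#' @param seed Integer seed.
#' @param match_compartment Optional `compartment_track`; switches on
#'   compartment matching.
#' @param max_tries Total placement attempts before giving up.
#' @return A [site_set()] with class `"random"`.
#' @export
randomize_sites <- function(sites, genome, mask = NULL, seed = 1,
                            match_compartment = NULL,
                            max_tries = 2000 * max(nrow(sites), 1)) {
  sizes <- sites$end - sites$start
  avoid <- if (is.null(mask)) NULL else if (is.data.frame(mask))
    as_granges(mask) else mask
  if (nrow(sites) == 0)
    return(site_set(data.frame(chrom = character(), start = numeric(),
                               end = numeric()), class = "random"))
  with_seed(seed, {
    if (is.null(match_compartment)) {
      placed <- place_intervals(sizes, genome, avoid = avoid,
                                max_tries = max_tries)
    } else {
      target <- site_labels_for_matching(match_compartment, sites)
      placed <- place_intervals_matched(sizes, genome, avoid, target,
                                        match_compartment, max_tries)
    }
    placed$id <- paste0("random_", seq_len(nrow(placed)))
    site_set(placed, class = "random")
  })
}

site_labels_for_matching <- function(ev, sites) {
  m <- site_mean_ev1(ev, sites, min_defined_frac = 0)
  ifelse(is.na(m) | m == 0, "undef", ifelse(m > 0, "A", "B"))
}

# placement with compartment-label count matching; consumes the RNG stream
place_intervals_matched <- function(sizes, genome, avoid, target_labels,
                                    ev, max_tries) {
  need <- table(factor(target_labels, levels = c("A", "B", "undef")))
  lens <- genome$chroms$length
  led <- interval_ledger(genome$chroms$name)
  out <- vector("list", length(sizes))
  tries <- 0
  for (k in seq_along(sizes)) {
    repeat {
      tries <- tries + 1
      check_that(tries <= max_tries,
                 "could not place compartment-matched sites after ",
                 max_tries, " attempts")
      ci <- sample.int(nrow(genome$chroms), 1, prob = lens)
      room <- lens[ci] - sizes[k]
      if (room <= 0) next
      start <- floor(runif(1, 0, room))
      ch <- genome$chroms$name[ci]
      if (ledger_overlaps(led, ch, start, start + sizes[k])) next
      cand_df <- data.frame(chrom = ch, start = start,
                            end = start + sizes[k])
      if (!is.null(avoid) && length(avoid) &&
          suppressWarnings(IRanges::overlapsAny(as_granges(cand_df),
                                                avoid))) next
      lab <- site_labels_for_matching(ev, site_set(cand_df, "tmp"))
      if (need[lab] <= 0) next
      need[lab] <- need[lab] - 1
      led <- ledger_add(led, ch, start, start + sizes[k])
      out[[k]] <- cand_df
      break
    }
  }
  do.call(rbind, out)
}

#' Mean expression signal per site
#'
#' Mean of a log2(cpm+1) RNA track over each site's overlapping bins.
#'
#' @param rna A [binned_track()] with unit `"log2_cpm1"` (typically 10 kb).
#' @param sites A [site_set()].
#' @return Numeric vector named by site id.
#' @export
site_expression <- function(rna, sites) {
  require_unit(rna, "log2_cpm1", "site_expression()")
  hits <- GenomicRanges::findOverlaps(as_granges(sites),
                                      as_granges(rna$bins))
  out <- stats::setNames(rep(NA_real_, nrow(sites)), sites$id)
  for (k in seq_len(nrow(sites))) {
    b <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == k]
    if (length(b)) out[k] <- mean(rna$value[b], na.rm = TRUE)
  }
  out
}

#' Compare enrichment between site groups and conditions
#'
#' Given per-site signal values for several conditions and a grouping of
#' sites (e.g. `B-to-A` rescue switchers vs `B-to-B` stayers), tests every
#' between-group contrast within each condition and every between-condition
#' contrast within each group with the two-tailed Mann-Whitney U test, and
#' adjusts the whole family by Benjamini-Hochberg. Groups with fewer than
#' two sites are skipped and flagged.
#'
#' @param values Named list, one numeric vector of per-site values per
#'   condition (equal lengths, site order shared).
#' @param groups Character/factor of per-site group labels (`NA` sites are
#'   dropped).
#' @return data.frame with `comparison`, `n1`, `n2`, `U`, `p`, `q`,
#'   `stars`, `skipped`, plus per-group per-condition means as attribute
#'   `group_means`.
#' @export
rescue_group_compare <- function(values, groups) {
  check_that(is.list(values) && !is.null(names(values)),
             "`values` must be a named list of per-condition vectors")
  groups <- as.character(groups)
  lens <- vapply(values, length, integer(1))
  check_that(all(lens == length(groups)),
             "value vectors must match the number of sites")
  glev <- unique(groups[!is.na(groups)])
  rows <- list()
  add_row <- function(name, x, y) {
    skipped <- length(x) < 2 || length(y) < 2
    res <- if (skipped) list(U = NA_real_, p = NA_real_) else
      mann_whitney_u(x, y)
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = name, n1 = length(x), n2 = length(y),
      U = res$U, p = res$p, skipped = skipped)
  }
  for (cond in names(values)) {
    v <- values[[cond]]
    if (length(glev) >= 2) {
      pairs <- utils::combn(glev, 2, simplify = FALSE)
      for (pr in pairs) {
        x <- v[groups == pr[1] & !is.na(groups) & !is.na(v)]
        y <- v[groups == pr[2] & !is.na(groups) & !is.na(v)]
        add_row(paste0(cond, ": ", pr[1], " vs ", pr[2]), x, y)
      }
    }
  }
  if (length(values) >= 2) {
    cpairs <- utils::combn(names(values), 2, simplify = FALSE)
    for (g in glev) {
      for (pr in cpairs) {
        x <- values[[pr[1]]][groups == g & !is.na(groups)]
        y <- values[[pr[2]]][groups == g & !is.na(groups)]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        add_row(paste0(g, ": ", pr[1], " vs ", pr[2]), x, y)
      }
    }
  }
  df <- do.call(rbind, rows)
  df$q <- NA_real_
  ok <- !df$skipped & !is.na(df$p)
  if (any(ok)) df$q[ok] <- bh_fdr(df$p[ok])
  df$stars <- ifelse(is.na(df$q), NA_character_, star_code(df$q))
  gm <- do.call(rbind, lapply(names(values), function(cond) {
    vapply(glev, function(g)
      mean(values[[cond]][groups == g], na.rm = TRUE), numeric(1))
  }))
  dimnames(gm) <- list(names(values), glev)
  attr(df, "group_means") <- gm
  rownames(df) <- NULL
  df
}

#' Intersect interval sets
#'
#' Regions covered by every input set (>= 1 bp overlap), reported as the
#' overlap regions themselves, as when intersecting peak calls across
#' replicates and cell lines.
#'
#' @param ... Two or more interval tables (`chrom`, `start`, `end`
#'   data.frames, [site_set()]s, or `GRanges`).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
common_intervals <- function(...) {
  sets <- list(...)
  check_that(length(sets) >= 2, "need at least two interval sets")
  grs <- lapply(sets, function(s) {
    gr <- if (is.data.frame(s)) as_granges(s) else s
    GenomicRanges::reduce(gr)
  })
  common <- Reduce(function(a, b)
    suppressWarnings(GenomicRanges::intersect(a, b, ignore.strand = TRUE)),
    grs)
  data.frame(chrom = as.character(GenomicRanges::seqnames(common)),
             start = GenomicRanges::start(common) - 1,
             end = GenomicRanges::end(common))
}
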