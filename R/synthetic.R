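#' Parameters of the synthetic Hi-C / track generator
#'
#' The generative model for cis contacts is
#' `E[c_ij] = scale * |i-j|^(-alpha) * exp(kappa * s_i * s_j)` where `s` is
#' the planted compartment sign, with `scale` set so the expected total cis
#' count equals `depth`. Counts are Poisson by default; a negative-binomial
#' option is available through `dispersion`. IP tracks are Poisson with a
#' multiplicative `exp(beta)` enrichment where the planted indicator is on.
#'
#' @param alpha Distance-decay exponent (> 0, dimensionless).
#' @param kappa Compartment modulation strength (>= 0).
#' @param depth Expected total cis contact count for the whole genome.
#' @param beta Log-scale IP-over-input enrichment inside A bins / site
#'   boundary flanks.
#' @param dispersion If non-`NULL`, negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); `NULL` means Poisson.
#' @param trans_fraction Fraction of all contacts that are trans, used only
#'   to populate the QC trans total (`cis:trans = (1-f):f`).
#' @param track_mean Expected input-track count per bin.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(alpha = 1, kappa = 0.4, depth = 2e6, beta = 1,
                       dispersion = NULL, trans_fraction = 0.1,
                       track_mean = 100) {
  check_that(is_scalar_number(alpha) && alpha > 0, "`alpha` must be > 0")
  check_that(is_scalar_number(kappa) && kappa >= 0, "`kappa` must be >= 0")
  check_that(is_scalar_number(depth) && depth > 0, "`depth` must be > 0")
  check_that(is_scalar_number(beta), "`beta` must be a finite number")
  check_that(is.null(dispersion) ||
               (is_scalar_number(dispersion) && dispersion > 0),
             "`dispersion` must be NULL or > 0")
  check_that(is_scalar_number(trans_fraction) && trans_fraction >= 0 &&
               trans_fraction < 1, "`trans_fraction` must be in [0, 1)")
  check_that(is_scalar_number(track_mean) && track_mean > 0,
             "`track_mean` must be > 0")
  structure(list(alpha = alpha, kappa = kappa, depth = depth, beta = beta,
                 dispersion = dispersion, trans_fraction = trans_fraction,
                 track_mean = track_mean),
            class = "sim_params")
}

draw_counts <- function(lambda, params) {
  if (is.null(params$dispersion)) {
    rpois(length(lambda), lambda)
  } else {
    rnbinom(length(lambda), mu = lambda, size = 1 / params$dispersion)
  }
}

#' Plant a two-state compartment profile with condition switches
#'
#' Generates alternating A/B blocks with geometric block lengths (matching
#' the heavy-tailed domain-size spectrum of real compartment segmentations)
#' for two synthetic replicate cell lines. In condition 2 a fraction of bins
#' flips sign: identically in both lines when `concordant`, independently
#' otherwise. `decoy_fraction` plants additional line-1-only flips, useful
#' for testing that a concordance-requiring classifier rejects them.
#'
#' @param genome A [genome_spec()].
#' @param bin_size Compartment bin size in bp (default 50 kb).
#' @param mean_block_len Mean block length in bp (>= 2 bins).
#' @param switch_fraction Per-bin flip probability in condition 2, in
#'   `[0, 0.5]`.
#' @param concordant If `TRUE`, both lines flip the same bins.
#' @param decoy_fraction Extra per-bin flip probability applied to line 1
#'   only (never overlapping planted switches).
#' @param seed Integer seed; same seed reproduces the truth bit-identically.
#' @return Object of class `planted_truth` with the bin table, per-line
#'   condition signs (`sign1` shared, `sign2_line1`, `sign2_line2`),
#'   `switch_bins` (bins flipping in both lines), `decoy_bins`, and `seed`.
#' @export
generate_compartment_profile <- function(genome, bin_size = 5e4,
                                         mean_block_len = 1e6,
                                         switch_fraction = 0,
                                         concordant = TRUE,
                                         decoy_fraction = 0,
                                         seed = 1) {
  check_that(is_scalar_number(switch_fraction) && switch_fraction >= 0 &&
               switch_fraction <= 0.5,
             "`switch_fraction` must be in [0, 0.5]")
  check_that(is_scalar_number(decoy_fraction) && decoy_fraction >= 0 &&
               decoy_fraction <= 0.5, "`decoy_fraction` must be in [0, 0.5]")
  check_that(mean_block_len >= 2 * bin_size,
             "`mean_block_len` must be at least 2 bins")
  bins <- genome_bins(genome, bin_size)
  idx <- cm_index0(bins)
  mean_block_bins <- mean_block_len / bin_size
  with_seed(seed, {
    sign1 <- rep(NA_integer_, nrow(bins))
    for (gi in idx) {
      n <- length(gi)
      s <- sample(c(-1L, 1L), 1)
      pos <- 1L
      while (pos <= n) {
        len <- rgeom(1, 1 / mean_block_bins) + 1L
        sign1[gi[pos:min(n, pos + len - 1L)]] <- s
        pos <- pos + len
        s <- -s
      }
    }
    n_bins <- nrow(bins)
    flip1 <- runif(n_bins) < switch_fraction
    flip2 <- if (concordant) flip1 else runif(n_bins) < switch_fraction
    decoy <- runif(n_bins) < decoy_fraction & !flip1 & !flip2
    structure(list(
      bins = bins, bin_size = bin_size,
      sign1 = sign1,
      sign2_line1 = sign1 * ifelse(flip1 | decoy, -1L, 1L),
      sign2_line2 = sign1 * ifelse(flip2, -1L, 1L),
      switch_bins = which(flip1 & flip2),
      decoy_bins = which(decoy),
      seed = seed), class = "planted_truth")
  })
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("planted_truth:", nrow(x$bins), "bins @", x$bin_size, "bp;",
      length(x$switch_bins), "planted switch bins,",
      length(x$decoy_bins), "decoy bins\n")
  invisible(x)
}

#' Planted signs for one line and condition
#'
#' @param truth A `planted_truth`.
#' @param line Cell line (1 or 2).
#' @param condition Condition (1 = baseline, 2 = switched).
#' @return Integer vector of per-bin signs in `{-1, +1}`.
#' @export
truth_signs <- function(truth, line = 1, condition = 1) {
  check_that(line %in% 1:2 && condition %in% 1:2, "line/condition must be 1 or 2")
  if (condition == 1) truth$sign1
  else if (line == 1) truth$sign2_line1
  else truth$sign2_line2
}

# genome implied by a truth object's bin table
truth_genome <- function(truth) {
  ends <- tapply(truth$bins$end, factor(truth$bins$chrom,
                                        levels = unique(truth$bins$chrom)), max)
  genome_spec(stats::setNames(as.numeric(ends), names(ends)))
}

#' Simulate a Hi-C contact map from planted compartments
#'
#' Cis counts follow
#' `E[c_ij] = scale * |i-j|^(-alpha) * exp(kappa * s_i * s_j)` (diagonal
#' excluded), scaled so the expected total equals `params$depth`, sampled as
#' Poisson (or negative binomial) and mirrored to a symmetric matrix. Trans
#' contacts are a single uniform-background total for QC ratios.
#'
#' @param truth A `planted_truth` from [generate_compartment_profile()].
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @param line,condition Which planted sign set to use.
#' @return A [contact_map()] of raw counts at the truth's bin size.
#' @export
simulate_hic <- function(truth, params, seed = 1, line = 1, condition = 1) {
  s <- truth_signs(truth, line, condition)
  idx <- cm_index0(truth$bins)
  lambdas <- lapply(names(idx), function(ch) {
    gi <- idx[[ch]]
    n <- length(gi)
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    lam <- ifelse(d == 0, 0, d^(-params$alpha)) *
      exp(params$kappa * outer(s[gi], s[gi]))
    diag(lam) <- 0
    lam
  })
  names(lambdas) <- names(idx)
  total <- sum(vapply(lambdas, function(l) sum(l[upper.tri(l)]), numeric(1)))
  scale <- params$depth / total
  with_seed(seed, {
    mats <- lapply(lambdas, function(lam) {
      n <- nrow(lam)
      ut <- which(upper.tri(lam))
      cnt <- draw_counts(scale * lam[ut], params)
      m <- matrix(0, n, n)
      m[ut] <- cnt
      m + t(m)
    })
    tf <- params$trans_fraction
    trans_total <- if (tf > 0) rpois(1, params$depth * tf / (1 - tf)) else 0
    map <- contact_map(truth$bins, mats, truth$bin_size,
                       trans_total = trans_total)
    empty <- vapply(map$matrices, function(m) sum(rowSums(m) == 0),
                    numeric(1))
    if (sum(empty) > 0.5 * nrow(map$bins))
      warning("over half of all bins have no contacts; depth may be too low")
    map
  })
}

#' Simulate a TAD-structured contact map
#'
#' A distance-decay background in which contacts between bins of the same
#' block are multiplied by `inside_boost` before count sampling. Block
#' boundaries are placed every `boundary_spacing` bp and recorded as truth.
#'
#' @param genome A [genome_spec()].
#' @param bin_size Bin size in bp (default 10 kb).
#' @param boundary_spacing Distance between planted boundaries in bp.
#' @param inside_boost Multiplicative within-block contact boost (>= 1).
#' @param params A [sim_params()] (its `alpha` and `depth` are used).
#' @param seed Integer seed.
#' @return List with `map` (a [contact_map()]) and `boundaries`
#'   (data.frame `chrom`, `start` bp, `bin` global bin index of the first
#'   bin after each boundary).
#' @export
simulate_tads <- function(genome, bin_size = 1e4, boundary_spacing = 5e5,
                          inside_boost = 3, params = sim_params(), seed = 1) {
  check_that(is_scalar_number(inside_boost) && inside_boost >= 1,
             "`inside_boost` must be >= 1")
  bins <- genome_bins(genome, bin_size)
  idx <- cm_index0(bins)
  block <- bins$start %/% boundary_spacing
  lambdas <- lapply(names(idx), function(ch) {
    gi <- idx[[ch]]
    n <- length(gi)
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    lam <- ifelse(d == 0, 0, d^(-params$alpha))
    same <- outer(block[gi], block[gi], "==")
    lam * ifelse(same, inside_boost, 1)
  })
  names(lambdas) <- names(idx)
  total <- sum(vapply(lambdas, function(l) sum(l[upper.tri(l)]), numeric(1)))
  scale <- params$depth / total
  boundaries <- do.call(rbind, lapply(names(idx), function(ch) {
    gi <- idx[[ch]]
    b <- block[gi]
    at <- which(diff(b) != 0) + 1L
    if (!length(at)) return(NULL)
    data.frame(chrom = ch, start = bins$start[gi[at]], bin = gi[at])
  }))
  with_seed(seed, {
    mats <- lapply(lambdas, function(lam) {
      n <- nrow(lam)
      ut <- which(upper.tri(lam))
      cnt <- draw_counts(scale * lam[ut], params)
      m <- matrix(0, n, n)
      m[ut] <- cnt
      m + t(m)
    })
    list(map = contact_map(bins, mats, bin_size), boundaries = boundaries)
  })
}

#' Simulate matched IP and input coverage tracks
#'
#' Input counts are Poisson with constant mean; IP counts gain a
#' multiplicative `exp(beta)` where the planted indicator is 1: inside A bins
#' (planted sign +1) and/or within `flank` of a site boundary.
#'
#' @param truth A `planted_truth` (supplies the genome and A/B signs).
#' @param sites Optional [site_set()]; bins within `flank` of a site start or
#'   end are enriched.
#' @param params A [sim_params()] (`beta`, `track_mean`, `dispersion`).
#' @param seed Integer seed.
#' @param bin_size Track bin size in bp (default 10 kb).
#' @param line,condition Which planted sign set drives the A-bin enrichment.
#' @param flank Half-width of the boundary enrichment window in bp.
#' @param compartment_effect If `FALSE`, only site boundaries are enriched.
#' @return List with `ip` and `input`, both count [binned_track()]s.
#' @export
simulate_track <- function(truth, sites = NULL, params = sim_params(),
                           seed = 1, bin_size = 1e4, line = 1, condition = 1,
                           flank = 2e4, compartment_effect = TRUE) {
  genome <- truth_genome(truth)
  bins <- genome_bins(genome, bin_size)
  s <- truth_signs(truth, line, condition)
  parent <- match(
    paste(bins$chrom, (bins$start %/% truth$bin_size) * truth$bin_size),
    paste(truth$bins$chrom, truth$bins$start))
  f <- if (compartment_effect) as.numeric(s[parent] == 1L) else
    numeric(nrow(bins))
  if (!is.null(sites) && nrow(sites) > 0) {
    edges <- data.frame(chrom = rep(sites$chrom, 2),
                        pos = c(sites$start, sites$end))
    gr_edges <- GenomicRanges::GRanges(
      edges$chrom,
      IRanges::IRanges(start = pmax(edges$pos - flank + 1, 1),
                       end = edges$pos + flank))
    hit <- IRanges::overlapsAny(as_granges(bins), gr_edges)
    f[hit] <- 1
  }
  with_seed(seed, {
    input <- draw_counts(rep(params$track_mean, nrow(bins)), params)
    ip <- draw_counts(params$track_mean * exp(params$beta * f), params)
    list(ip = binned_track(bins, ip, bin_size, unit = "counts"),
         input = binned_track(bins, input, bin_size, unit = "counts"))
  })
}

#' Generate random non-overlapping site intervals
#'
#' Sites have log-uniform lengths within `size_range` and are placed
#' uniformly over the genome (chromosome chosen proportionally to length),
#' rejecting overlaps with already-placed sites.
#'
#' @param genome A [genome_spec()].
#' @param n Number of sites.
#' @param size_range Length range `(min, max)` in bp.
#' @param seed Integer seed.
#' @param class Site class label for the whole set.
#' @param max_tries Total placement attempts before giving up.
#' @return A [site_set()] with `n` intervals.
#' @export
generate_sites <- function(genome, n, size_range = c(4e4, 4e5), seed = 1,
                           class = "random", max_tries = 200 * max(n, 1)) {
  check_that(is_count(n), "`n` must be a non-negative integer")
  check_that(size_range[1] > 0 && size_range[2] >= size_range[1],
             "invalid `size_range`")
  check_that(n * size_range[2] < sum(genome$chroms$length),
             "sites cannot fit in the genome")
  if (n == 0)
    return(site_set(data.frame(chrom = character(), start = numeric(),
                               end = numeric()), class = class))
  with_seed(seed, {
    sizes <- round(exp(runif(n, log(size_range[1]), log(size_range[2]))))
    placed <- place_intervals(sizes, genome, avoid = NULL,
                              max_tries = max_tries)
    placed$id <- paste0(class, "_", seq_len(n))
    site_set(placed, class = class)
  })
}

# Sorted per-chromosome interval ledger used during rejection sampling:
# supports O(log n) overlap queries against already-placed intervals.
interval_ledger <- function(chroms) {
  lapply(stats::setNames(vector("list", length(chroms)), chroms),
         function(x) list(start = numeric(), end = numeric()))
}

ledger_overlaps <- function(led, ch, s, e) {
  l <- led[[ch]]
  if (!length(l$start)) return(FALSE)
  i <- findInterval(s, l$start)
  (i >= 1 && l$end[i] > s) || (i < length(l$start) && l$start[i + 1] < e)
}

ledger_add <- function(led, ch, s, e) {
  l <- led[[ch]]
  i <- findInterval(s, l$start)
  led[[ch]] <- list(start = append(l$start, s, after = i),
                    end = append(l$end, e, after = i))
  led
}

# Rejection-sample non-overlapping intervals of the given sizes; `avoid` is
# an optional GRanges of forbidden regions. Consumes the caller's RNG stream.
place_intervals <- function(sizes, genome, avoid = NULL, max_tries = 1e5) {
  lens <- genome$chroms$length
  chrom_levels <- genome$chroms$name
  led <- interval_ledger(chrom_levels)
  out_chrom <- character(length(sizes))
  out_start <- numeric(length(sizes))
  tries <- 0
  for (k in seq_along(sizes)) {
    repeat {
      tries <- tries + 1
      check_that(tries <= max_tries,
                 "could not place sites after ", max_tries, " attempts")
      ci <- sample.int(nrow(genome$chroms), 1, prob = lens)
      room <- lens[ci] - sizes[k]
      if (room <= 0) next
      start <- floor(runif(1, 0, room))
      ch <- chrom_levels[ci]
      if (ledger_overlaps(led, ch, start, start + sizes[k])) next
      if (!is.null(avoid) && length(avoid)) {
        cand <- GenomicRanges::GRanges(
          ch, IRanges::IRanges(start = start + 1, end = start + sizes[k]))
        if (suppressWarnings(IRanges::overlapsAny(cand, avoid))) next
      }
      led <- ledger_add(led, ch, start, start + sizes[k])
      out_chrom[k] <- ch
      out_start[k] <- start
      break
    }
  }
  data.frame(chrom = out_chrom, start = out_start, end = out_start + sizes)
}

#' Synthetic GC-content track for eigenvector orientation
#'
#' GC fraction correlates with the planted baseline compartment sign (A bins
#' slightly GC-richer), mirroring the real-genome correlation that anchors
#' eigenvector orientation.
#'
#' @param truth A `planted_truth`.
#' @param seed Integer seed.
#' @param base Mean GC fraction.
#' @param effect Half-difference between A and B bins.
#' @param noise_sd Gaussian noise SD.
#' @return A [binned_track()] (unit `"gc"`) at the truth's bin size.
#' @export
simulate_gc <- function(truth, seed = 1, base = 0.41, effect = 0.02,
                        noise_sd = 0.01) {
  with_seed(seed, {
    gc <- base + effect * truth$sign1 + rnorm(nrow(truth$bins), 0, noise_sd)
    binned_track(truth$bins, gc, truth$bin_size, unit = "gc")
  })
}

#' Serialize / load planted truth as TSV
#'
#' Plain-text truth tables give test oracles file-level access to the
#' planted structure.
#'
#' @param truth A `planted_truth`.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  df <- cbind(truth$bins,
              sign1 = truth$sign1,
              sign2_line1 = truth$sign2_line1,
              sign2_line2 = truth$sign2_line2,
              switch = seq_len(nrow(truth$bins)) %in% truth$switch_bins,
              decoy = seq_len(nrow(truth$bins)) %in% truth$decoy_bins)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c(chrom = "character"))
  bins <- df[c("chrom", "start", "end")]
  structure(list(bins = bins, bin_size = max(df$end - df$start),
                 sign1 = df$sign1, sign2_line1 = df$sign2_line1,
                 sign2_line2 = df$sign2_line2,
                 switch_bins = which(df$switch),
                 decoy_bins = which(df$decoy), seed = NA_integer_),
            class = "planted_truth")
}
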