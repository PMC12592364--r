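test_that("site stack-ups center on midpoints with constant width and size order", {
  g <- genome_spec(c(chr1 = 1e6))
  track <- binned_track(genome_bins(g, 1e4),
                        as.numeric(seq_len(100) == 25), 1e4,
                        unit = "zscore")
  sites <- site_set(data.frame(chrom = "chr1",
                               start = c(2e5, 5e5, 8e5),
                               end = c(2.9e5, 6.2e5, 8.4e5)),
                    class = "blurred")
  st <- stackup(track, sites, flank = 5e4)
  expect_equal(dim(st$values), c(3L, 11L))
  expect_true(all(diff(st$sizes) <= 0))
  # the delta bin sits at the centre column of the site whose midpoint hits it
  row1 <- which(st$ids == "blurred_1")  # midpoint 245000 -> bin 25
  expect_equal(st$values[row1, 6], 1)
  expect_equal(sum(st$values[row1, -6]), 0)
  # off-chromosome cells are missing
  edge <- site_set(data.frame(chrom = "chr1", start = 0, end = 2e4),
                   class = "blurred")
  ste <- stackup(track, edge, flank = 5e4)
  expect_true(all(is.na(ste$values[1, 1:4])))
  expect_warning(
    stackup(track, site_set(data.frame(chrom = "chrZ", start = 0,
                                       end = 1e4)), flank = 5e4),
    "skipped")
})

test_that("mean profiles filter rows by size window", {
  st <- structure(list(values = rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)),
                       sizes = c(2e5, 1e5, 8e4),
                       ids = c("a", "b", "c"),
                       positions = c(-1e4, 0, 1e4)),
                  class = "stackup")
  mp <- mean_profile(st, size_window = c(6e4, 1.6e5))
  expect_equal(mp$mean, c(5.5, 6.5, 7.5))
  expect_equal(attr(mp, "n_rows"), 2L)
  one <- mean_profile(st, size_window = c(1.9e5, 2.1e5))
  expect_equal(one$mean, c(1, 2, 3))
  expect_warning(empty <- mean_profile(st, size_window = c(1, 2)),
                 "size window")
  expect_equal(nrow(empty), 0)
})

test_that("site mean EV1 replicates 50 kb values onto 10 kb bins", {
  ev <- ev_track(c(0.7, -1, 1, NA, 0.4), bin = 5e4)
  inside <- site_set(data.frame(chrom = "chr1", start = 1e4, end = 4e4))
  expect_equal(unname(site_mean_ev1(ev, inside)), 0.7)
  straddle <- site_set(data.frame(chrom = "chr1", start = 5e4, end = 1.5e5))
  expect_equal(unname(site_mean_ev1(ev, straddle)), 0)
  # half NA: mean over the defined half only (at the 50% threshold)
  half_na <- site_set(data.frame(chrom = "chr1", start = 1.5e5, end = 2.5e5))
  expect_equal(unname(site_mean_ev1(ev, half_na)), 0.4)
  # below the defined-fraction threshold the site is dropped
  mostly_na <- site_set(data.frame(chrom = "chr1", start = 1.6e5,
                                   end = 2.5e5))
  expect_true(is.na(unname(site_mean_ev1(ev, mostly_na,
                                         min_defined_frac = 0.6))))
})

test_that("quadrant classification maps sign pairs to compartment fates", {
  q <- quadrant_classify(c(0.5, -0.1, 0.5, -0.3, 0, 0.2),
                         c(-0.2, 0.3, 0.4, -0.2, 0.5, NA))
  expect_equal(q$labels[1:4],
               c("A-to-B", "B-to-A", "A-stable", "B-stable"))
  expect_true(all(is.na(q$labels[5:6])))
  expect_equal(q$n_informative, 4L)
  expect_equal(sum(q$proportions), 1)
  expect_equal(q$switch_proportion, 0.5)
  expect_error(quadrant_classify(1:3, 1:2), "unpaired")
})

test_that("quadrant labels are antisymmetric under condition swap", {
  set.seed(41)
  e1 <- rnorm(200); e2 <- rnorm(200)
  fwd <- quadrant_classify(e1, e2)
  rev <- quadrant_classify(e2, e1)
  swap <- c(`A-to-B` = "B-to-A", `B-to-A` = "A-to-B",
            `A-stable` = "A-stable", `B-stable` = "B-stable")
  expect_identical(unname(swap[fwd$labels]), rev$labels)
  expect_equal(fwd$switch_proportion, rev$switch_proportion)
})

test_that("cross-line summaries average quadrant proportions", {
  r1 <- quadrant_classify(c(1, 1, -1, 1), c(-1, 1, -1, 1))
  r2 <- quadrant_classify(c(1, 1, -1, -1), c(1, 1, -1, 1))
  s <- cross_line_quadrants(list(r1, r2))
  expect_equal(s$label, c("A-to-B", "B-to-A", "A-stable", "B-stable"))
  expect_equal(s$mean[1], mean(c(0.25, 0)))
  expect_equal(s$sd[1], stats::sd(c(0.25, 0)))
})

test_that("randomized sites preserve the exact length multiset and avoid masks", {
  g <- genome_spec(c(chr1 = 5e6, chr2 = 5e6))
  sites <- generate_sites(g, 40, size_range = c(2e4, 1e5), seed = 42,
                          class = "buried")
  rnd <- randomize_sites(sites, g, seed = 43)
  expect_equal(sort(rnd$end - rnd$start), sort(sites$end - sites$start))
  expect_identical(randomize_sites(sites, g, seed = 43), rnd)
  mask <- data.frame(chrom = "chr1", start = 0, end = 4e6)
  rnd_m <- randomize_sites(sites, g, mask = mask, seed = 44)
  hits <- IRanges::overlapsAny(compartshift:::as_granges(rnd_m),
                               compartshift:::as_granges(mask))
  expect_false(any(hits))
})

test_that("compartment-matched randomization reproduces label counts", {
  n_bins <- 100
  ev <- ev_track(rep(c(1, -1), length.out = n_bins) *
                   seq(1, 2, length.out = n_bins), bin = 5e4)
  g <- genome_spec(c(chr1 = n_bins * 5e4))
  sites <- generate_sites(g, 25, size_range = c(2e4, 4e4), seed = 45,
                          class = "buried")
  lab_in <- compartshift:::site_labels_for_matching(ev, sites)
  rnd <- randomize_sites(sites, g, seed = 46, match_compartment = ev)
  lab_out <- compartshift:::site_labels_for_matching(ev, rnd)
  expect_equal(table(factor(lab_out, c("A", "B", "undef"))),
               table(factor(lab_in, c("A", "B", "undef"))))
})

test_that("site expression averages the RNA track over each site", {
  g <- genome_spec(c(chr1 = 1e6))
  rna <- binned_track(genome_bins(g, 1e4), rep(2, 100), 1e4,
                      unit = "log2_cpm1")
  sites <- site_set(data.frame(chrom = "chr1", start = c(0, 5e5),
                               end = c(1e5, 6e5)))
  expect_equal(unname(site_expression(rna, sites)), c(2, 2))
  zero <- binned_track(genome_bins(g, 1e4), rep(0, 100), 1e4,
                       unit = "log2_cpm1")
  expect_equal(unname(site_expression(zero, sites)), c(0, 0))
  # raising signal inside one site moves only that site's mean
  v <- rep(0, 100); v[51:60] <- 3
  up <- binned_track(genome_bins(g, 1e4), v, 1e4, unit = "log2_cpm1")
  e <- site_expression(up, sites)
  expect_equal(unname(e), c(0, 3))
})

test_that("group comparisons detect planted shifts and stay null otherwise", {
  set.seed(47)
  groups <- c(rep("B-to-A", 30), rep("B-to-B", 200))
  null_vals <- list(cond1 = rnorm(230), cond2 = rnorm(230))
  res0 <- rescue_group_compare(null_vals, groups)
  expect_equal(nrow(res0), 4)  # 2 within-condition + 2 within-group
  expect_true(all(res0$q >= res0$p, na.rm = TRUE))
  expect_true(all(res0$p >= 0 & res0$p <= 1, na.rm = TRUE))

  shift <- rnorm(230) + ifelse(groups == "B-to-A", 1.8, 0)
  res1 <- rescue_group_compare(list(cond1 = rnorm(230), cond2 = shift),
                               groups)
  hit <- res1[res1$comparison == "cond2: B-to-A vs B-to-B", ]
  expect_lte(hit$q, 0.05)
  expect_equal(hit$n1, 30)
  expect_equal(hit$n2, 200)
  # identical values across groups give p near 1
  same <- rep(1:5, length.out = 230)
  res2 <- rescue_group_compare(list(cond1 = same), groups)
  expect_gt(res2$p[1], 0.9)
  # tiny groups are skipped, not tested
  res3 <- rescue_group_compare(list(cond1 = rnorm(31)),
                               c(rep("B-to-A", 1), rep("B-to-B", 30)))
  expect_true(res3$skipped[1])
  expect_true(is.na(res3$p[1]))
})

test_that("interval intersection keeps regions common to all sets", {
  a <- data.frame(chrom = "chr1", start = 0, end = 100)
  b <- data.frame(chrom = "chr1", start = 50, end = 150)
  expect_equal(common_intervals(a, b),
               data.frame(chrom = "chr1", start = 50, end = 100))
  expect_equal(common_intervals(a, a), a)
  disjoint <- data.frame(chrom = "chr1", start = 200, end = 300)
  expect_equal(nrow(common_intervals(a, disjoint)), 0)
  c3 <- data.frame(chrom = "chr1", start = 80, end = 120)
  expect_equal(common_intervals(a, b, c3)$start, 80)
  expect_equal(common_intervals(a, b, c3)$end, 100)
})

test_that("site sets round-trip through BED-like files", {
  g <- genome_spec(c(chr1 = 1e6))
  sites <- generate_sites(g, 5, size_range = c(1e4, 5e4), seed = 48,
                          class = "buried")
  path <- tempfile(fileext = ".bed")
  write_sites(sites, path)
  back <- read_sites(path)
  expect_equal(as.data.frame(back), as.data.frame(sites))
})
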