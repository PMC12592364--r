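test_that("compartment profiles alternate, switch as requested, and are seeded", {
  g <- genome_spec(c(chr1 = 5e6, chr2 = 5e6))
  t0 <- generate_compartment_profile(g, 5e4, mean_block_len = 2e5,
                                     switch_fraction = 0, seed = 3)
  expect_identical(t0$sign1, t0$sign2_line1)
  expect_identical(t0$sign1, t0$sign2_line2)
  expect_length(t0$switch_bins, 0)
  expect_true(all(t0$sign1 %in% c(-1L, 1L)))

  t1 <- generate_compartment_profile(g, 5e4, mean_block_len = 2e5,
                                     switch_fraction = 0.2, seed = 3)
  t2 <- generate_compartment_profile(g, 5e4, mean_block_len = 2e5,
                                     switch_fraction = 0.2, seed = 3)
  expect_identical(t1, t2)
  # switches only where the two conditions disagree
  expect_true(all(t1$sign1[t1$switch_bins] ==
                    -t1$sign2_line1[t1$switch_bins]))
  expect_true(all(t1$sign1[t1$switch_bins] ==
                    -t1$sign2_line2[t1$switch_bins]))
  expect_error(generate_compartment_profile(g, 5e4, switch_fraction = 0.7),
               "switch_fraction")
})

test_that("planted switch counts follow binomial sampling", {
  g <- genome_spec(c(chr1 = 5e8))
  tr <- generate_compartment_profile(g, 5e4, mean_block_len = 1e6,
                                     switch_fraction = 0.05, seed = 17)
  n <- nrow(tr$bins)
  expect_equal(n, 10000)
  expected <- n * 0.05
  sd3 <- 3 * sqrt(n * 0.05 * 0.95)
  expect_lt(abs(length(tr$switch_bins) - expected), sd3)
})

test_that("discordant and decoy flips never enter the concordant switch list", {
  g <- genome_spec(c(chr1 = 5e7))
  td <- generate_compartment_profile(g, 5e4, mean_block_len = 1e6,
                                     switch_fraction = 0.1,
                                     concordant = FALSE, seed = 5)
  both <- which(td$sign2_line1 != td$sign1 & td$sign2_line2 != td$sign1)
  expect_identical(td$switch_bins, both)

  tdec <- generate_compartment_profile(g, 5e4, mean_block_len = 1e6,
                                       switch_fraction = 0.05,
                                       decoy_fraction = 0.05, seed = 6)
  expect_length(intersect(tdec$switch_bins, tdec$decoy_bins), 0)
  # decoys flip line 1 only
  expect_true(all(tdec$sign2_line1[tdec$decoy_bins] ==
                    -tdec$sign1[tdec$decoy_bins]))
  expect_true(all(tdec$sign2_line2[tdec$decoy_bins] ==
                    tdec$sign1[tdec$decoy_bins]))
})

test_that("simulated Hi-C maps are symmetric, seeded and depth-conserving", {
  g <- genome_spec(c(chr1 = 1e7, chr2 = 1e7))
  tr <- generate_compartment_profile(g, 5e4, mean_block_len = 5e5, seed = 7)
  p <- sim_params(alpha = 1, kappa = 0.4, depth = 5e5)
  m1 <- simulate_hic(tr, p, seed = 8)
  m2 <- simulate_hic(tr, p, seed = 8)
  expect_identical(m1$matrices, m2$matrices)
  for (ch in names(m1$matrices))
    expect_identical(m1$matrices[[ch]], t(m1$matrices[[ch]]))
  total <- sum(vapply(m1$matrices,
                      function(m) sum(m[upper.tri(m)]), numeric(1)))
  expect_lt(abs(total - p$depth), 3 * sqrt(p$depth))
  expect_warning(simulate_hic(tr, sim_params(depth = 50), seed = 1),
                 "depth")
})

test_that("compartment modulation matches its closed form and vanishes at kappa 0", {
  g <- genome_spec(c(chr1 = 2.5e7))
  tr <- generate_compartment_profile(g, 5e4, mean_block_len = 1e6, seed = 9)
  p0 <- sim_params(alpha = 1, kappa = 0, depth = 2e6)
  m0 <- ice_normalize(simulate_hic(tr, p0, seed = 10), tol = 1e-4)
  oe0 <- observed_over_expected(m0, expected_cis(m0))
  cls0 <- oe_class_means(oe0$matrices$chr1, tr$sign1)
  expect_true(all(abs(cls0 - 1) < 0.05))

  p1 <- sim_params(alpha = 1, kappa = 0.4, depth = 2e6)
  m1 <- ice_normalize(simulate_hic(tr, p1, seed = 11), tol = 1e-4)
  oe1 <- observed_over_expected(m1, expected_cis(m1))
  o <- oe1$matrices$chr1
  ut <- upper.tri(o)
  same <- outer(tr$sign1, tr$sign1) > 0
  ratio <- mean(o[ut & same], na.rm = TRUE) /
    mean(o[ut & !same], na.rm = TRUE)
  expect_lt(abs(ratio - exp(2 * 0.4)) / exp(2 * 0.4), 0.1)
})

test_that("TAD simulation validates the boost and records boundaries on bin edges", {
  g <- genome_spec(c(chr1 = 5e6))
  expect_error(simulate_tads(g, 1e4, inside_boost = 0.5), "inside_boost")
  sim <- simulate_tads(g, 1e4, boundary_spacing = 5e5, inside_boost = 3,
                       params = sim_params(depth = 1e6), seed = 12)
  sim2 <- simulate_tads(g, 1e4, boundary_spacing = 5e5, inside_boost = 3,
                        params = sim_params(depth = 1e6), seed = 12)
  expect_identical(sim$map$matrices, sim2$map$matrices)
  expect_true(all(sim$boundaries$start %% 1e4 == 0))
  expect_equal(sim$boundaries$start, seq(5e5, 4.5e6, by = 5e5))
})

test_that("boost-free TAD maps have flat insulation", {
  g <- genome_spec(c(chr1 = 1e7))
  sim <- simulate_tads(g, 1e4, boundary_spacing = 5e5, inside_boost = 1,
                       params = sim_params(depth = 4e6), seed = 13)
  m <- ice_normalize(sim$map, tol = 1e-4)
  ins <- insulation_score(m, window = 1e5)
  expect_lt(stats::sd(ins$score, na.rm = TRUE), 0.1)
  expect_lt(abs(mean(ins$score, na.rm = TRUE)), 0.05)
})

test_that("IP track enrichment is null at beta 0 and ranks with beta", {
  g <- genome_spec(c(chr1 = 1e7))
  tr <- generate_compartment_profile(g, 5e4, mean_block_len = 5e5,
                                     seed = 14)
  p0 <- sim_params(beta = 0, track_mean = 200)
  tk0 <- simulate_track(tr, params = p0, seed = 15)
  tk0b <- simulate_track(tr, params = p0, seed = 15)
  expect_identical(tk0$ip$value, tk0b$ip$value)
  lr0 <- log2_ip_over_input(cpm_normalize(tk0$ip), cpm_normalize(tk0$input))
  expect_lt(abs(mean(lr0$value, na.rm = TRUE)), 0.02)

  a_minus_b <- vapply(c(0.5, 1, 2), function(beta) {
    tk <- simulate_track(tr, params = sim_params(beta = beta,
                                                 track_mean = 200),
                         seed = 16)
    z <- zscore_per_chromosome(
      log2_ip_over_input(cpm_normalize(tk$ip), cpm_normalize(tk$input)))
    parent <- tr$sign1[(z$bins$start %/% 5e4) + 1]
    mean(z$value[parent == 1], na.rm = TRUE) -
      mean(z$value[parent == -1], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(a_minus_b > 0))
  expect_true(all(diff(a_minus_b) > 0))
})

test_that("generated sites respect count, range, non-overlap and log-uniform sizes", {
  g <- genome_spec(c(chr1 = 5e8, chr2 = 5e8))
  expect_equal(nrow(generate_sites(g, 0, seed = 1)), 0)
  s <- generate_sites(g, 10000, size_range = c(1e3, 1e4), seed = 18)
  sizes <- s$end - s$start
  expect_true(all(sizes >= 1e3 & sizes <= 1e4))
  hits <- GenomicRanges::countOverlaps(compartshift:::as_granges(s),
                                       compartshift:::as_granges(s))
  expect_true(all(hits == 1))
  ks <- suppressWarnings(stats::ks.test(log(sizes), "punif",
                                        log(1e3), log(1e4)))
  expect_gt(ks$p.value, 0.01)
  s2 <- generate_sites(g, 50, size_range = c(1e3, 1e4), seed = 19)
  s3 <- generate_sites(g, 50, size_range = c(1e3, 1e4), seed = 19)
  expect_identical(s2, s3)
  expect_error(generate_sites(genome_spec(c(chr1 = 1e5)), 100,
                              size_range = c(1e3, 1e4), seed = 1),
               "fit")
})

test_that("truth tables round-trip through TSV", {
  g <- genome_spec(c(chr1 = 2e6))
  tr <- generate_compartment_profile(g, 5e4, mean_block_len = 2e5,
                                     switch_fraction = 0.2, seed = 20)
  path <- tempfile(fileext = ".tsv")
  write_truth(tr, path)
  back <- read_truth(path)
  expect_equal(back$sign1, tr$sign1)
  expect_equal(back$sign2_line1, tr$sign2_line1)
  expect_equal(back$switch_bins, tr$switch_bins)
})
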