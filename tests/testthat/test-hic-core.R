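test_that("triplet loading is symmetric, sums duplicates and validates coordinates", {
  g <- genome_spec(c(chr1 = 5e4))
  empty <- load_matrix(write_triplets(character()), g, 1e4)
  expect_true(all(empty$matrices$chr1 == 0))

  path <- write_triplets(c("chr1\t0\t10000\t2",
                           "chr1\t10000\t0\t3",
                           "chr1\t20000\t20000\t7"))
  m <- load_matrix(path, g, 1e4)
  expect_equal(m$matrices$chr1[1, 2], 5)  # duplicates (incl. mirrored) sum
  expect_equal(m$matrices$chr1[2, 1], 5)
  expect_equal(m$matrices$chr1[3, 3], 7)

  expect_error(load_matrix(write_triplets("chr1\t0\t70000\t1"), g, 1e4),
               "line 1")
  expect_error(load_matrix(write_triplets("chr1\t0\t15000\t1"), g, 1e4),
               "multiple")
  expect_error(load_matrix(write_triplets("chrX\t0\t0\t1"), g, 1e4),
               "chromosome")
})

test_that("contact maps round-trip through triplet files", {
  g <- genome_spec(c(chr1 = 1e6))
  tr <- generate_compartment_profile(g, 5e4, mean_block_len = 2e5, seed = 1)
  m <- simulate_hic(tr, sim_params(depth = 1e4), seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_matrix(m, path)
  back <- load_matrix(path, g, 5e4)
  expect_equal(back$matrices$chr1, m$matrices$chr1)
})

test_that("blacklist masking zeroes overlapped bins and is idempotent", {
  m <- uniform_map(10, v = 2)
  expect_equal(apply_blacklist(m, data.frame(chrom = character(),
                                             start = numeric(),
                                             end = numeric()))$mask,
               m$mask)
  # region straddling bins 3 and 4 masks both
  bl <- data.frame(chrom = "chr1", start = 29500, end = 30500)
  mm <- apply_blacklist(m, bl)
  expect_true(all(mm$mask[3:4]))
  expect_equal(sum(mm$matrices$chr1[3, ]), 0)
  expect_equal(sum(mm$matrices$chr1[, 4]), 0)
  expect_identical(apply_blacklist(mm, bl)$mask, mm$mask)
})

test_that("single-pass iterative correction matches the hand-computed update", {
  counts <- matrix(c(2, 1, 3,
                     1, 2, 1,
                     3, 1, 2), 3, 3, byrow = TRUE)
  m <- balanced_map(list(chr1 = counts), 1e4)
  m$weights <- NULL
  m1 <- ice_normalize(m, n_iter = 1)
  marg <- rowSums(counts)            # (6, 4, 6)
  w_hand <- (1 / marg) / mean(1 / marg)
  expect_equal(m1$weights, w_hand)
  expect_equal(balanced_matrix(m1, "chr1"), counts * outer(w_hand, w_hand))
})

test_that("equal-marginal matrices are left unchanged by balancing", {
  m <- uniform_map(8, v = 3)
  m$weights <- NULL
  m1 <- ice_normalize(m, n_iter = 1)
  expect_equal(m1$weights, rep(1, 8))
  expect_equal(balanced_matrix(m1, "chr1"), m$matrices$chr1)
})

test_that("tolerance-mode balancing equalizes marginals on random maps", {
  set.seed(42)
  n <- 50
  counts <- matrix(rpois(n * n, 20), n, n)
  counts <- counts + t(counts)
  m <- balanced_map(list(chr1 = counts), 1e4)
  m$weights <- NULL
  mb <- ice_normalize(m, tol = 1e-4)
  expect_lt(unname(marginal_cv(mb)["chr1"]), 1e-4)
})

test_that("zero-marginal bins are masked and fully masked maps error", {
  counts <- matrix(5, 6, 6)
  counts[4, ] <- 0; counts[, 4] <- 0
  m <- balanced_map(list(chr1 = counts), 1e4)
  m$weights <- NULL
  mb <- ice_normalize(m, n_iter = 1)
  expect_true(mb$mask[4])
  expect_true(is.na(mb$weights[4]))
  z <- balanced_map(list(chr1 = matrix(0, 4, 4)), 1e4)
  z$weights <- NULL
  expect_error(ice_normalize(z, n_iter = 1), "masked")
})

test_that("expected profile is flat for uniform maps and ignores masked bins", {
  m <- uniform_map(12, v = 2.5)
  ex <- expected_cis(m)
  expect_true(all(ex$table$expected == 2.5))
  mm <- apply_blacklist(uniform_map(12, v = 2.5),
                        data.frame(chrom = "chr1", start = 5e4, end = 6e4))
  ex2 <- expected_cis(mm)
  expect_true(all(ex2$table$expected == 2.5))
  expect_true(all(ex2$table$count <= ex$table$count))
})

test_that("O/E of a map against its own expected has per-distance mean one", {
  set.seed(7)
  n <- 40
  counts <- matrix(rpois(n * n, 15), n, n)
  counts <- counts + t(counts)
  m <- balanced_map(list(chr1 = counts), 1e4)
  oe <- observed_over_expected(m, expected_cis(m))
  o <- oe$matrices$chr1
  for (d in c(1, 5, 20)) {
    i <- seq_len(n - d)
    expect_equal(mean(o[cbind(i, i + d)]), 1, tolerance = 1e-12)
  }
  expect_true(all(is.na(diag(o))))
})

test_that("P(s) is flat on uniform maps and arm aggregation is count-weighted", {
  m <- uniform_map(64, v = 2)
  ps <- ps_curve(m)
  expect_true(all(abs(ps$ps - 2) < 1e-12))
  m2 <- balanced_map(list(chr1 = matrix(2, 64, 64),
                          chr2 = matrix(2, 64, 64)), 1e4)
  ps2 <- ps_curve(m2)
  expect_equal(ps2$ps, ps$ps)
  expect_equal(ps2$count, 2 * ps$count)
})

test_that("P(s) recovers the planted decay exponent", {
  g <- genome_spec(c(chr1 = 2e7))
  tr <- generate_compartment_profile(g, 1e4, mean_block_len = 1e6, seed = 4)
  m <- simulate_hic(tr, sim_params(alpha = 1, kappa = 0, depth = 2e6),
                    seed = 5)
  mb <- ice_normalize(m, tol = 1e-4)
  slope <- ps_slope(ps_curve(mb), s_range = c(1e5, 5e6))
  expect_lt(abs(slope - (-1)), 0.1)
})

test_that("cis/trans classification is inclusive at the short-range threshold", {
  counts <- matrix(0, 5, 5)
  counts[1, 3] <- 4; counts[3, 1] <- 4       # 20 kb apart at 10 kb bins
  counts[1, 4] <- 6; counts[4, 1] <- 6       # 30 kb apart
  diag(counts)[2] <- 3                       # distance 0
  m <- balanced_map(list(chr1 = counts), 1e4)
  m$trans_total <- 0
  qc <- cis_trans_ratio(m)
  expect_equal(qc$short_cis, 7)
  expect_equal(qc$long_cis, 6)
  expect_true(qc$undefined)
  expect_identical(qc$cis_trans, Inf)
})

test_that("simulated trans background yields the requested cis:trans ratio", {
  g <- genome_spec(c(chr1 = 1e7))
  tr <- generate_compartment_profile(g, 5e4, mean_block_len = 5e5, seed = 6)
  m <- simulate_hic(tr, sim_params(depth = 1e6, trans_fraction = 0.1),
                    seed = 7)
  qc <- cis_trans_ratio(m)
  expect_false(qc$undefined)
  expect_lt(abs(qc$cis_trans - 9), 0.3)
})

test_that("differential maps are zero on identity, antisymmetric, exact on doubling", {
  set.seed(11)
  n <- 40
  counts <- matrix(rpois(n * n, 30) + 1, n, n)
  counts <- counts + t(counts)
  a <- balanced_map(list(chr1 = counts), 1e4)
  b <- balanced_map(list(chr1 = 2 * counts), 1e4)
  d_aa <- differential_map(a, a, resolution = 5e4)
  expect_true(all(d_aa$matrices$chr1 == 0, na.rm = TRUE))
  d_ab <- differential_map(a, b, resolution = 5e4)
  d_ba <- differential_map(b, a, resolution = 5e4)
  expect_equal(d_ab$matrices$chr1, -d_ba$matrices$chr1)
  expect_true(all(abs(d_ab$matrices$chr1 - 1) < 1e-12, na.rm = TRUE))
  c_other <- balanced_map(list(chr1 = counts), 2e4)
  expect_error(differential_map(a, c_other, resolution = 1e5), "bin tables")
})
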