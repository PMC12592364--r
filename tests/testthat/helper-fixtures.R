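# in-code fixtures shared across test files

tiny_genome <- function(len = 2e5, n_chrom = 1, bin = 1e4) {
  genome_spec(stats::setNames(rep(len, n_chrom),
                              paste0("chr", seq_len(n_chrom))))
}

# a balanced map (unit weights) built from explicit matrices
balanced_map <- function(mats, bin = 1e4) {
  lens <- vapply(mats, function(m) nrow(m) * bin, numeric(1))
  g <- genome_spec(stats::setNames(lens, names(mats)))
  bins <- genome_bins(g, bin)
  cm <- contact_map(bins, mats, bin, weights = rep(1, nrow(bins)))
  cm
}

uniform_map <- function(n_bins = 30, v = 1, bin = 1e4) {
  balanced_map(list(chr1 = matrix(v, n_bins, n_bins)), bin)
}

# compartment track with given EV1 values
ev_track <- function(values, bin = 5e4, chrom = "chr1") {
  g <- genome_spec(stats::setNames(length(values) * bin, chrom))
  structure(list(bins = genome_bins(g, bin), ev1 = as.numeric(values),
                 resolution = bin),
            class = "compartment_track")
}

# count track over one chromosome
count_track <- function(values, bin = 1e4, chrom = "chr1",
                        unit = "counts") {
  g <- genome_spec(stats::setNames(length(values) * bin, chrom))
  binned_track(genome_bins(g, bin), values, bin, unit = unit)
}

write_triplets <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# brute-force Mann-Whitney oracle: U by direct pair counting, p by
# enumerating every assignment of the pooled values to the two groups
brute_mwu <- function(x, y) {
  u_stat <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  n1 <- length(x)
  sel <- utils::combn(length(pooled), n1)
  u_all <- apply(sel, 2, function(i) u_stat(pooled[i], pooled[-i]))
  u <- u_stat(x, y)
  eps <- 1e-9
  list(U = u, p = min(1, 2 * min(mean(u_all <= u + eps),
                                 mean(u_all >= u - eps))))
}

# mean O/E by compartment pair class (AA / BB / AB) for one chromosome
oe_class_means <- function(oe_mat, signs) {
  ut <- upper.tri(oe_mat)
  same_a <- outer(signs == 1, signs == 1)
  same_b <- outer(signs == -1, signs == -1)
  opp <- outer(signs, signs) < 0
  c(AA = mean(oe_mat[ut & same_a], na.rm = TRUE),
    BB = mean(oe_mat[ut & same_b], na.rm = TRUE),
    AB = mean(oe_mat[ut & opp], na.rm = TRUE))
}
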