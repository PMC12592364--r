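# compartshift

Downstream analysis of binned Hi-C contact maps and chromatin coverage
tracks, centred on the question of how a perturbation (for example, the loss
of a histone chaperone) reshapes higher-order genome organisation: which
50 kb bins switch A/B compartment concordantly across replicate cell lines,
how strongly compartments interact (saddle analysis), whether TAD borders
move (insulation scores), and how specific interval sets — such as blurred
and buried early-replication initiation zones — change compartment identity
relative to randomized controls.

The package is aimed at computational genomicists who have already binned
their Hi-C and ChIP/ATAC/RNA data and want a tested, deterministic,
configuration-driven implementation of this analysis stack. A synthetic-data
module plants compartment, TAD and enrichment ground truth so that every
stage can be validated end to end without any external download.

## Methods at a glance

- **Balancing.** Iterative correction: weights `w` chosen so that corrected
  counts `c'_ij = c_ij * w_i * w_j` have equal marginals. Both a
  single-iteration mode and a tolerance-converged mode are provided.
- **Compartments.** Per chromosome, the first eigenvector (EV1) of the
  Pearson correlation matrix of the O/E (observed-over-expected) map,
  scaled by the square root of its eigenvalue and oriented so that EV1
  correlates positively with GC content; `A` where EV1 > 0, `B` where
  EV1 < 0. A bin switches compartment only when it undergoes the same sign
  change in *both* replicate cell lines; the genome proportion switching is
  computed over non-masked bins.
- **Saddle plots.** 50 kb bins ranked by EV1, split into 50 equal-count
  percentile groups, and the mean O/E accumulated per group pair per
  chromosome arm, from the most strongly B to the most strongly A
  percentile; corner means summarize AA/BB/AB interaction strength, and
  differential saddles are `log2` ratios of two grids.
- **Insulation.** For each 10 kb bin, the mean balanced contact over the
  100 kb × 100 kb window of pairs crossing it, log2-normalized to the
  chromosome mean; TAD borders are prominent local minima, compared between
  conditions with an inclusive ±20 kb tolerance.
- **Tracks.** Fragment counting by midpoint, aggregation to 10 kb, cpm,
  `log2(IP/input)` with zeros treated as missing, per-chromosome z-scores,
  smoothing over 3 non-zero bins, and `log2(cpm+1)` for RNA.
- **Sites.** Mean EV1 per interval (50 kb EV1 replicated to 10 kb bins),
  quadrant classification of condition pairs (A-to-B, B-to-A, A-stable,
  B-stable) with cross-line mean ± SD, randomized controls matched for the
  exact size multiset (optionally also for compartment label counts), site
  stack-ups and size-windowed mean profiles.
- **Statistics.** Two-tailed Mann-Whitney U (`U = #{x_i > y_j} + ½·ties`)
  with exact enumeration for small samples and a tie- and
  continuity-corrected normal approximation otherwise; Benjamini-Hochberg
  FDR; inclusive significance stars (`*` ≤ 0.05, `**` ≤ 0.01, `***` ≤ 0.001).

## Worked example

Simulate a two-chromosome genome with planted compartments, call EV1 and
quantify compartmentalization:

```r
library(compartshift)

genome <- genome_spec(c(chr1 = 5e7, chr2 = 5e7))
truth <- generate_compartment_profile(genome, bin_size = 5e4,
                                      mean_block_len = 1e6,
                                      switch_fraction = 0.05, seed = 1)
params <- sim_params(alpha = 1, kappa = 0.4, depth = 2e6)

map <- simulate_hic(truth, params, seed = 2)
map <- ice_normalize(map, tol = 1e-4)
oe <- observed_over_expected(map, expected_cis(map))
ev <- compute_ev1(oe, simulate_gc(truth, seed = 3))

cor(ev$ev1, truth$sign1, use = "complete.obs")
#> [1] 0.986847
unlist(saddle_corners(saddle(oe, ev, n_quantiles = 50)))
#>        AA        BB        AB
#> 1.3294545 1.4604919 0.5529623
head(call_domains(ev), 3)
#>   chrom   start     end sign    size n_bins
#> 1  chr1       0 1200000    B 1200000     24
#> 2  chr1 1200000 3500000    A 2300000     46
#> 3  chr1 3500000 3900000    B  400000      8
mann_whitney_u(c(1, 2, 3), c(4, 5, 6), mode = "exact")
#> Mann-Whitney U = 0 (n1 = 3, n2 = 3), two-tailed p = 0.1 [exact]
```

The eigenvector recovers the planted compartment profile almost perfectly
(r ≈ 0.99); same-compartment corners of the saddle grid sit well above 1
and the AB corner well below 1, i.e. the map is compartmentalized; domains
are contiguous same-sign EV1 runs; and the fully separated 3-vs-3 example
gives the exact two-tailed Mann-Whitney p of 0.1 (2/20 assignments).

The full analysis graph (simulate → balance → EV1 → switching → saddle →
insulation → tracks → sites → statistics → report) is driven by one YAML
configuration whose defaults encode the analysis constants above:

```r
res <- run_pipeline(default_config(seed = 7), outdir = "run1")
```

writes bedGraph/BED/TSV artifacts plus `report.md`, deterministically for a
fixed seed. A thin command-line wrapper is installed at
`inst/scripts/compartshift-run.R`.

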