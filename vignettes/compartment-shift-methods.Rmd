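---
title: "Models and methods behind compartshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind compartshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

compartshift implements the downstream analysis stack used to ask how a
chromatin perturbation — the motivating case is loss of a histone chaperone
that deposits a replacement histone variant — reorganizes the genome at the
compartment scale, and what happens to specific interval sets such as
early-replication initiation zones ("blurred" sites, which are transcribed,
and "buried" sites, which are not). This vignette documents the models, the
tunable parameters, the numerical conventions, and the design decisions, in
the order data flows through the pipeline.

## The synthetic data model

Real analyses of this kind start from billions of sequenced read pairs; a
reusable implementation needs inputs whose correct answer is known. The
synthetic module therefore plants ground truth and generates data at desk
scale. It is first-class, tested code, not a fixture.

**Compartment profile.** Each chromosome is segmented into alternating
A/B blocks whose lengths (in 50 kb bins) are geometric with a configurable
mean (`mean_block_len`, default 1 Mb). A geometric length spectrum gives
many short domains and a heavy tail of multi-megabase ones, matching the
qualitative size spectrum of real compartment segmentations without extra
parameters. In condition 2 each bin flips sign independently with
probability `switch_fraction`; flips are shared between the two synthetic
replicate cell lines when `concordant = TRUE`, drawn independently
otherwise, and `decoy_fraction` plants additional line-1-only flips. Only
bins flipping in *both* lines are recorded as planted switches, which is
exactly the event the concordance classifier is supposed to recover.

**Contact maps.** Cis counts are Poisson with

$$E[c_{ij}] \;=\; s\,|i-j|^{-\alpha}\, e^{\kappa\, \sigma_i \sigma_j},$$

where $\sigma_i \in \{-1, +1\}$ is the planted sign, $\alpha$ the
distance-decay exponent, $\kappa$ the compartment strength, and $s$ set so
the expected total cis count equals `depth`. The multiplicative
$e^{\kappa \sigma_i \sigma_j}$ form is chosen because it makes saddle
corners analytically checkable: the expected O/E ratio between same-sign
and opposite-sign pairs is $e^{2\kappa}$ at every distance. A
negative-binomial option (`dispersion`) exists for over-dispersed counts;
Poisson is the default because planted-truth recovery does not require
more. Trans contacts are generated only as a uniform background total so
the short/long/trans QC ratio has something to measure. Defaults
$\alpha = 1$, $\kappa = 0.4$ are calibration choices producing realistic
P(s) slopes and saddle corner strengths (AA/BB ≈ 1.3–1.6, AB ≈ 0.5); they
are not claims about any particular dataset.

**TAD maps.** A decay-only background in which contacts within blocks of
`boundary_spacing` (default 500 kb) are multiplied by `inside_boost`
(default 3) before sampling; block edges are the planted borders.

**Tracks and sites.** Input coverage is Poisson with constant mean
(`track_mean` per 10 kb bin); IP coverage gains a factor $e^{\beta}$ inside
A bins and/or within ±20 kb of site boundaries — the latter mimics the
boundary-localized enrichment seen at initiation zones. Site intervals have
log-uniform lengths in a configurable range and are placed uniformly
without overlap. GC content is simulated as slightly A-elevated with noise,
which is all the eigenvector orientation step needs.

Default problem sizes (two 25 Mb chromosomes, 5e6 cis counts, 120 + 60
sites) were chosen once so that every stage has usable statistics while the
whole pipeline runs in well under a minute; the acceptance checks use two
50 Mb chromosomes with 1e6–5e6 cis counts per chromosome, the per-Mb
coverage of a production Hi-C library scaled to the toy genome. Site
density is deliberately higher per Mb than in a real genome so that
site-level group comparisons have workable group sizes at this scale.

**What the generator does not emulate.** No loops or stripes, no
sub-compartments, no structured trans contacts, uniform mappability and GC
composition of the background (GC affects only orientation, not counts), no
fragment-level biases, and site classes that differ only in their planted
enrichment geometry, not in sequence context. Passing tests therefore
demonstrate correctness of the analysis logic under the stated generative
model — they do not certify performance on real libraries with unmodeled
biases.

## Hi-C core

**Masking.** Any bin overlapping a blacklist interval by ≥ 1 bp is masked;
its rows and columns are zeroed, and masking is idempotent. Balancing never
resurrects masked bins, and bins with zero raw marginal are masked
automatically.

**Iterative correction.** The update divides each weight by the current
corrected marginal and renormalizes weights to mean 1 per chromosome, so a
single pass from flat weights gives $w_i \propto 1/\text{marginal}_i$. Two
modes are exposed because published practice varies: `n_iter = 1`
reproduces a single-pass correction exactly as some studies describe, and
`tol` mode iterates to convergence (marginal coefficient of variation below
`tol`, default used in the pipeline: 1e-4), which is the statistically
conventional choice. Whether a published "single iteration" was intentional
or shorthand cannot be decided from the outside; both are one configuration
switch apart, and the package defaults to the converged mode in the
pipeline while keeping single-pass as the function default.

**Expected, O/E, P(s).** Expected values are per-arm means at each bin
distance over unmasked pairs (each chromosome is one arm unless a
centromere split is supplied — synthetic genomes have none). O/E entries
are undefined on the diagonal, across arms, for masked bins and where
E(d) = 0. P(s) aggregates per-arm decay curves weighted by pair counts into
log-spaced distance bins (8 per decade); the log–log slope over a mid-range
window recovers $-\alpha$ within 0.1 at the depths above.

**Differential maps.** Balanced values are coarsened to 1 Mb by summation
before the log2 ratio, so the ratio is taken between normalized contact
sums; cells zero in either map are missing, making the output antisymmetric
under argument swap.

## Compartments

EV1 is computed per chromosome, in cis, from the Pearson correlation matrix
of the O/E columns (pairwise-complete), double-centred, using the
eigenvector of the largest-magnitude eigenvalue scaled by the square root
of its absolute value. The sign is flipped if the correlation with the GC
track is negative. Per-chromosome decomposition (rather than genome-wide)
matches how the rest of the stack is organized; chromosomes with fewer than
10 usable bins return NA with a warning. An EV1 of exactly 0 is treated as
NA rather than as a compartment, since the definition is sign-based.

The switch classifier labels a bin A-to-B only when EV1 is positive in the
baseline and negative in the perturbed condition in both cell lines, making
it symmetric in the lines and antisymmetric in condition order; any
undefined EV1 among the four inputs gives NA, and the reported proportion
is over non-NA bins.

Saddle grids use equal-count percentile assignment with deterministic ties
broken by genomic order, accumulate per arm and aggregate weighted by pair
counts, and are untrimmed by default (a `trim` quantile range is available)
because no trimming convention is universal. Cell standard errors are
tracked alongside means. One statistical caveat is worth stating: a 50×50
grid has 1275 distinct cells, so even under a perfectly calibrated null
about three cells are expected to deviate from 1 by more than 3 SE — a
simultaneous "every cell within 3 SE" check fails by multiplicity alone
with high probability, and the package's own calibration test documents
exactly this behaviour.

Domain calls are maximal same-sign runs (NA breaks runs; an NA-only
stretch is not a domain). Stack-ups centre each domain (or site) at its
midpoint snapped to the containing bin, extend ±flank, sort rows by size
descending with genomic-order tie-breaks, and mark out-of-chromosome cells
missing. How published figures selected equal numbers of A and B domains
for display is not derivable from their legends, so selection is left to
the caller via the `min_size` filter rather than guessed.

## Insulation

The insulation window for bin $i$ is the $w \times w$ square of pairs
$(a, b)$ with $i-w \le a < i < b \le i+w$ ($w$ = window/resolution,
default 100 kb at 10 kb bins). Scores are log2 ratios to the chromosome
mean of window means, which cancels any global scale factor. Scores are NA
where the window does not fit or where more than half of its cells are
masked. Borders are local minima with topographic prominence ≥
`min_prominence` (default 0.2 log2 units — a conservative level chosen so
that flat, noise-only maps yield essentially no borders; published work
states no threshold, so it is exposed as configuration). Border overlap
uses greedy nearest-first one-to-one matching within an inclusive ±20 kb
tolerance, preventing clustered borders from being counted twice.

## Tracks

Units are explicit tags and the normalization order is enforced:
counts → cpm → log2 ratio → z-score. Fragments are counted by midpoint —
the least ambiguous single-bin rule when the upstream convention is
unstated — and re-binning is restricted to count tracks so aggregation
always precedes normalization. Zeros in either IP or input make a log-ratio
bin missing (no pseudocount); this matches the treatment of zeros as
no-data implied by "non-zero" smoothing. Z-scores are per chromosome over
non-missing bins and idempotent; constant chromosomes become missing.
Smoothing averages each non-zero bin with its non-zero neighbours
(window 3), truncating at chromosome ends, and provably preserves the zero
set.

## Sites

Mean EV1 per site replicates the 50 kb signal onto 10 kb bins
piecewise-constantly (no interpolation — the simplest faithful reading of
re-binning to a finer grid) and averages over overlapping bins; sites with
under 50% defined bins are dropped by default (`min_defined_frac`), the
package's resolution of how masked-region sites were likely filtered.
Quadrant classification maps sign pairs to A-to-B / B-to-A /
A-stable / B-stable, reports proportions over informative sites, and
summarizes replicate lines as mean ± SD. Randomized controls preserve the
exact length multiset, are placed uniformly over the unmasked genome
(proportionally to chromosome length, not the original chromosomes, since
only size matching is claimed), and can additionally match compartment
label counts by rejection sampling. Group comparisons (e.g. rescue
switchers vs stayers) run Mann-Whitney tests for every between-group
contrast within condition and between-condition contrast within group,
with BH adjustment across that family — the FDR family is per invocation,
since no global family is definable from the outside.

## Statistics

The U statistic counts pairs with half-weight ties via the rank-sum
identity. Exact mode uses the Wilcoxon distribution when there are no ties
and full enumeration of group assignments when there are; auto mode is
exact for $n_1 n_2 \le 400$, which bounds runtime while keeping exactness
where it matters. The two-tailed p is $\min(1, 2\min(P(U\le u), P(U\ge u)))$
— the standard convention, stated explicitly because tail rules are often
left implicit. The normal mode applies tie and continuity corrections;
degenerate data give p = 1. BH adjustment delegates to `stats::p.adjust`.

## Known limitations

- Rank tests compare site groups whose interval sizes differ, so group
  variances differ even under the null; Mann-Whitney rejection rates are
  then mildly inflated (≈ 6% at a nominal 5% in the package's own
  simulations). This is inherent to the test, not specific to this
  implementation.
- Single-pass ICE leaves residual marginal variation by construction; use
  `tol` mode when downstream analyses assume equal marginals.
- EV1 sign orientation requires a GC track that genuinely correlates with
  activity; on genomes where it does not, orientation (though not the
  segmentation) is arbitrary per chromosome.
- The pipeline currently orchestrates simulated inputs end to end; analyses
  of real data use the same exported functions on maps imported from
  triplet files, but no cool/mcool importer is bundled.
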