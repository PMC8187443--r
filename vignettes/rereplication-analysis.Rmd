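---
title: "Models and methods behind rerepkit"
author: "rerepkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rerepkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rerepkit)
```

# The biological setting

Proliferating cells license many more replication origins than they use:
pre-replication complexes (CDT1-loaded MCM helicases) mark a large pool of
potential initiation sites in G1, of which only a fraction fire in any one
S phase. Normally, re-licensing of replicated DNA is blocked, so every
region is duplicated exactly once. When that block fails — for instance
when CDT1 escapes degradation — cells *re-replicate*: they re-initiate
synthesis on chromatin that has already been duplicated within the same
cycle, locally raising copy number above two and substituting BrdU into
both strands of the re-replicated duplexes (heavy-heavy DNA in a CsCl
gradient).

`rerepkit` implements the quantitative readouts of this phenotype —
replication timing from copy number, origin-usage comparisons from
nascent-strand sequencing, density-gradient fractionation, DNA-combing
fiber statistics, and chromatin association — together with a stochastic
simulator that generates all of these inputs with known ground truth, so
each analysis can be validated end to end.

# The simulator

## Genome and licensing

`build_genome()` draws a replication-timing field on a single synthetic
chromosome: white noise is low-pass filtered with a Gaussian kernel
(`smooth_bins`, the sd in bins) and min-max rescaled to $[0, 1]$ (0 =
earliest). Smoothing produces the contiguous early/late domains that real
chromosomes show; the kernel width sets the domain scale. The euchromatin
score is an A/B-compartment-style proxy,
$\mathrm{euch} = c\,(-z(\mathrm{timing})) + \sqrt{1 - c^2}\,\varepsilon$,
so `coupling` $c$ interpolates between an exact early↔open relationship
($c = 1$) and independence ($c = 0$).

`place_origins()` samples licensed origins with intensity
$\propto \exp(\kappa (1 - \mathrm{timing}))$: `skew` $\kappa > 0$
concentrates licensing on early, open chromatin, mirroring the biased
deposition of pre-replication complexes. Each origin's licensing `weight`
is the same intensity at its bin (mean-normalized); a configurable
fraction is flagged *dormant* — licensed sites that essentially never fire
during normal growth (`dormant_epsilon` times the base probability) and
activate only under replication stress.

## Per-cell replication kinetics

In `simulate_population()`, each cell draws an independent set of firing
origins (probability `fire_prob_normal * weight`, capped at 1). A fired
origin initiates at time equal to its local timing value plus clamped
Gaussian jitter (`firing_jitter`, S-phase units), and its two forks
progress at `fork_speed_kb_per_min`, so a bin's replication time is the
lower envelope $\min_i\, t_i + d(b, o_i)/(v\,T_S)$ over fired origins.
Asynchronous harvest samples per-cell S-phase progress $u \sim U(0,1)$,
interpreted as the *fraction of the genome replicated*: the
earliest-replicating fraction $u$ of bins is duplicated at harvest. This
constant-synthesis-rate reading makes the expected copy number an exact
monotone function of replication-time rank, which is the assumption that
copy-number-based timing inference rests on anyway; an earlier variant
that thresholded absolute replication times against per-cell extremes
added correlated cell-level noise with no biological content.

Modes:

* **normal** — one round; per-cell copy is 1 or 2, and every replicated
  bin yields two heavy-light (one-strand-labeled) duplexes.
* **rereplication** — cells are harvested in the re-replication phase with
  the first round complete (experimentally, re-replicating populations
  are sampled at late timepoints when nearly all cells re-replicate, with
  DNA content beyond 4N). Cells past `rerep_onset` (default 0.5 —
  re-initiation begins in mid-to-late S, not immediately after the first
  passage of a fork) run `rerep_rounds` rounds of re-licensing in which
  origins that fired in round one — never dormant ones, since
  re-replication draws on the same origin pool as normal growth — re-fire
  with probability
  $\min(1,\ \texttt{relicense\_prob} \cdot w_i \cdot e^{-\beta\,
  \mathrm{timing}_i})$. Each re-initiation copies an exponential tract
  (mean `rerep_tract_kb` per side) and converts one heavy-light duplex
  into a heavy-light plus a heavy-heavy pair. The tract length is drawn
  independently of timing, so the early bias of re-replication is carried
  *only* by $\beta$ (and by $\kappa$ through the weights): with
  $\beta = 0$ and unskewed licensing the re-replication landscape is flat
  by construction, which is the null the analyses are tested against.
* **stress** — dormant origins gain firing probability
  (`stress_dormant_prob`; an activated dormant origin behaves like a
  normal one, default equal to `fire_prob_normal`) and forks are slowed
  by `stress_speed_factor`; no re-round.

All probabilities are per label window or per replication round, not per
minute. The kinetics of re-licensing (per unit time versus per round) are
not experimentally established; the per-round model was chosen for
transparency and is a modeling convention, not an inference.

## Strand substitution and the density gradient

Fragment bookkeeping is semiconservative: an unreplicated bin contributes
one light-light duplex per cell, a replicated bin two heavy-light
duplexes, and each re-replication event one heavy-heavy duplex.
`label_doublings >= 2` models a label spanning multiple population
doublings as *complete* substitution (all heavy-heavy). Exact
semiconservative bookkeeping would leave the two original parental strands
unlabeled indefinitely (50% HL duplexes after exactly two doublings), but
long-label DNA is used in practice as the fully substituted heavy-heavy
control, and the unsubstituted remainder is discarded with the light
fractions; the simulator adopts that operational reading.

`simulate_gradient()` draws each duplex's buoyant density from
$N(\rho_{\mathrm{class}}, \sigma)$ with $\rho_{LL} < \rho_{HL} <
\rho_{HH}$ (defaults 1.70/1.75/1.80 g/ml, $\sigma$ = 0.01) and bins them
into equal-width fractions spanning the class densities ±4σ. A class's
*window* is the set of fractions whose center is nearest that class's
density; with $\sigma$ small against the 0.05 g/ml class separation the
heavy-heavy window mass recovers the simulated re-replicated fraction to
within binomial error.

## Fibers

`simulate_fibers()` models combed DNA: origins along a fiber follow a
Poisson process (gaps exponential with mean `mean_iod_kb`, default 120 kb,
in the normal 100–150 kb inter-origin range), and each origin's two forks
run for the total label time (20 + 20 min IdU/CldU at
`fork_speed_kb_per_min`, default 1.5). Independently per side, a fork
stalls with probability `stall_prob` at a uniform time within the window,
truncating that side. Measurement noise is multiplicative lognormal with
mean 1 and coefficient of variation `fiber_noise_cv` (default 5%), so real
control data's nonzero false-asymmetry rate is reproducible and tunable —
and exactly zero asymmetry is recovered when both stalling and noise are
switched off.

# The analyses

## Replication timing

`log2_ratio()` computes $\log_2\frac{s + c}{g_1 + c}$ per bin
(pseudocount $c$ = 1 read by default, which keeps unmappable or empty bins
finite), with optional median centering (off by default) and an optional
centered running mean (off by default; smoothing is an analysis choice,
not part of the definition). `stratify_by_range_percentile()` supports
two schemes. The six-group scheme places boundaries at fixed percentiles
of the total ratio *range* — not quantiles, so group sizes are unequal on
purpose. Which end of the range is "0%" is a convention; the package
orients the top 10% of the range as Very Early, because higher S/G1 copy
number means earlier replication in asynchronous cells. Intervals are
lower-closed with the top bin closed. The four-group scheme ranks bins by
ratio and cuts four equal-count groups, ties broken by genomic coordinate
for determinism.

## Amplification scores

The amplification score of an origin is the difference of log2
*nascent-strand* enrichments, re-replicating minus control, at the
origin's bin — i.e. how much more frequently the origin initiates in
re-replicating cells than in normal cells, measured against a sheared
genomic-DNA background and after library-size normalization. Using
nascent-strand (origin-activity) tracks rather than bulk copy-number
tracks matters: the copy-number control subtracts the full async timing
gradient and would impose a spurious late-positive offset on the score,
whereas initiation-frequency ratios isolate the re-firing bias itself —
they are flat when re-firing is unbiased and strictly graded by timing
when it is not. Group summaries report the median, quartiles and 5th/95th
percentiles; box displays use 1.5×IQR whiskers clipped to the data.

## Origin usage

Normalized counts default to a scale equal to the mean library size, so
values stay on the familiar reads-per-peak scale while being comparable
across conditions. The fraction analysis uses
$r = \log_2\frac{y + 1}{x + 1}$ and 10 equal-width half-open bins on
$[-R, R]$, $R = \max|r|$ over classified peaks, numbered from y-dominant
to x-dominant; equal-count deciles are available behind a flag since the
equal-width choice is a convention. Peak size classes (small 250–400,
large >400, excluded <250) are computed on a configurable condition
statistic (`mean`, `x`, `y` or `max`); the mean is the default, but
timing-stratified comparisons where the treated library is empty in late
groups are better served by sizing on the control condition (`x`), since
otherwise every late peak falls below the exclusion threshold and the
group cannot be scored at the fixed thresholds.

## Chromatin association

`segment_domains()` thresholds a track at a background quantile, merges
runs across gaps shorter than `min_gap_bp` and drops domains below
`min_size_bp`; a domain's height is the *maximum* bin value (peak height,
not mean). `quartile_stratify()` cuts equal-count peak-height quartiles
with coordinate tie-breaks, so the labeling is invariant to input order.
`inc_ratio()` counts sample intervals overlapping ≥1 bp of the reference
(each sample interval at most once; a pair-counting mode exists) and
divides by the sum of the two sets' sizes; sizes are interval *counts* by
default, with a covered-bp mode available — the "size of a file" in this
statistic is a convention, and the count reading keeps the ratio bounded
by $\min(n_s, n_r)/(n_s + n_r)$. All coordinates are 0-based, half-open.
`anchor_profile()` averages signal at bin offsets within ±`flank_bp` of
anchor positions; the matched random control draws the same number of
positions uniformly, excluding the real anchors ± flank, which requires an
anchor set sparse enough to leave background (profiles of dense origin
sets should be computed on a subsample).

# What the generator does and does not emulate

It emulates: contiguous timing domains; early-skewed licensing;
intermittent firing; passive replication by forks from neighbors; the
asynchronous copy-number gradient; re-initiation restricted to the normal
origin pool with a tunable early bias; dormant-origin activation under
stress; strand-level BrdU substitution with gradient fractionation; fork
stalling and optical noise on fibers; Poisson sequencing noise.

It does not emulate: sequence-level reads (no FASTQ, alignment or peak
calling — peak lists and counts are first-class objects), mappability or
GC bias, multiple chromosomes, chromatin contact maps (the euchromatin
score is a one-dimensional proxy, not a Hi-C eigenvector computation),
replication checkpoints, or cell death. Passing tests therefore show that
the analysis code correctly recovers the structures the generative model
contains — not that real libraries are free of the biases the model omits.

# Numerical and scale choices

Tests and the acceptance script run coverage-scale experiments on a 30 Mb
genome (3000 × 10 kb bins) with ~0.8 Mb timing domains, licensed origins
every ~17 kb (60/Mb) firing in 30% of cycles, 500-cell populations, 1000
reads/bin coverage and a 31-bin (310 kb) running mean on ratio tracks —
the regime where fired-origin spacing is far below the timing-domain
scale, which is what makes copy-number timing inference work in real
genomes. Timing-quartile recovery exceeds 90% across seeds under these
conditions. Nascent-strand experiments use 1500 reads per always-firing
origin (4000 for the timing-stratified fraction analysis, where late
origins fire rarely and shallow libraries would fall below the fixed
250-read exclusion threshold). Demo pipelines run a 4 Mb genome with 150
cells and finish in a few seconds.

Other numerical conventions: the exact Mann–Whitney branch is used for
$\min(n, m) \le 8$ without ties, the normal approximation with tie and
continuity corrections otherwise (the continuity correction keeps the two
branches within 0.02 of each other at $n = m = 8$); the 2×2 chi-square
uses no continuity correction by default; the asymmetric-fork rule is
strict (> 0.30) with $\max(L, R)$ as denominator — the conservative,
symmetric choice, configurable to the mean; random draws are scoped with
`withr::with_seed` so every function is bit-reproducible for a fixed seed
and leaves the caller's RNG state untouched.

# Known limitations

* One synthetic chromosome; multi-chromosome bookkeeping exists only in
  the interval utilities (BED/bedGraph/IncRatio), not in the simulator.
* The re-licensing clock is per round, not per minute; absolute times in
  the re-replication phase are not modeled.
* Copy number above ~2 per-cell is generated by overlapping exponential
  tracts, not by explicit nested fork structures; onion-skin
  intermediates are not represented.
* The gradient model treats fragment density as a pure mixture of three
  classes; partial substitution within a fragment (fragmentation across a
  replication boundary) is ignored.
* Library normalization is linear (single scale factor); no
  composition-aware normalization is provided.

```{r example}
g <- build_genome(n_bins = 400, bin_width = 10000, coupling = 0.9,
                  smooth_bins = 40, seed = 1)
o <- place_origins(g, density_per_mb = 30, skew = 2,
                   dormant_fraction = 0.15, seed = 2)
p <- sim_params(cells = 100)
pop <- simulate_population(g, o, p, "rereplication", seed = 3)
pop
fragment_class_counts(pop)
```
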