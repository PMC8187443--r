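# rerepkit

Analysis toolkit for **genome re-replication** experiments — the situation
in which replication licensing control breaks down (e.g. CDT1
stabilization after NEDDylation inhibition) and cells re-initiate DNA
synthesis on chromatin they have already replicated within the same cycle.
The package is aimed at computational biologists analyzing the sequencing
and single-fiber readouts of such experiments: copy-number-based
replication timing, nascent-strand origin maps, BrdU/CsCl density
gradients, DNA-combing fiber measurements, and chromatin-association
statistics. A seeded stochastic simulator generates every input the
analyses consume, so the whole pipeline is exercisable — and testable —
without any external data.

## What it computes

* **Replication timing** from binned coverage: the per-bin ratio
  `log2((S + c) / (G1 + c))` of asynchronous-S over G1 libraries orders the
  genome from late to early (early regions are present in more copies in
  asynchronous cells). Bins are stratified either into four equal-count
  groups, or by *range percentile* — boundaries at fixed fractions of the
  total ratio range, top 10% = Very Early down to bottom 10% = Very Late.
* **Origin-usage comparisons** between conditions: per-origin read counts
  are library-size normalized (`raw * scale / library_size`), paired into
  density-plot coordinates, given the statistic `r = log2((y+1)/(x+1))`,
  and split into 10 equal-width fractions from y-dominant to x-dominant,
  with peaks size-classed as small (250–400 reads) or large (>400).
  Dormant origins are called when the control count is below a low
  threshold and the treated count above a high one.
* **Amplification scores** per origin: the difference of log2
  nascent-strand enrichment, re-replicating minus control, summarized per
  timing group (median, quartiles, 5th/95th percentiles).
* **Fiber statistics** from DNA combing: fork rate (kb/min), inter-origin
  distances, and the asymmetric-fork rule `|L - R| / max(L, R) > 0.30`,
  with a Mann–Whitney rank-sum test (exact by enumeration for small
  samples) and the closed-form 2×2 chi-square
  `N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.
* **Chromatin association**: segmentation of re-replicated coverage into
  domains with peak-height quartiles; the interval inclusion ratio
  `IncRatio = n_overlaps / (size_sample + size_reference)`; Pearson
  correlation with a Hi-C-eigenvector-style euchromatin score; and
  origin-anchored signal profiles with a seeded random-anchor control.
* **The simulator**: smooth random replication-timing fields, licensing
  with early skew `exp(kappa * (1 - timing))`, per-cell origin firing and
  fork progression, re-firing of the *same* origin pool with probability
  `relicense_prob * weight * exp(-beta * timing)`, dormant-origin
  activation under stress, fork stalling on fibers, semiconservative
  BrdU strand bookkeeping (LL/HL/HH duplexes) and CsCl gradient
  fractionation.

## Worked example

The config-driven pipeline simulates one experiment end to end and runs
every analysis stage:

```r
library(rerepkit)
cfg <- system.file("extdata", "demo_config.yaml", package = "rerepkit")
report <- run_pipeline(cfg, out_dir = "demo_out")
```

On the shipped demo configuration (4 Mb genome, 150 cells, seed 1) the
report contains, among others:

```
asymmetric forks     control  8.41 %   treated 25.58 %   (chi-square 64.9)
median fork rate     control  1.50     treated  0.98 kb/min
median inter-origin  control 82.1      treated 43.1 kb
eigen correlation R  0.695
dormant share        stress 0.151      re-replication 0
gradient HH mass     0.104
```

Reading it: the treated (re-replicating) arm shows three times more
asymmetric forks (frequent stalling), slower forks and halved inter-origin
distances (more initiation events); the re-replicated coverage correlates
with the euchromatin score (open chromatin re-replicates preferentially);
stress activates a distinct dormant-origin population while
re-replication reuses the normal origin pool (dormant share 0); and about
10% of duplexes in the re-replicating population carry BrdU on both
strands (heavy-heavy DNA). Every output file is written under `demo_out/`
with a `manifest.json` of md5 checksums — rerunning with the same seed
reproduces them bit for bit.

Single analyses work standalone:

```r
fib <- simulate_fibers(sim_params(stall_prob = 0.20), n_fibers = 300, seed = 3)
asymmetry_summary(fib, threshold = 0.30)
#> <asymmetry_summary> 134/572 asymmetric (23.4%) at threshold 0.30 (0 excluded)
rank_sum_test(c(1, 2, 3), c(10, 11, 12))$p.value
#> [1] 0.1
```

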