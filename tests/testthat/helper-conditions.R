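## The frozen study conditions for coverage-scale experiments: a 30 Mb
## genome with ~0.8 Mb timing domains, licensed origins every ~17 kb
## (60/Mb) firing in 30% of cycles, 500-cell populations, 1000 reads/bin
## coverage and 1500 reads per always-firing origin. A 31-bin running mean
## (310 kb, well below the timing-domain scale) smooths coverage ratios.

study_genome <- function(seed, coupling = 0.9) {
  build_genome(3000, 10000, coupling = coupling, smooth_bins = 80,
               seed = seed)
}

study_origins <- function(genome, seed, skew = 2, dormant_fraction = 200 / 1800) {
  place_origins(genome, density_per_mb = 60, skew = skew,
                dormant_fraction = dormant_fraction, seed = seed)
}

study_params <- function(...) sim_params(cells = 500, ...)

study_ratio <- function(genome, pop, g1_seed, s_seed, depth = 1000) {
  g1 <- simulate_coverage(genome, NULL, depth, seed = g1_seed)
  s <- simulate_coverage(genome, pop, depth, seed = s_seed)
  log2_ratio(s, g1, smooth_bins = 31)
}

## true timing quartiles of the genome field, on the same orientation as
## the inferred groups (earliest timing = Early = highest ratio)
true_timing_groups <- function(genome) {
  stratify_by_range_percentile(
    as_ratio_track(-genome$timing, bin_width = genome$bin_width),
    "four_equal")
}

ratio_as_value_track <- function(ratio) {
  data.frame(chrom = ratio$chrom, start = ratio$start, end = ratio$end,
             value = ratio$log2_ratio)
}
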