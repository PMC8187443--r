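## Shared fixture builders. Everything is generated in code at test time.

tiny_genome <- function(n_bins = 200, bin_width = 10000, seed = 1,
                        coupling = 1, smooth_bins = 20) {
  build_genome(n_bins, bin_width, coupling = coupling,
               smooth_bins = smooth_bins, seed = seed)
}

## plain track on n unit-spaced bins
flat_track <- function(values, bin_width = 10, chrom = "chrT") {
  n <- length(values)
  data.frame(chrom = chrom, start = (seq_len(n) - 1) * bin_width,
             end = seq_len(n) * bin_width, value = as.numeric(values))
}

as_ratio_track <- function(values, bin_width = 10, chrom = "chrT") {
  n <- length(values)
  structure(
    data.frame(chrom = chrom, start = (seq_len(n) - 1) * bin_width,
               end = seq_len(n) * bin_width, log2_ratio = as.numeric(values)),
    class = c("ratio_track", "data.frame"),
    pseudocount = 1, median_centered = FALSE, smooth_bins = 0)
}

## hand-built origin_pairs for origin-usage tests
make_pairs <- function(x, y, position = seq_along(x) * 1000) {
  structure(
    data.frame(origin_id = seq_along(x), position = position,
               x_raw = x, y_raw = y, x = x, y = y),
    class = c("origin_pairs", "data.frame"), x_cond = "x", y_cond = "y")
}

## hand-built fiber_set
make_fibers <- function(left, right, fiber_id = seq_along(left),
                        pos = seq_along(left) * 100, label_minutes = 40) {
  structure(
    data.frame(fiber_id = fiber_id, origin_pos_kb = pos,
               left_kb = left, right_kb = right),
    class = c("fiber_set", "data.frame"), label_minutes = label_minutes)
}

random_intervals <- function(n, span = 100000, max_len = 2000, seed = 1,
                            chroms = c("chrA", "chrB")) {
  withr::with_seed(seed, {
    start <- floor(runif(n, 0, span))
    len <- ceiling(runif(n, 1, max_len))
    data.frame(chrom = sample(chroms, n, replace = TRUE),
               start = start, end = start + len)
  })
}

## O(n^2) all-pairs overlap oracle (0-based half-open intervals)
brute_force_overlaps <- function(sample, reference) {
  hits <- vapply(seq_len(nrow(sample)), function(i) {
    any(sample$chrom[i] == reference$chrom &
          sample$start[i] < reference$end &
          reference$start < sample$end[i])
  }, logical(1))
  sum(hits)
}

bin_of_positions <- function(genome, pos) {
  pmin(genome$n_bins, floor(pos / genome$bin_width) + 1L)
}
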