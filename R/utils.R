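## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Gaussian low-pass filter with reflecting boundaries; sd in bins.
gauss_smooth <- function(x, sd_bins) {
  n <- length(x)
  if (sd_bins <= 0 || n < 3L) return(x)
  half <- min(ceiling(3 * sd_bins), n - 1L)
  k <- stats::dnorm(seq(-half, half), sd = sd_bins)
  k <- k / sum(k)
  xp <- c(rev(x[seq_len(half)]), x, rev(x[seq(n - half + 1L, n)]))
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[seq(half + 1L, half + n)])
}

## Centered running mean (odd window), reflecting boundaries.
run_mean <- function(x, window) {
  if (window <= 1L) return(x)
  if (window %% 2L == 0L) window <- window + 1L
  n <- length(x)
  half <- min((window - 1L) %/% 2L, n - 1L)
  xp <- c(rev(x[seq_len(half)]), x, rev(x[seq(n - half + 1L, n)]))
  out <- stats::filter(xp, rep(1 / (2 * half + 1), 2 * half + 1), sides = 2)
  as.numeric(out[seq(half + 1L, half + n)])
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

## Assert two binned tracks share the same binning.
check_same_bins <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !identical(a$chrom, b$chrom) ||
      !identical(a$start, b$start) ||
      !identical(a$end, b$end)) {
    stop_invalid("tracks do not share the same binning")
  }
  invisible(TRUE)
}

check_track <- function(track) {
  need <- c("chrom", "start", "end", "value")
  if (!is.data.frame(track) || !all(need %in% names(track))) {
    stop_invalid("a track must be a data.frame with columns chrom/start/end/value")
  }
  if (nrow(track) == 0L) stop_invalid("track is empty")
  invisible(TRUE)
}

## data.frame of bins for a genome_model (0-based, half-open)
genome_bins <- function(genome) {
  starts <- (seq_len(genome$n_bins) - 1L) * genome$bin_width
  data.frame(chrom = genome$chrom, start = starts,
             end = starts + genome$bin_width)
}

make_track <- function(genome, value) {
  b <- genome_bins(genome)
  b$value <- as.numeric(value)
  b
}

## Bin index (1-based) for a base-pair position; NA outside the genome.
bin_of <- function(genome, pos) {
  idx <- floor(pos / genome$bin_width) + 1L
  idx[pos < 0 | idx > genome$n_bins] <- NA_integer_
  as.integer(idx)
}

## Derive a bounded child seed from a base seed and a stage offset.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}
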