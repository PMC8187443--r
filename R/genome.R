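#' Build a synthetic binned genome with replication timing and chromatin state
#'
#' Generates one synthetic chromosome divided into `n_bins` fixed-width bins.
#' The replication-timing field is a smooth random surface in `[0, 1]`
#' (0 = earliest replicating, 1 = latest), obtained by Gaussian low-pass
#' filtering of white noise followed by min-max rescaling, so that contiguous
#' early and late replication domains emerge as they do along real
#' chromosomes. The euchromatin score is a Hi-C-eigenvector-like proxy:
#' positive values mark open, A-compartment-like chromatin. It is built as
#' `coupling * (-z(timing)) + sqrt(1 - coupling^2) * noise`, so with
#' `coupling = 1` it is exactly the standardized negative of timing (early
#' regions euchromatic) and with `coupling = 0` it is independent noise.
#'
#' @param n_bins number of bins (>= 1).
#' @param bin_width bin width in bp (>= 1).
#' @param chrom chromosome name used in every emitted track.
#' @param coupling number in `[0, 1]`; strength of the (negative)
#'   timing-euchromatin coupling.
#' @param smooth_bins standard deviation, in bins, of the Gaussian kernel
#'   used to smooth the timing field. Larger values give broader timing
#'   domains; default 20 bins.
#' @param seed integer seed; the same configuration and seed always yield an
#'   identical genome.
#' @return An object of class `genome_model`: a list with elements `chrom`,
#'   `n_bins`, `bin_width`, `timing`, `euchromatin`, `coupling` and `seed`.
#' @examples
#' g <- build_genome(n_bins = 200, bin_width = 10000, seed = 1)
#' range(g$timing)
#' cor(g$timing, g$euchromatin, method = "spearman")
#' @export
build_genome <- function(n_bins, bin_width, chrom = "chrS", coupling = 1,
                         smooth_bins = 20, seed = 1L) {
  if (length(n_bins) != 1L || is.na(n_bins) || n_bins < 1) {
    stop_invalid("invalid config: n_bins must be >= 1")
  }
  if (length(bin_width) != 1L || is.na(bin_width) || bin_width < 1) {
    stop_invalid("invalid config: bin_width must be >= 1")
  }
  if (coupling < 0 || coupling > 1) {
    stop_invalid("invalid config: coupling must be in [0, 1]")
  }
  n_bins <- as.integer(n_bins)
  withr::with_seed(as.integer(seed), {
    timing <- gauss_smooth(stats::rnorm(n_bins), smooth_bins)
    rng <- range(timing)
    timing <- if (diff(rng) > 0) (timing - rng[1]) / diff(rng) else
      rep(0.5, n_bins)
    z <- if (stats::sd(timing) > 0) as.numeric(scale(timing)) else
      numeric(n_bins)
    euch <- coupling * (-z) + sqrt(max(0, 1 - coupling^2)) * stats::rnorm(n_bins)
  })
  structure(
    list(chrom = chrom, n_bins = n_bins, bin_width = as.numeric(bin_width),
         timing = timing, euchromatin = euch, coupling = coupling,
         seed = as.integer(seed)),
    class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %s: %d bins x %g bp (%.2f Mb), coupling %.2f, seed %d\n",
              x$chrom, x$n_bins, x$bin_width,
              x$n_bins * x$bin_width / 1e6, x$coupling, x$seed))
  invisible(x)
}

#' Genome length in bp
#' @param genome a `genome_model`.
#' @return total length in bp.
#' @export
genome_length <- function(genome) genome$n_bins * genome$bin_width

#' Per-bin tracks of a synthetic genome
#'
#' Extract the timing or euchromatin field as a bedGraph-style track
#' (`chrom`, `start`, `end`, `value`; 0-based, half-open).
#'
#' @param genome a `genome_model`.
#' @param what `"timing"` or `"euchromatin"`.
#' @return a track `data.frame`.
#' @export
genome_track <- function(genome, what = c("timing", "euchromatin")) {
  what <- match.arg(what)
  make_track(genome, genome[[what]])
}

#' Place replication origins on a synthetic genome
#'
#' Origin placement follows an inhomogeneous intensity proportional to
#' `exp(skew * (1 - timing))`: with `skew = 0` origins are uniform; positive
#' `skew` concentrates licensing in early-replicating regions, emulating the
#' biased deposition of pre-replication complexes (CDT1/MCM loading) on open
#' chromatin. Each origin carries a licensing weight proportional to the same
#' intensity at its bin (normalized to mean 1), and a fraction of origins is
#' flagged dormant: licensed sites that essentially never fire during normal
#' growth and activate only under replication stress.
#'
#' @param genome a `genome_model`.
#' @param density_per_mb expected origins per Mb (> 0).
#' @param skew licensing skew `kappa` (>= 0 gives early preference).
#' @param dormant_fraction fraction of origins flagged dormant.
#' @param seed integer seed.
#' @return an `origin_set`: a data.frame with columns `position` (bp,
#'   strictly increasing), `weight` (>= 0, mean 1) and `dormant` (logical).
#' @examples
#' g <- build_genome(1000, 10000, seed = 1)
#' o <- place_origins(g, density_per_mb = 10, skew = 2, seed = 2)
#' nrow(o)
#' @export
place_origins <- function(genome, density_per_mb, skew = 0,
                          dormant_fraction = 0, seed = 1L) {
  if (density_per_mb <= 0) stop_invalid("invalid config: density_per_mb must be > 0")
  if (dormant_fraction < 0 || dormant_fraction > 1) {
    stop_invalid("invalid config: dormant_fraction must be in [0, 1]")
  }
  len_mb <- genome_length(genome) / 1e6
  n_exp <- density_per_mb * len_mb
  if (n_exp < 1) {
    warning("expected origin count < 1; returning an empty origin set")
    return(empty_origin_set(genome))
  }
  n <- max(1L, round(n_exp))
  intensity <- exp(skew * (1 - genome$timing))
  withr::with_seed(as.integer(seed), {
    bins <- sample.int(genome$n_bins, n, replace = TRUE,
                       prob = intensity / sum(intensity))
    pos <- (bins - 1) * genome$bin_width +
      stats::runif(n, 0, genome$bin_width)
    ord <- order(pos)
    pos <- pos[ord]
    bins <- bins[ord]
    ## continuous draws collide with probability zero, but keep the
    ## strictly-increasing invariant robust anyway
    while (any(diff(pos) <= 0)) {
      dup <- which(diff(pos) <= 0) + 1L
      pos[dup] <- pos[dup] + 1e-6
    }
    weight <- intensity[bins]
    weight <- weight / mean(weight)
    dormant <- rep(FALSE, n)
    nd <- round(dormant_fraction * n)
    if (nd > 0) dormant[sample.int(n, nd)] <- TRUE
  })
  structure(
    data.frame(position = pos, weight = weight, dormant = dormant),
    class = c("origin_set", "data.frame"),
    chrom = genome$chrom, genome_length = genome_length(genome))
}

empty_origin_set <- function(genome) {
  structure(
    data.frame(position = numeric(0), weight = numeric(0),
               dormant = logical(0)),
    class = c("origin_set", "data.frame"),
    chrom = genome$chrom, genome_length = genome_length(genome))
}

#' @export
print.origin_set <- function(x, ...) {
  cat(sprintf("<origin_set> %d origins (%d dormant) on %s\n",
              nrow(x), sum(x$dormant), attr(x, "chrom") %||% "?"))
  if (nrow(x)) NextMethod()
  invisible(x)
}
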