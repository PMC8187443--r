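#' Segment a coverage track into re-replication domains
#'
#' Bins above a background threshold (a quantile of the track values) are
#' collected into runs; runs separated by gaps shorter than `min_gap_bp`
#' are merged (the gap is absorbed into the domain), and domains shorter
#' than `min_size_bp` are dropped. Each domain carries its peak height, the
#' maximum track value inside the interval.
#'
#' @param track a coverage track (chrom/start/end/value, equal-width bins).
#' @param background_quantile quantile of the values defining background
#'   (default 0.5; bins strictly above it are signal).
#' @param min_gap_bp gaps strictly shorter than this are merged (bp).
#' @param min_size_bp domains shorter than this are dropped (bp).
#' @return a `domain_set`: data.frame `chrom`, `start`, `end`, `size_bp`,
#'   `peak_height`, sorted and non-overlapping; attribute `threshold`.
#'   A track entirely at/below threshold gives an empty set (no error).
#' @export
segment_domains <- function(track, background_quantile = 0.5,
                            min_gap_bp = 0, min_size_bp = 0) {
  check_track(track)
  threshold <- stats::quantile(track$value, background_quantile, names = FALSE)
  above <- track$value > threshold
  empty <- structure(
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               size_bp = numeric(0), peak_height = numeric(0)),
    class = c("domain_set", "data.frame"), threshold = threshold)
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(b0 = starts[r$values], b1 = ends[r$values])
  ## merge runs across sub-threshold gaps shorter than min_gap_bp
  if (nrow(runs) > 1L) {
    gap_bp <- (track$start[runs$b0[-1]] - track$end[runs$b1[-nrow(runs)]])
    new_dom <- c(TRUE, gap_bp >= min_gap_bp)
    grp <- cumsum(new_dom)
    runs <- data.frame(b0 = tapply(runs$b0, grp, min),
                       b1 = tapply(runs$b1, grp, max))
  }
  dom <- data.frame(
    chrom = track$chrom[runs$b0],
    start = track$start[runs$b0],
    end = track$end[runs$b1])
  dom$size_bp <- dom$end - dom$start
  dom$peak_height <- mapply(function(i, j) max(track$value[i:j]),
                            runs$b0, runs$b1)
  dom <- dom[dom$size_bp >= min_size_bp, , drop = FALSE]
  rownames(dom) <- NULL
  if (!nrow(dom)) return(empty)
  structure(dom, class = c("domain_set", "data.frame"), threshold = threshold)
}

#' Stratify domains into peak-height quartiles
#'
#' Domains are ranked by peak height (descending, ties broken by genomic
#' coordinate) and split into four equal-count groups labeled `high`,
#' `mid-high`, `mid-low`, `low`; group sizes differ by at most one.
#'
#' @param domains a `domain_set` with >= 4 domains.
#' @return the `domain_set` sorted by coordinate with an added ordered
#'   factor column `quartile`.
#' @export
quartile_stratify <- function(domains) {
  n <- nrow(domains)
  if (n < 4) stop_invalid("too few domains: need >= 4 to form quartiles")
  lev <- c("high", "mid-high", "mid-low", "low")
  ord <- order(-domains$peak_height, domains$chrom, domains$start)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  domains$quartile <- factor(lev[ceiling(4 * rank / n)], levels = lev,
                             ordered = TRUE)
  out <- domains[order(domains$chrom, domains$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Inclusion-ratio overlap statistic between two interval sets
#'
#' `IncRatio = n_overlaps / (size_sample + size_reference)`, where
#' `n_overlaps` counts sample intervals intersecting at least one reference
#' interval by >= 1 bp (half-open coordinates), and sizes default to
#' interval counts. A sample interval overlapping several reference
#' intervals counts once (mode `"sample"`); `"pairs"` counts every
#' overlapping pair. `size_mode = "bp"` measures sizes in covered bp
#' instead.
#'
#' @param sample,reference data.frames with `chrom`, `start`, `end`
#'   (0-based, half-open; `end > start`).
#' @param size_mode `"count"` (default) or `"bp"`.
#' @param count_mode `"sample"` (default) or `"pairs"`.
#' @return an `overlap_report`: list `n_overlaps`, `size_sample`,
#'   `size_reference`, `inc_ratio`.
#' @export
inc_ratio <- function(sample, reference, size_mode = c("count", "bp"),
                      count_mode = c("sample", "pairs")) {
  size_mode <- match.arg(size_mode)
  count_mode <- match.arg(count_mode)
  check_intervals <- function(x, what) {
    if (!all(c("chrom", "start", "end") %in% names(x))) {
      stop_invalid(what, " must have chrom/start/end columns")
    }
    if (any(x$end <= x$start)) {
      stop_invalid("malformed interval in ", what, ": end <= start")
    }
  }
  check_intervals(sample, "sample")
  check_intervals(reference, "reference")
  as_gr <- function(x) {
    GenomicRanges::GRanges(x$chrom,
                           IRanges::IRanges(start = x$start + 1, end = x$end))
  }
  sg <- as_gr(sample)
  rg <- as_gr(reference)
  cnt <- GenomicRanges::countOverlaps(sg, rg)
  n_over <- if (count_mode == "sample") sum(cnt > 0) else sum(cnt)
  ss <- if (size_mode == "count") nrow(sample) else sum(sample$end - sample$start)
  sr <- if (size_mode == "count") nrow(reference) else sum(reference$end - reference$start)
  structure(list(n_overlaps = n_over, size_sample = ss, size_reference = sr,
                 inc_ratio = if (ss + sr > 0) n_over / (ss + sr) else 0),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> %d overlaps; sizes %g + %g; IncRatio %.4f\n",
              x$n_overlaps, x$size_sample, x$size_reference, x$inc_ratio))
  invisible(x)
}

#' Correlation of re-replication abundance with the euchromatin eigen score
#'
#' Pearson correlation of two binned tracks (re-replicated coverage versus
#' an A/B-compartment-style eigen score), plus per-abundance-group eigen
#' distributions: bins are split into equal-count groups by re-replication
#' abundance (low to high) and each group's eigen scores are summarized
#' with the box convention — median, 25th/75th percentiles, and whiskers at
#' the most extreme values within 1.5 x IQR of the box.
#'
#' @param rerep_track,eigen_track tracks on identical bins with >= 3 bins;
#'   neither may be constant.
#' @param n_groups number of abundance groups (default 4).
#' @return list `R` (Pearson), `groups` (per-group summary data.frame),
#'   `group_of_bin`.
#' @export
eigen_correlation <- function(rerep_track, eigen_track, n_groups = 4) {
  check_track(rerep_track)
  check_track(eigen_track)
  check_same_bins(rerep_track, eigen_track)
  x <- rerep_track$value
  y <- eigen_track$value
  if (length(x) < 3) stop_invalid("need >= 3 bins")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_invalid("undefined correlation: constant input track")
  }
  R <- stats::cor(x, y)
  lev <- if (n_groups == 4) c("low", "mid-low", "mid-high", "high") else
    paste0("g", seq_len(n_groups))
  ord <- order(x, seq_along(x))
  rank <- integer(length(x))
  rank[ord] <- seq_along(x)
  grp <- factor(lev[ceiling(n_groups * rank / length(x))], levels = lev,
                ordered = TRUE)
  summ <- do.call(rbind, lapply(lev, function(l) {
    v <- y[grp == l]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(group = l, n = length(v), median = q[2], q25 = q[1],
               q75 = q[3],
               whisker_lo = min(v[v >= q[1] - 1.5 * iqr]),
               whisker_hi = max(v[v <= q[3] + 1.5 * iqr]))
  }))
  summ$group <- factor(summ$group, levels = lev, ordered = TRUE)
  list(R = R, groups = summ, group_of_bin = grp)
}

#' Signal profile centered on a set of anchors
#'
#' Mean signal at each bin offset within `+/- flank_bp` of the anchor
#' positions (e.g. licensing-factor ChIP coverage centered on replication
#' origins), optionally stratified by replication-timing group, plus a
#' matched random-anchor control: the same number of positions drawn
#' uniformly from the track while excluding the real anchors' flanks.
#'
#' @param signal a coverage track with equal-width bins.
#' @param anchors anchor positions in bp.
#' @param flank_bp flank on each side (>= 1 bin).
#' @param groups optional `timing_groups` on the same bins; adds per-group
#'   profiles and group labels on the anchor scores.
#' @param random_control draw the seeded random-anchor control (default
#'   TRUE).
#' @param seed integer seed for the control.
#' @return an `anchor_profile`: list `offsets_bp`, `profile` (mean signal
#'   per offset), `per_anchor` (position, score = mean over the window,
#'   group), `group_profiles` (matrix, groups x offsets, if stratified),
#'   `random_profile`, `random_se` (per-offset standard error of the
#'   random control), `n_clipped`.
#' @export
anchor_profile <- function(signal, anchors, flank_bp, groups = NULL,
                           random_control = TRUE, seed = 1L) {
  check_track(signal)
  bw <- signal$end[1] - signal$start[1]
  k <- floor(flank_bp / bw)
  if (k < 1) stop_invalid("flank_bp must cover at least one bin")
  n <- nrow(signal)
  abin <- findInterval(anchors, c(signal$start, signal$end[n]),
                       rightmost.closed = FALSE)
  abin[anchors < signal$start[1] | anchors >= signal$end[n]] <- NA_integer_
  usable <- !is.na(abin) & abin - k >= 1 & abin + k <= n
  n_clipped <- sum(!usable)
  if (!any(usable)) stop_invalid("no anchors with a full window inside the track")
  abin <- abin[usable]
  apos <- anchors[usable]
  offs <- seq(-k, k)
  idx <- outer(abin, offs, "+")
  vals <- matrix(signal$value[idx], nrow = length(abin))
  profile <- colMeans(vals)
  score <- rowMeans(vals)
  grp <- NULL
  group_profiles <- NULL
  if (!is.null(groups)) {
    if (length(groups$group_of_bin) != n) {
      stop_invalid("timing groups do not match the signal binning")
    }
    grp <- groups$group_of_bin[abin]
    lev <- levels(groups$group_of_bin)
    group_profiles <- t(vapply(lev, function(l) {
      if (any(grp == l)) colMeans(vals[grp == l, , drop = FALSE])
      else rep(NA_real_, length(offs))
    }, numeric(length(offs))))
    colnames(group_profiles) <- offs * bw
  }
  random_profile <- NULL
  random_se <- NULL
  if (random_control) {
    allowed <- setdiff(seq(k + 1L, n - k), unique(unlist(
      lapply(abin, function(b) seq(max(1L, b - k), min(n, b + k))))))
    if (length(allowed)) {
      rbin <- withr::with_seed(as.integer(seed), {
        sample(allowed, length(abin), replace = length(allowed) < length(abin))
      })
      ridx <- outer(rbin, offs, "+")
      rmat <- matrix(signal$value[ridx], nrow = length(rbin))
      random_profile <- colMeans(rmat)
      random_se <- apply(rmat, 2, stats::sd) / sqrt(nrow(rmat))
    }
  }
  per_anchor <- data.frame(position = apos, score = score)
  if (!is.null(grp)) per_anchor$group <- grp
  structure(list(offsets_bp = offs * bw, profile = profile,
                 per_anchor = per_anchor, group_profiles = group_profiles,
                 random_profile = random_profile, random_se = random_se,
                 n_clipped = n_clipped, flank_bp = flank_bp),
            class = "anchor_profile")
}

#' Simulate a licensing-factor binding track
#'
#' A CDT1/MCM-style ChIP coverage proxy: Poisson reads around a baseline,
#' with Gaussian-shaped enrichment at each origin scaled by its licensing
#' weight — the pre-replication-complex density the origin was placed with.
#'
#' @param genome a `genome_model`.
#' @param origins an `origin_set`.
#' @param background expected background reads per bin.
#' @param enrichment peak enrichment (fold over background, per unit
#'   licensing weight) at the origin bin.
#' @param decay_bins Gaussian sd of the peak shape, in bins.
#' @param seed integer seed.
#' @return a coverage track.
#' @export
simulate_chip_track <- function(genome, origins, background = 20,
                                enrichment = 5, decay_bins = 2, seed = 1L) {
  n <- genome$n_bins
  mu <- rep(1, n)
  if (nrow(origins)) {
    obin <- bin_of(genome, origins$position)
    half <- ceiling(4 * decay_bins)
    for (i in seq_len(nrow(origins))) {
      lo <- max(1L, obin[i] - half)
      hi <- min(n, obin[i] + half)
      d <- (lo:hi) - obin[i]
      mu[lo:hi] <- mu[lo:hi] +
        enrichment * origins$weight[i] * exp(-d^2 / (2 * decay_bins^2))
    }
  }
  val <- withr::with_seed(as.integer(seed), stats::rpois(n, background * mu))
  make_track(genome, val)
}
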