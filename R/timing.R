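#' Log2 coverage ratio track (S or re-replicating over G1)
#'
#' Replication timing in asynchronous populations is read out from copy
#' number: early-replicating regions are present in more copies than
#' late-replicating ones, so the per-bin `log2((s + c) / (g1 + c))` ratio
#' orders the genome from late (low) to early (high). A pseudocount `c > 0`
#' keeps the ratio finite in empty bins.
#'
#' @param s_cov,g1_cov coverage tracks (data.frames with
#'   `chrom`/`start`/`end`/`value`) on identical bins; `s_cov` is the
#'   asynchronous S-phase (or re-replicating) library, `g1_cov` the G1
#'   library.
#' @param pseudocount pseudocount added to both numerator and denominator
#'   (> 0; default 1 read).
#' @param median_center subtract the median ratio (off by default; recorded
#'   in the output's attributes).
#' @param smooth_bins optional centered running-mean window in bins (0 = no
#'   smoothing, the default).
#' @return a `ratio_track`: data.frame `chrom`/`start`/`end`/`log2_ratio`
#'   with attributes `pseudocount`, `median_centered`, `smooth_bins`.
#' @examples
#' s  <- data.frame(chrom = "c", start = 0:1 * 10, end = 1:2 * 10, value = c(2, 4))
#' g1 <- data.frame(chrom = "c", start = 0:1 * 10, end = 1:2 * 10, value = c(2, 2))
#' log2_ratio(s, g1, pseudocount = 1)$log2_ratio
#' @export
log2_ratio <- function(s_cov, g1_cov, pseudocount = 1,
                       median_center = FALSE, smooth_bins = 0) {
  check_track(s_cov)
  check_track(g1_cov)
  check_same_bins(s_cov, g1_cov)
  if (pseudocount <= 0) stop_invalid("invalid config: pseudocount must be > 0")
  lr <- log2((s_cov$value + pseudocount) / (g1_cov$value + pseudocount))
  if (smooth_bins > 1) lr <- run_mean(lr, smooth_bins)
  if (median_center) lr <- lr - stats::median(lr)
  structure(
    data.frame(chrom = s_cov$chrom, start = s_cov$start, end = s_cov$end,
               log2_ratio = lr),
    class = c("ratio_track", "data.frame"),
    pseudocount = pseudocount, median_centered = median_center,
    smooth_bins = smooth_bins)
}

six_levels <- c("Very Early", "Early", "Mid-Early",
                "Mid-Late", "Late", "Very Late")
four_levels <- c("Early", "Mid-Early", "Mid-Late", "Late")

#' Stratify bins into replication-timing groups
#'
#' Two schemes, both oriented so that a *higher* S/G1 ratio (more copies in
#' asynchronous cells) means *earlier* replication:
#'
#' * `six_range` — boundaries are placed at fixed percentiles of the total
#'   ratio *range* (not quantiles): measuring from the top of the range,
#'   0-10% is Very Early, 10-30% Early, 30-50% Mid-Early, 50-70% Mid-Late,
#'   70-90% Late and 90-100% Very Late. Intervals are half-open with the
#'   top (Very Early) bin closed, so group bin-counts need not be equal.
#' * `four_equal` — bins are ranked by ratio and split into four
#'   equal-count groups (Early, Mid-Early, Mid-Late, Late); ties are broken
#'   by genomic position for determinism.
#'
#' @param ratio a `ratio_track`.
#' @param scheme `"four_equal"` or `"six_range"`.
#' @return a `timing_groups` object: list with `bins` (the track's bins),
#'   `group_of_bin` (ordered factor, earliest level first), `boundaries`
#'   (ratio values, `six_range` only), `scheme`.
#' @export
stratify_by_range_percentile <- function(ratio,
                                         scheme = c("four_equal", "six_range")) {
  scheme <- match.arg(scheme)
  if (!inherits(ratio, "ratio_track")) stop_invalid("ratio must be a ratio_track")
  lr <- ratio$log2_ratio
  n <- length(lr)
  if (scheme == "six_range") {
    rng <- range(lr)
    if (diff(rng) == 0) {
      stop_invalid("degenerate range: six_range needs >= 2 distinct ratio values")
    }
    ## position within the range; intervals lower-closed, top bin closed,
    ## and the top 10% of the range is Very Early (highest copy = earliest)
    q <- (lr - rng[1]) / diff(rng)
    cuts <- c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1)
    idx <- findInterval(q, cuts, rightmost.closed = TRUE, all.inside = TRUE)
    grp <- factor(rev(six_levels)[idx], levels = six_levels, ordered = TRUE)
    boundaries <- rng[1] + cuts[2:6] * diff(rng)
  } else {
    ord <- order(-lr, ratio$start)
    rank <- integer(n)
    rank[ord] <- seq_len(n)
    idx <- ceiling(4 * rank / n)
    grp <- factor(four_levels[idx], levels = four_levels, ordered = TRUE)
    boundaries <- NULL
  }
  structure(
    list(bins = data.frame(chrom = ratio$chrom, start = ratio$start,
                           end = ratio$end),
         group_of_bin = grp, boundaries = boundaries, scheme = scheme),
    class = "timing_groups")
}

#' @export
print.timing_groups <- function(x, ...) {
  cat(sprintf("<timing_groups> scheme=%s, %d bins\n", x$scheme,
              length(x$group_of_bin)))
  print(table(x$group_of_bin))
  invisible(x)
}

## Map bp positions onto a timing_groups' bins; NA outside.
bin_in_groups <- function(groups, positions) {
  b <- groups$bins
  idx <- findInterval(positions, c(b$start, b$end[nrow(b)]),
                      rightmost.closed = FALSE)
  idx[positions < b$start[1] | positions >= b$end[nrow(b)]] <- NA_integer_
  as.integer(idx)
}

#' Amplification scores per replication-timing group
#'
#' The amplification score of an element (an origin, or a bin) is the
#' difference of log2 coverage ratios, re-replicating minus control, at the
#' element's bin: how much more a region is over-represented in
#' re-replicating DNA than ordinary asynchronous replication would produce.
#' Scores are summarized per timing group with the box convention used for
#' the sequencing figures: median, 25th/75th percentiles and 5th/95th
#' percentile ranges.
#'
#' @param rerep,control `ratio_track`s on identical bins (re-replicating/G1
#'   and S/G1).
#' @param groups a `timing_groups` on the same bins.
#' @param elements optional vector of bp positions (e.g. origin midpoints);
#'   `NULL` scores every bin.
#' @return an `amplification_table`: list with `elements` (data.frame
#'   `position`, `bin`, `group`, `score`) and `summary` (per-group `n`,
#'   `median`, `q25`, `q75`, `p5`, `p95`; groups of size 0 keep `NA`
#'   summaries).
#' @export
amplification_scores <- function(rerep, control, groups, elements = NULL) {
  check_same_bins(rerep, control)
  if (length(groups$group_of_bin) != nrow(rerep)) {
    stop_invalid("timing groups do not match the tracks' binning")
  }
  if (is.null(elements)) {
    bin <- seq_len(nrow(rerep))
    position <- (rerep$start + rerep$end) / 2
  } else {
    position <- elements
    bin <- bin_in_groups(groups, elements)
    keep <- !is.na(bin)
    if (!all(keep)) {
      warning(sum(!keep), " element(s) outside the binned genome dropped")
      position <- position[keep]
      bin <- bin[keep]
    }
    if (!length(bin)) stop_invalid("no elements map to a timing group")
  }
  score <- rerep$log2_ratio[bin] - control$log2_ratio[bin]
  grp <- groups$group_of_bin[bin]
  lev <- levels(groups$group_of_bin)
  qs <- function(v, p) if (length(v)) stats::quantile(v, p, names = FALSE) else NA_real_
  summ <- data.frame(
    group = factor(lev, levels = lev, ordered = TRUE),
    n = as.integer(table(factor(grp, levels = lev))),
    median = vapply(lev, function(l) qs(score[grp == l], 0.5), 0),
    q25 = vapply(lev, function(l) qs(score[grp == l], 0.25), 0),
    q75 = vapply(lev, function(l) qs(score[grp == l], 0.75), 0),
    p5 = vapply(lev, function(l) qs(score[grp == l], 0.05), 0),
    p95 = vapply(lev, function(l) qs(score[grp == l], 0.95), 0),
    row.names = NULL)
  structure(list(elements = data.frame(position = position, bin = bin,
                                       group = grp, score = score),
                 summary = summ),
            class = "amplification_table")
}

#' @export
print.amplification_table <- function(x, ...) {
  cat(sprintf("<amplification_table> %d scored elements\n", nrow(x$elements)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Permutation trend test across ordered groups
#'
#' Jonckheere-style monotone-trend test: the statistic is the Spearman
#' correlation between the ordered group index and the value; its null
#' distribution is obtained by permuting group labels. Two-sided.
#'
#' @param values numeric vector.
#' @param groups ordered factor (or coercible) of the same length.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `statistic` (Spearman rho) and `p.value`.
#' @export
group_trend_test <- function(values, groups, n_perm = 499, seed = 1L) {
  g <- as.integer(as.factor(groups))
  if (length(values) != length(g) || length(values) < 3) {
    stop_invalid("values/groups must be equal length >= 3")
  }
  obs <- stats::cor(g, values, method = "spearman")
  perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      stats::cor(sample(g), values, method = "spearman")
    }, 0)
  })
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(statistic = obs, p.value = p)
}
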