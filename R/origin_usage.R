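#' Library-size normalization of per-origin read counts
#'
#' `normalized_i = raw_i * scale / library_size` — the per-million style
#' scaling used to make nascent-strand peak read counts comparable across
#' libraries of different depth.
#'
#' @param raw numeric vector of raw counts.
#' @param library_size total reads in the library (> 0).
#' @param scale target library size (default 1e6).
#' @return numeric vector of normalized counts.
#' @export
normalize_counts <- function(raw, library_size, scale = 1e6) {
  if (length(library_size) != 1 || is.na(library_size) || library_size <= 0) {
    stop_invalid("invalid config: library_size must be > 0")
  }
  raw * scale / library_size
}

#' Build an origin-usage table from per-condition read counts
#'
#' Bundles per-origin raw read counts for several sequencing conditions and
#' applies library-size normalization. The normalization scale defaults to
#' the mean library size across conditions, so normalized counts stay on the
#' familiar reads-per-peak scale while being comparable between conditions.
#'
#' @param origins an `origin_set` (positions define the peak intervals).
#' @param counts named list of equal-length integer vectors, one per
#'   condition.
#' @param half_width half-width (bp) of the peak interval drawn around each
#'   origin midpoint.
#' @param scale normalization scale; `NULL` (default) uses the mean library
#'   size.
#' @return an `origin_usage_table`: list with `intervals` (data.frame
#'   `origin_id`, `chrom`, `start`, `end`, `position`), `raw` and
#'   `normalized` (matrices, origins x conditions), `library_sizes`,
#'   `scale`.
#' @export
usage_table <- function(origins, counts, half_width = 500, scale = NULL) {
  if (!length(counts) || is.null(names(counts)) || any(names(counts) == "")) {
    stop_invalid("counts must be a non-empty named list")
  }
  n <- nrow(origins)
  if (any(vapply(counts, length, 1L) != n)) {
    stop_invalid("every condition must have one count per origin")
  }
  raw <- do.call(cbind, lapply(counts, as.numeric))
  rownames(raw) <- NULL
  lib <- colSums(raw)
  if (any(lib <= 0)) {
    warning("condition(s) with empty library: ",
            paste(names(counts)[lib <= 0], collapse = ", "),
            "; left unnormalized")
  }
  if (is.null(scale)) scale <- mean(lib[lib > 0])
  if (!length(scale) || !is.finite(scale)) scale <- 1e6
  normalized <- raw
  for (j in seq_len(ncol(raw))) {
    if (lib[j] > 0) normalized[, j] <- normalize_counts(raw[, j], lib[j], scale)
  }
  pos <- origins$position
  structure(
    list(intervals = data.frame(
           origin_id = seq_len(n),
           chrom = rep(attr(origins, "chrom") %||% "chrS", n),
           start = pmax(0, floor(pos) - half_width),
           end = floor(pos) + half_width,
           position = pos),
         raw = raw, normalized = normalized,
         library_sizes = lib, scale = scale),
    class = "origin_usage_table")
}

#' @export
print.origin_usage_table <- function(x, ...) {
  cat(sprintf("<origin_usage_table> %d origins x %d conditions (%s)\n",
              nrow(x$raw), ncol(x$raw),
              paste(colnames(x$raw), collapse = ", ")))
  invisible(x)
}

#' Pair two conditions of an origin-usage table
#'
#' One row per origin with the x- and y-condition normalized (and raw)
#' counts — the substrate of the density-plot comparison in which origins
#' used at similar frequency in both conditions sit on the diagonal.
#'
#' @param table an `origin_usage_table`.
#' @param x_cond,y_cond condition names.
#' @return an `origin_pairs` data.frame (`origin_id`, `position`, `x_raw`,
#'   `y_raw`, `x`, `y`) with attributes `x_cond`, `y_cond`.
#' @export
pair_conditions <- function(table, x_cond, y_cond) {
  for (cond in c(x_cond, y_cond)) {
    if (!cond %in% colnames(table$raw)) {
      stop_invalid("unknown condition '", cond, "'")
    }
  }
  structure(
    data.frame(origin_id = table$intervals$origin_id,
               position = table$intervals$position,
               x_raw = table$raw[, x_cond],
               y_raw = table$raw[, y_cond],
               x = table$normalized[, x_cond],
               y = table$normalized[, y_cond]),
    class = c("origin_pairs", "data.frame"),
    x_cond = x_cond, y_cond = y_cond)
}

#' Stratify paired origins into log-ratio fractions and peak size classes
#'
#' Each classified peak gets the statistic `r = log2((y + c) / (x + c))` and
#' is assigned to one of `n_fractions` equal-width half-open bins spanning
#' `[-R, R]`, `R = max |r|` over classified peaks (values at `+R` fall in
#' the extreme bin). Fractions are numbered from the most y-dominant
#' (fraction 1: highest `y` vs `x` ratio) to the most x-dominant. Peaks are
#' size-classified on the mean of the two conditions' normalized counts:
#' small for 250-400 reads, large above 400, excluded below 250 (thresholds
#' configurable).
#'
#' @param pairs an `origin_pairs` data.frame.
#' @param n_fractions number of ratio fractions (>= 2; default 10).
#' @param small `c(lo, hi)` read range of the small-peak class.
#' @param large_min reads above which a peak is large.
#' @param min_count reads below which a peak is excluded (defaults to
#'   `small[1]`).
#' @param pseudocount pseudocount `c` in the log ratio.
#' @param size_stat which statistic defines a peak's size: `"mean"` (default),
#'   `"x"`, `"y"` or `"max"`.
#' @param binning `"width"` (equal-width in log-ratio, default) or `"count"`
#'   (equal-count deciles).
#' @return a `fraction_summary`: list with `summary` (per fraction: ratio
#'   interval, `n_small`, `n_large`, `n`), `per_peak` (origin, `r`, `size`,
#'   `class`, `fraction`), `n_excluded`, `breaks`.
#' @export
ratio_fractions <- function(pairs, n_fractions = 10, small = c(250, 400),
                            large_min = 400, min_count = small[1],
                            pseudocount = 1,
                            size_stat = c("mean", "x", "y", "max"),
                            binning = c("width", "count")) {
  size_stat <- match.arg(size_stat)
  binning <- match.arg(binning)
  if (n_fractions < 2) stop_invalid("invalid config: n_fractions must be >= 2")
  x <- pairs$x
  y <- pairs$y
  size <- switch(size_stat, mean = (x + y) / 2, x = x, y = y,
                 max = pmax(x, y))
  cls <- ifelse(size < min_count, "excluded",
                ifelse(size > large_min, "large", "small"))
  r <- log2((y + pseudocount) / (x + pseudocount))
  keep <- cls != "excluded"
  per_peak <- data.frame(origin_id = pairs$origin_id, r = r, size = size,
                         class = cls, fraction = NA_integer_)
  if (!any(keep)) {
    warning("all peaks excluded by the minimum-count threshold")
    empty <- data.frame(fraction = integer(0), r_lo = numeric(0),
                        r_hi = numeric(0), n_small = integer(0),
                        n_large = integer(0), n = integer(0))
    return(structure(list(summary = empty, per_peak = per_peak,
                          n_excluded = sum(!keep), breaks = numeric(0)),
                     class = "fraction_summary"))
  }
  R <- max(abs(r[keep]))
  if (R == 0) R <- .Machine$double.eps
  if (binning == "width") {
    breaks <- seq(-R, R, length.out = n_fractions + 1L)
    idx_asc <- findInterval(r[keep], breaks, rightmost.closed = TRUE,
                            all.inside = TRUE)
  } else {
    ord <- order(r[keep], pairs$origin_id[keep])
    rk <- integer(sum(keep))
    rk[ord] <- seq_len(sum(keep))
    idx_asc <- ceiling(n_fractions * rk / sum(keep))
    breaks <- seq(-R, R, length.out = n_fractions + 1L)
  }
  ## fraction 1 = most y-dominant (largest r)
  per_peak$fraction[keep] <- n_fractions + 1L - idx_asc
  fr <- factor(per_peak$fraction[keep], levels = seq_len(n_fractions))
  summ <- data.frame(
    fraction = seq_len(n_fractions),
    r_lo = rev(breaks[-(n_fractions + 1L)]),
    r_hi = rev(breaks[-1L]),
    n_small = as.integer(table(fr[per_peak$class[keep] == "small"])),
    n_large = as.integer(table(fr[per_peak$class[keep] == "large"])))
  summ$n <- summ$n_small + summ$n_large
  structure(list(summary = summ, per_peak = per_peak,
                 n_excluded = sum(!keep), breaks = breaks),
            class = "fraction_summary")
}

#' @export
print.fraction_summary <- function(x, ...) {
  cat(sprintf("<fraction_summary> %d classified peaks (%d excluded)\n",
              sum(x$summary$n), x$n_excluded))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Detect activated dormant origins
#'
#' A dormant origin is essentially silent during normal growth but fires
#' under the treated condition: normalized control count below `low_thresh`
#' and treated count above `high_thresh`. The returned share is relative to
#' all treated-active origins (treated count above `low_thresh`).
#'
#' @param pairs an `origin_pairs` with x = control, y = treated.
#' @param low_thresh,high_thresh detection thresholds (low < high).
#' @return list with `origins` (subset of `pairs`), `n`, `n_treated_active`,
#'   `share`.
#' @export
detect_dormant <- function(pairs, low_thresh = 50, high_thresh = 250) {
  if (low_thresh >= high_thresh) {
    stop_invalid("invalid config: low_thresh must be < high_thresh")
  }
  hit <- pairs$x < low_thresh & pairs$y > high_thresh
  active <- pairs$y > low_thresh
  list(origins = pairs[hit, , drop = FALSE],
       n = sum(hit),
       n_treated_active = sum(active),
       share = if (sum(active)) sum(hit) / sum(active) else 0)
}

#' Origin-usage comparison within replication-timing groups
#'
#' Re-runs the pairing / fraction analysis separately within each timing
#' group, so a shift of fraction mass toward the treated-dominant side in
#' early groups (and the control-dominant side in late groups) becomes
#' visible.
#'
#' @param pairs an `origin_pairs` (must carry origin `position`s).
#' @param groups a `timing_groups` covering the genome the origins live on.
#' @param ... passed on to [ratio_fractions()].
#' @return a `stratified_pairs`: list with `pairs` (per-origin group
#'   labels), `summaries` (named list of `fraction_summary`, one per group;
#'   groups with no origins get `NULL`), `mean_r` (per-group mean log
#'   ratio), `n_dropped` (origins outside the binned genome).
#' @export
timing_stratified_pairs <- function(pairs, groups, ...) {
  bin <- bin_in_groups(groups, pairs$position)
  dropped <- is.na(bin)
  pr <- pairs[!dropped, , drop = FALSE]
  grp <- groups$group_of_bin[bin[!dropped]]
  lev <- levels(groups$group_of_bin)
  summaries <- stats::setNames(vector("list", length(lev)), lev)
  mean_r <- stats::setNames(rep(NA_real_, length(lev)), lev)
  for (l in lev) {
    sub <- pr[grp == l, , drop = FALSE]
    if (!nrow(sub)) next
    summaries[[l]] <- suppressWarnings(ratio_fractions(sub, ...))
    if (nrow(summaries[[l]]$summary)) {
      kept <- summaries[[l]]$per_peak
      mean_r[l] <- mean(kept$r[kept$class != "excluded"])
    }
  }
  pr$group <- grp
  structure(list(pairs = pr, summaries = summaries, mean_r = mean_r,
                 n_dropped = sum(dropped)),
            class = "stratified_pairs")
}
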