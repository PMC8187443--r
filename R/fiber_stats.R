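#' Replication fork progression rate
#'
#' Labeled track length divided by label time. When both sequential labels
#' are measured, use the total length over the total label time.
#'
#' @param length_kb labeled track length(s), kb (>= 0).
#' @param label_minutes label duration, minutes (> 0).
#' @return fork rate(s), kb/min.
#' @export
fork_rate <- function(length_kb, label_minutes) {
  if (any(label_minutes <= 0)) {
    stop_invalid("invalid config: label_minutes must be > 0")
  }
  if (any(length_kb < 0, na.rm = TRUE)) {
    stop_invalid("invalid record: negative track length")
  }
  length_kb / label_minutes
}

#' Inter-origin distances on combed fibers
#'
#' Center-to-center distances between successive origins on the same fiber;
#' fibers with a single origin contribute nothing.
#'
#' @param fibers a `fiber_set` (columns `fiber_id`, `origin_pos_kb`).
#' @return numeric vector of distances (kb).
#' @export
inter_origin_distances <- function(fibers) {
  if (!nrow(fibers)) return(numeric(0))
  ord <- order(fibers$fiber_id, fibers$origin_pos_kb)
  pos <- fibers$origin_pos_kb[ord]
  id <- fibers$fiber_id[ord]
  d <- diff(pos)
  d[id[-1] == id[-length(id)]]
}

#' Classify a bidirectional fork structure as symmetric or asymmetric
#'
#' A fork pair is asymmetric when the relative difference between the left
#' and right labeled fork lengths exceeds the threshold:
#' `|L - R| / max(L, R) > threshold` (strictly greater; default 0.30). The
#' `max` denominator is the conservative, symmetric choice; `"mean"` is
#' available.
#'
#' @param left_kb,right_kb labeled fork lengths (kb, >= 0; not both zero).
#' @param threshold relative-difference threshold (default 0.30).
#' @param denominator `"max"` (default) or `"mean"`.
#' @return character vector, `"symmetric"` or `"asymmetric"`.
#' @examples
#' classify_fork_symmetry(10, 6)    # 0.40 -> asymmetric
#' classify_fork_symmetry(10, 7.1)  # 0.29 -> symmetric
#' @export
classify_fork_symmetry <- function(left_kb, right_kb, threshold = 0.30,
                                   denominator = c("max", "mean")) {
  denominator <- match.arg(denominator)
  if (any(left_kb < 0 | right_kb < 0)) {
    stop_invalid("invalid record: negative fork length")
  }
  if (any(left_kb == 0 & right_kb == 0)) {
    stop_invalid("invalid record: both fork lengths are zero")
  }
  den <- switch(denominator,
                max = pmax(left_kb, right_kb),
                mean = (left_kb + right_kb) / 2)
  ifelse(abs(left_kb - right_kb) / den > threshold,
         "asymmetric", "symmetric")
}

#' Asymmetric-fork prevalence in a fiber set
#'
#' Applies [classify_fork_symmetry()] to every origin-centered bidirectional
#' structure with both sides measured; structures missing one side (NA) are
#' excluded from the denominator and counted separately.
#'
#' @param fibers a `fiber_set` (columns `left_kb`, `right_kb`).
#' @param threshold relative-difference threshold (default 0.30).
#' @param denominator passed to [classify_fork_symmetry()].
#' @return an `asymmetry_summary`: list `n_forks`, `n_asymmetric`,
#'   `percentage`, `threshold`, `n_excluded`.
#' @export
asymmetry_summary <- function(fibers, threshold = 0.30,
                              denominator = c("max", "mean")) {
  ok <- is.finite(fibers$left_kb) & is.finite(fibers$right_kb)
  n_excluded <- sum(!ok)
  if (!any(ok)) stop_invalid("empty input: no bidirectional forks with both sides measured")
  cls <- classify_fork_symmetry(fibers$left_kb[ok], fibers$right_kb[ok],
                                threshold, denominator)
  n <- length(cls)
  na <- sum(cls == "asymmetric")
  structure(list(n_forks = n, n_asymmetric = na,
                 percentage = 100 * na / n, threshold = threshold,
                 n_excluded = n_excluded),
            class = "asymmetry_summary")
}

#' @export
print.asymmetry_summary <- function(x, ...) {
  cat(sprintf("<asymmetry_summary> %d/%d asymmetric (%.1f%%) at threshold %.2f (%d excluded)\n",
              x$n_asymmetric, x$n_forks, x$percentage, x$threshold,
              x$n_excluded))
  invisible(x)
}

#' Two-sample rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when `min(n, m) <= 8` and there are no ties; normal
#' approximation with tie and continuity corrections otherwise. Two-sided.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @param method `"auto"` (the branch rule above), `"exact"` or `"normal"`.
#' @return list `U` (Mann-Whitney U of `sample_a`), `p.value`, `method`.
#' @export
rank_sum_test <- function(sample_a, sample_b,
                          method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (!length(sample_a) || !length(sample_b)) {
    stop_invalid("invalid input: both samples must be non-empty")
  }
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  exact <- switch(method,
                  auto = !ties && min(length(sample_a), length(sample_b)) <= 8,
                  exact = TRUE,
                  normal = FALSE)
  res <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, exact = exact, correct = !exact))
  list(U = unname(res$statistic), p.value = res$p.value,
       method = if (exact) "exact" else "normal")
}

#' Chi-square test for a 2x2 table
#'
#' `chisq = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, 1 degree of freedom;
#' no continuity correction by default.
#'
#' @param a,b,c,d cell counts (row 1: a, b; row 2: c, d); all >= 0, both
#'   margins > 0.
#' @param correct apply Yates' continuity correction.
#' @return list `statistic`, `p.value`, `df`.
#' @export
two_by_two_chisq <- function(a, b, c, d, correct = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop_invalid("invalid table: negative count")
  if (a + b <= 0 || c + d <= 0 || a + c <= 0 || b + d <= 0) {
    stop_invalid("invalid table: zero margin")
  }
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(res$statistic), p.value = res$p.value, df = 1)
}
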