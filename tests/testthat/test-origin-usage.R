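test_that("library-size normalization is the linear per-million scaling", {
  expect_equal(normalize_counts(c(10, 20), 1e6, 1e6), c(10, 20))
  expect_equal(normalize_counts(c(10, 20), 2e6, 1e6), c(5, 10))
  expect_equal(normalize_counts(c(0, 0, 0), 1234), c(0, 0, 0))
  expect_error(normalize_counts(1:3, 0), "library_size")
})

test_that("condition pairing keeps one row per origin and flags unknown names", {
  g <- tiny_genome(seed = 61)
  o <- place_origins(g, 10, seed = 62)
  n <- nrow(o)
  tab <- usage_table(o, list(a = rep(100, n), b = rep(200, n)),
                     scale = NULL)
  pr <- pair_conditions(tab, "a", "a")
  expect_equal(pr$x, pr$y)
  pr2 <- pair_conditions(tab, "a", "b")
  expect_equal(nrow(pr2), n)
  ## y raw = 2x raw, but library normalization puts both on a common scale
  expect_equal(pr2$y_raw, 2 * pr2$x_raw)
  expect_equal(pr2$y, pr2$x)
  expect_error(pair_conditions(tab, "a", "nope"), "unknown condition")
})

test_that("peak size classes follow the read-count thresholds", {
  pr <- make_pairs(x = c(300, 500, 100), y = c(300, 500, 100))
  fr <- ratio_fractions(pr)
  expect_equal(fr$per_peak$class, c("small", "large", "excluded"))
  expect_equal(fr$n_excluded, 1)
  expect_equal(sum(fr$summary$n), 2)
})

test_that("equal peaks land together in the half-open bin starting at zero", {
  pr <- make_pairs(x = rep(300, 7), y = rep(300, 7))
  fr <- ratio_fractions(pr, n_fractions = 10)
  f <- unique(fr$per_peak$fraction)
  expect_length(f, 1)
  row <- fr$summary[fr$summary$fraction == f, ]
  expect_equal(row$r_lo, 0)
  expect_equal(row$n, 7L)
})

test_that("fraction counts conserve the classified peaks", {
  for (s in 1:5) {
    xy <- withr::with_seed(s, matrix(rpois(400, 400), ncol = 2))
    pr <- make_pairs(xy[, 1], xy[, 2])
    fr <- ratio_fractions(pr)
    expect_equal(sum(fr$summary$n),
                 sum(fr$per_peak$class != "excluded"))
    expect_equal(sum(fr$summary$n) + fr$n_excluded, nrow(pr))
  }
})

test_that("swapping the two conditions reflects ratios and reverses fractions", {
  xy <- withr::with_seed(11, matrix(260 + rgamma(600, 20, 0.05), ncol = 2))
  pr <- make_pairs(xy[, 1], xy[, 2])
  prs <- make_pairs(xy[, 2], xy[, 1])
  a <- ratio_fractions(pr, n_fractions = 10)
  b <- ratio_fractions(prs, n_fractions = 10)
  keep <- a$per_peak$class != "excluded"
  expect_equal(b$per_peak$r[keep], -a$per_peak$r[keep])
  expect_equal(b$per_peak$fraction[keep], 11L - a$per_peak$fraction[keep])
  expect_equal(b$per_peak$class, a$per_peak$class)
})

test_that("all-excluded input warns and returns an empty summary", {
  pr <- make_pairs(x = c(10, 20), y = c(15, 12))
  expect_warning(fr <- ratio_fractions(pr), "excluded")
  expect_equal(nrow(fr$summary), 0)
})

test_that("dormant origins are low in control and high after treatment", {
  pr <- make_pairs(x = c(0, 400, 30), y = c(500, 500, 100))
  d <- detect_dormant(pr, low_thresh = 50, high_thresh = 250)
  expect_equal(d$origins$origin_id, 1L)
  expect_equal(d$n_treated_active, 3L)  # treated counts above low_thresh
  expect_equal(d$share, 1 / 3)
  expect_error(detect_dormant(pr, 250, 50), "low_thresh")
})

test_that("timing stratification degenerates to the global analysis for one group", {
  ## descending ratio so origins placed on the left all fall in 'Early'
  vals <- seq(100, 1, length.out = 100)
  r <- as_ratio_track(vals, bin_width = 1000)
  grp <- stratify_by_range_percentile(r, "four_equal")
  xy <- withr::with_seed(21, matrix(rpois(60, 500), ncol = 2))
  pos <- withr::with_seed(22, runif(30, 0, 24000))  # leftmost quarter
  pr <- make_pairs(xy[, 1], xy[, 2], position = pos)
  strat <- timing_stratified_pairs(pr, grp)
  expect_equal(strat$n_dropped, 0)
  expect_equal(strat$summaries[["Early"]]$summary$n,
               ratio_fractions(pr)$summary$n)
  expect_null(strat$summaries[["Late"]])
})

test_that("origins outside the binned genome are dropped and counted", {
  r <- as_ratio_track(1:50, bin_width = 1000)
  grp <- stratify_by_range_percentile(r, "four_equal")
  pr <- make_pairs(c(500, 600), c(500, 600), position = c(2000, 99000))
  strat <- timing_stratified_pairs(pr, grp)
  expect_equal(strat$n_dropped, 1)
  expect_equal(nrow(strat$pairs), 1)
})
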