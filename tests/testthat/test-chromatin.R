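test_that("domain segmentation merges short gaps and keeps peak heights", {
  expect_equal(nrow(segment_domains(flat_track(rep(0, 20)))), 0)

  v <- c(rep(0, 5), rep(3, 10), rep(0, 5))
  v[10] <- 7
  d <- segment_domains(flat_track(v), background_quantile = 0.5)
  expect_equal(nrow(d), 1)
  expect_equal(d$peak_height, 7)
  expect_equal(d$start, 5 * 10)
  expect_equal(d$end, 15 * 10)

  ## two blocks split by a 2-bin gap: merged when min_gap_bp > 20
  v2 <- c(rep(5, 4), 0, 0, rep(5, 4), rep(0, 10))
  d_split <- segment_domains(flat_track(v2), min_gap_bp = 10)
  expect_equal(nrow(d_split), 2)
  d_merged <- segment_domains(flat_track(v2), min_gap_bp = 30)
  expect_equal(nrow(d_merged), 1)
  expect_equal(d_merged$size_bp, 100)

  ## min_size filter
  d_min <- segment_domains(flat_track(v2), min_gap_bp = 10, min_size_bp = 50)
  expect_equal(nrow(d_min), 0)
})

test_that("domains cover exactly the retained above-threshold runs", {
  v <- withr::with_seed(41, rpois(300, 3))
  tr <- flat_track(v)
  d <- segment_domains(tr, background_quantile = 0.6, min_gap_bp = 25)
  thr <- attr(d, "threshold")
  above <- v > thr
  in_domain <- rep(FALSE, length(v))
  for (i in seq_len(nrow(d))) {
    in_domain[tr$start >= d$start[i] & tr$end <= d$end[i]] <- TRUE
  }
  ## every above-threshold bin is inside a domain and every domain edge bin
  ## is above threshold
  expect_true(all(in_domain[above]))
  for (i in seq_len(nrow(d))) {
    expect_true(above[which(tr$start == d$start[i])])
    expect_true(above[which(tr$end == d$end[i])])
  }
})

test_that("peak-height quartiles are equal-count, deterministic and order-free", {
  d8 <- structure(
    data.frame(chrom = "c", start = (0:7) * 100, end = (0:7) * 100 + 50,
               size_bp = 50, peak_height = c(5, 1, 8, 3, 7, 2, 6, 4)),
    class = c("domain_set", "data.frame"))
  q <- quartile_stratify(d8)
  expect_equal(as.integer(table(q$quartile)), rep(2L, 4))
  expect_equal(as.character(q$quartile[q$peak_height >= 7]), rep("high", 2))

  ties <- d8
  ties$peak_height <- rep(1, 8)
  qt <- quartile_stratify(ties)
  expect_equal(as.integer(table(qt$quartile)), rep(2L, 4))
  expect_equal(as.character(qt$quartile[1:2]), rep("high", 2))

  for (s in 1:100) {
    perm <- withr::with_seed(s, sample(8))
    qp <- quartile_stratify(d8[perm, ])
    expect_equal(qp$quartile[order(qp$start)], q$quartile[order(q$start)])
  }

  expect_error(quartile_stratify(d8[1:3, ]), "too few")
})

test_that("inclusion ratio matches its formula on a constructed example", {
  sample <- data.frame(chrom = "c", start = c(0, 100, 200, 300),
                       end = c(50, 150, 250, 350))
  reference <- data.frame(chrom = "c",
                          start = c(40, 120, 500, 600, 700, 800),
                          end = c(60, 130, 510, 610, 710, 810))
  r <- inc_ratio(sample, reference)
  expect_equal(r$n_overlaps, 2)
  expect_equal(r$inc_ratio, 2 / (4 + 6))

  disjoint <- data.frame(chrom = "c", start = 1000, end = 1100)
  expect_equal(inc_ratio(sample, disjoint)$inc_ratio, 0)
  expect_error(inc_ratio(data.frame(chrom = "c", start = 10, end = 10),
                         reference), "malformed")
})

test_that("interval overlap counting agrees with the all-pairs brute force", {
  for (s in 1:6) {
    sm <- random_intervals(1000, seed = s)
    rf <- random_intervals(1000, seed = 100 + s)
    r <- inc_ratio(sm, rf)
    expect_equal(r$n_overlaps, brute_force_overlaps(sm, rf))
    bound <- min(r$size_sample, r$size_reference) /
      (r$size_sample + r$size_reference)
    expect_lte(r$inc_ratio, bound)
  }
})

test_that("inclusion ratio hits its upper bound when the smaller set is nested", {
  inner <- data.frame(chrom = "c", start = c(10, 110), end = c(20, 120))
  outer <- data.frame(chrom = "c", start = c(0, 100, 200),
                      end = c(50, 150, 250))
  r <- inc_ratio(inner, outer)
  expect_equal(r$inc_ratio, 2 / 5)
})

test_that("eigen correlation is exact on linear signals and null on noise", {
  x <- flat_track(withr::with_seed(51, runif(1000)))
  lin <- x
  lin$value <- 3 * x$value + 2
  expect_equal(eigen_correlation(x, lin)$R, 1)

  y <- flat_track(withr::with_seed(52, rnorm(1000)))
  expect_lt(abs(eigen_correlation(x, y)$R), 0.1)  # null sd ~ 1/sqrt(1000)

  const <- flat_track(rep(1, 1000))
  expect_error(eigen_correlation(x, const), "constant")
})

test_that("per-abundance-group eigen summaries use the 1.5 IQR whisker convention", {
  x <- flat_track(seq_len(400))
  y <- flat_track(withr::with_seed(53, rnorm(400)))
  e <- eigen_correlation(x, y)
  expect_equal(as.integer(e$groups$n), rep(100L, 4))
  for (i in 1:4) {
    g <- e$groups[i, ]
    expect_lte(g$q25, g$median)
    expect_lte(g$median, g$q75)
    expect_gte(g$whisker_lo, g$q25 - 1.5 * (g$q75 - g$q25))
    expect_lte(g$whisker_hi, g$q75 + 1.5 * (g$q75 - g$q25))
  }
})

test_that("anchor profiles reproduce constants and impulses", {
  sig <- flat_track(rep(4, 100))
  pr <- anchor_profile(sig, anchors = c(300, 500, 700), flank_bp = 30,
                       random_control = FALSE)
  expect_true(all(pr$profile == 4))
  expect_true(all(pr$per_anchor$score == 4))

  imp <- flat_track(rep(0, 100))
  anchors <- c(305, 505, 705)
  imp$value[floor(anchors / 10) + 1] <- 1
  pr2 <- anchor_profile(imp, anchors, flank_bp = 30, random_control = FALSE)
  mid <- (length(pr2$profile) + 1) / 2
  expect_equal(pr2$profile[mid], 1)
  expect_equal(pr2$profile[1], 0)
  expect_equal(pr2$profile[length(pr2$profile)], 0)
})

test_that("anchors too close to the track edge are clipped and counted", {
  sig <- flat_track(rep(1, 50))
  pr <- anchor_profile(sig, anchors = c(5, 250, 495), flank_bp = 30,
                       random_control = FALSE)
  expect_equal(pr$n_clipped, 2)
  expect_equal(nrow(pr$per_anchor), 1)
})

test_that("profiles of shuffled signal are flat within three standard errors", {
  base <- withr::with_seed(61, rpois(2000, 20))
  shuffled <- flat_track(withr::with_seed(62, sample(base)))
  anchors <- withr::with_seed(63, sort(runif(150, 5000, 15000)))
  pr <- anchor_profile(shuffled, anchors, flank_bp = 50,
                       random_control = FALSE)
  se <- sd(shuffled$value) / sqrt(nrow(pr$per_anchor))
  expect_true(all(abs(pr$profile - mean(shuffled$value)) <= 3 * se))
})
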