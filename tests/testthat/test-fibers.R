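test_that("fork rate is length over label time", {
  expect_equal(fork_rate(20, 20), 1)
  expect_equal(fork_rate(0, 20), 0)
  expect_equal(fork_rate(40, 40), 1)
  expect_error(fork_rate(10, 0), "label_minutes")
})

test_that("inter-origin distances are successive center-to-center gaps per fiber", {
  f <- make_fibers(left = c(5, 5), right = c(5, 5), fiber_id = c(1, 1),
                   pos = c(10, 110))
  expect_equal(inter_origin_distances(f), 100)
  f1 <- make_fibers(left = c(5, 5), right = c(5, 5), fiber_id = c(1, 2),
                    pos = c(10, 110))
  expect_equal(inter_origin_distances(f1), numeric(0))
})

test_that("the 30% asymmetry rule is strict and uses the larger fork", {
  expect_equal(classify_fork_symmetry(10, 10), "symmetric")
  expect_equal(classify_fork_symmetry(10, 6), "asymmetric")   # 0.40
  expect_equal(classify_fork_symmetry(10, 7.1), "symmetric")  # 0.29
  expect_equal(classify_fork_symmetry(10, 7), "symmetric")    # exactly 0.30
  expect_error(classify_fork_symmetry(0, 0), "both")
  expect_error(classify_fork_symmetry(-1, 5), "negative")
})

test_that("fork classification is symmetric in left and right", {
  lr <- withr::with_seed(31, matrix(rexp(200, 1 / 30) + 0.1, ncol = 2))
  expect_equal(classify_fork_symmetry(lr[, 1], lr[, 2]),
               classify_fork_symmetry(lr[, 2], lr[, 1]))
})

test_that("raising the asymmetry threshold never finds more asymmetric forks", {
  f <- simulate_fibers(sim_params(stall_prob = 0.3), 400, seed = 32)
  n <- vapply(c(0.1, 0.2, 0.3, 0.4, 0.5),
              function(th) asymmetry_summary(f, th)$n_asymmetric, 0L)
  expect_true(all(diff(n) <= 0))
})

test_that("asymmetry percentages summarize the classified forks", {
  f <- make_fibers(left = rep(10, 10),
                   right = c(rep(10, 7), 1, 1, 1))
  s <- asymmetry_summary(f, 0.30)
  expect_equal(s$n_forks, 10)
  expect_equal(s$n_asymmetric, 3)
  expect_equal(s$percentage, 30)

  all_even <- make_fibers(left = rep(8, 5), right = rep(8, 5))
  expect_equal(asymmetry_summary(all_even)$percentage, 0)

  one_sided <- make_fibers(left = c(10, NA), right = c(10, 5))
  s2 <- asymmetry_summary(one_sided)
  expect_equal(s2$n_forks, 1)
  expect_equal(s2$n_excluded, 1)
  expect_error(asymmetry_summary(make_fibers(left = NA_real_, right = 3)),
               "empty")
})

test_that("asymmetry prevalence rises with the stall probability", {
  pct <- vapply(c(0, 0.2, 0.4), function(sp) {
    f <- simulate_fibers(sim_params(stall_prob = sp, fiber_noise_cv = 0),
                         1500, seed = 77)
    asymmetry_summary(f)$percentage
  }, 0)
  expect_equal(pct[1], 0)
  expect_true(all(diff(pct) > 0))
})

test_that("rank-sum test reproduces the exact enumeration value", {
  ## all 3 of sample_a below sample_b: U = 0; of the choose(6,3) = 20
  ## arrangements only the two extremes are as extreme, two-sided p = 2/20
  res <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(res$U), 0)
  expect_equal(res$p.value, 0.1)
  expect_equal(res$method, "exact")

  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p.value, 0.99)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("exact and normal-approximation branches agree closely at n = m = 8", {
  worst <- 0
  for (s in 1:100) {
    ab <- withr::with_seed(1000 + s, rnorm(16))
    a <- ab[1:8]
    b <- ab[9:16] + 0.5
    pe <- rank_sum_test(a, b, method = "exact")$p.value
    pn <- rank_sum_test(a, b, method = "normal")$p.value
    worst <- max(worst, abs(pe - pn))
  }
  expect_lte(worst, 0.02)
})

test_that("rank-sum p-value decreases with the shift between samples", {
  a <- withr::with_seed(9, rnorm(60))
  p <- vapply(c(0.2, 0.6, 1.2), function(sh) {
    rank_sum_test(a, a + sh)$p.value
  }, 0)
  expect_true(all(diff(p) < 0))
})

test_that("the 2x2 chi-square matches the closed form", {
  ## N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)) computed directly as the oracle
  closed_form <- function(a, b, c, d) {
    (a + b + c + d) * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
  }
  res <- two_by_two_chisq(10, 90, 30, 70)
  expect_equal(res$statistic, closed_form(10, 90, 30, 70))
  expect_equal(res$statistic, 12.5)

  expect_equal(two_by_two_chisq(20, 40, 10, 20)$statistic, 0)
  expect_equal(two_by_two_chisq(30, 70, 10, 90)$statistic,
               two_by_two_chisq(10, 90, 30, 70)$statistic)
  expect_error(two_by_two_chisq(0, 0, 5, 5), "margin")
})
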