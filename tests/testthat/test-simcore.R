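test_that("build_genome obeys its geometry, range and determinism contracts", {
  g <- build_genome(1000, 10000, seed = 5)
  expect_equal(genome_length(g), 10000000)
  expect_true(all(g$timing >= 0 & g$timing <= 1))
  g2 <- build_genome(1000, 10000, seed = 5)
  expect_identical(g$timing, g2$timing)
  expect_identical(g$euchromatin, g2$euchromatin)
  expect_error(build_genome(0, 100), "n_bins")
  expect_error(build_genome(10, 0), "bin_width")
})

test_that("full timing-euchromatin coupling gives strong negative rank correlation", {
  g <- build_genome(1000, 10000, coupling = 1, seed = 7)
  expect_lt(cor(g$timing, g$euchromatin, method = "spearman"), -0.8)
})

test_that("origin placement is uniform without skew and early-biased with skew", {
  g <- tiny_genome(n_bins = 1000, seed = 3)
  early_half <- g$timing < median(g$timing)
  o <- place_origins(g, density_per_mb = 10, skew = 0, seed = 11)
  in_early <- mean(early_half[bin_of_positions(g, o$position)])
  n <- nrow(o)
  expect_lt(abs(in_early - 0.5), 1.96 * sqrt(0.25 / n))  # binomial 95% band

  frac <- vapply(1:20, function(s) {
    os <- place_origins(g, 10, skew = 3, seed = 100 + s)
    mean(early_half[bin_of_positions(g, os$position)])
  }, 0)
  expect_gt(mean(frac), 0.70)
})

test_that("origin sets are strictly increasing, weighted and dormant-flagged", {
  g <- tiny_genome(seed = 4)
  o <- place_origins(g, 20, skew = 2, dormant_fraction = 0.25, seed = 9)
  expect_true(all(diff(o$position) > 0))
  expect_true(all(o$weight >= 0))
  expect_equal(sum(o$dormant), round(0.25 * nrow(o)))
  expect_warning(o0 <- place_origins(g, 1e-9), "empty")
  expect_equal(nrow(o0), 0)
})

test_that("a cell forced to the end of S is fully duplicated with heavy-light fragments", {
  g <- tiny_genome(seed = 2)
  o <- place_origins(g, 20, seed = 2)
  p <- sim_params(cells = 1, fire_prob_normal = 1)
  pop <- simulate_population(g, o, p, "normal", seed = 6, s_progress = 1)
  expect_true(all(pop$copy_per_bin == 2))
  cc <- fragment_class_counts(pop)
  expect_equal(unname(cc["HL"]), 2 * g$n_bins)
  expect_equal(unname(cc["LL"]), 0)
  expect_equal(unname(cc["HH"]), 0)
})

test_that("normal mode conserves copy number and never produces heavy-heavy DNA", {
  g <- tiny_genome(seed = 8)
  o <- place_origins(g, 15, dormant_fraction = 0.1, seed = 8)
  for (s in c(1, 22, 333)) {
    pop <- simulate_population(g, o, sim_params(cells = 40), "normal", seed = s)
    expect_gte(pop$copy_range["min"], 1)
    expect_lte(pop$copy_range["max"], 2)
    expect_equal(unname(fragment_class_counts(pop)["HH"]), 0)
  }
})

test_that("re-replication over-duplicates early-replicating regions", {
  g <- tiny_genome(n_bins = 1000, seed = 13, smooth_bins = 50)
  o <- place_origins(g, 20, skew = 2, seed = 14)
  p <- sim_params(cells = 500, rerep_bias = 2)
  pop <- simulate_population(g, o, p, "rereplication", seed = 15)
  dec <- findInterval(g$timing, quantile(g$timing, 0:10 / 10),
                      rightmost.closed = TRUE, all.inside = TRUE)
  expect_gt(mean(pop$copy_per_bin[dec == 1]), mean(pop$copy_per_bin[dec == 10]))
  expect_gte(pop$copy_range["max"], 2)
})

test_that("heavy-heavy fragment bookkeeping recounts re-replication events exactly", {
  g <- tiny_genome(seed = 21)
  o <- place_origins(g, 20, skew = 1, seed = 22)
  p <- sim_params(cells = 100)
  pop <- simulate_population(g, o, p, "rereplication", seed = 23)
  cc <- fragment_class_counts(pop)
  extra_total <- sum(pop$copy_per_bin) * pop$cells - 2 * g$n_bins * pop$cells
  expect_equal(unname(cc["HH"]), extra_total)
  expect_equal(unname(cc["LL"]), 0)  # first round complete at harvest
})

test_that("unknown simulation mode is rejected", {
  g <- tiny_genome(seed = 1)
  o <- place_origins(g, 10, seed = 1)
  expect_error(simulate_population(g, o, sim_params(cells = 1), "banana"),
               "mode")
})

test_that("simulation is bit-identical for a fixed seed", {
  g <- tiny_genome(seed = 31)
  o <- place_origins(g, 15, seed = 32)
  p <- sim_params(cells = 25)
  a <- simulate_population(g, o, p, "rereplication", seed = 33)
  b <- simulate_population(g, o, p, "rereplication", seed = 33)
  expect_identical(a$copy_per_bin, b$copy_per_bin)
  expect_identical(a$fragments, b$fragments)
  fa <- simulate_fibers(p, 50, seed = 34)
  fb <- simulate_fibers(p, 50, seed = 34)
  expect_identical(fa, fb)
})

test_that("noise-free unstalled fibers have identical 40 kb forks", {
  p <- sim_params(fork_speed_kb_per_min = 1, stall_prob = 0,
                  fiber_noise_cv = 0)
  f <- simulate_fibers(p, 30, seed = 3)
  expect_true(all(f$left_kb == 40))
  expect_true(all(f$right_kb == 40))
  expect_equal(nrow(simulate_fibers(p, 0, seed = 1)), 0)
})

test_that("fiber origin spacing is Poisson with the configured mean", {
  p <- sim_params(mean_iod_kb = 120)
  f <- simulate_fibers(p, 6000, extra_origin_mean = 1, seed = 41)
  d <- inter_origin_distances(f)
  expect_gt(length(d), 4000)
  expect_lt(abs(mean(d) - 120) / 120, 0.05)
})

test_that("nascent read counts follow the firing frequencies", {
  g <- tiny_genome(seed = 51)
  o <- place_origins(g, 20, seed = 52)
  silent <- simulate_population(g, o, sim_params(cells = 10,
                                                 fire_prob_normal = 0),
                                "normal", seed = 53)
  expect_true(all(simulate_nascent_reads(o, silent, 1000, seed = 54) == 0))

  pop <- simulate_population(g, o, sim_params(cells = 200), "normal",
                             seed = 55)
  r1 <- simulate_nascent_reads(o, pop, 1000, seed = 56)
  r2 <- simulate_nascent_reads(o, pop, 2000, seed = 57)
  ratio <- sum(r2) / sum(r1)
  expect_lt(abs(ratio - 2), 3 * 2 / sqrt(sum(r1)))  # Poisson error band
  expect_error(simulate_nascent_reads(o, pop, 0), "depth")
})

test_that("the density gradient separates classes and conserves mass", {
  frag <- data.frame(bin_index = 1L, strand1_labeled = TRUE,
                     strand2_labeled = FALSE, count = 5000)
  prof <- simulate_gradient(frag, n_fractions = 21, sd = 1e-6, seed = 2)
  expect_equal(sum(prof$mass), 5000)
  expect_equal(sum(prof$mass > 0), 1)
  i <- which(prof$mass > 0)
  expect_lt(abs((prof$density_lo[i] + prof$density_hi[i]) / 2 - 1.75),
            prof$density_hi[1] - prof$density_lo[1])

  expect_error(simulate_gradient(frag[0, ]), "empty")
  expect_error(simulate_gradient(frag, densities = c(1.8, 1.75, 1.7)),
               "increasing")
})
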