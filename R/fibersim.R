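#' Simulate DNA-combing fibers
#'
#' Each fiber carries one or more labeled bidirectional origin structures.
#' Origin positions along a fiber follow a Poisson process: inter-origin
#' gaps are exponential with mean `mean_iod_kb`. Both forks of an origin run
#' at `fork_speed_kb_per_min` for the total label time
#' (`label_minutes_first + label_minutes_second`); independently on each
#' side, with probability `stall_prob`, the fork stalls at a uniformly
#' distributed time within the window, truncating that side's labeled
#' length. Optical measurement noise is multiplicative lognormal with
#' coefficient of variation `fiber_noise_cv` (mean 1; exactly no noise when
#' the CV is 0).
#'
#' @param params a `sim_params` (fields used: fork speed, label minutes,
#'   `stall_prob`, `fiber_noise_cv`, `mean_iod_kb`).
#' @param n_fibers number of fibers (>= 0; 0 gives an empty set).
#' @param mean_iod_kb mean inter-origin distance in kb; defaults to
#'   `params$mean_iod_kb`.
#' @param extra_origin_mean mean of the Poisson number of additional origins
#'   per fiber beyond the first (default 1, so fibers often carry two or
#'   more origins and yield inter-origin distances).
#' @param seed integer seed.
#' @return a `fiber_set`: data.frame with columns `fiber_id`,
#'   `origin_pos_kb`, `left_kb`, `right_kb`; attribute `label_minutes`.
#' @export
simulate_fibers <- function(params = sim_params(), n_fibers,
                            mean_iod_kb = params$mean_iod_kb,
                            extra_origin_mean = 1, seed = params$seed) {
  if (n_fibers < 0) stop_invalid("invalid config: n_fibers must be >= 0")
  label_min <- params$label_minutes_first + params$label_minutes_second
  full_kb <- params$fork_speed_kb_per_min * label_min
  if (n_fibers == 0) {
    out <- data.frame(fiber_id = integer(0), origin_pos_kb = numeric(0),
                      left_kb = numeric(0), right_kb = numeric(0))
    return(structure(out, class = c("fiber_set", "data.frame"),
                     label_minutes = label_min))
  }
  withr::with_seed(as.integer(seed), {
    k <- 1L + stats::rpois(n_fibers, extra_origin_mean)
    nfk <- sum(k)
    fiber_id <- rep(seq_len(n_fibers), k)
    ## first origin offset, then exponential gaps along each fiber
    gaps <- stats::rexp(nfk, 1 / mean_iod_kb)
    first <- sequence(k) == 1L
    gaps[first] <- stats::runif(sum(first), 0, mean_iod_kb / 2)
    pos <- stats::ave(gaps, fiber_id, FUN = cumsum)

    stall_side <- function(n) {
      len <- rep(full_kb, n)
      stalled <- stats::runif(n) < params$stall_prob
      len[stalled] <- full_kb * stats::runif(sum(stalled))
      len
    }
    left <- stall_side(nfk)
    right <- stall_side(nfk)
    if (params$fiber_noise_cv > 0) {
      sdlog <- sqrt(log(1 + params$fiber_noise_cv^2))
      left <- left * exp(stats::rnorm(nfk, -sdlog^2 / 2, sdlog))
      right <- right * exp(stats::rnorm(nfk, -sdlog^2 / 2, sdlog))
    }
  })
  structure(
    data.frame(fiber_id = fiber_id, origin_pos_kb = pos,
               left_kb = left, right_kb = right),
    class = c("fiber_set", "data.frame"), label_minutes = label_min)
}

#' @export
print.fiber_set <- function(x, ...) {
  cat(sprintf("<fiber_set> %d origin structures on %d fibers (label %g min)\n",
              nrow(x), length(unique(x$fiber_id)),
              attr(x, "label_minutes") %||% NA))
  if (nrow(x)) utils::str(as.data.frame(utils::head(x, 3)))
  invisible(x)
}

#' Simulate CsCl density-gradient fractionation of labeled fragments
#'
#' Implements the Meselson-Stahl readout: every duplex fragment has a
#' buoyant density drawn from a normal distribution centered on its class
#' density (light-light < heavy-light < heavy-heavy, i.e. 0, 1 or 2
#' BrdU-substituted strands) with standard deviation `sd`. Fragments are
#' binned into `n_fractions` equal-width gradient fractions spanning the
#' class densities plus/minus `4 * sd`; total histogram mass equals the
#' number of input fragments.
#'
#' @param fragments fragment table as produced in a `population_result`
#'   (`bin_index`, `strand1_labeled`, `strand2_labeled`, `count`), or a
#'   `population_result` itself.
#' @param n_fractions number of gradient fractions (>= 2).
#' @param densities increasing numeric vector `c(LL, HL, HH)` of class
#'   buoyant densities (g/ml).
#' @param sd within-class density spread (g/ml).
#' @param seed integer seed.
#' @return a `gradient_profile`: data.frame with one row per fraction
#'   (`fraction`, `density_lo`, `density_hi`, `mass`, `LL`, `HL`, `HH`),
#'   attributes `densities`, `sd`.
#' @export
simulate_gradient <- function(fragments, n_fractions = 20,
                              densities = c(1.70, 1.75, 1.80), sd = 0.01,
                              seed = 1L) {
  if (inherits(fragments, "population_result")) fragments <- fragments$fragments
  if (is.null(fragments) || nrow(fragments) == 0 || sum(fragments$count) == 0) {
    stop_invalid("empty input: no fragments to fractionate")
  }
  if (length(densities) != 3 || any(diff(densities) <= 0)) {
    stop_invalid("invalid config: densities must be strictly increasing c(LL, HL, HH)")
  }
  if (n_fractions < 2) stop_invalid("invalid config: n_fractions must be >= 2")
  nsub <- fragments$strand1_labeled + fragments$strand2_labeled
  cls <- rep.int(nsub + 1L, fragments$count)  # 1=LL, 2=HL, 3=HH
  n <- length(cls)
  rho <- withr::with_seed(as.integer(seed),
                          stats::rnorm(n, densities[cls], sd))
  lo <- densities[1] - 4 * sd
  hi <- densities[3] + 4 * sd
  rho <- pmin(pmax(rho, lo), hi)
  breaks <- seq(lo, hi, length.out = n_fractions + 1L)
  f <- findInterval(rho, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  tab <- function(sel) tabulate(f[sel], nbins = n_fractions)
  out <- data.frame(
    fraction = seq_len(n_fractions),
    density_lo = breaks[-(n_fractions + 1L)],
    density_hi = breaks[-1L],
    mass = tabulate(f, nbins = n_fractions),
    LL = tab(cls == 1L), HL = tab(cls == 2L), HH = tab(cls == 3L))
  structure(out, class = c("gradient_profile", "data.frame"),
            densities = densities, sd = sd)
}

#' Mass share of a gradient profile falling in one class's density window
#'
#' A fraction belongs to a class's window when its center density is nearer
#' that class's buoyant density than either other class's (so the heavy-heavy
#' window is the heavy half of the gradient).
#'
#' @param profile a `gradient_profile`.
#' @param class_name `"LL"`, `"HL"` or `"HH"`.
#' @return proportion of total mass in the window.
#' @export
gradient_window_mass <- function(profile, class_name = c("HH", "HL", "LL")) {
  class_name <- match.arg(class_name)
  dens <- attr(profile, "densities")
  ctr <- (profile$density_lo + profile$density_hi) / 2
  nearest <- apply(abs(outer(ctr, dens, "-")), 1, which.min)
  want <- match(class_name, c("LL", "HL", "HH"))
  sum(profile$mass[nearest == want]) / sum(profile$mass)
}
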