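#' Simulation parameters
#'
#' Collects the knobs of the cell-population simulator. Probabilities are
#' applied per label window / per replication round, not per minute.
#'
#' @param fork_speed_kb_per_min replication fork speed (kb/min, > 0).
#' @param stall_prob probability that a fork side stalls during the label
#'   window (DNA-combing model).
#' @param fire_prob_normal per-origin base firing probability per S phase;
#'   origins fire in only a subset of cell cycles (intermittent origins).
#' @param rerep_bias strength `beta >= 0` of the early preference of
#'   re-firing; the re-licensing probability is multiplied by
#'   `exp(-beta * timing)`.
#' @param relicense_prob base probability that an origin that fired in the
#'   first round is re-licensed and re-fires within the same cycle.
#' @param rerep_onset fraction of S-phase progress that must be completed
#'   before any re-initiation is allowed (re-replication does not start
#'   immediately after the initial replication event).
#' @param rerep_tract_kb mean length (kb, per side) of the exponentially
#'   distributed re-replicated tract around a re-fired origin.
#' @param rerep_rounds number of successive re-licensing rounds available
#'   within the re-replication phase (the earliest-replicating regions can
#'   undergo multiple re-initiations).
#' @param licensing_skew default licensing skew `kappa` used by pipelines.
#' @param label_minutes_first,label_minutes_second durations of the two
#'   sequential analog labels (IdU then CldU), minutes.
#' @param cells number of cells in the simulated population.
#' @param depth expected sequencing reads for an origin firing in every cell.
#' @param s_phase_min nominal S-phase duration in minutes (sets how far a
#'   fork travels per unit of S-phase progress).
#' @param firing_jitter standard deviation of the (clamped) normal jitter
#'   added to the origin firing time, in S-phase units.
#' @param dormant_epsilon multiplier on `fire_prob_normal` for dormant
#'   origins during unperturbed growth (near zero).
#' @param stress_dormant_prob firing probability gained by dormant origins
#'   under replication stress.
#' @param stress_speed_factor multiplicative fork slow-down under stress.
#' @param fiber_noise_cv coefficient of variation of the multiplicative
#'   lognormal measurement noise on combed fiber lengths.
#' @param mean_iod_kb mean inter-origin distance on fibers (kb).
#' @param label_doublings number of population doublings spanned by the BrdU
#'   label; `>= 2` models a fully substituted heavy-heavy control.
#' @param seed default integer seed for simulations using these parameters.
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(fork_speed_kb_per_min = 1.5,
                       stall_prob = 0.06,
                       fire_prob_normal = 0.3,
                       rerep_bias = 2,
                       relicense_prob = 0.3,
                       rerep_onset = 0.5,
                       rerep_tract_kb = 50,
                       rerep_rounds = 2,
                       licensing_skew = 2,
                       label_minutes_first = 20,
                       label_minutes_second = 20,
                       cells = 500,
                       depth = 1500,
                       s_phase_min = 480,
                       firing_jitter = 0.05,
                       dormant_epsilon = 0.01,
                       stress_dormant_prob = 0.3,
                       stress_speed_factor = 0.5,
                       fiber_noise_cv = 0.05,
                       mean_iod_kb = 120,
                       label_doublings = 1,
                       seed = 1L) {
  p <- list(fork_speed_kb_per_min = fork_speed_kb_per_min,
            stall_prob = stall_prob,
            fire_prob_normal = fire_prob_normal,
            rerep_bias = rerep_bias,
            relicense_prob = relicense_prob,
            rerep_onset = rerep_onset,
            rerep_tract_kb = rerep_tract_kb,
            rerep_rounds = as.integer(rerep_rounds),
            licensing_skew = licensing_skew,
            label_minutes_first = label_minutes_first,
            label_minutes_second = label_minutes_second,
            cells = as.integer(cells),
            depth = depth,
            s_phase_min = s_phase_min,
            firing_jitter = firing_jitter,
            dormant_epsilon = dormant_epsilon,
            stress_dormant_prob = stress_dormant_prob,
            stress_speed_factor = stress_speed_factor,
            fiber_noise_cv = fiber_noise_cv,
            mean_iod_kb = mean_iod_kb,
            label_doublings = label_doublings,
            seed = as.integer(seed))
  probs <- c("stall_prob", "fire_prob_normal", "relicense_prob",
             "rerep_onset", "dormant_epsilon", "stress_dormant_prob")
  for (nm in probs) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop_invalid("invalid config: ", nm, " must be in [0, 1]")
    }
  }
  for (nm in c("fork_speed_kb_per_min", "s_phase_min", "mean_iod_kb",
               "rerep_tract_kb")) {
    if (p[[nm]] <= 0) stop_invalid("invalid config: ", nm, " must be > 0")
  }
  if (p$rerep_bias < 0) stop_invalid("invalid config: rerep_bias must be >= 0")
  if (p$cells < 0) stop_invalid("invalid config: cells must be >= 0")
  class(p) <- "sim_params"
  p
}

#' Simulate a cell population replicating (or re-replicating) its genome
#'
#' Per cell, origins fire independently with their per-origin probability; an
#' origin's firing time is its local replication-timing value plus clamped
#' normal jitter, and forks extend bidirectionally at constant speed, so each
#' bin's replication time is the lower envelope of `t_i + dist/v` over fired
#' origins. Asynchronous harvesting samples a uniform S-phase progress per
#' cell, interpreted as the fraction of the genome already replicated
#' (cells synthesize DNA at a roughly constant rate through S): the
#' earliest-replicating fraction `u` of bins is duplicated at harvest.
#'
#' Modes:
#' * `normal` — one round only; per-cell bin copy is 1 or 2.
#' * `rereplication` — cells are harvested in the re-replication phase, with
#'   the first round complete (baseline copy 2 everywhere; re-replicating
#'   populations are sampled at late timepoints when nearly all cells
#'   re-replicate). Cells past `rerep_onset` enter the re-phase, in which
#'   origins that fired in the first round (never dormant ones:
#'   re-replication draws on the same pool as normal growth) re-fire with
#'   probability `relicense_prob * weight * exp(-rerep_bias * timing)` and
#'   re-replicate an exponential tract, raising local copy above 2 and
#'   creating heavy-heavy (both-strand BrdU-substituted) fragments.
#' * `stress` — dormant origins gain firing probability
#'   (`stress_dormant_prob`) and forks are slowed; no re-round.
#'
#' Fragment bookkeeping is semiconservative: an unreplicated bin contributes
#' one light-light duplex, a replicated bin two heavy-light duplexes, and
#' each re-replication event converts one heavy-light duplex into a
#' heavy-light plus a heavy-heavy pair. With `label_doublings >= 2` the label
#' spans multiple doublings and fragments are recorded as fully substituted
#' (all heavy-heavy), matching the use of long-label DNA as the heavy-heavy
#' gradient control.
#'
#' @param genome a `genome_model`.
#' @param origins an `origin_set` on that genome.
#' @param params a `sim_params` list.
#' @param mode `"normal"`, `"rereplication"` or `"stress"`.
#' @param seed integer seed (defaults to `params$seed`).
#' @param s_progress optional fixed S-phase progress in `[0, 1]` applied to
#'   every cell instead of uniform sampling (1 = end of S).
#' @return a `population_result`: list with `copy_per_bin` (mean copy over
#'   cells), `firing_normal` / `firing_re` (per-origin initiation counts by
#'   round), `fragments` (data.frame `bin_index`, `strand1_labeled`,
#'   `strand2_labeled`, `count`), `copy_range` (min/max per-cell copy seen),
#'   `mode`, `cells`.
#' @export
simulate_population <- function(genome, origins, params = sim_params(),
                                mode = c("normal", "rereplication", "stress"),
                                seed = params$seed, s_progress = NULL) {
  if (!inherits(genome, "genome_model")) stop_invalid("genome must be a genome_model")
  if (params$cells < 1) stop_invalid("invalid config: cells must be >= 1")
  if (is.character(mode) && length(mode) == 1L &&
      !mode %in% c("normal", "rereplication", "stress")) {
    stop_invalid("invalid config: unknown mode '", mode, "'")
  }
  mode <- match.arg(mode)
  if (!is.null(s_progress) && (s_progress < 0 || s_progress > 1)) {
    stop_invalid("s_progress must be in [0, 1]")
  }

  n_bins <- genome$n_bins
  n_org <- nrow(origins)
  bw_kb <- genome$bin_width / 1000
  v <- params$fork_speed_kb_per_min *
    if (mode == "stress") params$stress_speed_factor else 1
  ## S-phase-progress units consumed per bin of fork travel
  c_slope <- bw_kb / (v * params$s_phase_min)
  obin <- bin_of(genome, origins$position)
  p_fire <- pmin(1, params$fire_prob_normal * origins$weight)
  p_fire[origins$dormant] <- params$fire_prob_normal * params$dormant_epsilon
  if (mode == "stress") p_fire[origins$dormant] <- params$stress_dormant_prob

  copy_sum <- numeric(n_bins)
  ll <- hl <- hh <- numeric(n_bins)
  n1 <- n2 <- integer(max(n_org, 1L))
  cmin <- Inf
  cmax <- -Inf
  xb <- seq_len(n_bins) * c_slope
  full_label <- params$label_doublings >= 2

  withr::with_seed(as.integer(seed), {
    for (cell in seq_len(params$cells)) {
      u <- if (is.null(s_progress)) stats::runif(1) else s_progress
      fired <- if (n_org) stats::runif(n_org) < p_fire else logical(0)
      if (mode != "rereplication" && !any(fired)) {
        copy_sum <- copy_sum + 1
        if (full_label) hh <- hh + 1 else ll <- ll + 1
        cmin <- min(cmin, 1)
        cmax <- max(cmax, 1)
        next
      }
      n1[fired] <- n1[fired] + 1L
      fi <- which(fired)
      if (mode == "rereplication") {
        ## cells are harvested in the re-replication phase: the first round
        ## is complete, so every duplex is an already-replicated template
        rep_b <- rep(TRUE, n_bins)
      } else {
        t <- pmin(1, pmax(0, genome$timing[obin[fi]] +
                            stats::rnorm(length(fi), 0, params$firing_jitter)))
        ## per-bin replication time: lower envelope of t_i + |x_b - x_i| * c
        g <- rep(Inf, n_bins)
        ord <- order(t, decreasing = TRUE)  # smallest firing time written last
        g[obin[fi][ord]] <- t[ord]
        fwd <- cummin(g - xb) + xb
        bwd <- rev(cummin(rev(g + xb))) - xb
        rt <- pmin(fwd, bwd)
        ## harvest: u is the fraction of the genome this cell has replicated
        ## (cells progress through S at a constant genome-synthesis rate)
        k <- round(u * n_bins)
        rep_b <- if (k >= n_bins) rep(TRUE, n_bins) else if (k < 1)
          rep(FALSE, n_bins) else rt <= sort(rt, partial = k)[k]
      }
      copy_cell <- 1 + as.numeric(rep_b)

      extra <- numeric(n_bins)
      if (mode == "rereplication" && u > params$rerep_onset && length(fi)) {
        cand <- fi[!origins$dormant[fi]]
        if (length(cand)) {
          p2 <- pmin(1, params$relicense_prob * origins$weight[cand] *
                       exp(-params$rerep_bias * genome$timing[obin[cand]]))
          for (round in seq_len(max(1L, params$rerep_rounds %||% 1L))) {
            refired <- cand[stats::runif(length(cand)) < p2]
            if (!length(refired)) next
            n2[refired] <- n2[refired] + 1L
            lt <- stats::rexp(length(refired), 1 / params$rerep_tract_kb)
            rtr <- stats::rexp(length(refired), 1 / params$rerep_tract_kb)
            lo <- pmax(1L, bin_of(genome, pmax(0, origins$position[refired] - lt * 1000)))
            hi <- pmin(n_bins, obin[refired] + ceiling(rtr / bw_kb))
            dacc <- numeric(n_bins + 1L)
            for (j in seq_along(refired)) {
              dacc[lo[j]] <- dacc[lo[j]] + 1
              dacc[hi[j] + 1L] <- dacc[hi[j] + 1L] - 1
            }
            extra <- extra + cumsum(dacc[seq_len(n_bins)])
          }
          copy_cell <- copy_cell + extra
        }
      }
      copy_sum <- copy_sum + copy_cell
      if (full_label) {
        hh <- hh + copy_cell
      } else {
        ll <- ll + as.numeric(!rep_b)
        hl <- hl + 2 * as.numeric(rep_b)
        hh <- hh + extra
      }
      cmin <- min(cmin, copy_cell)
      cmax <- max(cmax, copy_cell)
    }
  })

  frag <- rbind(
    data.frame(bin_index = seq_len(n_bins), strand1_labeled = FALSE,
               strand2_labeled = FALSE, count = ll),
    data.frame(bin_index = seq_len(n_bins), strand1_labeled = TRUE,
               strand2_labeled = FALSE, count = hl),
    data.frame(bin_index = seq_len(n_bins), strand1_labeled = TRUE,
               strand2_labeled = TRUE, count = hh))
  frag <- frag[frag$count > 0, , drop = FALSE]
  rownames(frag) <- NULL

  structure(
    list(copy_per_bin = copy_sum / params$cells,
         firing_normal = if (n_org) n1[seq_len(n_org)] else integer(0),
         firing_re = if (n_org) n2[seq_len(n_org)] else integer(0),
         fragments = frag,
         copy_range = c(min = cmin, max = cmax),
         mode = mode, cells = params$cells, seed = as.integer(seed)),
    class = "population_result")
}

#' @export
print.population_result <- function(x, ...) {
  cat(sprintf("<population_result> mode=%s, %d cells, mean copy %.3f (per-cell range %g-%g)\n",
              x$mode, x$cells, mean(x$copy_per_bin),
              x$copy_range[1], x$copy_range[2]))
  invisible(x)
}

#' Fragment class tallies of a simulated population
#'
#' Collapse a population's fragment table into light-light / heavy-light /
#' heavy-heavy totals (one BrdU-substituted strand = heavy-light; both =
#' heavy-heavy).
#'
#' @param pop a `population_result`.
#' @return named numeric vector `c(LL=, HL=, HH=)`.
#' @export
fragment_class_counts <- function(pop) {
  f <- pop$fragments
  cls <- ifelse(f$strand1_labeled & f$strand2_labeled, "HH",
                ifelse(f$strand1_labeled | f$strand2_labeled, "HL", "LL"))
  out <- c(LL = 0, HL = 0, HH = 0)
  agg <- tapply(f$count, cls, sum)
  out[names(agg)] <- agg
  out
}

#' Simulate a binned read-coverage track from a population
#'
#' Per-bin reads are Poisson with mean `depth * copy_per_bin` (so a G1
#' population, copy 1 everywhere, averages `depth` reads per bin and a fully
#' duplicated genome twice that).
#'
#' @param genome a `genome_model`.
#' @param pop a `population_result`, or `NULL` for a G1 (copy-1) library.
#' @param depth expected reads per bin per genome copy.
#' @param seed integer seed.
#' @return a track `data.frame` (chrom/start/end/value).
#' @export
simulate_coverage <- function(genome, pop = NULL, depth = 100, seed = 1L) {
  if (depth <= 0) stop_invalid("invalid config: depth must be > 0")
  copy <- if (is.null(pop)) rep(1, genome$n_bins) else pop$copy_per_bin
  if (length(copy) != genome$n_bins) stop_invalid("population/genome bin mismatch")
  val <- withr::with_seed(as.integer(seed),
                          stats::rpois(genome$n_bins, depth * copy))
  make_track(genome, val)
}

#' Simulate nascent-strand sequencing read counts per origin
#'
#' Reads per origin are Poisson with mean `depth * f_i`, where `f_i` is the
#' origin's per-cell initiation frequency in the requested round. The
#' `"re"` round counts only re-initiations on already-replicated templates —
#' the heavy-heavy (HH) nascent-strand library — while `"normal"` counts
#' first-round initiations (the heavy-light library).
#'
#' @param origins the `origin_set` the population was simulated with.
#' @param population a `population_result`.
#' @param depth expected reads for an origin initiating in every cell (> 0).
#' @param seed integer seed.
#' @param round `"normal"` or `"re"`.
#' @return integer vector of read counts, one per origin.
#' @export
simulate_nascent_reads <- function(origins, population, depth, seed = 1L,
                                   round = c("normal", "re")) {
  round <- match.arg(round)
  if (depth <= 0) stop_invalid("invalid config: depth must be > 0")
  counts <- if (round == "normal") population$firing_normal else
    population$firing_re
  if (length(counts) != nrow(origins)) {
    stop_invalid("origin set does not match the simulated population")
  }
  freq <- if (length(counts)) counts / population$cells else numeric(0)
  withr::with_seed(as.integer(seed),
                   stats::rpois(length(freq), depth * freq))
}

#' Bin per-origin nascent-strand reads into a coverage track
#'
#' Sums (normalized) nascent-strand read counts of all origins falling in
#' each genome bin — the binned origin-activity signal that, taken as a
#' ratio over a sheared genomic-DNA control, yields the nascent-strand
#' enrichment tracks used for amplification scoring.
#'
#' @param genome a `genome_model`.
#' @param origins an `origin_set` on that genome.
#' @param reads numeric vector of per-origin read counts.
#' @return a track `data.frame`.
#' @export
nascent_track <- function(genome, origins, reads) {
  if (length(reads) != nrow(origins)) {
    stop_invalid("one read count per origin required")
  }
  val <- numeric(genome$n_bins)
  obin <- bin_of(genome, origins$position)
  ok <- !is.na(obin)
  if (any(ok)) {
    agg <- tapply(reads[ok], obin[ok], sum)
    val[as.integer(names(agg))] <- agg
  }
  make_track(genome, val)
}
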