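#' Default pipeline configuration
#'
#' A compact demo-scale configuration exercising every analysis stage:
#' genome, origin licensing, population simulation in all three modes,
#' coverage and nascent-strand libraries, fibers, density gradient, timing,
#' origin usage, fiber statistics and chromatin association.
#'
#' @param seed global seed.
#' @return a nested configuration list (the same structure a YAML config
#'   file deserializes to).
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    genome = list(n_bins = 400L, bin_width = 10000L, chrom = "chrS",
                  coupling = 0.9, smooth_bins = 40),
    origins = list(density_per_mb = 30, skew = 2, dormant_fraction = 0.15),
    params = list(cells = 150L, depth = 1500, fire_prob_normal = 0.3),
    coverage_depth = 300,
    fibers = list(n_fibers = 300L, stall_prob_control = 0.06,
                  stall_prob_treated = 0.20, treated_speed_factor = 0.67),
    gradient = list(n_fractions = 20L, densities = c(1.70, 1.75, 1.80),
                    sd = 0.01),
    analysis = list(pseudocount = 1, smooth_bins = 11,
                    asymmetry_threshold = 0.30, fractions = 10L,
                    small = c(250, 400), large_min = 400,
                    dormant_low = 50, dormant_high = 250,
                    domain_background_quantile = 0.5,
                    domain_min_gap_bp = 20000, domain_min_size_bp = 20000,
                    flank_bp = 30000, profile_anchors = 150L),
    inputs = list())
}

#' Validate a pipeline configuration
#'
#' Schema checks run before any stage: required sections, positive
#' thresholds, probabilities in range, and existence of any externally
#' supplied input files. Errors abort before simulation starts.
#'
#' @param config a configuration list, or a path to a YAML file.
#' @return the validated (fully defaulted) config, invisibly usable.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_invalid("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  base <- default_config(seed = config$seed %||% 1L)
  merge2 <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge2(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  cfg <- merge2(base, config)
  a <- cfg$analysis
  for (nm in c("pseudocount", "asymmetry_threshold", "fractions",
               "large_min", "dormant_low", "dormant_high", "flank_bp")) {
    if (!is.numeric(a[[nm]]) || a[[nm]] <= 0) {
      stop_invalid("invalid config: analysis$", nm, " must be > 0")
    }
  }
  if (a$dormant_low >= a$dormant_high) {
    stop_invalid("invalid config: dormant_low must be < dormant_high")
  }
  if (length(a$small) != 2 || a$small[1] >= a$small[2]) {
    stop_invalid("invalid config: analysis$small must be c(lo, hi) with lo < hi")
  }
  if (cfg$genome$n_bins < 1 || cfg$genome$bin_width < 1) {
    stop_invalid("invalid config: genome n_bins/bin_width must be >= 1")
  }
  for (p in unlist(cfg$inputs)) {
    if (!file.exists(p)) stop_invalid("missing input file: ", p)
  }
  cfg
}

#' Run the full simulation-to-analysis pipeline
#'
#' Stages: simulate (genome, origins, populations, coverage and
#' nascent-strand libraries, fibers, gradient) -> timing -> origin usage ->
#' fiber statistics -> domains/chromatin -> report. Every stage's outputs
#' are written under `out_dir` and a `manifest.json` records the config,
#' seed and md5 checksum of every file, so a rerun with the same seed is
#' verifiably identical. If `inputs$s_cov`/`inputs$g1_cov` bedGraph paths
#' are supplied, the timing stage analyzes those tracks instead of the
#' simulated ones.
#'
#' @param config configuration list or YAML path (see [default_config()]).
#' @param out_dir output directory (created).
#' @param seed overrides `config$seed` when given.
#' @return invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL) {
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  s0 <- as.integer(cfg$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(writer, obj, rel) {
    p <- file.path(out_dir, rel)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    writer(obj, p)
    files <<- c(files, p)
    p
  }

  ## --- simulate ------------------------------------------------------
  g <- cfg$genome
  genome <- build_genome(g$n_bins, g$bin_width, chrom = g$chrom,
                         coupling = g$coupling, smooth_bins = g$smooth_bins,
                         seed = child_seed(s0, 1))
  origins <- place_origins(genome, cfg$origins$density_per_mb,
                           skew = cfg$origins$skew,
                           dormant_fraction = cfg$origins$dormant_fraction,
                           seed = child_seed(s0, 2))
  params <- do.call(sim_params, cfg$params)
  pop_norm <- simulate_population(genome, origins, params, "normal",
                                  seed = child_seed(s0, 3))
  pop_rerep <- simulate_population(genome, origins, params, "rereplication",
                                   seed = child_seed(s0, 4))
  pop_stress <- simulate_population(genome, origins, params, "stress",
                                    seed = child_seed(s0, 5))
  dcov <- cfg$coverage_depth
  g1_cov <- simulate_coverage(genome, NULL, dcov, seed = child_seed(s0, 6))
  s_cov <- simulate_coverage(genome, pop_norm, dcov, seed = child_seed(s0, 7))
  rerep_cov <- simulate_coverage(genome, pop_rerep, dcov,
                                 seed = child_seed(s0, 8))
  emit(write_bedgraph, g1_cov, "simulate/g1_cov.bedGraph")
  emit(write_bedgraph, s_cov, "simulate/s_cov.bedGraph")
  emit(write_bedgraph, rerep_cov, "simulate/rerep_cov.bedGraph")
  emit(write_bedgraph, genome_track(genome, "euchromatin"),
       "simulate/euchromatin.bedGraph")

  depth <- params$depth
  counts <- list(
    control_hl = simulate_nascent_reads(origins, pop_norm, depth,
                                        seed = child_seed(s0, 9)),
    mln_hl = simulate_nascent_reads(origins, pop_rerep, depth,
                                    seed = child_seed(s0, 10)),
    mln_hh = simulate_nascent_reads(origins, pop_rerep, depth,
                                    seed = child_seed(s0, 11), round = "re"),
    stress = simulate_nascent_reads(origins, pop_stress, depth,
                                    seed = child_seed(s0, 12)))
  tab <- usage_table(origins, counts)
  for (cond in names(counts)) {
    bed <- tab$intervals[, c("chrom", "start", "end")]
    bed$name <- paste0("origin_", tab$intervals$origin_id)
    bed$score <- counts[[cond]]
    emit(write_bed, bed, sprintf("simulate/origins_%s.bed", cond))
  }

  fib <- cfg$fibers
  p_ctrl <- params; p_ctrl$stall_prob <- fib$stall_prob_control
  p_trt <- params; p_trt$stall_prob <- fib$stall_prob_treated
  ## re-replicating cells: slower forks, closer initiation events
  p_trt$fork_speed_kb_per_min <- params$fork_speed_kb_per_min *
    (fib$treated_speed_factor %||% 1)
  p_trt$mean_iod_kb <- params$mean_iod_kb / 2
  fibers_ctrl <- simulate_fibers(p_ctrl, fib$n_fibers,
                                 seed = child_seed(s0, 13))
  fibers_trt <- simulate_fibers(p_trt, fib$n_fibers,
                                seed = child_seed(s0, 14))
  emit(write_tsv, fibers_ctrl, "simulate/fibers_control.tsv")
  emit(write_tsv, fibers_trt, "simulate/fibers_treated.tsv")

  grad <- simulate_gradient(pop_rerep, cfg$gradient$n_fractions,
                            cfg$gradient$densities, cfg$gradient$sd,
                            seed = child_seed(s0, 15))
  emit(write_tsv, as.data.frame(grad), "simulate/gradient_profile.tsv")

  ## --- timing --------------------------------------------------------
  a <- cfg$analysis
  if (!is.null(cfg$inputs$s_cov)) s_cov <- read_bedgraph(cfg$inputs$s_cov)
  if (!is.null(cfg$inputs$g1_cov)) g1_cov <- read_bedgraph(cfg$inputs$g1_cov)
  ratio_s <- log2_ratio(s_cov, g1_cov, a$pseudocount,
                        smooth_bins = a$smooth_bins)
  ratio_rerep <- log2_ratio(rerep_cov, g1_cov, a$pseudocount,
                            smooth_bins = a$smooth_bins)
  groups4 <- stratify_by_range_percentile(ratio_s, "four_equal")
  groups6 <- stratify_by_range_percentile(ratio_s, "six_range")
  ## amplification scores are computed on nascent-strand enrichment
  ## (re-replicating vs control origin activity over a genomic background)
  gdna <- simulate_coverage(genome, NULL, 100, seed = child_seed(s0, 18))
  amp <- amplification_scores(
    log2_ratio(nascent_track(genome, origins, tab$normalized[, "mln_hh"]),
               gdna, a$pseudocount),
    log2_ratio(nascent_track(genome, origins, tab$normalized[, "control_hl"]),
               gdna, a$pseudocount),
    groups4, elements = origins$position)
  emit(write_bedgraph,
       stats::setNames(ratio_s, c("chrom", "start", "end", "value")),
       "timing/log2_s_over_g1.bedGraph")
  grp_bed <- groups6$bins
  grp_bed$name <- as.character(groups6$group_of_bin)
  emit(write_bed, grp_bed, "timing/timing_groups6.bed")
  emit(write_tsv, amp$summary, "timing/amplification_summary.tsv")

  ## --- origin usage --------------------------------------------------
  pairs_hh <- pair_conditions(tab, "control_hl", "mln_hh")
  pairs_stress <- pair_conditions(tab, "control_hl", "stress")
  fr <- ratio_fractions(pairs_hh, a$fractions, a$small, a$large_min)
  strat <- timing_stratified_pairs(pairs_hh, groups6,
                                   n_fractions = a$fractions,
                                   small = a$small, large_min = a$large_min)
  dorm_stress <- detect_dormant(pairs_stress, a$dormant_low, a$dormant_high)
  dorm_rerep <- detect_dormant(pairs_hh, a$dormant_low, a$dormant_high)
  emit(write_tsv, fr$summary, "origins/fraction_summary.tsv")
  emit(write_tsv, as.data.frame(pairs_hh), "origins/pairs_control_vs_hh.tsv")
  if (nrow(dorm_stress$origins)) {
    bed <- tab$intervals[match(dorm_stress$origins$origin_id,
                               tab$intervals$origin_id),
                         c("chrom", "start", "end")]
    bed$name <- "dormant"
    emit(write_bed, bed, "origins/dormant_stress.bed")
  }

  ## --- fibers --------------------------------------------------------
  asym_ctrl <- asymmetry_summary(fibers_ctrl, a$asymmetry_threshold)
  asym_trt <- asymmetry_summary(fibers_trt, a$asymmetry_threshold)
  rate_ctrl <- fork_rate(fibers_ctrl$left_kb + fibers_ctrl$right_kb,
                         attr(fibers_ctrl, "label_minutes") * 2)
  rate_trt <- fork_rate(fibers_trt$left_kb + fibers_trt$right_kb,
                        attr(fibers_trt, "label_minutes") * 2)
  mw <- rank_sum_test(rate_ctrl, rate_trt)
  chisq <- two_by_two_chisq(asym_ctrl$n_asymmetric,
                            asym_ctrl$n_forks - asym_ctrl$n_asymmetric,
                            asym_trt$n_asymmetric,
                            asym_trt$n_forks - asym_trt$n_asymmetric)
  fiber_report <- list(
    control = list(percent_asymmetric = asym_ctrl$percentage,
                   n_forks = asym_ctrl$n_forks,
                   median_rate_kb_min = stats::median(rate_ctrl),
                   median_iod_kb = stats::median(
                     inter_origin_distances(fibers_ctrl))),
    treated = list(percent_asymmetric = asym_trt$percentage,
                   n_forks = asym_trt$n_forks,
                   median_rate_kb_min = stats::median(rate_trt),
                   median_iod_kb = stats::median(
                     inter_origin_distances(fibers_trt))),
    rank_sum_p = mw$p.value, chisq_stat = chisq$statistic,
    chisq_p = chisq$p.value)
  emit(function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                           digits = NA),
       fiber_report, "fibers/summary.json")

  ## --- domains / chromatin -------------------------------------------
  domains <- segment_domains(ratio_to_track(ratio_rerep),
                             a$domain_background_quantile,
                             a$domain_min_gap_bp, a$domain_min_size_bp)
  report_domains <- NULL
  if (nrow(domains) >= 4) {
    domains <- quartile_stratify(domains)
    bed <- domains[, c("chrom", "start", "end")]
    bed$name <- as.character(domains$quartile)
    bed$score <- round(domains$peak_height, 4)
    emit(write_bed, bed, "domains/rerep_domains.bed")
    euch_iv <- intervals_above(genome_track(genome, "euchromatin"), 0)
    ir <- inc_ratio(domains[domains$quartile == "high", , drop = FALSE],
                    euch_iv)
    report_domains <- list(n_domains = nrow(domains),
                           mean_size_kb = mean(domains$size_bp) / 1000,
                           high_vs_euchromatin_inc_ratio = ir$inc_ratio)
  }
  eig <- eigen_correlation(ratio_to_track(ratio_rerep),
                           genome_track(genome, "euchromatin"))
  chip <- simulate_chip_track(genome, origins, seed = child_seed(s0, 16))
  n_anch <- min(a$profile_anchors %||% 150L, nrow(origins))
  anch <- withr::with_seed(child_seed(s0, 19),
                           sort(sample(origins$position, n_anch)))
  prof <- anchor_profile(chip, anch, a$flank_bp, groups6,
                         seed = child_seed(s0, 17))
  profile_tsv <- data.frame(offset_bp = prof$offsets_bp,
                            mean_signal = prof$profile,
                            random = prof$random_profile %||%
                              rep(NA_real_, length(prof$profile)))
  emit(write_tsv, profile_tsv, "domains/anchor_profile.tsv")

  ## --- report / manifest ---------------------------------------------
  report <- list(
    seed = s0,
    genome = list(n_bins = genome$n_bins, bin_width = genome$bin_width,
                  n_origins = nrow(origins)),
    fibers = fiber_report,
    gradient_hh_mass = gradient_window_mass(grad, "HH"),
    amplification_medians = stats::setNames(amp$summary$median,
                                            as.character(amp$summary$group)),
    dormant_share_stress = dorm_stress$share,
    dormant_share_rereplication = dorm_rerep$share,
    eigen_R = eig$R,
    domains = report_domains)
  emit(function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                           digits = NA),
       report, "report.json")

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, cfg_path)
  manifest <- list(
    seed = s0,
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = data.frame(
      path = sub(paste0("^", out_dir, "/?"), "", files),
      md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

## ratio_track -> plain coverage-style track (value column)
ratio_to_track <- function(ratio) {
  data.frame(chrom = ratio$chrom, start = ratio$start, end = ratio$end,
             value = ratio$log2_ratio)
}

## merge consecutive bins above a threshold into intervals
intervals_above <- function(track, threshold) {
  above <- track$value > threshold
  if (!any(above)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(chrom = track$chrom[starts[r$values]],
             start = track$start[starts[r$values]],
             end = track$end[ends[r$values]])
}
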