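# Demo-scale pipeline configuration. Any field omitted here falls back to
# the package defaults (see default_config()); probabilities are per label
# window / replication round.
seed: 1
genome:
  n_bins: 400          # 4 Mb at 10 kb bins
  bin_width: 10000
  chrom: chrS
  coupling: 0.9        # timing-euchromatin coupling in [0, 1]
  smooth_bins: 40      # timing-domain scale (sd of smoothing kernel, bins)
origins:
  density_per_mb: 30   # licensed origins per Mb
  skew: 2              # licensing skew kappa (early preference)
  dormant_fraction: 0.15
params:
  cells: 150
  depth: 1500          # expected reads per always-firing origin
  fire_prob_normal: 0.3
coverage_depth: 300    # reads per bin per genome copy
fibers:
  n_fibers: 300
  stall_prob_control: 0.06
  stall_prob_treated: 0.20
  treated_speed_factor: 0.67   # slower forks while re-replicating
gradient:
  n_fractions: 20
  densities: [1.70, 1.75, 1.80]   # LL / HL / HH buoyant densities, g/ml
  sd: 0.01
analysis:
  pseudocount: 1
  smooth_bins: 11
  asymmetry_threshold: 0.30
  fractions: 10
  small: [250, 400]
  large_min: 400
  dormant_low: 50
  dormant_high: 250
  domain_background_quantile: 0.5
  domain_min_gap_bp: 20000
  domain_min_size_bp: 20000
  flank_bp: 30000
  profile_anchors: 150
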