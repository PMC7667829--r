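# Ground-truthed synthetic fixtures emulating the characterized packaging
# systems. Magnitudes follow the characterized systems: a lambda-like
# temperate phage with a 1:10,000 specialized-transduction flank ratio and
# ~25 kbp flanks; a P22-like generalized transducer with a 44 kbp headful
# and six pac-like sites; a P1-like quasi-random packager with low (<10x)
# coverage unevenness; a PBSX-like GTA with 13 kbp fragments and a 30-fold
# packaging bias; a lateral transducer with a 1:240 frequency. Coverage
# levels are chosen so every signature clears the detector's raw-depth
# gates (see the methods vignette).
bin_size: 100
read_length: 150
fixtures:
  lambda_like:
    contig_length: 300000
    circular: false
    n_particles: 2000000
    wgs_mean_depth: 100
    prophage:
      start: 125000
      end: 173500
      induction_rate: 1.0
      f_spec: 2.0e-4        # 1e-4 per side: plateau/flank = 10,000
      capsid: 48500
      min_retained: 23500   # max flank extent 25 kbp
      side_bias: 0.5
  p22_like:
    genome_length: 1300000
    circular: false
    n_particles: 20000
    wgs_mean_depth: 100
    headful: 44000
    q: 0.6
    pac_positions: [100000, 300000, 500000, 700000, 900000, 1100000]
  p1_like:
    genome_length: 2000000
    circular: true
    n_fragments: 40000
    fragment_size: 90000
    bias_fold: 6.0
    bias_corr: 200000
    wgs_mean_depth: 100
  pbsx_like:
    genome_length: 2000000
    circular: true
    n_fragments: 600000
    fragment_size: 13000
    bias_fold: 30.0         # calibrated so smoothed expected max/min = 30
    bias_corr: 150000
    wgs_mean_depth: 100
    ori_gradient: 1.3
  faecalis_like:
    contig_length: 600000
    circular: false
    n_particles: 200000
    wgs_mean_depth: 100
    prophage:
      start: 100000
      end: 140000
      induction_rate: 1.0
      f_spec: 0.0
      lateral_ratio: 240    # lateral initiation rate = induction/240
      q: 0.75
      lateral_direction: right
  community_like:
    n_standard: 22
    n_dominant: 10          # abundant community members, standard pattern
    n_contamination: 4
    n_induction: 6
    n_island: 2
    n_specialized: 5
    n_lateral: 5
    n_generalized: 4
    n_gta: 4
    rate_scale: 1.0
    induction_depth: 5000
    element_depth: 50000    # specialized/lateral plateau particle count
    spec_ratio: 50          # specialized frequency 1:50 (per side)
    lateral_ratio: 40       # lateral frequency 1:40
    pac_depth: 3000         # generalized initiations per pac site
    gta_depth: 2000         # mean GTA coverage
    gta_bias_fold: 3.0
    contam_fraction: 0.02
    noise_rate: 0.3         # stray VLP read depth per bin
    wgs_mean: 100
    wgs_sdlog: 0.4
    dominant_wgs_mean: 1400
    headful: 44000
    q_pac: 0.6
    q_lateral: 0.75
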