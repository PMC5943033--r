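# Paper-calibrated synthetic scenario: the planted per-stage parameters are
# the reported group means of the zebrafish islet aging study (see the
# methods vignette). Cell counts per islet grow with age; they are
# order-of-magnitude choices and stay configurable here.
voxel_size_um: 0.5
nucleus_radius_um: 3.0
noise_model:
  photon_scale: 2.0
  background: 2.0
  blur_sigma_um: 0.5
seed: 1
stages:
  35dpf:
    n_islets: 5
    cells_min: 300
    cells_max: 600
    p_proliferating: 0.0153
    gfp_mixture: {w_high: 0.05, mu_low: 1.6, sigma_low: 0.4, mu_high: 4.1, sigma_high: 0.4}
  3mpf:
    n_islets: 9
    cells_min: 600
    cells_max: 1000
    p_proliferating: 0.0015
    gfp_mixture: {w_high: 0.40, mu_low: 1.6, sigma_low: 0.4, mu_high: 4.1, sigma_high: 0.4}
    p_edu_given_gfp_high: 0.01
    p_edu_given_gfp_low: 0.04
    detection_prob: {bact1: 0.98, ef1a: 0.98, rpl13a: 0.98, ins: 0.95, isl1: 0.90,
                     neurod1: 0.90, tnfrsf1b: 0.25, ikbaa: 0.30, tnfa: 0.10, socs2: 0.20}
    facs: {w_high: 0.35, mu_low: 3.4, sigma_low: 0.5, mu_high: 5.7, sigma_high: 0.5}
  1ypf:
    n_islets: 10
    cells_min: 800
    cells_max: 1200
    p_proliferating: 0.0006
    gfp_mixture: {w_high: 0.90, mu_low: 1.6, sigma_low: 0.4, mu_high: 4.1, sigma_high: 0.4}
    p_edu_given_gfp_high: 0.005
    p_edu_given_gfp_low: 0.02
    detection_prob: {bact1: 0.98, ef1a: 0.98, rpl13a: 0.98, ins: 0.95, isl1: 0.90,
                     neurod1: 0.90, tnfrsf1b: 0.60, ikbaa: 0.65, tnfa: 0.30, socs2: 0.50}
    facs: {w_high: 0.80, mu_low: 3.4, sigma_low: 0.5, mu_high: 5.7, sigma_high: 0.5}
  mosaic_23dpf:
    n_islets: 9
    cells_min: 150
    cells_max: 300
    p_cfp: 0.30
    p_prolif_given_cfp: 0.0108
    p_prolif_given_nocfp: 0.0844
  larva_injected:
    n_islets: 6
    cells_min: 25
    cells_max: 40
    # per-cell NF-kB reporter positivity in tnfrsf1b-injected larvae
    gfp_mixture: {w_high: 0.322, mu_low: 1.1, sigma_low: 0.4, mu_high: 4.4, sigma_high: 0.4}
  larva_control:
    n_islets: 5
    cells_min: 25
    cells_max: 40
    gfp_mixture: {w_high: 0.024, mu_low: 1.1, sigma_low: 0.4, mu_high: 4.4, sigma_high: 0.4}
extras:
  macrophage:
    3mpf: {n_animals: 5, leuko_min: 8, leuko_max: 16, p_tnfa: 0.25}
    1ypf: {n_animals: 5, leuko_min: 10, leuko_max: 20, p_tnfa: 0.17}
  bulk_qpcr:
    reference_gene: bact2
    n_replicates: 4
    noise_sd: 0.2
    # socs2 planted at 2.6x: "more than 2.5-fold" enrichment
    fold_changes: {bact2: 1.0, socs2: 2.6, cish: 1.2, spry4: 1.1, trib3: 1.2,
                   rapgef4: 1.0, tnfa: 1.3, tnfrsf1b: 1.2}
  gfp_transcript:
    reference_gene: bact1
    n_replicates: 4
    noise_sd: 0.2
    fold_changes: {bact1: 1.0, gfp: 1.5}
  indexed:
    n_cells: 5000
    target_r2: 0.28
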