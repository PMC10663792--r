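simulation:
  plot_edge: 200.0
  n_replicates: 25.0
  years: 320.0
  rng_seed: 1.0
  k: 0.6
  light_layer_width: 0.5
  ceiling: 100.0
  dbh_min: 0.01
  stress_rel_incr: 0.003
  stress_years: 2.0
  stress_mort: 0.1
  f_stem: 0.52
  crowd_mort_max: 0.03
  p_fall: 0.5
  fall_height: 18.0
  damage_p: 0.6
pfts:
- pft_id: 1
  h0: 30.0
  h1: 0.5
  c0: 20.0
  f_crown: 0.35
  la0: 628.3185307
  la1: 2.0
  rho: 0.09
  form: 0.45
  alpha: 0.0116
  pmax: 0.00265
  r_main: 0.35
  r_growth: 0.925
  m_b: 0.025
  d_max: 0.88
  i_seed: 200.0
  i_min: 0.25
  shade_tolerant: no
- pft_id: 2
  h0: 36.0
  h1: 0.52
  c0: 19.0
  f_crown: 0.35
  la0: 737.1747162
  la1: 2.0
  rho: 0.35
  form: 0.45
  alpha: 0.009
  pmax: 0.00216
  r_main: 0.088
  r_growth: 0.725
  m_b: 0.018
  d_max: 1.0
  i_seed: 50.0
  i_min: 0.08
  shade_tolerant: no
- pft_id: 3
  h0: 42.0
  h1: 0.58
  c0: 18.0
  f_crown: 0.4
  la0: 916.0884178
  la1: 2.0
  rho: 0.45
  form: 0.45
  alpha: 0.0073
  pmax: 0.00178
  r_main: 0.04
  r_growth: 0.725
  m_b: 0.011
  d_max: 2.2
  i_seed: 120.0
  i_min: 0.03
  shade_tolerant: yes
- pft_id: 4
  h0: 42.0
  h1: 0.58
  c0: 17.0
  f_crown: 0.45
  la0: 862.524263
  la1: 2.0
  rho: 0.55
  form: 0.45
  alpha: 0.0064
  pmax: 0.00157
  r_main: 0.034
  r_growth: 0.725
  m_b: 0.009
  d_max: 2.6
  i_seed: 95.0
  i_min: 0.01
  shade_tolerant: yes
profile:
  dhs:
  - 100.0
  - 20.0
  - 10.0
  - 2.0
  cell_edges:
  - 200.0
  - 100.0
  - 20.0
brt:
  learning_rates:
  - 0.05
  - 0.01
  - 0.005
  bag_fractions:
  - 0.3
  - 0.5
  - 0.66
  cv_folds: 10.0
  fraction: 0.5
  cap: 15900.0
  boundary: 160.0
fixtures:
  n_trees: 100.0
  height_dist: uniform
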