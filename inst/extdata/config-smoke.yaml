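# Small end-to-end configuration: 24x24 landscape, 50 replicates, 10 years.
name: smoke
seed: 42
landscape:
  rows: 24
  cols: 24
  cell_size_km: 1
  gradient: hill
occurrences:
  n_presence: 120
  n_background: 240
landcover:
  fraction_unsuitable: 0.2
  clustering: true
sdm:
  algorithms: [glm, maxent_like, random_forest]
  k: 5
climate:
  trend_temp_per_year: 0.06
  trend_prec_frac_per_year: -0.004
  coarse_factor: 4
  noise_sd_temp: 0.2
  noise_cv_prec: 0.05
  window: 10
  update_every: 5
demography:
  years: 12
  initial_counts: [600, 300, 300]
  observation_noise_cv: 0.05
  n_resamples: 60
patches:
  suitability_threshold: 0.5
  neighborhood_km: 5
  density: 100
simulation:
  n_replicates: 50
  horizon_years: 10
  quasi_extinction_threshold: 10
harvest:
  quota: 5
  interval: 2
  min_population: 50
landcover_expansion:
  rate: 0.01
  adjacency_radius: 1
scenarios:
  baseline: {climate: false, landcover: intensification, harvest: NONE}
  CC: {climate: true, landcover: intensification, harvest: NONE}
  LC: {climate: false, landcover: expansion, harvest: NONE}
  CCLC: {climate: true, landcover: expansion, harvest: NONE}
  CCLC_ALL: {climate: true, landcover: expansion, harvest: ALL}
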