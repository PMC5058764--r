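# Fully populated pipeline configuration (matches default_config()).
# Any key can be overridden; absent keys keep their defaults.
n_patients: 1108
constants:
  epithelial_fraction: 0.1
  benign_secretion: 0.30
  psa_exclusion_max: 20
  gland_percentile_cut: 95
cohort: {}          # overrides for cohort_sim_params()
expression: {}      # overrides for expression_sim_params()
meta:
  n_perm: 2000
  alpha: 0.05
survival:
  covariates: [epe, svi, positive_margins, grade_intermediate, grade_high, ln_tpsad]
ihc:
  low_grade_od: 0.8
  high_grade_od: 0.5
  n_images: 10
  image_size: 256
  noise_sd: 2
  n_regions: 3
  region_size: 64
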