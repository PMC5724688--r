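# Default rice-stand configuration: booting-stage canopy at 20 plants m-2,
# Shanghai (31 N), day of year 235, half-hour diurnal steps.
site:
  latitude: 31.0
  day_of_year: 235
  time_step_h: 0.5
canopy:
  plants_x: 3
  plants_y: 3
  tillers: 11
  segments: 5
  angle_factor: 1.0
  height_factor: 1.0
  lai_factor: 1.0
chl:
  mean: 494.7          # umol m-2, area-weighted canopy mean
  distribution: uniform  # or measured_like
  multiplier: 1.0
optics:
  a_max: 0.96          # asymptotic PAR absorbance
  chl_ref: 494.7
  abs_at_ref: 0.90     # absorbance at the reference chlorophyll
  r_share: 0.5         # reflected share of unabsorbed PAR
nitrogen:
  nla_flag: 1.6        # flag-leaf N, g m-2
  n_b: 0.4             # basal leaf N, g m-2
  beta: 0.8
  alpha: 0.45
  form: power          # b = beta * GAI^(-alpha)
acclimation:
  photo_frac: 0.75     # photosynthetic fraction of leaf N
  grid_size: 40
scenario:
  n_strategy: lhc_only   # or constant_total_n
trace:
  rays_per_m2: 20000
  max_bounces: 2
  energy_cutoff: 0.01
  soil_reflectance: 0.0
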