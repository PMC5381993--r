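# Default generating parameters for the synthetic occupational cohort.
# Versioned so calibration corridors are reproducible; marginal outputs are
# calibrated to the demographic/vital-status profile of a mid-century male
# smelter workforce (~8,000 workers, entry 1939-1956, follow-up to 1990,
# ~5.6% dead of respiratory cancer, ~21% heart disease, ~34% other causes).
version: 1
n_workers: 8014
seed: 2026
max_age: 90
admin_end_year: 1990
entry_age_distribution:
  median: 31.6      # years; log-normal above an 18-year floor
  spread: 0.60      # sdlog of the log-normal; must be > 0
entry_calendar_window:
  start_year: 1939
  end_year: 1956
category_concentrations:   # mg/m^3 time-weighted airborne concentration
  light: 0.29
  medium: 0.58
  heavy: 11.4
gamma: 0.1                 # heavy-category discount (filtration masks)
baseline:
  p_us_born: 0.867
  p_unexposed_pre_entry: 0.026
  p_long_tenure: 0.33      # fraction with work history well before entry
  tenure_shape: 1.2        # gamma-distributed extra pre-entry years
  tenure_scale: 5.0
  pre_entry_category_probs:
    light: 0.55
    medium: 0.30
    heavy: 0.15
# Generating coefficients, keyed by the fitting module's design-matrix column
# names (the "linear" model form). Log-odds scale; age_c = (age-50)/10,
# year_c = (year-1950)/10, cum_work_c = post-entry years worked / 10,
# exposure windows in mg/m^3-years.
models:
  d_resp:
    intercept: -7.7
    age_c: 1.15
    year_c: -0.05
    employed: -0.25
    cum_work_c: -0.05
    us_born: 0.10
    pre_entry_years: 0.005
    pre_entry_exposure: 0.05
    w_2_5: 0.09
    w_5_10: 0.06
    w_10_20: 0.04
  d_heart:
    intercept: -5.7
    age_c: 0.95
    year_c: -0.10
    employed: -0.35
    cum_work_c: -0.05
    us_born: 0.05
    pre_entry_years: 0.005
    pre_entry_exposure: 0.03
    w_2_5: 0.05
    w_5_10: 0.03
    w_10_20: 0.02
  d_other:
    intercept: -5.0
    age_c: 0.85
    year_c: -0.05
    employed: -0.35
    cum_work_c: -0.05
    us_born: -0.05
    pre_entry_years: 0.005
    pre_entry_exposure: 0.02
    w_2_5: 0.04
    w_5_10: 0.025
    w_10_20: 0.015
  leave_work:
    intercept: -3.8
    age_c: 0.70
    w_recent_1_5: 2.3    # log-odds of leaving work per mg/m^3-year of
                         # exposure in the preceding 1-5 years (the
                         # healthy-worker-survivor confounding loop)
  return_work:
    intercept: -2.5
    age_c: -0.60
  exposure_category:
    zeta_1: 0.2          # cumulative-logit thresholds: light | medium
    zeta_2: 1.73         # medium | heavy
    age_c: -0.20
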