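model:
  n_draws: 10000
  seed: 42
  weighting: equal
  rr_scale: raw
  spread_mode: select
  discount_rate: '0.018'
  horizon: 10
scenarios:
- label: 20%
  f_lm: '9.3'
  f_mh: '18.8'
  mode: calibrated
  mean_reduction: '0.0355'
- label: 80%
  f_lm: '35.5'
  f_mh: '48.3'
  mode: calibrated
  mean_reduction: '0.1345'
cost_tables:
  us:
    file: cost_table_us.csv
    country: United States
    currency: US$
    units: billion
    base_year: 2013
    cpi_factor: '1.1180218446601942'
    annual_growth: '0.0354'
    total_2017: '368.5'
  canada:
    file: cost_table_canada.csv
    country: Canada
    currency: Can$
    units: million
    base_year: 2010
    cpi_factor: '1.0499853415420697'
    annual_growth: '0.013'
    total_2017: '14326'
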