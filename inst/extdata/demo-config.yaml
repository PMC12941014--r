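# Demo pipeline: 5x5 rook lattice, one calendar year at monthly
# resolution plus the four-year yearly panel, small sampler settings.
output_dir: demo-output
seed: 20180101
stages: [simulate, moran, fit, compare, effects, timeseries]
simulate:
  rows: 5
  cols: 5
  contiguity: rook
  likelihood: poisson
  years: [2018, 2019, 2020, 2021]
  month_years: [2018]
moran:
  n_perm: 999
fit:
  models: [1, 2, 4]
  draws: 500
  warmup: 500
  chains: 2
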