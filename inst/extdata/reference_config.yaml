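# Default run configuration: all nine reference planting scenarios for the
# Suwon street-tree site, flat absorption accounting, 70% intensive ratio,
# 20-year replacement cycle, monthly simulation 2021-2050.
scenarios: all
mode: flat
target_ratio: 0.7
replacement_period_months: 240
horizon_months: 360
start_year: 2021
start_month: 1
scheme: first_order
output_dir: results
seed: 1
log_level: info
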