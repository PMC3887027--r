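# Old-adult (40-week) beta cells, 5 mmol/l glucose.
# Calibration preset: near-flat numbers at all glucose concentrations.
scenario_name = old_5mM
n_cells_initial = 2000
duration_days = 15
time_step_days = 0.05
recruitment_hazard = 0:0.004
death_hazard = 0.006
cycle_length_days = 1.0
s_phase_fraction = 0.3
refractory_days = 4
disintegration_days = 5
fraction_insulin_positive = 0.9
label_windows = EdU:3:6,BrdU:7:10
rng_seed = 1
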