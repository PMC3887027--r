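# Young-adult beta cells, 5 mmol/l glucose + glucokinase activator.
# Calibration preset: GKA lowers the glucose threshold for recruitment, so
# the recruitment schedule matches the 20 mmol/l preset while death stays
# at the 5 mmol/l level.
scenario_name = adult_5mM_gka
n_cells_initial = 2000
duration_days = 15
time_step_days = 0.05
recruitment_hazard = 0:0.007,3:0.028,6:0.055,9:0.025,12:0.008
death_hazard = 0.022
cycle_length_days = 1.0
s_phase_fraction = 0.3
refractory_days = 4
disintegration_days = 5
fraction_insulin_positive = 0.9
label_windows = EdU:3:6,BrdU:7:10
rng_seed = 1
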