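# Young-adult beta cells, 20 mmol/l glucose + glucokinase activator.
# Calibration preset: no further increase over the 20 mmol/l schedule
# (GKA does not enlarge the glucose-recruitable pool).
scenario_name = adult_20mM_gka
n_cells_initial = 2000
duration_days = 15
time_step_days = 0.05
recruitment_hazard = 0:0.007,3:0.028,6:0.055,9:0.025,12:0.008
death_hazard = 0.005
cycle_length_days = 1.0
s_phase_fraction = 0.3
refractory_days = 4
disintegration_days = 5
fraction_insulin_positive = 0.9
label_windows = EdU:3:6,BrdU:7:10
rng_seed = 1
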