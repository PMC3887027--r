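# Neonatal (2-3 day) beta cells, 10 mmol/l glucose.
# Calibration preset: high recruitment (not increased versus 5 mmol/l),
# no refractory period, roughly doubling numbers.
scenario_name = neonatal_10mM
n_cells_initial = 2000
duration_days = 15
time_step_days = 0.05
recruitment_hazard = 0:0.10,3:0.161,6:0.14,10:0.02
death_hazard = 0.030
cycle_length_days = 1.0
s_phase_fraction = 0.3
refractory_days = 0
disintegration_days = 5
fraction_insulin_positive = 0.75
label_windows = EdU:3:6,BrdU:7:10
rng_seed = 1
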