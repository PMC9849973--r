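# Default simulation scenario: a small sisorid catfish population under
# heavy total mortality, sampled with gear whose logistic selectivity was
# calibrated to reproduce the motivating field sample's length structure
# (n = 725, TL mean ~5.8 cm, modal 0.5-cm class 5.5-6.0 cm).
n_fish: 725
linf_mean: 9.09
linf_cv: 0.035
k: 0.94
t0: 0.0
z: 2.12
lwr_a: 0.0061
lwr_b: 3.33
weight_sigma: 0.18
selectivity_l50: 5.0
selectivity_slope: 2.6
sl_ratio_mean: 0.813
sl_ratio_sd: 0.01
seed: 1
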