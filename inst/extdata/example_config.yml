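# protocol defaults with an explicit seed
threshold_ratio: 2.0
min_component_area_um2: 30
exclusion_wake_threshold: 0.60
exclusion_window_min: 45
seed: 17
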