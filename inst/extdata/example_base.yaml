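# Example base-model scenario: 2e6 total cells/mL, E:T 1, CD3 low,
# CD19 medium, 100 ng/mL BiTE, 60 min co-incubation.
model: base
total_density_per_ml: 2.0e+06
et_ratio: 1
cd3: L
cd19: M
bite_ngml: 100
duration_min: 60
scaled_volume_ul: 0.1
replicates: 10
seed: 1
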