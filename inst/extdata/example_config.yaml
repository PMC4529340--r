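n_samples_per_cohort: 90.0
n_genes: 2000.0
n_mirnas: 400.0
marker_separation: 4.0
batch_shift: 0.0
noise_sd: 0.5
seed: 1.0
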