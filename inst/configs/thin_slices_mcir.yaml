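# Thin-slice phantom experiment 2: alternating fit with averaging MCIR
regime: thin_slice
model: linear_sdot
cpg_spacing: 10
reference: mcir-average
seed: 1
target_dfe: 5.98
max_iter: 150
n_outer: 6
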