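# Thick-slice phantom experiment 2: alternating fit with super-resolution MCIR
regime: thick_slice
model: linear_sdot
cpg_spacing: 5
reference: mcir-superres
seed: 1
target_dfe: 2.98
max_iter: 120
n_outer: 7
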