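# Slab phantom experiment 1: linear value+derivative model, true reference
regime: slab
model: linear_sdot
cpg_spacing: 5
reference: "true"
seed: 1
target_dfe: 3.53
max_iter: 250
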