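# Full-image phantom experiment: periodic B-spline phase model, true reference
regime: full
model: periodic_bspline
cpg_spacing: 5
reference: "true"
seed: 1
target_dfe: 3.56
max_iter: 400
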