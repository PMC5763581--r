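# respfit

Unified image registration and surrogate-driven respiratory motion modelling
from full and partial image data, in R.

Respiratory motion models relate the motion of the lungs and abdominal organs
to easily measured surrogate signals (skin displacement, a respiratory belt,
spirometry), so that motion can be estimated during treatments or
acquisitions where it cannot be imaged directly.  They are usually built in
two stages — register a set of dynamic images, then regress the resulting
transformations against the surrogates.  That two-stage route needs full
images, which many acquisitions (cine CT slabs, fast-helical CT slices,
multi-slice MR) simply do not provide.

`respfit` instead optimises the correspondence-model coefficients **R**
directly on all frames of dynamic data at once, through a single
registration-style cost

    C_total = sum_t SSD( P_t , A_t( T(I_0, M_t) ) ),   M_t = sum_n R_n phi_n(S_t)

where `T` is a cubic B-spline free-form deformation of the reference image
`I_0`, `A_t` is an image acquisition operator (identity, row extraction for
slabs and thin slices, or a Gaussian slice profile for thick slices), and
`phi(S_t)` is the model basis — linear in the surrogate value and its
temporal derivative, polynomial, or a periodic cubic B-spline on respiratory
phase.  Gradients flow through the exact chain rule using the adjoint
operators `A_t*` (back-embedding) and push-interpolation (the adjoint of the
warp), so the model can be fitted to data from which no single frame could be
registered on its own.  When no reference image exists, the package
alternates fitting with motion-compensated image reconstruction (MCIR) —
weighted averaging, or super-resolution by iterative back-projection — and
estimates the motion model and a motion-free image jointly.

A seeded 2D lung-like phantom simulator with known ground-truth motion, the
four canonical partial-data acquisition regimes, and displacement-field-error
/ image-agreement / snap-to-voxel landmark evaluation utilities round out the
package.

## Worked example

Simulate the slab-acquisition phantom study (17 couch positions x 8 rows x
11 times = 187 slab frames with 3% Gaussian noise), fit the linear
value + derivative correspondence model against the true reference image,
and evaluate the pooled displacement-field error:

```r
library(respfit)

ds <- simulate_dataset(phantom_spec("slab", seed = 1, target_dfe = 3.53,
                                    target_p95 = 11.09))
model <- fit_model(ds$frames, ds$specs, ds$surrogate, ds$I_true,
                   kind = "linear_sdot",
                   fit_config(cpg_spacing = 5, levels = 3, max_iter = 250,
                              tol = 1e-5))

model_dfe_stats(ds, NULL)    # no-motion baseline
#>   mean       sd      p95       n
#> 1 3.53 3.967828 11.01386 1979208
model_dfe_stats(ds, model)   # fitted model
#>        mean        sd      p95       n
#> 1 0.3939451 0.4074224 1.248256 1979208
```

The baseline row says the simulated breathing moves each pixel inside the
phantom by 3.53 px on average (95th percentile 11 px).  After the unified
fit the same pooled error drops to 0.39 px mean / 1.25 px p95 — the model
has recovered the motion to well under a pixel almost everywhere, from slabs
that individually cover only 6% of the image.

Without any reference image, the same fit runs inside the alternating
MCIR scheme:

```r
fm <- fit_with_mcir(ds$frames, ds$specs, ds$surrogate, "linear_sdot",
                    fit_config(cpg_spacing = 5), n_outer = 3)
fm$I0          # motion-compensated reconstruction at the mean position
fm$cost_trace  # per-round total cost (non-increasing)
```

A thin command-line front end (`exec/respfit`) exposes
`simulate | fit | fit-mcir | evaluate | run`, and `inst/configs/` holds one
YAML per canonical phantom experiment for `run_experiment()`.

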