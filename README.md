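# sbtomo

Split Bregman total-variation (TV) iterative reconstruction for
limited-data fan-beam and cone-beam CT, in R.

When a CT acquisition has only a few dozen projections and/or an angular
span well below 360°, the analytic Feldkamp–Davis–Kress (FDK) method
produces severe streaks and edge distortion. `sbtomo` reconstructs such
data by solving the TV-constrained problem

```
min ||∇u||₁   s.t.   ||Au − f||₂² ≤ σ²,   u ≥ 0,   u ∈ Ω
```

with the Split Bregman formulation: each outer iteration solves the
normal equation `K u = μ Aᵀf^k + λ ∇ᵀ(d^k − b^k)`,
`K = μ AᵀA + λ ∇ᵀ∇ + β I`, matrix-free with BiCGStab, applies the
closed-form isotropic shrinkage to the split gradient variables, and
updates the Bregman variables `f^{k+1} = f^k + f − Au^{k+1}`,
`b^{k+1} = b^k + ∇u^{k+1} − d^{k+1}`.

The package is aimed at researchers prototyping limited-data
reconstruction methods: everything runs at desk scale on one CPU, with
the same structure a production implementation would have.

What is inside:

- **Matrix-free operators** — ray-driven (Siddon) forward projection and
  two backprojectors (exact matched adjoint, and the classical
  voxel-driven form), with memory-bounded chunk partitioning whose output
  is bit-identical to the unchunked path. Dense-matrix oracles for
  verification on small grids.
- **Split Bregman solver** (`reconstruct_tv`) with non-negativity and
  field-of-view constraints, isotropic shrinkage, per-iteration
  convergence trace, and early stopping at <1% relative change.
- **FDK baseline** (`reconstruct_fdk`) — cosine weighting, Ram-Lak/Hann
  ramp filtering, distance-weighted backprojection.
- **Simulator** — Shepp-Logan / disc / random-ellipsoid phantoms,
  Poisson counting noise, optional supersampled projection to avoid the
  inverse crime.
- **Metrics** — masked RMSE and ROI-based SNR (dB).
- **IO and CLI** — MetaImage/NIfTI volumes, multi-page TIFF projection
  stacks with a YAML geometry sidecar, and a `ctrecon` command-line tool
  (`inst/cli/ctrecon`) with `simulate`, `recon-fdk`, `recon-tv` and
  `evaluate` subcommands.

## Worked example

```r
library(sbtomo)

# 45 projections over 150 degrees of a piecewise-constant phantom
vol  <- make_phantom(phantom_spec("discs", c(64, 64)))
geom <- default_geometry(vol$grid, num_proj = 45, span = 150)
f    <- simulate_acquisition(vol, geom)

fdk <- reconstruct_fdk(f, vol$grid)
tv  <- reconstruct_tv(f, vol$grid, recon_params(), reference = vol)

m <- fov_mask(vol$grid)
round(c(fdk = rmse(fdk, vol, m), tv = rmse(tv$volume, vol, m)), 4)
#>    fdk     tv
#> 0.1871 0.0303

tail(tv$trace, 1)
#>    iteration  residual rel_residual  rel_change krylov_iterations       rmse
#> 13        13 0.8593682  0.001352794 0.009953946                12 0.02638403
```

The TV reconstruction cuts the RMSE against ground truth by about a
factor of six relative to FDK on this limited-span case, and `tv$trace`
shows the monotone RMSE decay across outer iterations. Default
reconstruction parameters are `alpha = 0.003`, `mu = 20`, `lambda = 2`,
`beta = 3` with at most 35 outer iterations.

The same pipeline from the shell:

```sh
inst/cli/ctrecon simulate --phantom discs --dim 64 --numproj 45 --span 150 --out case
inst/cli/ctrecon recon-fdk --input case.tif --dim 64 --out fdk.mhd
inst/cli/ctrecon recon-tv  --input case.tif --dim 64 --out tv.mhd --trace trace.csv
inst/cli/ctrecon evaluate  --input tv.mhd --reference case_truth.mhd --out metrics.csv
```

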