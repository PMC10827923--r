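# gpmorph

Gaussian-process morphable models of 3D shape and albedo built from a
**single vertex-colored template**, with the downstream machinery such
models exist for: inverse rendering of 2D images, nonrigid 3D registration,
mixture ("KDE") models over several templates, an unsupervised wake-sleep
learning loop, and the standard model-quality measures.

## Who this is for

Statistical shape and appearance models (3D morphable models, 3DMMs) are
normally built by PCA over many registered scans. When only one scan — or
none beyond an artist template — is available, the covariance has to come
from somewhere else. `gpmorph` builds it analytically: the template is the
mean, and shape and albedo covariances are matrix-valued Gaussian-process
kernels over the template surface. The resulting model is PCA-compatible
(mean + orthonormal eigenbasis + eigenvalues) and drops into any pipeline
that consumes a linear morphable model.

## The model

A morphable model here is a pair of Gaussian processes over the template
vertices, one mapping to positions (mm) and one to RGB albedo:

- **Shape kernel.** A coarse-to-fine sum of squared-exponential kernels on
  physical distance, `Σ_std(a,b,c,A,B,C) = a·RBF_A + b·RBF_B + c·RBF_C`,
  multiplied by `I₃`: `K_s = I₃ Σ₀`. The bilaterally symmetric variant adds
  a mirrored term, `K_s^sym(x,y) = I₃ Σ₀(x,y) + α Φ_m Σ₀(x, Φ_m y)`, where
  `Φ_m` is the sagittal reflection: left–right deformation components of
  mirror pairs anticorrelate, the other two correlate.
- **Albedo kernels.** The same multiscale construction on physical distance
  (`K_a,xyz`), a second RBF kernel on the *template's colour distances*
  (`K_a,rgb` — vertices with similar albedo covary, a proxy for part
  structure), their average `K_a = 0.5 (K_a,xyz + K_a,rgb)`, and variants
  with an RGB channel-correlation multiplier `M_x` (ones on the diagonal,
  `x` off-diagonal) and bilateral symmetry.
- **Low-rank form.** Kernels are decomposed by the Nyström method into the
  leading eigenpairs of their Gram operator; samples are
  `mean + Σ cᵢ √λᵢ φᵢ` with standard-normal coefficients.

Fitting to images is analysis-by-synthesis: a spherical-harmonics
Lambertian rasterizer renders the model, foreground pixels get a Gaussian
likelihood, background pixels an empirical histogram model, and a
Metropolis–Hastings sampler with coarse-to-fine Gaussian drift updates
pose, illumination and coefficients, returning the maximum-posterior state.

## Worked example

```r
library(gpmorph)

# a symmetric vertex-colored test head (exactly mirror-symmetric)
t <- make_template(n_vertices = 200)
print(t$mesh)
#> vcmesh: 200 vertices, 396 triangles
#>   extent (mm): x [-70.0, 70.0]  y [-77.9, 77.9]  z [-80.0, 80.0]

# kernels at the package defaults
cfg <- kernel_config()
ks  <- make_shape_kernel(cfg, symmetric = TRUE, mirror = t$mirror)
ka  <- make_albedo_kernel(cfg, "full_sym", template = t$mesh, mirror = t$mirror)

eval_kernel(make_shape_kernel(cfg), t$mesh, 1, 1)[1, 1]   # a_s+b_s+c_s
#> [1] 15
eval_kernel(make_albedo_kernel(cfg, "full", template = t$mesh), t$mesh, 1, 1)[1, 1]
#> [1] 0.0275                                # 0.5*((0.02+0.01+0.01)+0.015)

# build a rank-20 model, draw a sample, project it back
mod <- build_model(t$mesh, ks, ka, rank_s = 20, rank_a = 20, seed = 1)
s   <- sample_mesh(mod, seed = 7)
pr  <- project_mesh(mod, s)
max(abs(pr$c_s - attr(s, "coefficients")$c_s))
#> [1] 3.552714e-15                          # sampling/projection duality

# register a model draw back onto the template topology
scan <- sample_mesh(mod, seed = 12)
fit  <- register_scan(mod, scan, registration_config(steps = 300, seed = 2))
fit$report$chamfer                          # mm
#> [1] 1.611486
```

The first kernel value is the shape variance per axis at a vertex (the sum
of the three RBF amplitudes); the albedo value is the combined kernel's
per-channel variance. The near-zero projection error shows the eigenbasis
is orthonormal and the model PCA-compatible; the final Chamfer distance of
1.6 mm (on a head roughly 140 mm across, against a rank-20 target) shows
the registration recovered the scan to about one percent of the object
scale.

A command-line front end covering the common operations is installed at
`system.file("exec", "gpmorph", package = "gpmorph")`:

```sh
gpmorph fixtures --n 200 --seed 1 -o fx/
gpmorph build --template fx/template.ply --rank 50 -o model.gpm
gpmorph sample model.gpm --seed 7 -o sample.ply
gpmorph chamfer sample.ply fx/template.ply
```

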