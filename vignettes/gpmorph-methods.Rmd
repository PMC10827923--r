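---
title: "Single-template morphable models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-template morphable models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the model, the numerical choices, and the reasoning
behind design decisions that were genuinely open. It states no empirical
result beyond what the package's test suite and `scripts/acceptance.R`
themselves compute.

## The generative model

A morphable model is a mean mesh plus two Gaussian processes over its
vertex set: one with values in position space (mm) and one in RGB albedo
space (unit cube). Both are specified by matrix-valued covariance kernels
`K(x, y) ∈ R^{3×3}` and reduced to a finite linear model through the
leading eigenpairs of the Gram operator on the mesh vertices, so that a
sample is `mean + Σᵢ cᵢ √λᵢ φᵢ` with `cᵢ ~ N(0, 1)`. Everything downstream
(projection, priors, PCA interoperability, the quality metrics) relies
only on this linear form, which is exactly the form of a PCA-built model.

### Kernel family and hyperparameters

All kernels are built from the squared-exponential
`RBF_σ(x, y) = exp(−‖x−y‖²/σ²)`. The exponent convention — `σ²` in the
denominator, no factor 2 — follows the Gaussian-process morphable-model
literature this construction extends; since the source conventions differ
silently, `kernel_config(rbf_convention = "half_sigma2")` switches to
`exp(−r²/(2σ²))` for sensitivity checks. With the default convention the
bandwidth is the distance at which correlation falls to `e⁻¹`.

The defaults (all exposed in `kernel_config()`):

| group | parameters | default | unit |
|---|---|---|---|
| shape amplitudes | `a_s, b_s, c_s` | 7, 5, 3 | – |
| shape bandwidths | `A_s, B_s, C_s` | 100, 50, 10 | mm |
| albedo (shape-space) amplitudes | `a_a, b_a, c_a` | 0.02, 0.01, 0.01 | – |
| albedo (shape-space) bandwidths | `A_a, B_a, C_a` | 500, 20, 2 | mm |
| albedo (colour-space) | `d`, `D` | 0.015, 0.15 | –, colour |
| symmetry strength | `alpha` | 0.7 | – |
| channel correlation | `beta`, `gamma` | 0.9375, 0.95 | – |

Amplitudes are variances per channel/axis at zero distance — the standard
shape kernel has `15·I₃` on its diagonal, the combined albedo kernel
`0.0275·I₃`. `beta` and `gamma` sit inside the channel-correlation matrix
`M_x` (ones on the diagonal, `x` off-diagonal), which is positive
semidefinite exactly for `x ∈ [−1/2, 1]` (eigenvalues `1+2x`, `1−x`,
`1−x`); the configuration validator enforces that range.

Two further choices the construction leaves open:

- **Colour metric.** The colour-space kernel measures distance between
  *template* albedos, fixed at kernel construction. Measuring between
  current sample albedos would make the kernel state-dependent and destroy
  the linear-Gaussian structure.
- **Mirrored terms.** The mirrored kernel term evaluates the scalar kernel
  at the reflected 3D position `Φ_m y` of the second argument — an
  arbitrary-point RBF evaluation, so no mirror-symmetric topology is
  required of the mesh. For shape the term carries the multiplier
  `α Φ_m` (left–right components anticorrelate); for albedo the
  multiplier is *not* mirrored (`α M_β` only), because colour deformations
  on opposite sides should match, not negate. The colour-metric kernel
  gets no mirrored term at all: on a bilaterally symmetric template its
  metric is already symmetric.

### Low-rank reduction

`nystrom_decompose()` draws `m` inducing vertices uniformly without
replacement (seeded), forms the inducing Gram `W` and cross-Gram `C`, and
eigendecomposes through `B = C W^{−1/2}`: the SVD of `B` gives exactly
orthonormal eigenfunctions over all vertices and eigenvalues `S²`. With
the full vertex set as inducing points this reproduces the dense
eigendecomposition to machine precision, which is the oracle the test
suite checks against (`exact_decompose()`). Components with eigenvalues
below `10⁻¹⁰` of the maximum are dropped. Default ranks are
`min(3N, 50)` on test-scale meshes; the dense Gram path refuses matrices
beyond 3000 rows and larger problems must go through Nyström.

PCA construction from mesh collections uses divisor `m − 1` (sample
variance); a two-mesh set `{mean+v, mean−v}` therefore has the single
eigenvalue `2‖v‖²`. Colour samples are clipped to `[0,1]` with a
per-vertex flag so linearity assertions can exclude clipped vertices.

## Synthetic study system

The test bed replaces licensed face data with a parametric, exactly
bilaterally symmetric "head": a UV-sphere tessellation (even longitude
count, so the mirror image of the vertex set is the vertex set) scaled to
ellipsoid radii 70 × 90 × 80 mm, with two mirrored dark eye patches and a
central mouth patch painted by angular distance. The generator returns the
mirror operator and the vertex involution alongside the mesh, so symmetry
can be asserted to `10⁻⁹` rather than assumed. Rendered datasets draw yaw
uniformly on (−90°, 90°), pitch on (−30°, 30°), roll on (−60°, 60°) —
the ranges the learning experiments assume — under ambient-dominant
order-2 spherical-harmonics illumination. Illumination is ambient-plus-
low-order rather than point lights because the renderer is SH-native; a
point light would be projected onto the same 9 SH bands anyway.

What these fixtures do *not* emulate: scanner noise, occlusion, hair,
expression, perspective extremes, or the albedo statistics of real skin.
Passing tests demonstrate internal correctness of kernels, decomposition,
inference and learning dynamics — not face-recognition accuracy on
photographs.

The fixture camera places the head at 450 mm with focal length 180 px for
a 64-px frame: the head width fills the frame with a slight top/bottom
crop, as in standard face crops. This geometry matters — with the head at
two-thirds the frame width, pose information weakens noticeably, and with
the silhouette clipped on all sides it degrades further — so it is fixed
as the study condition for the inference experiments.

## Inverse rendering

The renderer is a z-buffered software rasterizer with per-pixel normal
interpolation, Lambertian order-2 spherical-harmonics shading (9
coefficients per channel, camera frame), back-face culling and `[0,1]`
radiance clipping. The image likelihood treats silhouette pixels as
isotropic Gaussian residuals (`σ_fg`, default 0.05 colour units — kept
after an explicit sweep showed larger values trade pose precision for no
robustness gain) and background pixels as draws from a Laplace-smoothed
16³-bin colour histogram of the observed image. An optional foreground
outlier mixture (`fg_outlier`) bounds the penalty of any single bad
pixel with a uniform floor; it defaults to off because both outlier
variants measured — the empirical background density (contaminated by
the foreground it is estimated from) and a uniform floor — let
misaligned poses survive long enough for the coefficient blocks to
compensate, collapsing pose recovery on fixtures. The pure Gaussian
model does carry a small frontalization bias (silhouette shrinkage,
about a degree and a half of yaw on fixtures), but it is the lesser of
the two effects.

The sampler is block Metropolis–Hastings with Gaussian drift:

- **Blocks and weights.** pose 0.4, shape 0.3, albedo 0.15, illumination
  0.15. Pose error dominates early misfit, so pose moves get the largest
  share.
- **Proposals.** Single-parameter pose drift with a three-scale mixture
  (9°/3°/0.5° at weights 0.2/0.4/0.4); coefficient updates mix
  all-coordinate drift (sd 0.2 coarse / 0.05 fine) with single-coordinate
  jumps at 4× those scales; illumination drifts with sd 0.05 plus a
  periodic greedy closed-form re-estimation (accepted only if the
  posterior does not decrease).
- **Phases.** `n_1` lighting-only steps (default 1000) seeded by one
  closed-form estimate, then `n_2` full steps (default 10000). Before
  phase 1 a deterministic coarse yaw scan (±12° in 3° steps, model mean,
  9 renders) corrects the initializer's basin: starting in the wrong
  basin lets the coefficient blocks compensate a wrong pose, after which
  single-block moves cannot escape. After sampling, a deterministic
  coordinate-descent polish refines the pose of the returned
  maximum-posterior state.
- **Priors.** Standard normal on coefficients; beta(2, 2) mapped onto the
  admissible range of each angle (frontal-preferring); optional isotropic
  Gaussian landmark term (default 4 px).

Alternatives measured and rejected during development, recorded here
because the negative results are informative: annealing `σ_fg`, coupling
pose proposals with an illumination refresh, shear-compensated pose+
translation moves, Metropolized independence restarts around the
initializer, and delaying the albedo block all *reduced* pose recovery on
the same benchmark — each one either lets illumination/albedo explain away
pose error or wastes the step budget.

The grid initializer (`pose_grid_init`) is the deterministic stand-in for
a learned pose regressor: it scores the model mean over a pose grid and
returns the argmax, with ties broken to the lowest lexicographic index.

## Registration

`register_scan()` searches coefficients with the same Gaussian-drift
engine to maximize
`−w_ch·Chamfer − w_alb·albedo-discrepancy + w_prior·log-prior`. The
Chamfer distance is vertex-to-vertex (symmetrized mean nearest-vertex
distance): at a few hundred vertices per fixture, point-to-surface adds
cost without changing conclusions, and the surface-sampled variant can be
emulated by subdividing inputs. The albedo term is the symmetrized mean
closest-point RGB distance on the surface rather than a multi-view
rendered pixel error — it preserves the constraint's content without
introducing view-sampling choices. Post-processing removes net translation
(iterated closest-point centroid matching, which is the translation-only
least-squares solution) and re-extracts albedo by casting rays along
template normals into the scan (20 mm cutoff, nearest-vertex fallback,
flagged per vertex).

Registration weights default to `w_ch = 1 /mm`, `w_alb = 20`,
`w_prior = 0.02`: at those scales a 1 mm Chamfer error, a 0.05 RGB
discrepancy and one prior standard deviation are comparable.

## Wake–sleep learning

One iteration: (wake) per image — pose initialization (oracle scene or
grid search), MCMC fit under the current model, a silhouette
intersection-over-union gate against the initializer's render
(`r_1 = 0.625`, inclusive), shape-from-shading refinement, an albedo-drift
gate with threshold `r_2 − n·r_3` (8 − 0.5 per completed iteration);
(sleep) spike denoising against each pre-refinement fit, rigid alignment
to the reference template, PCA rebuild capped at `accepted − 1`
components. An iteration accepting fewer than two reconstructions carries
the model forward unchanged.

Two deliberately exposed ambiguities:

- **Drift units.** A mean RGB distance in the unit cube cannot exceed
  `√3`, so a threshold of 8 cannot be a raw colour distance. The gate
  therefore applies a configurable `drift_scale` (default 100, i.e.
  thresholds live on a 0–100 scale and the initial gate is an effective
  0.08 mean RGB distance), and announces the convention at first use
  rather than hiding it.
- **Silhouette pairing.** The gate compares the initializer's render with
  the final fitted render — the reading in which the two inference stages
  must agree on rough pose.

Shape-from-shading minimizes, by gradient descent with adaptive step
sizes, a vertex-aggregated image residual (observed pixels pooled onto
vertices through the barycentric weights of the entry rasterization, the
pixel-to-vertex assignment then frozen) plus squared distance from the
model subspaces and the negative log-prior of the projections. The frozen
assignment makes the objective a smooth function of vertex positions
(through the one-ring vertex-normal chain, backpropagated in compiled
code) and albedos, so the analytic gradient can be — and is — verified
against numerical differentiation in the tests. `w_sub = Inf` degenerates
to hard projection onto the model subspaces. Pose and illumination are
held fixed throughout, and the learning-loop test sizes are 150–300
vertices, 20–40 images, `n_2` 1500–2000 and `n_3` 100–200 — chosen as the
smallest sizes at which subspace recovery is unambiguous.

Ground-truth models for recovery experiments use shape modes
orthogonalized against the six rigid-motion fields of the template;
without that deflation the rigid alignment step of the sleep phase
removes exactly the component being measured, and the experiment measures
the alignment convention instead of learning.

## Model-quality metrics

Specificity, generalization and compactness follow the standard
statistical-shape-model definitions, with per-vertex corresponding-vertex
distances (all metric meshes share topology). Specificity draws at
different component counts share the first-`k` coefficient rows of one
seeded matrix — a variance-reduction contract that makes the curve
monotone in expectation rather than jittering between counts.

## Known limitations

- The rasterizer has no shadows, no specular term and a single pinhole;
  illumination lives in the camera frame.
- Vertex-to-vertex Chamfer under-resolves registration error below the
  edge length of the fixture meshes.
- KDE-model inference is exhaustive per component; cost grows linearly in
  the number of components by construction.
- The wake-sleep loop replaces the learned pose-regressor stage with
  oracle or grid initialization; nothing in the package learns a
  feed-forward recognizer.
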