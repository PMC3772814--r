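---
title: "Model-constrained motion recovery for quasi-static elastography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-constrained motion recovery for quasi-static elastography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elastofilt)
```

## The problem

Quasi-static ultrasound elastography images tissue strain under slow
probe compression. The axial displacement component (along the beam) is
measurable with sub-wavelength precision from RF phase shifts, but the
lateral component is an order of magnitude noisier because conventional
probes resolve poorly across the beam — and without a credible lateral
field, the lateral- and shear-strain images that clinicians increasingly
want are unusable. `elastofilt` recovers the full 2-D displacement field
by fusing sparse, noisy displacement measurements with a plane-strain
linear-elastic finite-element (FE) model through a game-theoretic
H-infinity filter, then differentiates the recovered field into all five
plane-strain strain images.

## The model chain

**Motion tracking.** RF frames before and after compression are
demodulated to analytic signals. For each overlapping depth segment of
each line, the phase of the zero-lag complex cross-correlation between
the pre-segment and the (re-windowed) post-segment measures the echo
time lag, hence the axial displacement `d = c*tau/2`. Phase alone is
ambiguous beyond a quarter wavelength, so each segment's lag is
predicted from its two already-processed neighbors (mean of the segment
above in the same line and the same-depth segment in the previous line);
the post window is shifted by the implied integer sample lag and only
the residual phase is trusted. The very first segment has no neighbor:
by default it is seeded with a coarse integer-lag correlation search,
which also resolves global shifts beyond the alias limit; the
`seed_lag = "zero"` option instead assumes zero displacement at the
probe face for every line's first segment, the right convention for pure
contact compression. The neighbor-mean prior and the seeding rule are
exposed as options because the displacement-continuity assumption behind
them is a modeling choice, not a theorem.

**Biomechanical constraint.** The tissue is modeled as an isotropic
plane-strain linear-elastic body meshed with constant-strain triangles
(consistent element mass, `rho*A/12` pattern; Rayleigh damping
`C = alpha*M + beta*K`). Known displacements — the supported bottom
edge, and measured values at sampled boundary nodes — are enforced by
diagonal penalties with confidence weights `kappa` (default `1e6`,
roughly `4e4` times the stiffness scale), which lets the forward model
run without ever measuring the contact force. Ground-truth phantom
solves use exact Dirichlet elimination instead, because a penalty leaves
a `O(1/kappa)` residual that would contaminate convergence and patch
tests.

**State-space form and filtering.** With `x = [U; U']`, the equation of
motion becomes `x' = A x + b`, discretized exactly through the
augmented-matrix exponential (unconditionally stable for the stiff
penalty-augmented system). The H-infinity filter iterates the
game-theoretic a-priori recursion

    Lambda = I - gamma^-2 S P + H' V^-1 H P
    K      = P Lambda^-1 H' V^-1
    x+     = F x + G + F K (y - H x)
    P+     = F P Lambda^-1 F' + Q

against the fixed measurement vector (quasi-static assimilation), and
the displacement half of the final state is the recovered field. As
`gamma` grows the recursion collapses exactly to the Kalman filter — the
package carries an independent textbook Kalman implementation purely as
a test oracle for that limit.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `gamma` | 1 | worst-case energy-gain bound (dimensionless) |
| `q` | 1e-5 | process-noise weight (model trust; dimensionless weight on mm-scale states) |
| `v_axial` / `v_lateral` | 1e-4 / 1 | measurement-noise weights |
| `s_velocity` | 0 | estimation-error weight on velocity states |
| `p0` | 1e-3 | initial-uncertainty diagonal |
| `n_iter` | 100 | filter iterations |
| `dt` | 0.01 s | pseudo-time step |
| `kappa` | 1e6 | boundary-penalty confidence |
| `alpha_R`, `beta_R` | 0.05 | Rayleigh damping weights |

Three of these deserve their reasoning spelled out, because naive
choices fail in instructive ways.

* **`s_velocity = 0`.** The state stacks displacements (~0.1 mm) over
  velocities that are two orders of magnitude larger. Weighting both
  equally in the H-infinity cost makes the worst-case game about
  velocity error, and at `gamma = 1` the Riccati recursion then
  diverges. The estimation-error weight is meant to follow the state
  scaling; since only displacement accuracy matters for strain imaging,
  the velocity half carries zero weight (S stays symmetric PSD).
* **`p0 = 1e-3`.** For the a-priori filter the attenuation level caps
  the uncertainty the S-weighted subspace may carry: feasibility
  requires `P < gamma^2` there. A "large" `P0` with `gamma = 1`
  violates this at the first step and the filter is unstable — observed
  empirically exactly as the theory predicts.
* **`dt = 0.01 s`.** The Rayleigh-damped model relaxes at about
  `1/beta = 20 /s`, so 100 iterations must span several relaxation
  times; at `dt = 1 ms` the estimate is still far from equilibrium when
  the iterations stop.

The measurement weights were then fixed by a pilot gain-balance
calibration on the phantom: `v_axial` small enough that the trustworthy
axial data bend the uniform model toward the inclusion (this is what
makes the inclusion visible in the strain images), `v_lateral` large
enough that the 10 dB lateral channel cannot drag the lateral estimate
away from the model. The filter treats these as designer weights, not
noise statistics — that is the point of the H-infinity formulation.

A note on feasibility checking: the adopted game-theoretic algorithm
deliberately runs without per-step definiteness checks. When
`check_feasibility = TRUE`, the package verifies the a-priori-filter
existence condition `P > 0` and `P^-1 - gamma^-2 S > 0`. The weaker
condition with the measurement term added (`+ H' V^-1 H`) is necessary
but demonstrably not sufficient: a direct worst-case operator-norm
computation on small seeded systems shows recursions satisfying it can
exceed the energy bound by orders of magnitude, while the stricter
condition gives 200/200 bound satisfaction at `gamma = 1.2x` the
bisected infimum.

## The synthetic phantom

The generator reproduces the standard numerical experiment: a 40 x 40 mm
soft block (25 kPa) with a stiff 5 mm-radius circular inclusion
(80 kPa), compressed 2 % axially with the bottom edge on rollers (axially
fixed, laterally free, one central lateral pin) — this boundary choice
makes the homogeneous phantom match the closed-form uniaxial plane-strain
solution exactly, which anchors several tests. Measurement noise is
drawn per component from one of five families (Gaussian, uniform,
Poisson, Rayleigh, exponential), centered by subtracting the
distribution mean, and scaled so the realized SNR is exact; the study
designs use 30/10 dB (axial/lateral) for the sweep experiment and
axial-only 20/15 dB for the noise-robustness table. The default mesh
spacing is 1 mm (41 x 41 nodes) with a 21 x 21 measurement lattice —
measurements deliberately sparser than the mesh, as in the original
experimental design.

What the generator does *not* emulate: speckle decorrelation between
frames, depth-dependent attenuation, beamforming artifacts, 3-D motion,
and nonlinear or viscoelastic tissue behavior. Passing the synthetic
studies therefore demonstrates correctness of the estimation machinery
under the stated elastic model, not clinical performance.

## The incompressibility baseline

The classical alternative recovers lateral displacement from axial
strain alone by assuming incompressibility (`eps_xx = -eps_yy` in plane
strain) and integrating laterally, followed by first-difference
regularized least squares (`smoothing_weight = 0.1`). Its two failure
modes — bias growing as the true Poisson's ratio falls below 0.5, and
amplified differentiation noise — are exactly what the model-constrained
filter avoids. In the sweep comparison the baseline integrates from the
domain centerline (`origin = "center"`), where the phantom's true
lateral displacement vanishes by symmetry; integrating from the left
edge (the literal default) would charge the baseline a constant-offset
error it does not deserve.

## Problem sizes and numerical choices

The studies in the test suite and the acceptance script run a
scaled-down phantom: an 11 x 11 node mesh (4 mm spacing) with the full
node lattice measured, 100 filter iterations, 16 noise realisations per
sweep point and 100 per noise-type cell (all realisations of a
configuration share one Riccati recursion, since the gain sequence does
not depend on measured values — repeats cost only matrix-vector work).
These sizes were chosen so every study completes in minutes on one CPU;
the full-size default configuration runs the same code unchanged.
At coarse grids the baseline's differentiation noise shrinks (fewer,
wider strain cells), so the margin over the baseline at `nu = 0.49` is
structurally thinner at test scale than at the full 21-point grid — the
sweep therefore averages EDR over noise realisations to report a stable
mean.

Other numerical choices: `P` is re-symmetrized every step
(floating-point drift control); the discretization uses the exact
augmented-matrix exponential rather than an Euler step; degenerate
(zero-area) triangles abort assembly with the offending element named;
the strain convention fixes axial strain `= d(u_ax)/d(axial)`, lateral
strain `= d(u_lat)/d(lateral)`, axial-shear `= d(u_ax)/d(lateral)`,
lateral-shear `= d(u_lat)/d(axial)` and shear as their half-sum — the
one naming that keeps the five images distinct and the shear identity
exact. Internally, lengths are mm and moduli kPa; a stiffness entry in
kPa*mm then equals N/m per metre of out-of-plane thickness, so density
enters as `rho * 1e-6` kg per mm^2 per metre — with tissue-like values
this puts structural frequencies at O(100 rad/s), well scaled for
`dt = 0.01 s`.

## A short tour

```{r tour, eval = FALSE}
cfg <- phantom_config(mesh_density = 4, measurement_grid = c(11, 11))
sim <- simulate_phantom(cfg, seed = 1)        # truth + 30/10 dB noise
fit <- filter_phantom(sim)                    # H-infinity recovery
strain <- strain_from_displacement(fit$fields[[1]])
plot(strain, "eps_axial")                     # inclusion visible
edr(fit$fields[[1]], sim$truth)               # lateral error ratio
tiam_phantom(sim)$edr                         # baseline for comparison
```

## Known limitations

The recovered lateral field can never be better than the biomechanical
model where no lateral data exist: with a spatially uniform modulus the
lateral error floor is the inclusion-blindness of that model (EDR about
0.06 at test scale), which honest tuning cannot remove — only richer
models (heterogeneous or jointly estimated moduli, explicitly out of
scope here) could. The filter weights are global constants; per-point
confidence from correlation quality is plumbed through `kappa` but not
exploited adaptively. Modulus reconstruction, nonlinear constitutive
models and streaming (time-varying) measurement sequences are out of
scope.
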