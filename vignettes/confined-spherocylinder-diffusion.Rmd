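---
title: "Effective diffusion of spherocylinders in a narrowing conical channel"
author: "conediff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective diffusion of spherocylinders in a narrowing conical channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`conediff` simulates a single rigid spherocylinder — a cylinder of length
`l` capped by two hemispheres of radius `r`, total mass 1, uniform density —
performing overdamped Brownian motion inside an axisymmetric conical pore.
The wall radius falls linearly, `R(z) = R0 + z (RL − R0)/L`, from the
reflecting wide end at `z = 0` to the absorbing narrow end at `z = L`;
`R0 = RL` recovers a cylindrical pore. Time is discrete and counted in
steps; each step is

1. **Translation attempt.** `Δx = σx ξ` with `ξ` a standard Gaussian
   3-vector. The move is rejected (position unchanged) if the displaced body
   would intersect the wall or the center of mass would leave through the
   entrance (`z < 0`).
2. **Rotation attempt.** A rotation axis `Â` is drawn uniformly over
   directions, the moment of inertia about it is
   `M(Â) = Mxx (1 − cos²ψ) + Mzz cos²ψ` with `cosψ = Â·û`, the angle is
   Gaussian with standard deviation `σφ = σx M(Â)^{-1/2}` (energy
   equipartition between translational and rotational degrees of freedom),
   and the rotated body is again accepted only if collision-free.

Time advances by exactly one unit whether or not either attempt is accepted;
rejected attempts are the microscopic origin of the slow effective dynamics.
After both sub-moves, absorption is checked: the first step at which the
center of mass satisfies `z ≥ L` is the first passage time (FPT).

Assumptions worth stating explicitly: translational and rotational noise are
decoupled (no hydrodynamic mobility tensor), noise is isotropic, a single
particle occupies the channel, and the wall interaction is a hard-core
rejection rather than a force.

### Collision geometry

The body occupies the Minkowski sum of its axis segment and a ball of radius
`r`, so it avoids the wall iff the perpendicular distance from the axis
segment to the cone surface is at least `r` everywhere. Along the segment
that clearance is a concave function (linear wall radius minus a convex
radial distance), so checking the two *endpoints* is exact — this endpoint
reduction makes each step O(1). The clearance itself is
`(R(z) − ρ)/sqrt(1 + s²)`, `s = (RL − R0)/L`; the `sqrt(1 + s²)` factor is
the difference between the horizontal gap and the true 3D distance (0.014%
at the default geometry, but kept exact so steep cones remain correct). A
brute-force surface-sampling oracle (`collision_oracle()`) cross-checks the
predicate in the test suite.

The wall is extrapolated linearly beyond `z ∈ [0, L]`: the channel ends are
defined for the *center of mass* only (rejected entrance crossings, absorbing
exit), and a long body straddling either plane still sees a consistent
lateral wall. This is one consistent reading of a protocol that never
describes end-cap walls; without it, long rods would be artificially trapped
near both ends.

### Inertia model

With uniform density, the cylinder and hemisphere masses obey
`m1/m2 = 3l/(2r)` and `m1 + 2m2 = 1`, so `m1 = 3l/(3l+4r)`,
`m2 = 2r/(3l+4r)`. The principal moments are

```
Mxx = Myy = m1 (l²/12 + r²/4) + 2 m2 (2r²/5 + l²/4 + 3lr/8)
Mzz       = (m1/2 + 4 m2/5) r²
```

(the `3lr/8` cross term is the parallel-axis shift of a hemisphere whose
center of mass sits `3r/8` above its flat face). Monte-Carlo integration of
`∫ρ² dm` over the solid confirms both expressions in the tests. `σφ` is not
capped: a tiny sphere has `σφ` of several radians, i.e. its orientation
randomizes every step, which is harmless because a sphere's rotation never
changes the occupied region.

## Defaults and parameters

| parameter | default | meaning |
|---|---|---|
| `L` | 15 | channel length (the wide-end *diameter* is the length unit) |
| `R0`, `RL` | 0.5, 0.25 | wall radii at the wide / narrow end |
| `sigma_x` | 0.05 | translational noise per step |
| `n_rep` | 1000 | trajectories per ensemble |
| `max_steps` | 5e7 | censoring cap; escape rates ~5e-7/step make FPTs of order 1e6–1e7 for the largest particles |
| `sample_times` | log-spaced, ≤200/decade | state-recording grid |
| `occ_per_traj` | 2000 | linear-stride occupation samples per trajectory |

The particle must satisfy `r < RL` (exit feasibility). Insertion places the
center of mass on-axis at `z = 0` with a uniformly distributed feasible
orientation (rejection sampling); on-axis is symmetric and feasible for
every particle size, and uniform-feasible is the maximum-entropy choice for
a protocol that does not specify one. Long rods can only start near-axial,
which is also the orientation they adopt dynamically.

Reproducibility: the compiled kernel uses xoshiro256++ seeded through
splitmix64 from `(seed, substream)`; trajectory `i` owns substream
`stream_offset + i`, so ensembles are bit-identical for a given
configuration regardless of execution order, and parameter scans place each
grid cell on a disjoint substream block.

## Analysis toolchain

**MSD and the anomalous exponent.** The survivor-averaged MSD at recorded
time `t` averages `|x(t) − x(0)|²` over trajectories not yet absorbed;
absorbed tracers leave the average permanently. The exponent is obtained by
least squares of `D t^α` *in linear space* over `[0.01·tmin, tmin]`, where
`tmin` is the earliest FPT in the ensemble — only data collected before any
tracer crossed the whole channel enter the fit. Because states are recorded
on a log-spaced grid, each point is weighted by the time interval it
represents, which makes the fit equivalent (in the Riemann-sum sense) to
fitting every integer step in the window — the natural reading of fitting a
fully stored curve — and invariant to the recording grid density. The
log–log regression used for initialization is reported alongside.

Two caveats the fits make visible. First, `tmin` is an extreme order
statistic: it shrinks as `n_rep` grows and fluctuates strongly between
seeds, and since the measured curves are not pure power laws (early
entrance-layer transient, transverse saturation at `⟨ρ²⟩ ≈ R²/2`, incipient
axial saturation just below `tmin`), the fitted `α` inherits that
window-placement noise at small ensemble sizes. Second, even in the
cylindrical control these same confinement transients depress the fitted
`α` below 1 by several hundredths, so "normal diffusion" appears as
`α` slightly below — not exactly at — unity.

**First passage and survival.** `fpt_median()` reports the sample median of
uncensored FPTs and refuses to answer when more than 10% of trajectories are
censored. `survival_curve()` gives `S(t)`, the fraction still inside at `t`
(censored trajectories count as surviving up to the cap), and
`fit_exponential()` fits `ln S` linearly over the band `S ∈ [0.01, 0.9]`,
excluding the early non-exponential transient and the noisy tail; the band
is configurable and recorded in the fit object.

**Occupation statistics.** Position (`f(z)`) and orientation (`p(θ)`,
`θ = arccos|u_z| ∈ [0, π/2]` since the axis is a director) histograms pool a
dedicated *linear-stride* sampling channel rather than the log-spaced state
records, so they are genuinely time-weighted occupation fractions. The
orientation histogram also reports the density divided by `sin θ`, the
isotropic measure, because a raw `p(θ)` of isotropic directors is
proportional to `sin θ` — without that normalization "uniform orientations"
and "flat histogram" are different claims. The entropic force is the
log-density gradient `F_S(z) ∝ d ln f/dz` by central differences at bin
centers (one-sided at the edges, exact for log-linear profiles);
proportionality constant 1.

## What the simulator shows

At the default geometry the conical channel produces effective subdiffusion
(`α < 1`) for every particle size examined, in contrast to the cylindrical
control, where the exponent stays near 1; medians of the FPT grow and
survival rates `λ` fall as the radius grows at fixed length; `f(z)`
decreases toward the narrow end, i.e. the entropic force pushes the tracer
back toward the wide entrance. These statements are exactly what the test
suite and `scripts/acceptance.R` recompute; the package makes no empirical
claim beyond what those runs print.

Problem sizes used by the checks (chosen to keep a full run on one CPU in
minutes): ensembles of 200 trajectories per particle size for the
subdiffusion checks with a 5e6-step cap; the length scan at radius 0.1 uses
200 trajectories per cell with a 2e6-step cap (the MSD window needs data
only up to `tmin`, far below the cap); the cylindrical control uses 1000
trajectories; the long-rod survival fit uses 100 trajectories to absorption
under a 2e7-step cap.

## Limitations

- No hydrodynamics: the drag is shape-independent and wall-independent; real
  rods in real pores couple translation and rotation to the fluid.
- The rejection wall is not a reflecting boundary in the continuum sense; it
  adds a thin boundary layer of slowed dynamics (visible as a few-percent
  reduction of the effective axial diffusivity in wide channels, and as an
  early-time transient near the entrance).
- Single-particle physics only; no crowding, binding, or external drift.
- The anomalous exponent is an *effective*, window-dependent quantifier, not
  evidence of a scale-free mechanism; its estimator is noisy at small
  `n_rep` through `tmin` (see above), so length-profiles of `α` need large
  ensembles before fine features (such as the location of a shallow
  minimum) stabilize.

```{r example, eval = FALSE}
library(conediff)
cfg <- sim_config(particle = spherocylinder(l = 1, r = 0.1),
                  n_rep = 100, seed = 42, max_steps = 5e6)
res <- run_ensemble(cfg)
analyze_ensemble(res)
```
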