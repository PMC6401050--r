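---
title: "Methods: desk-scale blast lung injury simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale blast lung injury simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastrat)
```

This vignette is the package's account of the science behind each stage of
the simulation chain: the models, their assumptions, the parameters that
matter, and the design choices made where the problem was genuinely open.

## 1. Blast source

A charge is described by its TNT-equivalent mass `W` (default 0.010 kg) and
the radius of the spherical initial wave (0.10 m) on which the computed
source pressure is imposed. The peak side-on overpressure at scaled distance
`R = r / W^(1/3)` follows the empirical three-term law

$$P(R) = \frac{0.084}{R} + \frac{0.27}{R^2} + \frac{0.7}{R^3}.$$

**Unit convention.** We evaluate the formula in MPa and convert to kPa at
the API boundary. The law is sometimes quoted with `P` "in kPa", but at the
initial-wave surface of a 10 g charge (`R = 0.464`) the raw value is 8.43 —
credible only as MPa, where it matches the conventional source figure of
8442 kPa to 0.1%. That residual is rounding in the published figure;
comparisons in this package use a 1% relative tolerance for this quantity.

**Waveform.** The source history is triangular: zero at ignition, peak at
`ramp_peak_time = 0.75` s, zero at `end_time = 1.5` s. Only the rise is
prescribed as linear by the source description; the decline shape is
unspecified, and we take it linear for symmetry and testability (the
triangle integrates to `peak * end_time / 2`, which the tests verify by
quadrature). Only peak values matter downstream; no negative phase is
modelled.

## 2. Synthetic body geometry

The CT-derived anatomy of the original modelling chain is not distributable,
so the package generates a parametric stand-in whose fidelity is
deliberately only qualitative: the downstream validation statistics operate
on the packaged monitor-table fixtures, not on this mesh. The body is an
ellipsoid of 20.11 cm (length, y) x 10.32 cm (width, x) x 10.04 cm (height,
z), resting on the ground plane z = 0 with the head at +y and the
charge-facing left flank at -x. Nested regions, all fixed fractions of the
outer semi-axes (see `rat_anatomy()` in the source):

| layer | definition | thickness at default dims |
|---|---|---|
| skin+muscle | elliptic radial coordinate rho in (0.78, 1] | ~11 mm |
| rib shell | rho in (0.56, 0.78], thoracic band, perforated along y (period 25 mm) | ~11 mm |
| lungs | ellipsoid scaled 0.9 x 0.56 of the body section, split at a 3 mm mediastinal half-gap | ~23 mm wide each |
| heart | ellipsoid semi-axes (14, 16, 15) mm between the lungs | 28 mm |

Cubes of a structured grid whose centres fall inside the outer ellipsoid are
split into six Kuhn tetrahedra (conforming across cubes); element labels are
assigned by centroid containment with heart taking precedence over lung
where the regions overlap, so labels partition the mesh by construction.
The default resolution of 10 mm yields roughly 6,200 elements and 1,500
nodes — three orders of magnitude below a CT-scale mesh, by design. A
resolution too coarse to resolve a layer, or coarser than a quarter of the
smallest body dimension, is rejected with the offending layer named.

**Monitor points.** Six named points per lung (apex pulmonis, middle
lateral, lower lateral, lower interior, lower anterior, interior) are placed
at fixed fractions of the lung bounding box and snapped to the nearest
lung-surface face centroid (ties broken by exclusion of already-used faces,
in fixed name order, so placement is deterministic). The fractions are an
explicit convention of this package — only the names and the qualitative
anatomy are prescribed upstream. The *interior* point sits on the lower half
of the medial face (height fraction 0.30): in the published monitor table
the interior point carries the largest pressures of the six, and the
described injury pattern loads the interior/underside surfaces hardest, so a
mid-height medial placement (which reads the mediastinally shielded band)
would misrepresent the point.

## 3. Simplified propagation

The original chain solves transient compressible CFD; this package replaces
it with a deterministic analytic loading model, because the quantity used
downstream is only the peak pressure per surface node:

1. **Incident wave:** each exterior node receives
   `peak_overpressure(scaled_distance(d, W))` at its own range `d` from the
   charge (one shared code path with the source law).
2. **Facing amplification:** charge-facing nodes are amplified by the
   *acoustic limit* of the reflection coefficient, `1 + cos(theta)`, where
   `theta` is the local incidence angle; shadowed nodes get side-on incident
   pressure only. The full Rankine–Hugoniot normal-reflection factor
   `2(7 P0 + 4 Ps) / (7 P0 + Ps)` is implemented and exported
   (`reflection_coefficient()`, running from 2 in the acoustic limit to 8 in
   the strong-shock limit for gamma = 1.4), but it describes an ideal sharp
   shock striking a rigid wall. The source here ramps over 750 ms — a
   quasi-static loading on the centimetre scale of a rat — so pressure
   doubling, not shock reflection, is the appropriate facing factor. This
   choice also tracks the reference CFD surface maxima: with it the
   predicted peak body-surface pressures at 40–80 cm standoff fall within
   the ±35% agreement band asserted in the tests, while the
   Rankine–Hugoniot factor (3.9 at the 40 cm flank) would overshoot the
   reference values roughly twofold.
3. **Ground reflection:** a mirror charge below the ground plane adds
   `P_image * (z + H) / d_image` — the incident image-wave pressure weighted
   by the grazing cosine of the bounce, since a near-grazing ground
   reflection transmits only the small normal component of the wave onto the
   flank. The term is non-negative, so removing the ground can only lower
   pressures (a tested invariant).

The 1e-4 relative convergence criterion of the CFD stage is retained as the
default tolerance for any iterative sub-solver in this module (the shipped
model is closed-form and does not iterate). Diffraction, wrap-around timing,
drag loading and negative-phase loading are out of scope.

## 4. Structural response

Linear elastic, small strain, constant-strain linear tetrahedra. Materials
(literature constants): lung E = 1.2e4 Pa, nu = 0.32; rib E = 6.6 GPa,
nu = 0.3; skin/muscle/heart lumped at E = 480 MPa, nu = 0.45. Densities are
needed only by the lumped mass matrix of the transient mode and are nominal
(1000 kg/m^3 soft tissue, 1500 kg/m^3 bone) — no densities are prescribed
upstream.

- **Constraints.** No boundary conditions are prescribed upstream either; we
  fix all dofs of the nodes in the lowest 5% of the z-range (the
  ground-contact strip). This is a documented constant of the package.
- **Loading.** Nodal peak pressures become consistent nodal tractions along
  the inward face normals (face pressure = mean of its three nodal values).
- **Solver.** Direct sparse Cholesky on the constrained system; the static
  relative residual must be below 1e-8 (much tighter than the propagation
  stage's 1e-4, appropriate for a direct linear solve). The solution
  machinery is verified by a patch test (uniform uniaxial stress exact to
  1e-6 at any mesh), the `sigma l / E` bar oracle, rigid-body mode counts,
  and work–energy consistency.
- **Von Mises stress** is constant per element; monitor points read the
  nearest lung-surface element by centroid distance and fail loudly if that
  distance exceeds two element sizes.
- **Transient mode.** Average-acceleration Newmark (beta = 1/4,
  gamma = 1/2), lumped mass, optional mass-proportional damping; verified
  against the closed-form 1-dof step response and against the static
  solution under heavy damping. The primary analysis mode is linear static,
  matching the structural stage it emulates; damping defaults to zero
  because none is specified upstream.

Whether the lung should be loaded by the transmitted or the raw surface
pressure is not specified upstream; here the exterior of the full layered
body is loaded and transmission through skin, rib and mediastinum is
emergent. Consequently the absolute lung stress magnitudes are not
comparable to the reference monitor table — the tests assert the *patterns*
(apex lowest, interior/lower points higher, monotone decay with standoff),
and the validation statistics run on the packaged fixtures.

## 5. Validation statistics

The unit of correlation is the monitor point (n = 6), pairing each
standoff/side's six simulated lung pressures with the six averaged Smith
scores (edema + hemorrhage + inflammation, each 0–4, totals 0–12, fractional
after averaging over pathologists). `pearson()` refuses constant input
rather than returning 0 — an undefined correlation must not silently enter a
report. Its p-value uses the exact small-sample t transform
`t = r sqrt((n-2)/(1-r^2))` on n-2 df, two-tailed; `paired_t()` is the
classical paired t-test (df = 5), two-tailed. Two-tailed tests reproduce the
published significances (0.015, 0.111, 0.809, ...), which is how the
sidedness was fixed. Reports keep full precision and round to 3 decimals
only for display. Correlations at or above 0.8 are flagged strong,
mirroring the "less than 0.80 = weak" reading of the reference table.

The fixture transcriptions resolve the concatenated digit runs of the
source tables by choosing the parse that reproduces the printed
correlations; every block in the CSV carries its verification statistic as
a comment. Two notes: the (60 cm, R) correlation is 0.947 (the running-text
0.941 is treated as a typo), and the (70 cm, R) Pearson significance
recomputes as 0.065 from r = 0.783, n = 6 (the printed 0.605 appears to be
a transposition). All ten correlations, including (50 cm, R) = 0.908, are
reproduced to three decimals by the shipped parses.

## 6. Synthetic score generator

The generator emulates the validation study's design — 5 injured groups of
6 rats at 40–80 cm plus 6 untreated rats, each section scored by 3
pathologists and averaged — with the simplest identifiable link consistent
with the assumed monotone pressure–injury association:

- latent score = `clip(intercept + slope * pressure, 0, 12)`;
- observed score = mean of `n_scorers * n_rats_per_group` = 18 draws of
  latent + N(0, `scorer_noise_sd`), each draw clipped to [0, 12];
- untreated scores use latent 0 and an offset seed.

Defaults, chosen once: intercept 0; slope 0.004 score/Pa, which maps the
largest fixture pressure (2916 Pa) to 11.7 — inside the Smith range, so with
zero noise the link is exactly linear and the pipeline identity check
(`r = 1` for every group) is exact; noise SD 1.0, about one Smith point of
inter-pathologist disagreement. What the generator does *not* emulate:
gravity-driven fluid redistribution, time-since-injury effects, inter-rat
variance components distinct from scorer noise, and integer-valued raw
scores. Passing recovery tests therefore show that the *analysis* recovers a
planted monotone association under exchangeable Gaussian noise — not that
real pathology behaves this way.

## 7. Problem sizes and runtimes

All shipped checks run at desk scale by choice: the default 10 mm mesh
(~6,200 elements) for the geometry, propagation and pipeline tests; 6–8
cell bars and 2^3-cell boxes for the solver oracles; 500 replicates per
noise level for the recovery experiment (3 levels); 200 replicates for the
paired-t power check. The full suite completes in well under a minute.

## 8. Known limitations

- The propagation model has no diffraction, no time histories, and a single
  empirical range law far outside the fitted range of most such laws at
  `R < 1`; it is a loading generator for the structural stage, not a CFD
  replacement.
- The geometry is topologically faithful (layered, watertight, labelled)
  but anatomically schematic; lobe structure, airways and limbs are absent.
- Linear elasticity cannot represent alveolar rupture, viscoelasticity or
  large deformation; von Mises stress is an injury *surrogate*.
- The Smith-score fixtures inherit the transcription ambiguities of their
  source; each parse is annotated with the statistic that verifies it.
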