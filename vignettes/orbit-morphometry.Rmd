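---
title: "Automated orbital morphometry: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated orbital morphometry: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(orbitometry)
```

This vignette is the package's own account of its methods: what is modeled,
which knobs matter, what the synthetic data can and cannot show, and where
the genuinely open design choices were decided.

## The measurement model

The bony orbit is treated as a cavity bounded by bone everywhere except a
planar anterior opening (the rim) and, possibly, small posterior gaps
(fissures, canals). Measurement proceeds in five stages.

**Bone detection.** CT attenuation separates air (~ -1000 HU), soft tissue
(~ 0-100 HU) and cortical bone (>> 300 HU). The bone cut is chosen by Otsu's
criterion — the integer-HU histogram split maximizing between-class
variance — restricted to voxels above `air_hu_cutoff` (default -200 HU) so
that the air mode cannot dominate the optimization. The cut is placed
halfway between the neighboring occupied histogram values, which makes it
deterministic and leaves noise-free phantoms with a bone mask identical to
the generator's labels. A constant sub-histogram has no cut and raises an
error.

**Gap bridging.** Orbital walls are thin enough to vanish from CT slices,
so the raw bone mask leaks. We close it morphologically with a ball of
physical radius `gap_bridge_radius_mm` (default 1.5 mm: seals one-to-two
voxel dropouts at typical ~0.5-0.7 mm voxels without sealing real
apertures, which are centimetres wide). Dilation and erosion are computed
from an exact anisotropic Euclidean distance transform, so the result is
identical to explicit ball morphology but linear-time.

**Cavity growth.** From a small seed ball (radius `seed_ball_radius_mm`,
2 mm) the cavity front advances one 6-connected voxel layer per iteration,
blocked by the bridged bone mask and by air (the open air outside the rim
stops the front, so the cavity ends at the anatomical opening). Two leak
guards run:

* the spike rule of the configuration (`leak_guard_factor`, default 5):
  an iteration adding more than that multiple of the median of all previous
  increments aborts;
* a plausibility ceiling `max_volume_ml` (default 60 mL). Adult orbital
  volumes stay below about 40 mL, so only a front that has escaped the
  orbit can reach the ceiling. This second rule exists because a breakout
  through a wall defect grows *gradually* — normal front growth itself
  reaches about four times its running median (the increments of an
  expanding ball are quadratic in the iteration number), so no spike
  threshold can separate the two regimes; we verified this on constructed
  fracture phantoms before adding the ceiling.

**Reclaim.** Closing a thin wall around an acute apex necessarily swallows
cavity tissue where the cavity is narrower than the structuring ball; on a
40 mm cone phantom this shortens the measured depth by ~2.5 mm. After the
primary growth, coherent pockets of bridged-but-not-bone tissue voxels
(6-connected components of at least `reclaim_min_voxels` = 8 voxels — a
2 x 2 x 2 block — touching the cavity) are therefore returned to the
cavity. Isolated wall-dropout voxels do not qualify, which keeps the
posterior landmark (below) robust to the perforated wall. Everything
beyond the bridged shell remains unreachable, so bridging still seals gaps.

**Closures and mesh.** Boundary faces whose outside is not bone form the
apertures; each 26-connected aperture patch receives a planar cap (its
faces projected onto the least-squares plane of their centers). The
largest cap is the anterior closure, all others posterior; a posterior cap
larger than `posterior_cap_area_max_mm2` (300 mm^2) only warns, because
whether a tool should cap or include canal volume is genuinely unspecified
— the cutoff is exposed for exactly that reason. Cavity voxels are split
into six tetrahedra about the main diagonal, so the mesh volume
`sum(|det|)/6` equals the voxel volume *exactly* and the boundary is
watertight by construction (asserted in tests via edge counts and the
Euler characteristic).

## The three measurements and the profile

* **Volume** (mL): tetrahedron volume sum; cross-checked in the tests
  against a divergence-theorem surface integral over the labeled boundary
  (agreement to 1e-9).
* **Surface area** (mm^2): raw voxel boundaries overestimate curved areas
  by ~50% (staircase effect), so area is measured on the 0.5 iso-surface of
  the Gaussian-smoothed binary mask, extracted by marching tetrahedra. The
  smoothing sigma defaults to one voxel (the largest spacing component):
  enough to remove the staircase, small enough that curvature shrinkage is
  negligible at orbital scales (hemisphere area error ~ -1%, cone ~ -3% at
  0.5 mm voxels). Closure caps are included by default; whether published
  orbital areas include them is unstated, so `include_closures` is exposed
  (it moves the V/A ratio by a few percent).
* **Axial depth** (mm): distance from the area-weighted centroid of the
  anterior cap to the farthest mesh vertex, ties broken lexicographically
  (deterministic). On a hemisphere every surface point is equidistant from
  the rim center, so the posterior landmark is degenerate there by
  geometry, not by implementation; depth is still recovered to within a
  voxel diagonal.
* **Profile**: each tetrahedron centroid projects onto the depth axis;
  volumes accumulate into 10 equal bins (half-open, last closed), bin 1 at
  the rim, bin 10 at the apex. Volume projecting anterior to the cap
  mid-point is excluded and reported separately; profile + exclusion always
  equals the mesh volume (to 1e-9 mL).

All morphometry is invariant under origin translation and mirroring
(tested), so left and right orbits are measured identically.

## The phantom generator

Phantoms are the study conditions, not a tuning dial. A cavity of known
shape — hemisphere (V = 2/3 pi r^3), cone (V = 1/3 pi a^2 h) or paraboloid
(V = 1/2 pi a^2 h, the default for cohorts: blunt apex, rim-heavy volume
distribution like a real orbit) — is filled with soft tissue (+40 HU),
wrapped in a bone shell (+700 HU, thickness 1.5 mm) and opened anteriorly
into air (-1000 HU). `wall_gap_fraction` (default 0.05) of shell voxels are
replaced by soft tissue under a fixed seed, emulating the discontinuous
thin bone of real walls; 5% scattered dropout is well below any percolation
threshold, so the shell stays effectively sealed after bridging while still
exercising it. Two defects reproduce documented failure modes:

* `lacrimal_channel`: a 1.5 mm tunnel through the wall into an external
  0.6 mL soft-tissue pocket. Segmentation swallows it, overestimating
  volume by the recorded extra volume (tested to +-10%) — large enough to
  trip the 0.2 mL asymmetry screen against an intact contralateral side.
* `wall_fracture`: a ~100 mm^2 wall patch is removed and the retro-aperture
  exterior embedded in soft tissue; unguarded growth escapes, and the
  volume ceiling reports a leak.

What the phantoms deliberately omit: scanner noise, beam hardening, partial
volume blur, real orbital anatomy (fissures, optic canal). Passing tests
therefore demonstrate the correctness and determinism of the geometry
pipeline under idealized attenuation, not clinical accuracy on real CT.

## The cohort simulator

Per-subject depth is drawn from gender-specific normals; volume follows
`V = alpha_gender + beta * L + eps` with a *shared* slope (depth is the
only structural predictor of volume; the gender intercept gap of ~1.2 mL is
far inside its extrapolated standard error, which is what makes Gender
non-significant in the interaction model); area follows volume the same
way. Per-gender noise SDs are solved so the squared correlations hit their
targets in expectation; the shared slopes are the means of the two
per-gender ideals, a compromise that reproduces the target means exactly
and the SDs to within ~10%.

Side values split the subject value by half the left-right difference,
whose SD (`lr_sd_volume_ml` = 0.07 mL) we interpret as the SD of the
*difference*: with a 0.2 mL screening threshold this yields ~0.4% natural
flags, consistent with a screened cohort in which every retained subject
differs by at most 0.2 mL (a per-side reading would produce ~4% natural
flags and inflate the expected exclusion count). The corresponding depth
and area difference SDs (0.15 mm, 10 mm^2) are set small on the same
argument; any positive value makes the larger-vs-smaller comparison
paired-significant while leaving it unpaired-invisible.

Unilateral defects occur with probability 12/186 (5:3:4 lacrimal :
fracture : anatomical asymmetry, matching the reported breakdown of
excluded cases) and shift that side's tabulated volume by 0.3-1.5 mL.
Each subject also yields a phantom-spec pair whose closed-form depth and
volume equal the drawn side values; the emitted table remains the
authority for area statistics, since phantom area is geometry-determined.

## Statistics

Unpaired comparisons use Welch's t (robust default; the huge p gaps make
the choice immaterial). The ICC is the two-way ANOVA single-measurement
form, absolute agreement by default (consistency exposed), computed from
the mean-squares decomposition and tested against an `aov`-equivalent
oracle to 1e-10. No multiple-testing correction is applied anywhere. The
percent gender difference uses the female mean as denominator; the V/A
ratio converts areas to cm^2.

The validation harness executes the full pipeline for every
(subject, side, operator, run) combination — 240 runs at the default
protocol — rather than caching: ICC = 1.0 is then a measured property of
end-to-end determinism (fixed seeds, deterministic tie-breaks, no
parallelism), not an assumption. Injected operator jitter drives the ICC
below 1, confirming the statistic reacts.

## Numerical choices and problem sizes

Voxel phantoms in the test suite run at 0.5 mm spacing (grids around
100^3); the refinement study uses 1.0 / 0.5 / 0.25 mm, and the Monte-Carlo
statistical checks use 100 cohorts of 174 subjects. The repeatability
protocol (10 subjects, 240 pipeline runs at 0.5 mm) completes in a few
minutes on one core. Ties in Otsu's criterion take the lowest maximizing
cut; ties in the posterior landmark take the lexicographically smallest
vertex; bins are half-open with the last closed. Degenerate inputs
(constant images, sealed cavities, seeds in bone or air, single-rater ICC
matrices, zero-variance paired differences) raise errors or warnings
rather than returning silently wrong numbers.

## Known limitations

* The attenuation model is three-valued; no noise or partial-volume model,
  so the automatic threshold problem is easier than on clinical CT.
* Seed placement inside the orbit is taken from phantom metadata; automatic
  orbit localization on arbitrary head CTs is out of scope (a seed must be
  supplied for clinical volumes).
* The DICOM support is a minimal uncompressed explicit-VR little-endian
  reader/writer for round-tripping phantoms; compressed or implicit-VR
  clinical archives are not handled (NIfTI is the primary format).
* The depth landmark is geometrically degenerate on a perfect hemisphere;
  real orbits (and the cone/paraboloid families) have a unique apex.
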