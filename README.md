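# orbitometry

Automated measurement of the bony orbit from CT-like attenuation volumes,
with synthetic phantoms and cohort statistics.

## The problem

The orbit is a roughly pyramidal bony cavity with no anterior bony border,
several posterior gaps, and walls so thin that they are often discontinuous
on CT. Orbital volume, surface area and axial depth drive surgical decisions
(trauma, Graves' orbitopathy, implant design), but manual CT segmentation is
slow and inter-observer variability blurs comparisons. `orbitometry`
implements an automated measurement pipeline of the kind used by clinical
orbital-analysis software, plus everything needed to validate it without
patient data:

1. **Segmentation** — an automatic bone threshold (Otsu over the
   tissue/bone part of the histogram), morphological *gap bridging* of the
   thin walls (Euclidean closing with a ball of physical radius, default
   1.5 mm), bounded region growing from an interior seed with a leak guard,
   and automatic planar *anterior/posterior closures* over the remaining
   apertures.
2. **Morphometry** — the cavity is decomposed into tetrahedra; volume is
   `V = Σ |det| / 6` over the tetrahedra (exactly the voxel volume), surface
   area `A` is measured on a Gaussian-smoothed marching-tetrahedra boundary
   (raw voxel faces overestimate area by ~50%), axial depth `L` is the
   distance from the anterior-closure mid-point to the farthest mesh vertex,
   and the volume is profiled into 10 equal bins along the normalized depth
   axis (bin 10 at the apex).
3. **Phantoms** — hemisphere / cone / paraboloid cavities with closed-form
   `V`, `A`, `L`, wrapped in a perforated bone shell (configurable voxel
   dropout), with optional lacrimal-channel and wall-fracture defects that
   reproduce the classic failure modes of automated orbital segmentation.
4. **Cohort statistics** — left–right asymmetry screening (|ΔV| > 0.2 mL),
   Shapiro–Wilk normality, Welch and paired t tests (gender, side,
   larger-vs-smaller designs), the interaction regression
   `V ~ 1 + Gender + L + Gender:L`, squared Pearson correlations, ANOVA
   based intraclass correlation coefficients (ICC(A,1)/ICC(C,1)), and the
   derived gender-difference and `V/A` ratios.
5. **Validation harness** — replays a 10-subject × 2-orbit × 6-operator ×
   2-run repeatability protocol (240 measurements) through the deterministic
   pipeline and reports intra-/inter-operator ICCs.

## Worked example

```r
library(orbitometry)

spec <- phantom_spec("paraboloid", depth_mm = 38, aperture_radius_mm = 21,
                     wall_gap_fraction = 0.05, rng_seed = 4)
ph <- make_phantom(spec)
ph$truth
#> <phantom_truth> V = 26.323 mL, A = 5047.6 mm^2, depth = 38 mm, defect: none

m <- measure_orbit(ph$volume, ph$truth$seed_voxel)
m
#> <orbit_metrics> (left)
#>   volume: 26.3275 mL
#>   surface area: 4972.28 mm^2
#>   axial depth: 38.043 mm
#>   profile (anterior -> apex, mL): 4.72 4.49 3.96 3.43 2.9 2.37 1.84 1.31
#>   0.784 0.248
#>   excluded anterior: 0.2855 mL
```

The measured volume is within 0.02% of the closed form (26.323 mL), the
smoothed surface area within 1.5%, and the depth within a tenth of a voxel;
per-bin volume decreases linearly toward the apex, as it must for a
paraboloid (cross-section shrinks linearly with depth).

A synthetic cohort drawn at the package defaults (91 male / 83 female,
reference means and correlation targets) reproduces the qualitative
statistics of adult orbit studies:

```r
co <- make_cohort(cohort_gen_params(rng_seed = 42))
sc <- screen_asymmetry(co$table)      # 0.2 mL rule
stats_report(sc$retained)
#> <stats_report> 161 subjects
#>   gender volume difference: 16.72 %
#>   volume/area ratio (4-cell average): 0.7368 mL/cm^2
#>   volume p: male vs female (left) 1.01e-12, left vs right paired (male)
#>   0.0148, larger vs smaller paired (male) <2e-16 / unpaired 0.926
#>   model (left) Depth p: <2e-16, Gender p: 0.314, Gender:Depth p: 0.465
```

Gender differences are highly significant, sides are indistinguishable,
the larger-vs-smaller comparison is paired-significant but unpaired
non-significant, and only depth predicts volume in the interaction model.

A command-line front end covers the same workflow
(`generate | segment | measure | analyze | validate | pipeline`):

```sh
Rscript exec/orbitometry pipeline --out results/run1 --log results/run1.jsonl
```

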