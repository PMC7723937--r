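---
title: "Atlas-based knee cartilage modelling: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-based knee cartilage modelling: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cartatlas)
```

This vignette is the package's own account of the science and the
numerical decisions behind it: what is modelled, which knobs matter, what
the synthetic data emulate, and where the deliberate simplifications lie.

## 1. Morphometry and template matching

A knee is summarized by five lengths (mm): the maximum medial-lateral
femoral length ML (transepicondylar axis), the maximum anterior-posterior
lengths of the medial and lateral condyles (AP medial, AP lateral), and
the medial and lateral tibiofemoral joint space widths (JSW), read as the
combined femoral-plus-tibial cartilage thickness of a compartment. Only
positivity is enforced — no ordering among the five is assumed.

Matching normalizes all five by ML (so the descriptor is a pure shape,
with the ML entry identically 1) and ranks library templates by the RMSE
over the five normalized fields. Design choices, made once:

* the RMSE includes the ML term even though it is identically zero —
  harmless, and symmetric in the five fields;
* ties keep library order (the ranking is stable);
* scaling uses the *medial* ratios for the x (AP) and z (thickness) axes,
  because only the medial compartment is meshed; the lateral dimensions
  participate in matching only. `scale_template(use_lateral = TRUE)`
  averages medial and lateral ratios instead, for sensitivity studies;
* the scaling origin defaults to the centroid of the contact-surface node
  set; it is configurable and affects only the rigid placement, not
  strains.

## 2. Simplified gait loading

The loading input is a stance-phase waveform — axial tibiofemoral force in
multiples of body weight and knee flexion in degrees on a 0–100% stance
grid. The packaged default is a representative double-peaked curve of the
kind measured by instrumented knee implants (peaks ≈ 2.5–2.6 BW in early
and late stance, midstance valley ≈ 1.9 BW, flexion 5°–40°); it is an
editable CSV input, not a constant of the method.

The force applied to the medial compartment model is

```
medial_force(t) = axial_force_bw(t) * mass * g * medial_share * (1 - meniscus_fraction)
```

with `g = 9.81`, `medial_share = 0.5` by default, and `meniscus_fraction`
defaulting to the mean of the atlas library's per-template fractions
(the meniscus is not meshed; its load share is simply removed). The stance
grid defaults to 101 uniform points and 100% stance maps to 0.6 s.

## 3. The FRPVE cartilage material

Total stress decomposes as `sigma_t = sigma_nf + sigma_f - p I`:

* **Nonfibrillar matrix** — compressible neo-Hookean solid parameterized
  by small-strain moduli (E_m, nu_m):
  `sigma_nf = [mu (B - I) + lambda ln(J) I] / J` with `F = I + eps`.
  At infinitesimal strain this is exactly linear isotropic elasticity.
* **Fibril network** — tension-only, viscoelastic. Each orientation
  carries a standard-linear-solid law: equilibrium spring
  `sigma_eq = E_0 eps + E_eps eps^2` in parallel with a Maxwell branch
  whose spring tangent is `k(eps) = E_0 + 2 E_eps eps` and whose damper is
  `eta`; the overstress obeys
  `d(sigma_ov)/dt = k deps/dt - (k/eta) sigma_ov`, discretized by backward
  Euler. Limits that serve as the testable contract: `eta -> 0` recovers
  the purely elastic law; constant strain relaxes monotonically to
  `sigma_eq`; compressed fibrils (and fibrils whose viscous unloading
  would drive the total negative) carry nothing.
* **Fluid** — interstitial pressure `p`, handled by the solver.

Architecture: two *primary* fibril bundles follow the Benninghoff arcade —
along the surface split-line direction (±) at depth `h_z = 0`, bending
continuously (normalized linear blend) to the surface normal at
`h_z = 1` — plus 13 *secondary* bundles on a fixed spherical-Fibonacci
hemisphere set (deterministic stand-in for "randomly oriented"
directions). Primary bundles are three times as dense as secondary ones
(configurable); all bundle weights sum to 1.

Default constants (femoral / tibial): E_m 0.215 / 0.106 MPa, E_0
0.92 / 0.18 MPa, E_eps 150 / 23.06 MPa, nu_m 0.15, eta 1062 MPa s,
permeability 6 / 18 ×10⁻¹⁵ m⁴/(N s) (converted to mm⁴/(N s) internally),
fluid fraction `n_f = 0.8 - 0.15 h_z`. The fluid-fraction profile is a
tissue descriptor; permeability is constant per tissue (no void-ratio
coupling). The same properties are used for every subject.

## 4. The poroelastic solver

Geometrically linear, Biot coefficient 1, incompressible constituents:
momentum `div(sigma_eff) - grad p + t = 0` and mass balance
`d(div u)/dt - div(k grad p) = 0`, discretized with equal-order trilinear
u/p hexahedra (2×2×2 quadrature), backward-Euler stepping, and a
Brezzi–Pitkaranta pressure-Laplacian stabilization with coefficient
`0.25 h_e² / (lambda + 2 mu)` to suppress the equal-order pair's spurious
pressure modes in the undrained limit. The stabilization's artificial
compressibility scales with h² and is negligible at the mesh sizes used
(relative pressure error contribution ≈ 10⁻³ at 20 elements through the
thickness).

Contact with the rigid femoral condyle is force-controlled in two nested
loops: an inner Newton solve at fixed condyle height (penalty contact,
default 10 MPa/mm), and an outer secant/bisection iteration on the height
until the total contact force matches the prescribed axial force to 0.1%.
A cross-step estimate of the force-height slope usually lands the first
trial within tolerance. The contact patch seals (no drainage) while
flagged; free side faces drain; the bone interface is fixed and sealed.
Knee flexion translates the condyle centre anteriorly (femoral rollback,
default 0.05 mm/deg).

Newton safeguards, all of which were found necessary on coarse meshes
with tension-only fibrils: a consistent J-dependent neo-Hookean tangent
plus rank-one fibril tangents; increment capping at 25% of the layer
thickness; merit backtracking; automatic damping when a period-2 cycle is
detected; automatic bisection of the load/time increment on
non-convergence; and C¹ regularization of the three switching
nonlinearities (fibril tension onset over 2×10⁻³ strain, the viscous
tension clamp over 10⁻³ MPa, penalty contact onset over 0.5% of the layer
thickness). The exported scalar fibril kernel keeps the exact,
unregularized law. Convergence demands a force residual below 10⁻⁶ of the
applied load; when a nonsmooth switch traps the iteration in a small
limit cycle around the solution, the best iterate is accepted provided
its force imbalance is below 10⁻³ of the current load (or of the
schedule's peak load, with a 2% relative guard) — in practice this arises
only near terminal lift-off, where the affected forces are a fraction of
a newton.

**Verification.** The nonfibrillar poroelastic limit is verified against
the closed-form one-dimensional consolidation series (`terzaghi_pressure`)
on a 20-element column (relative L2 pore-pressure error < 2% at
mid-consolidation) with monotone convergence under refinement over 5, 10
and 20 elements; the undrained response of a sealed, laterally free
column is isochoric to machine precision. A laterally *confined* column
cannot serve for the incompressibility check: there the volumetric strain
equals the axial strain identically, so the check is run in uniaxial
stress.

## 5. Response summarization

At every stance frame the contact region is the set of elements with at
least one flagged contact node. "Peak" is the signed extremum in the
physically adverse direction (maximum for tensile stress/strain, fibril
strain and pore pressure; minimum for compressive strain); the average is
the element-top-face-area-weighted mean of element-mean integration-point
values. Principal values come from the symmetric eigendecomposition of
the *total* stress (fluid pressure included). Fibril strain at a point is
the largest tensile strain over all fibril orientations. Frames with an
empty contact region yield `NA` with a warning — never fabricated values.

## 6. Reliability statistics

`icc_2way_random_absolute` implements ICC(2,1) from the two-way ANOVA
mean squares, with the F-based confidence interval using Satterthwaite
degrees of freedom (the standard absolute-agreement single-measurement
interval). Classification bands: below 0.5 poor, 0.5–0.75 moderate,
above 0.75 to 0.9 good, above 0.9 excellent — so "ICC > 0.75" is exactly
good-or-excellent, which is what `count_reliable` counts (strict
exceedance). A degenerate zero-variance table returns ICC 1 with a
warning rather than NaN. The bundled `icc_examples.csv` provides a
40-entry worked example (five parameters × four raters × CT and MR); on
its printed point estimates the CT count at 0.75 is 18 of 20 and the MRI
count is 15 of 20.

## 7. Nonparametric 1-D SPM

Paired trajectories are compared pointwise by the paired t statistic;
family-wise inference uses the sign-flip permutation distribution of the
maximum |t| over the stance grid. With n ≤ 12 subjects all 2ⁿ flips are
enumerated (deterministic; n = 9 gives 512), otherwise seeded Monte-Carlo
with 10 000 draws (a budget covering 2ⁿ enumerates instead). The critical
threshold is the ceiling((1−alpha)·P)-th order statistic of the max-|t|
distribution; maximal contiguous supra-threshold runs are reported with
max-statistic p-values. Numerical conventions worth noting:

* the observed statistic is taken from the permutation engine's identity
  row so that it ties its own permutation value exactly;
* zero-variance points get a signed-infinity sentinel (zero if the mean
  is also zero), applied symmetrically to every permutation — an exactly
  constant difference therefore attains the minimal p of 2/2ⁿ, and at
  n = 5 (minimal p 1/16) nothing can be significant at alpha = 0.05;
* identical conditions return a zero t curve and no clusters.

The empirical type-I error of the whole procedure is close to, and
slightly below, alpha because of the discreteness of the 512-point null —
the acceptance suite measures it at roughly 0.05 over 1000 null
replicates.

## 8. Synthetic data: what it does and does not emulate

The generators draw anatomical dimensions from normal distributions with
means/SDs representative of adult distal-femur morphometry (ML 80 ± 4,
AP medial 53 ± 4, AP lateral 62 ± 4.5, JSW medial 3.8 ± 1.2, JSW lateral
5.4 ± 0.8 mm), body mass 80 ± 12 kg, and per-template meniscus support
fractions uniform on 0.25–0.45. A template is a parametric
condyle-plateau: a hexahedral tibial cartilage slab whose footprint spans
AP medial × ML/2 and whose thickness is JSW medial/2, under a rigid
spherical femoral counter-surface of radius 8 × AP medial — a conforming,
nearly flat surface emulating meniscus-supported cartilage-on-cartilage
contact, which also keeps the geometrically linear solver inside its
valid strain range. Measuring a generated mesh recovers the generating
dimensions by construction, closing the loop with the morphometry layer.

Rater tables follow `value = mean + subject + error` with known variance
components, so the population ICC is sigma²_s/(sigma²_s + sigma²_e);
paired trajectories are smooth subject curves plus a user-supplied effect
profile and noise. All generators are pure functions of (spec, counts):
fixed seed, identical bytes.

What the synthetic data deliberately *omit*: real anatomical shape
variation beyond the five dimensions, menisci as geometry, subject
ligament/muscle forces, imaging noise, and any subject-specific material
variation. Green tests therefore demonstrate the correctness and
determinism of the machinery — matching, scaling, loading, the material
law, the solver, the statistics — not the clinical fidelity of any
particular simulated value.

## 9. Problem sizes and limitations

Default desk-scale sizes, chosen once: 5 × 5 × 2-element tibial slabs
(about 430 coupled unknowns), 101 stance points over 0.6 s, 21-template
libraries, nine-subject demonstration cohorts; the consolidation
verification uses up to 20 elements through the thickness. A full
nine-subject pipeline run takes a few minutes on one CPU.

Known limitations: geometrically linear kinematics (strains of tens of
percent are reported as engineering measures); a rigid, impermeable
counter-surface instead of two deformable cartilage layers; no
patellofemoral or lateral compartment; no depth-dependent permeability;
element-resolution-limited contact patches. These are the package's
deliberate trade-offs for transparent, fast, fully testable mechanics.
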