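# cartatlas

Atlas-based finite-element modelling of medial-compartment knee cartilage
mechanics in R, with the companion reliability and trajectory statistics.

## The problem

Generating a subject-specific finite-element (FE) model of the knee
normally requires segmenting cartilage from MR images, meshing it, and
assigning material properties and boundary conditions by hand — hours of
expert work per knee. The atlas-based shortcut replaces all of that with
**five length measurements** of the distal femur and tibiofemoral joint:

* ML — maximum medial-lateral length (clinical transepicondylar axis),
* AP medial / AP lateral — maximum anterior-posterior condylar lengths,
* JSW medial / JSW lateral — tibiofemoral joint space widths, read as the
  combined cartilage thickness of each compartment.

The workflow implemented here:

1. **Normalize** the five dimensions by ML, so knees are compared by shape
   (`normalize_dimensions()`).
2. **Match** the subject to a library of pre-built template FE models by
   minimum RMSE over the normalized dimensions (`match_template()`).
3. **Scale** the winning template mesh anisotropically — AP ratio along x,
   ML ratio along y, JSW ratio along z (`scale_template()`).
4. **Load** the medial compartment with a simplified gait cycle: a generic
   stance waveform scaled by body weight, 50% of the axial force assigned
   to the medial compartment, and the meniscus' share of load subtracted
   (`build_loading()`).
5. **Simulate** the stance phase with a mixed displacement/pore-pressure
   poroelastic solver whose cartilage is a fibril-reinforced
   poroviscoelastic (FRPVE) material,

   sigma_t = sigma_nf + sigma_f − p I,

   i.e. a compressible neo-Hookean nonfibrillar matrix, a tension-only
   viscoelastic collagen fibril network following a Benninghoff arcade
   (split-line-aligned at the articular surface, perpendicular at bone,
   plus 13 quasi-uniform secondary orientations), and interstitial fluid
   pressure (`run_gait()`, `solve_fe()`, `frpve_params()`).
6. **Summarize** each simulation into the five response parameters —
   maximum principal stress, maximum/minimum principal strain, fibril
   strain, pore pressure — as peak and contact-area-averaged trajectories
   over stance (`summarize_history()`).

Two statistics modules accompany the modelling chain:

* `icc_2way_random_absolute()` — ICC(2,1), two-way random effects,
  absolute agreement, single measurement, with the F-based 95% CI and the
  Koo-Li classification (`classify_icc()`, `count_reliable()`), for
  intrarater reliability of the five measurements;
* `snpm_paired()` — nonparametric 1-D statistical parametric mapping by
  sign-flip permutation with max-|t| thresholding, for paired comparison
  of stance trajectories (e.g. CT-based vs MRI-based models of the same
  subjects).

Everything the pipeline consumes can be generated synthetically with
controlled statistical structure (`fixture_spec()`, `gen_atlas_library()`,
`gen_subject_dims()`, `gen_rater_table()`, `gen_paired_trajectories()`).

## Worked example

```r
library(cartatlas)

# a synthetic 21-template library and one subject
spec <- fixture_spec(seed = 7)
lib  <- gen_atlas_library(spec)
subj <- anat_dims(ml = 80, ap_medial = 53, ap_lateral = 62,
                  jsw_medial = 3.8, jsw_lateral = 5.4)

head(match_template(subj, lib), 3)
#>   atlas_id        rmse
#> 1  atlas19 0.007402007
#> 2  atlas07 0.012458806
#> 3  atlas11 0.012976558

scaled  <- scale_template(lib$atlases[[19]], subj)
loading <- build_loading(resample_waveform(default_gait_waveform(), 101),
                         body_mass_kg = 80,
                         meniscus_fraction = library_meniscus_fraction(lib))
hist <- run_gait(scaled, loading)
traj <- summarize_history(hist)
round(max(traj$pore_pressure_peak), 3)      # peak fluid pressure, MPa
#> [1] 0.742
round(min(traj$min_principal_strain_peak), 3)  # peak compressive strain
#> [1] -0.349
```

The peak pore pressure (~0.74 MPa here) is the largest interstitial fluid
pressure reached on the contact patch during stance; the peak minimum
principal strain (~-0.35) is the largest compressive strain. Both are in
the range expected for a soft, conforming desk-scale cartilage layer under
roughly half body weight.

The reliability worked example uses the bundled table of intrarater ICC
point estimates (five parameters × four raters × two imaging modalities):

```r
ex <- reported_icc_examples()
count_reliable(ex$icc[ex$modality == "CT"])   # ICC > 0.75
#> [1] 18
count_reliable(ex$icc[ex$modality == "MRI"])
#> [1] 15
```

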