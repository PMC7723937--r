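# Seeded synthetic generators for every input the pipeline consumes:
# template atlas libraries (parametric condyle-plateau geometries), subject
# dimension tables, rater-measurement tables with known variance
# components, and paired trajectory sets with known localized effects.
# Every generator is a pure function of (spec, counts): a fixed seed gives
# identical output.

#' Specification for the synthetic fixture generators
#'
#' Dimension means and SDs default to values representative of adult
#' distal-femur morphometry (ML about 80 +/- 4 mm, AP medial about
#' 53 +/- 4 mm, AP lateral about 62 +/- 4.5 mm, JSW medial about
#' 3.8 +/- 1.2 mm, JSW lateral about 5.4 +/- 0.8 mm).
#'
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param n_atlases Number of templates in a generated library. Default 21.
#' @param dim_means,dim_sds Named numeric vectors over the five dimension
#'   fields (mm).
#' @param mass_mean,mass_sd Body mass distribution (kg).
#' @param meniscus_range Range of per-template meniscus support fractions.
#' @param sigma2_subject,sigma2_error Variance components (mm^2) for rater
#'   tables; the expected ICC(2,1) is
#'   `sigma2_subject / (sigma2_subject + sigma2_error)`.
#' @param effect_profile Function of stance percent (vector) returning the
#'   condition-B minus condition-A shift for paired trajectories; default
#'   zero (exchangeable null).
#' @param traj_sd Between-point trajectory noise SD.
#' @param mesh_nx,mesh_ny,mesh_nz Element counts of generated tibial
#'   cartilage layers.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_atlases = 21L,
                         dim_means = c(ml = 80, ap_medial = 53,
                                       ap_lateral = 62, jsw_medial = 3.8,
                                       jsw_lateral = 5.4),
                         dim_sds = c(ml = 4, ap_medial = 4,
                                     ap_lateral = 4.5, jsw_medial = 1.2,
                                     jsw_lateral = 0.8),
                         mass_mean = 80, mass_sd = 12,
                         meniscus_range = c(0.25, 0.45),
                         sigma2_subject = 9, sigma2_error = 1,
                         effect_profile = function(s) rep(0, length(s)),
                         traj_sd = 1,
                         mesh_nx = 5L, mesh_ny = 5L, mesh_nz = 2L) {
  if (any(dim_sds < 0) || mass_sd < 0 || sigma2_subject < 0 ||
      sigma2_error < 0 || traj_sd < 0)
    stop("spreads and variance components must be non-negative",
         call. = FALSE)
  structure(list(seed = as.integer(seed), n_atlases = as.integer(n_atlases),
                 dim_means = dim_means, dim_sds = dim_sds,
                 mass_mean = mass_mean, mass_sd = mass_sd,
                 meniscus_range = meniscus_range,
                 sigma2_subject = sigma2_subject,
                 sigma2_error = sigma2_error,
                 effect_profile = effect_profile, traj_sd = traj_sd,
                 mesh_nx = as.integer(mesh_nx), mesh_ny = as.integer(mesh_ny),
                 mesh_nz = as.integer(mesh_nz)),
            class = "fixture_spec")
}

draw_dims <- function(spec, n) {
  f <- names(spec$dim_means)
  out <- lapply(f, function(p) {
    v <- rnorm(n, spec$dim_means[[p]], spec$dim_sds[[p]])
    pmax(v, 0.2 * spec$dim_means[[p]])   # keep physically positive
  })
  matrix(unlist(out), n, length(f), dimnames = list(NULL, f))
}

# parametric condyle-plateau template: hexahedral tibial cartilage layer
# (footprint ap_medial x ml/2, thickness jsw_medial/2) plus a rigid
# spherical femoral counter-surface resting over its centre
build_template <- function(id, dims, meniscus_fraction, spec) {
  ap <- dims[["ap_medial"]]; ml <- dims[["ml"]]; jsw <- dims[["jsw_medial"]]
  th <- jsw / 2
  mesh <- hex_grid_mesh(spec$mesh_nx, spec$mesh_ny, spec$mesh_nz,
                        lx = ap, ly = ml / 2, lz = th,
                        x0 = -ap / 2, y0 = -ml / 2, z0 = 0)
  sets <- mesh$node_sets
  sets$tibial_cartilage <- seq_len(nrow(mesh$nodes))
  sets$tibial_bottom <- sets$zmin
  sets$contact_surface <- sets$zmax
  mesh <- hex_mesh(mesh$nodes, mesh$elems, sets)
  r <- 8 * ap
  condyle <- list(radius = r,
                  center = c(0, -ml / 4, th + r))
  template_atlas(id, mesh, as_anat_dims(dims), meniscus_fraction,
                 condyle = condyle)
}

#' Generate a synthetic atlas library
#'
#' Draws `n_atlases` dimension sets from the spec's distributions and
#' builds one parametric condyle-plateau template per draw (see
#' [fixture_spec()]); meniscus support fractions are drawn uniformly from
#' `meniscus_range`. Deterministic under the spec seed.
#'
#' @param spec A [fixture_spec()].
#' @return An [atlas_library()].
#' @examples
#' lib <- gen_atlas_library(fixture_spec(seed = 7, n_atlases = 3))
#' @export
gen_atlas_library <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$n_atlases < 1L) stop("n_atlases must be >= 1", call. = FALSE)
  set.seed(spec$seed)
  dims <- draw_dims(spec, spec$n_atlases)
  mfrac <- runif(spec$n_atlases, spec$meniscus_range[1],
                 spec$meniscus_range[2])
  atlas_library(lapply(seq_len(spec$n_atlases), function(i)
    build_template(sprintf("atlas%02d", i), dims[i, ], mfrac[i], spec)))
}

#' Generate a synthetic subject dimension table
#'
#' @param spec A [fixture_spec()].
#' @param n_subjects Number of subjects.
#' @return Data frame in the [read_subject_dims()] layout.
#' @export
gen_subject_dims <- function(spec, n_subjects = 9L) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1000L)
  dims <- draw_dims(spec, n_subjects)
  mass <- pmax(rnorm(n_subjects, spec$mass_mean, spec$mass_sd), 35)
  data.frame(subject_id = sprintf("subj%02d", seq_len(n_subjects)),
             dims, body_mass_kg = mass, stringsAsFactors = FALSE)
}

#' Generate a rater-measurement table with known variance components
#'
#' Cell values follow `value = mean + subject_effect + error` with
#' `subject_effect ~ N(0, sigma2_subject)` per subject and independent
#' `error ~ N(0, sigma2_error)` per trial, so the population ICC(2,1) is
#' `sigma2_subject / (sigma2_subject + sigma2_error)`.
#'
#' @param spec A [fixture_spec()].
#' @param n_subjects,n_raters,n_trials Table dimensions (>= 2, >= 1, >= 2).
#' @param parameter,modality Label columns.
#' @return Long-format data.frame in the [read_ratings()] layout.
#' @export
gen_rater_table <- function(spec, n_subjects = 9L, n_raters = 4L,
                            n_trials = 3L, parameter = "ML",
                            modality = "CT") {
  stopifnot(inherits(spec, "fixture_spec"))
  if (n_subjects < 2L || n_raters < 1L || n_trials < 2L)
    stop("need n_subjects >= 2, n_raters >= 1, n_trials >= 2",
         call. = FALSE)
  set.seed(spec$seed + 2000L)
  mu <- if (parameter %in% names(spec$dim_means))
    spec$dim_means[[parameter]] else 80
  out <- list()
  for (r in seq_len(n_raters)) {
    subj <- rnorm(n_subjects, 0, sqrt(spec$sigma2_subject))
    err <- matrix(rnorm(n_subjects * n_trials, 0,
                        sqrt(spec$sigma2_error)), n_subjects)
    vals <- mu + subj + err
    out[[r]] <- data.frame(
      subject_id = rep(sprintf("subj%02d", seq_len(n_subjects)), n_trials),
      rater = r,
      trial = rep(seq_len(n_trials), each = n_subjects),
      modality = modality, parameter = parameter,
      value_mm = as.vector(vals), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate paired trajectories with a known effect profile
#'
#' Condition A curves are smooth random subject trajectories; condition B
#' adds the spec's `effect_profile` (a function of stance percent) plus
#' independent noise. A zero effect profile yields an exchangeable null.
#'
#' @param spec A [fixture_spec()].
#' @param n_subjects,n_points Matrix dimensions.
#' @return List `cond_a`, `cond_b` (n_subjects x n_points), `stance_pct`.
#' @export
gen_paired_trajectories <- function(spec, n_subjects = 9L,
                                    n_points = 101L) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (n_subjects < 2L) stop("need n_subjects >= 2", call. = FALSE)
  set.seed(spec$seed + 3000L)
  s <- seq(0, 100, length.out = n_points)
  base <- outer(rep(1, n_subjects), sin(s / 100 * pi))
  subj_amp <- rnorm(n_subjects, 1, 0.2)
  a <- base * subj_amp + matrix(rnorm(n_subjects * n_points, 0,
                                      spec$traj_sd), n_subjects)
  eff <- spec$effect_profile(s)
  b <- a + matrix(eff, n_subjects, n_points, byrow = TRUE) +
    matrix(rnorm(n_subjects * n_points, 0, spec$traj_sd), n_subjects)
  list(cond_a = a, cond_b = b, stance_pct = s)
}

#' Write a complete runnable demo fixture set
#'
#' Writes an atlas library directory, a subject dimensions CSV, a ratings
#' CSV and the gait waveform CSV under `dir`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @param n_subjects Number of demo subjects.
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(spec, dir, n_subjects = 9L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas_library(gen_atlas_library(spec), file.path(dir, "atlases"))
  write_subject_dims(gen_subject_dims(spec, n_subjects),
                     file.path(dir, "subjects.csv"))
  rt <- gen_rater_table(spec, n_subjects)
  write.csv(rt, file.path(dir, "ratings.csv"), row.names = FALSE,
            quote = FALSE)
  file.copy(system.file("extdata", "gait_waveform.csv",
                        package = "cartatlas"),
            file.path(dir, "gait_waveform.csv"), overwrite = TRUE)
  invisible(dir)
}
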