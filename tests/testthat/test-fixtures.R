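# Synthetic generators: determinism, invariants, self-consistency with the
# morphometry layer, and variance-component structure.

test_that("the default library has 21 templates and is seed-deterministic", {
  spec <- fixture_spec(seed = 9)
  lib1 <- gen_atlas_library(spec)
  expect_identical(length(lib1$atlases), 21L)
  lib2 <- gen_atlas_library(fixture_spec(seed = 9))
  for (i in seq_along(lib1$atlases)) {
    expect_identical(lib1$atlases[[i]]$mesh$nodes,
                     lib2$atlases[[i]]$mesh$nodes)
    expect_identical(lib1$atlases[[i]]$meniscus_fraction,
                     lib2$atlases[[i]]$meniscus_fraction)
  }
  lib3 <- gen_atlas_library(fixture_spec(seed = 10))
  expect_false(identical(lib1$atlases[[1]]$mesh$nodes,
                         lib3$atlases[[1]]$mesh$nodes))
})

test_that("generated templates satisfy the atlas invariants", {
  lib <- gen_atlas_library(fixture_spec(seed = 21, n_atlases = 5))
  ids <- vapply(lib$atlases, function(a) a$atlas_id, "")
  expect_false(anyDuplicated(ids) > 0)
  for (a in lib$atlases) {
    expect_true(all(mesh_jacobians(a$mesh) > 0))
    expect_true(a$meniscus_fraction >= 0 && a$meniscus_fraction < 1)
    expect_true(all(c("tibial_cartilage", "tibial_bottom",
                      "contact_surface") %in% names(a$mesh$node_sets)))
    expect_equal(sqrt(rowSums(a$split_line_field^2)),
                 rep(1, nrow(a$split_line_field)), tolerance = 1e-12)
  }
})

test_that("measuring a generated mesh recovers the generating dimensions", {
  lib <- gen_atlas_library(fixture_spec(seed = 33, n_atlases = 8))
  for (a in lib$atlases) {
    m <- measure_dimensions(a)
    expect_equal(unclass(m), unclass(a$dims), tolerance = 0.01)
  }
})

test_that("rater tables carry the prescribed variance components", {
  # zero error: every downstream ICC is exactly 1
  spec0 <- fixture_spec(seed = 41, sigma2_subject = 9, sigma2_error = 0)
  rt0 <- gen_rater_table(spec0, 8, 2, 3)
  tab0 <- icc_table(rt0)
  expect_equal(tab0$icc, rep(1, nrow(tab0)), tolerance = 1e-12)
  # sigma_s^2 = 9, sigma_e^2 = 1 at n = 50: ICC near 0.9
  spec <- fixture_spec(seed = 42, sigma2_subject = 9, sigma2_error = 1)
  rt <- gen_rater_table(spec, 50, 1, 3)
  m <- ratings_matrix(rt, "ML", 1, "CT")
  r <- icc_2way_random_absolute(m)
  expect_lt(abs(r$icc - 0.9), 0.05)
  # determinism
  rt2 <- gen_rater_table(fixture_spec(seed = 42, sigma2_subject = 9,
                                      sigma2_error = 1), 50, 1, 3)
  expect_identical(rt$value_mm, rt2$value_mm)
  expect_error(gen_rater_table(spec, 1, 1, 3), ">= 2")
})

test_that("paired trajectories honor the effect profile and seed", {
  spec0 <- fixture_spec(seed = 51, traj_sd = 0,
                        effect_profile = function(s) rep(0, length(s)))
  tr0 <- gen_paired_trajectories(spec0, 6, 51)
  expect_identical(tr0$cond_a, tr0$cond_b)
  eff <- function(s) ifelse(s >= 60 & s <= 65, 2, 0)
  spec1 <- fixture_spec(seed = 51, traj_sd = 0, effect_profile = eff)
  tr1 <- gen_paired_trajectories(spec1, 6, 101)
  d <- tr1$cond_b - tr1$cond_a
  expect_equal(max(abs(d[, tr1$stance_pct < 60])), 0)
  expect_equal(d[, tr1$stance_pct == 62], rep(2, 6), tolerance = 1e-12)
  # seeded reproducibility
  tr2 <- gen_paired_trajectories(fixture_spec(seed = 51, traj_sd = 0,
                                              effect_profile = eff), 6, 101)
  expect_identical(tr1$cond_a, tr2$cond_a)
})

test_that("a complete fixture set is written and readable", {
  dir <- tempfile()
  write_fixture_set(fixture_spec(seed = 61, n_atlases = 2), dir,
                    n_subjects = 3)
  expect_true(file.exists(file.path(dir, "subjects.csv")))
  lib <- read_atlas_library(file.path(dir, "atlases"))
  expect_identical(length(lib$atlases), 2L)
  subs <- read_subject_dims(file.path(dir, "subjects.csv"))
  expect_identical(nrow(subs), 3L)
  rt <- read_ratings(file.path(dir, "ratings.csv"))
  expect_true(all(c("subject_id", "value_mm") %in% names(rt)))
  w <- read_gait_waveform(file.path(dir, "gait_waveform.csv"))
  expect_s3_class(w, "gait_waveform")
})
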