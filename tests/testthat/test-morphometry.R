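# Anatomical dimensions, normalization, template matching and scaling.

test_that("normalization divides every field by ML and is scale invariant", {
  # rater-1 mean dimensions of the reference measurement table
  d <- anat_dims(79.84, 52.95, 61.66, 3.82, 5.38)
  n <- normalize_dimensions(d)
  expect_equal(n[["ap_medial"]], 52.95 / 79.84, tolerance = 1e-12)
  expect_identical(n[["ml"]], 1)
  expect_equal(unclass(n),
               c(ml = 1, ap_medial = 52.95 / 79.84,
                 ap_lateral = 61.66 / 79.84, jsw_medial = 3.82 / 79.84,
                 jsw_lateral = 5.38 / 79.84), tolerance = 1e-12)
  for (c_ in c(0.5, 2, 10)) {
    scaled <- anat_dims(c_ * 79.84, c_ * 52.95, c_ * 61.66, c_ * 3.82,
                        c_ * 5.38)
    expect_equal(unclass(normalize_dimensions(scaled)), unclass(n),
                 tolerance = 1e-12)
  }
})

test_that("dimension validation rejects non-positive and missing values", {
  expect_error(anat_dims(-1, 50, 60, 4, 5), "positive")
  expect_error(anat_dims(0, 50, 60, 4, 5), "positive")
  expect_error(anat_dims(NA, 50, 60, 4, 5), "finite")
})

test_that("match_template agrees with the exhaustive-search oracle", {
  set.seed(42)
  for (rep in 1:200) {
    lib <- random_library(5)
    subj <- random_dims()
    ranked <- match_template(subj, lib)
    oracle <- match_oracle(subj, lib)
    expect_identical(ranked$atlas_id[1], oracle$atlas_id)
    expect_equal(ranked$rmse[1], oracle$rmse, tolerance = 1e-12)
    expect_true(!is.unsorted(ranked$rmse))
  }
})

test_that("exact-match template has rmse zero and single atlas always wins", {
  lib <- random_library(4)
  target <- lib$atlases[[3]]$dims
  ranked <- match_template(target, lib)
  expect_identical(ranked$atlas_id[1], "rnd03")
  expect_equal(ranked$rmse[1], 0)
  one <- atlas_library(list(toy_cube_atlas()))
  r1 <- match_template(random_dims(), one)
  expect_identical(r1$atlas_id, "cube")
})

test_that("matching ties are broken by library order", {
  a1 <- toy_cube_atlas(anat_dims(80, 50, 60, 4, 5)); a1$atlas_id <- "first"
  a2 <- toy_cube_atlas(anat_dims(40, 25, 30, 2, 2.5)); a2$atlas_id <- "second"
  lib <- atlas_library(list(a1, a2))   # identical normalized shapes
  r <- match_template(anat_dims(60, 40, 44, 3, 4), lib)
  expect_identical(r$atlas_id[1], "first")
  expect_equal(r$rmse[1], r$rmse[2], tolerance = 1e-12)
})

test_that("scaling by identical dimensions is the identity", {
  a <- toy_cube_atlas()
  s <- scale_template(a, a$dims)
  expect_lt(max(abs(s$mesh$nodes - a$mesh$nodes)), 1e-12)
  expect_identical(s$mesh$elems, a$mesh$elems)
  expect_identical(s$meniscus_fraction, a$meniscus_fraction)
})

test_that("doubling ML doubles y-coordinates relative to the origin", {
  a <- toy_cube_atlas()
  target <- unclass(a$dims); target[["ml"]] <- 2 * target[["ml"]]
  origin <- c(0.2, 0.4, 1)
  s <- scale_template(a, as_anat_dims(as.list(target)), origin = origin)
  expect_equal(s$mesh$nodes[, 2] - origin[2],
               2 * (a$mesh$nodes[, 2] - origin[2]), tolerance = 1e-12)
  expect_equal(s$mesh$nodes[, 1], a$mesh$nodes[, 1], tolerance = 1e-12)
  expect_equal(s$mesh$nodes[, 3], a$mesh$nodes[, 3], tolerance = 1e-12)
})

test_that("toy cube scaling matches the hand-computed affine map", {
  a <- toy_cube_atlas(anat_dims(ml = 2, ap_medial = 1, ap_lateral = 1.2,
                                jsw_medial = 1, jsw_lateral = 1.1))
  # target scale factors sx = 1.1, sy = 0.9, sz = 1.2
  tgt <- anat_dims(ml = 2 * 0.9, ap_medial = 1.1, ap_lateral = 1.2,
                   jsw_medial = 1.2, jsw_lateral = 1.1)
  origin <- c(0, 0, 0)
  s <- scale_template(a, tgt, origin = origin)
  expected <- sweep(a$mesh$nodes, 2L, c(1.1, 0.9, 1.2), `*`)
  expect_equal(s$mesh$nodes, expected, tolerance = 1e-12)
})

test_that("scaling preserves topology and positive Jacobians", {
  set.seed(7)
  a <- gen_atlas_library(fixture_spec(seed = 3, n_atlases = 1))$atlases[[1]]
  for (rep in 1:10) {
    f <- runif(3, 0.5, 2)
    tgt <- unclass(a$dims)
    tgt[["ap_medial"]] <- tgt[["ap_medial"]] * f[1]
    tgt[["ml"]] <- tgt[["ml"]] * f[2]
    tgt[["jsw_medial"]] <- tgt[["jsw_medial"]] * f[3]
    s <- scale_template(a, as_anat_dims(as.list(tgt)))
    expect_identical(dim(s$mesh$nodes), dim(a$mesh$nodes))
    expect_identical(s$mesh$elems, a$mesh$elems)
    expect_true(all(mesh_jacobians(s$mesh) > 0))
    expect_equal(sqrt(rowSums(s$split_line_field^2)),
                 rep(1, nrow(s$split_line_field)), tolerance = 1e-12)
  }
})

test_that("zero or negative scale factors are rejected", {
  a <- toy_cube_atlas()
  bad <- unclass(a$dims)
  bad[["ap_medial"]] <- -1
  expect_error(scale_template(a, as_anat_dims(as.list(bad))))
})
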