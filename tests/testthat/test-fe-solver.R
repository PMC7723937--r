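# Poroelastic solver verification: rest state, consolidation against the
# closed-form series solution, undrained incompressibility, sealed-boundary
# fluid conservation, contact mechanics and energy sanity.

test_that("zero load gives zero displacement and pressure at all steps", {
  prob <- consolidation_column_problem(n_elem = 4, load_mpa = 0,
                                       times = c(1, 2, 3))
  h <- solve_fe(prob)
  expect_lt(max(abs(h$U)), 1e-12)
  expect_lt(max(abs(h$P)), 1e-12)
})

test_that("consolidation pore pressure matches the closed-form series", {
  params <- frpve_params("tibial")
  cv <- consolidation_coefficient(params)
  prob <- consolidation_column_problem(n_elem = 10, load_mpa = 0.001,
                                       params = params)
  h <- solve_fe(prob, store_fields = FALSE)
  zn <- h$mesh$nodes[, 3]
  edge <- which(abs(h$mesh$nodes[, 1]) < 1e-9 &
                  abs(h$mesh$nodes[, 2]) < 1e-9)
  edge <- edge[order(zn[edge])]
  tchar <- 1 / cv
  for (tv in c(0.1, 0.2)) {
    k <- which.min(abs(h$time - tv * tchar))
    pan <- terzaghi_pressure(1 - zn[edge], h$time[k], 0.001, cv, 1)
    err <- sqrt(sum((h$P[k, edge] - pan)^2)) / sqrt(sum(pan^2))
    expect_lt(err, 0.03)
  }
})

test_that("instantaneous sealed response of a free column is isochoric", {
  prob <- consolidation_column_problem(n_elem = 8, load_mpa = 0.001,
                                       times = 0.01, drained_top = FALSE,
                                       confined = FALSE)
  h <- solve_fe(prob)
  eps <- h$strain[1, , ]
  vol <- rowSums(eps[, 1:3])
  ax <- eps[, 3]
  expect_lt(max(abs(vol)) / max(abs(ax)), 0.01)
  # undrained uniaxial stress: mean total stress is carried by pressure
  expect_equal(mean(h$P[1, ]), 0.001 / 3, tolerance = 0.05)
})

test_that("sealed boundaries conserve fluid volume", {
  prob <- consolidation_column_problem(n_elem = 8, load_mpa = 0.002,
                                       times = c(0.01, 0.02, 0.05),
                                       drained_top = FALSE,
                                       confined = FALSE)
  h <- solve_fe(prob)
  # total volumetric strain integrates to ~0 relative to axial change
  for (k in seq_along(h$time)) {
    eps <- h$strain[k, , ]
    tot_vol <- sum(rowSums(eps[, 1:3]) * h$gp$w)
    axial <- sum(abs(eps[, 3]) * h$gp$w)
    expect_lt(abs(tot_vol), 1e-8 * max(axial, 1e-12))
  }
})

test_that("external work bounds stored elastic energy (dissipation >= 0)", {
  params <- frpve_params("tibial")
  prob <- consolidation_column_problem(n_elem = 6, load_mpa = 0.001,
                                       params = params)
  h <- solve_fe(prob)
  top <- h$mesh$node_sets$zmax
  area <- 0.25^2
  # external work of the constant top traction (trapezoid in displacement)
  uz_top <- apply(h$U[, top, 3, drop = FALSE], 1L, mean)
  W <- -0.001 * area * uz_top[length(uz_top)]   # force down, moves down
  # elastic energy of the (linear limit) effective stress at final time
  k <- length(h$time)
  p_gp <- cartatlas:::gp_pressure(h, k, seq_along(h$gp$w))
  sig_eff <- h$stress[k, , ]
  sig_eff[, 1:3] <- sig_eff[, 1:3] + p_gp
  eps <- h$strain[k, , ]
  U_el <- 0.5 * sum(rowSums(sig_eff * eps) * h$gp$w)
  expect_gt(W, U_el * (1 - 1e-6))
  expect_gt(U_el, 0)
})

test_that("rigid-surface contact evaluation follows the penalty law", {
  a <- toy_cube_atlas()
  # far surface: no contact
  far <- contact_step(a$mesh, condyle = list(radius = 5,
                                             center = c(0.5, 0.5, 10)),
                      penalty = 10)
  expect_identical(sum(far$flags), 0L)
  expect_identical(far$total_force, 0)
  # near-flat surface pressed to uniform overlap delta on the flat top
  delta <- 0.01
  big_r <- 1e6
  ct <- contact_step(a$mesh,
                     condyle = list(radius = big_r,
                                    center = c(0.5, 0.5, 1 - delta + big_r)),
                     penalty = 10)
  expect_true(all(ct$flags))
  # residual curvature of the huge sphere bounds the traction deviation
  expect_lt(max(abs(ct$traction - 10 * delta)), 1e-4)
  expect_equal(ct$total_force, 10 * delta * 1, tolerance = 1e-3)
  expect_error(contact_step(a$mesh, condyle = list(radius = 1,
                                                   center = c(0, 0, 2)),
                            penalty = -1), "positive")
})

test_that("gait run balances the prescribed axial force per frame", {
  h <- small_gait_history()
  ld <- small_gait_loading()
  err <- abs(h$contact_force - ld$medial_force_n) /
    pmax(ld$medial_force_n, 1)
  expect_lt(max(err, na.rm = TRUE), 0.01)
  expect_identical(nrow(h$contact_flags), length(ld$stance_pct))
  # bookkeeping: one stored frame per stance point
  expect_identical(length(h$time), nrow(ld))
})

test_that("unconstrained problems raise an informative error", {
  mesh <- hex_grid_mesh(1, 1, 1, 1, 1, 1)
  p <- frpve_params("tibial")
  prob <- fe_problem(mesh, p, fibrils_on = FALSE, dirichlet = list(),
                     traction = list(nodes = mesh$node_sets$zmax,
                                     pressure = 0.001),
                     time_grid = 1)
  expect_error(solve_fe(prob), "rigid-body")
})
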