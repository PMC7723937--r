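# FRPVE material kernel: fluid fraction, fibril architecture, the
# tension-only viscoelastic fibril law, the neo-Hookean matrix and the
# total-stress decomposition.

test_that("fluid fraction follows the linear depth profile", {
  expect_equal(fluid_fraction(0), 0.8)
  expect_equal(fluid_fraction(1), 0.65)
  expect_equal(fluid_fraction(0.5), 0.8 - 0.15 * 0.5)
  h <- seq(0, 1, by = 0.05)
  expect_true(all(diff(fluid_fraction(h)) < 0))
  expect_error(fluid_fraction(-0.1), "0, 1")
  expect_error(fluid_fraction(1.1), "0, 1")
})

test_that("primary fibril arcade interpolates split line to normal", {
  s <- c(1, 0, 0); n <- c(0, 0, 1)
  d0 <- primary_fibril_directions(0, s, n)
  expect_equal(drop(d0[1, ] %*% s), 1, tolerance = 1e-12)
  expect_equal(drop(d0[2, ] %*% s), -1, tolerance = 1e-12)
  d1 <- primary_fibril_directions(1, s, n)
  expect_equal(abs(drop(d1[1, ] %*% n)), 1, tolerance = 1e-12)
  expect_equal(abs(drop(d1[2, ] %*% n)), 1, tolerance = 1e-12)
  # unit norm across random depths and frames
  set.seed(1)
  for (i in 1:100) {
    R <- random_rotation()
    sr <- R %*% s; nr <- R %*% n
    d <- primary_fibril_directions(runif(1), sr, nr)
    expect_equal(sqrt(rowSums(d^2)), c(1, 1), tolerance = 1e-12)
  }
  expect_error(primary_fibril_directions(0.5, c(1, 0, 0), c(1, 0, 0)),
               "orthogonal")
  expect_error(primary_fibril_directions(0.5, c(2, 0, 0), c(0, 0, 1)),
               "unit")
})

test_that("secondary fibril set is 13 unit, pairwise non-parallel vectors", {
  d <- secondary_fibril_directions()
  expect_identical(nrow(d), 13L)
  expect_equal(sqrt(rowSums(d^2)), rep(1, 13), tolerance = 1e-12)
  G <- abs(d %*% t(d))
  diag(G) <- 0
  expect_lt(max(G), 1 - 1e-6)
  # deterministic
  expect_identical(d, secondary_fibril_directions())
})

test_that("fibrils carry tension only and the elastic limit is exact", {
  p <- frpve_params("tibial")
  r <- fibril_stress_update(-0.05, fibril_state0(), dt = 0.1, p)
  expect_identical(r$stress, 0)
  p0 <- frpve_params("tibial", eta = 0)
  for (eps in c(0.01, 0.05, 0.12)) {
    r <- fibril_stress_update(eps, fibril_state0(), dt = 0.1, p0)
    expect_equal(r$stress, p0$e_0 * eps + p0$e_eps * eps^2,
                 tolerance = 1e-12)
  }
  expect_error(fibril_stress_update(0.05, fibril_state0(), dt = 0, p),
               "positive")
})

test_that("held strain relaxes monotonically to the closed-form equilibrium
           and the transient matches a fine-step ODE oracle", {
  for (tissue in c("tibial", "femoral")) {
    p <- frpve_params(tissue)
    eps <- 0.05
    r <- fibril_stress_update(eps, fibril_state0(), dt = 1e-3, p)
    stresses <- r$stress
    st <- r$state
    # march to t = 1e4 s in coarse steps
    for (i in 1:200) {
      r <- fibril_stress_update(eps, st, dt = 50, p)
      st <- r$state
      stresses <- c(stresses, r$stress)
    }
    expect_true(all(diff(stresses) <= 1e-12))
    eq <- fibril_equilibrium_stress(eps, p)
    expect_true(all(stresses >= eq - 1e-12))
    expect_equal(r$stress, eq, tolerance = 1e-3)
    # transient at t = 100 s against dt = 1e-3 explicit integration
    st <- fibril_stress_update(eps, fibril_state0(), dt = 1e-3, p)$state
    pkg <- NA
    for (i in 1:2000) {
      out <- fibril_stress_update(eps, st, dt = 0.05, p)
      st <- out$state; pkg <- out$stress
    }
    oracle <- fibril_ode_oracle(eps, 100, p)
    expect_equal(pkg, oracle, tolerance = 1e-3)
  }
})

test_that("nonfibrillar stress reduces to Hooke's law at small strain", {
  p <- frpve_params("femoral")
  expect_equal(nonfibrillar_stress(matrix(0, 3, 3), p), matrix(0, 3, 3))
  e <- 1e-6
  s <- nonfibrillar_stress(diag(c(e, 0, 0)), p)
  lam <- p$e_m * p$nu_m / ((1 + p$nu_m) * (1 - 2 * p$nu_m))
  mu <- p$e_m / (2 * (1 + p$nu_m))
  expect_equal(s[1, 1], (lam + 2 * mu) * e, tolerance = 1e-6)
  expect_equal(s[2, 2], lam * e, tolerance = 1e-6)
  # random small strains against the Voigt-form linear-elastic oracle
  set.seed(3)
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam; diag(D)[1:3] <- lam + 2 * mu; diag(D)[4:6] <- mu
  for (i in 1:20) {
    v <- rnorm(6, sd = 1e-5)
    eps <- matrix(c(v[1], v[4] / 2, v[5] / 2,
                    v[4] / 2, v[2], v[6] / 2,
                    v[5] / 2, v[6] / 2, v[3]), 3, 3)
    sig <- nonfibrillar_stress(eps, p)
    ref <- D %*% v
    expect_equal(c(sig[1, 1], sig[2, 2], sig[3, 3],
                   sig[1, 2], sig[1, 3], sig[2, 3]),
                 as.numeric(ref), tolerance = 1e-4)
  }
  expect_error(nonfibrillar_stress(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0),
                                          3, 3), p), "symmetric")
})

test_that("total stress obeys the additive decomposition", {
  p <- frpve_params("tibial")
  # zero strain, zero pressure
  r0 <- total_stress(material_point_state(matrix(0, 3, 3)), p)
  expect_equal(r0$stress, matrix(0, 3, 3))
  # zero strain, p = 0.5 MPa: exactly -p I
  rp <- total_stress(material_point_state(matrix(0, 3, 3),
                                          pore_pressure = 0.5), p)
  expect_equal(rp$stress, -0.5 * diag(3), tolerance = 1e-15)
  # additivity: total - (-pI) - nonfibrillar == fibril term exactly
  set.seed(5)
  eps <- diag(c(0.03, -0.01, 0.02)); eps[1, 2] <- eps[2, 1] <- 0.01
  st <- material_point_state(eps, pore_pressure = 0.2, h_z = 0.4)
  r <- total_stress(st, p, dt = 0.1)
  expect_equal(r$stress - r$components$pressure - r$components$nonfibrillar,
               r$components$fibril, tolerance = 1e-15)
})

test_that("single active fibril reproduces hand assembly", {
  # strain uniaxial along the split line at the surface: primary fibril 1
  # is the only stretched primary; secondary fibrils also project
  p <- frpve_params("tibial", eta = 0, n_secondary = 13L)
  eps_ax <- 0.05
  eps <- diag(c(eps_ax, 0, 0))
  st <- material_point_state(eps, h_z = 0)
  r <- total_stress(st, p, dt = 1)
  w <- cartatlas:::fibril_weights(p)
  dirs <- rbind(primary_fibril_directions(0, c(1, 0, 0), c(0, 0, 1)),
                secondary_fibril_directions())
  hand <- nonfibrillar_stress(eps, p)
  for (i in seq_len(nrow(dirs))) {
    d <- dirs[i, ]
    ef <- drop(d %*% eps %*% d)
    if (ef > 0)
      hand <- hand + w[i] * (p$e_0 * ef + p$e_eps * ef^2) * tcrossprod(d)
  }
  expect_equal(r$stress, hand, tolerance = 1e-12)
})

test_that("tensile stiffness along the split line exceeds compressive", {
  p <- frpve_params("tibial")
  e <- 0.02
  st_t <- total_stress(material_point_state(diag(c(e, 0, 0))), p, dt = 1)
  st_c <- total_stress(material_point_state(diag(c(-e, 0, 0))), p, dt = 1)
  expect_gt(st_t$stress[1, 1], abs(st_c$stress[1, 1]))
})

test_that("total stress is equivariant under rotations", {
  p <- frpve_params("femoral")
  set.seed(9)
  eps <- diag(c(0.04, -0.02, 0.01)); eps[1, 3] <- eps[3, 1] <- 0.015
  for (i in 1:20) {
    R <- random_rotation()
    st <- material_point_state(eps, pore_pressure = 0.1, h_z = 0.3)
    r <- total_stress(st, p, dt = 0.5)
    st_rot <- material_point_state(
      R %*% eps %*% t(R), pore_pressure = 0.1, h_z = 0.3,
      split_line = as.numeric(R %*% c(1, 0, 0)),
      surface_normal = as.numeric(R %*% c(0, 0, 1)),
      secondary_dirs = secondary_fibril_directions() %*% t(R))
    r_rot <- total_stress(st_rot, p, dt = 0.5)
    expect_equal(r_rot$stress, R %*% r$stress %*% t(R), tolerance = 1e-9)
  }
})

test_that("material config YAML round-trips the preset constants", {
  path <- system.file("extdata", "materials.yaml", package = "cartatlas")
  cfg <- read_material_config(path)
  expect_equal(cfg$femoral$e_m, 0.215)
  expect_equal(cfg$femoral$e_eps, 150)
  expect_equal(cfg$tibial$e_0, 0.18)
  expect_equal(cfg$tibial$k_perm_mm, 18e-3)
  expect_equal(cfg$tibial$eta, 1062)
})
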