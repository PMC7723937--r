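# Shared builders for the test suite. Everything is generated in code;
# no binary fixtures.

# a unit-cube single-element template atlas with hand-checkable geometry
toy_cube_atlas <- function(dims = anat_dims(2, 1, 1.2, 1, 1.1)) {
  mesh <- hex_grid_mesh(1, 1, 1, lx = 1, ly = 1, lz = 1)
  sets <- mesh$node_sets
  sets$tibial_cartilage <- seq_len(8L)
  sets$tibial_bottom <- sets$zmin
  sets$contact_surface <- sets$zmax
  mesh <- hex_mesh(mesh$nodes, mesh$elems, sets)
  template_atlas("cube", mesh, dims, meniscus_fraction = 0.3)
}

# random anatomical dimensions in plausible adult ranges
random_dims <- function() {
  anat_dims(runif(1, 70, 92), runif(1, 45, 62), runif(1, 52, 72),
            runif(1, 2, 6), runif(1, 3.5, 7.5))
}

# brute-force template matching oracle, independent of match_template
match_oracle <- function(subject, library) {
  sv <- unclass(normalize_dimensions(subject))
  best_i <- 0L; best_r <- Inf
  for (i in seq_along(library$atlases)) {
    av <- unclass(normalize_dimensions(library$atlases[[i]]$dims))
    r <- 0
    for (f in names(sv)) r <- r + (sv[[f]] - av[[f]])^2
    r <- sqrt(r / length(sv))
    if (r < best_r) { best_r <- r; best_i <- i }
  }
  list(atlas_id = library$atlases[[best_i]]$atlas_id, rmse = best_r)
}

# small random atlas library with dimension-only templates (cube meshes)
random_library <- function(n) {
  atlas_library(lapply(seq_len(n), function(i) {
    a <- toy_cube_atlas(random_dims())
    a$atlas_id <- sprintf("rnd%02d", i)
    a
  }))
}

# explicit fine-step ODE oracle for the fibril standard-linear-solid:
# constant strain eps held from t = 0 with instantaneous loading;
# overstress ODE d(sov)/dt = -(k/eta) sov, k = E0 + 2 Ee eps
fibril_ode_oracle <- function(eps, t_end, params, dt = 1e-3) {
  k <- params$e_0 + 2 * params$e_eps * eps
  seq_ <- params$e_0 * eps + params$e_eps * eps^2
  sov <- k * eps                      # instantaneous Maxwell spring stretch
  n <- round(t_end / dt)
  for (i in seq_len(n)) sov <- sov + dt * (-(k / params$eta) * sov)
  seq_ + sov
}

# rotate a Voigt-free symmetric tensor
rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# hand-built two-element field history for response summarization oracles
tiny_history <- function(stress1, stress2, flags = c(TRUE, TRUE)) {
  mesh <- hex_grid_mesh(2, 1, 1, lx = 2, ly = 1, lz = 1)
  sets <- mesh$node_sets
  sets$tibial_cartilage <- seq_len(nrow(mesh$nodes))
  sets$tibial_bottom <- sets$zmin
  sets$contact_surface <- sets$zmax
  mesh <- hex_mesh(mesh$nodes, mesh$elems, sets)
  ngp <- 16L
  stress <- array(0, c(1L, ngp, 6L))
  strain <- array(0, c(1L, ngp, 6L))
  for (g in 1:8) { stress[1, g, ] <- stress1; strain[1, g, ] <- stress1 }
  for (g in 9:16) { stress[1, g, ] <- stress2; strain[1, g, ] <- stress2 }
  cs <- mesh$node_sets$contact_surface
  # flag the surface nodes belonging to element 1 and/or 2
  xmid <- 1
  fl <- rep(FALSE, length(cs))
  if (flags[1]) fl <- fl | mesh$nodes[cs, 1] < xmid + 1e-9
  if (flags[2]) fl <- fl | mesh$nodes[cs, 1] > xmid - 1e-9
  structure(list(
    time = 1, stance_pct = 50,
    U = array(0, c(1L, nrow(mesh$nodes), 3L)),
    P = matrix(0, 1L, nrow(mesh$nodes)),
    stress = stress, strain = strain,
    fibril_strain = matrix(c(rep(0.01, 8), rep(0.03, 8)), 1L),
    contact_flags = matrix(fl, 1L),
    contact_nodes = cs, condyle_z = NA_real_,
    contact_force = NA_real_, mesh = mesh,
    gp = list(x = matrix(0, ngp, 3L), elem = rep(1:2, each = 8L),
              w = rep(1 / 8, ngp), h_z = rep(0.5, ngp))),
    class = "field_history")
}

# small gait run shared by solver/response/pipeline tests (cached)
.small_gait_cache <- new.env()
small_gait_history <- function() {
  if (!is.null(.small_gait_cache$h)) return(.small_gait_cache$h)
  spec <- fixture_spec(seed = 11, n_atlases = 2, mesh_nx = 4L,
                       mesh_ny = 4L, mesh_nz = 2L)
  lib <- gen_atlas_library(spec)
  w <- resample_waveform(default_gait_waveform(), 21)
  ld <- build_loading(w, 75, library_meniscus_fraction(lib))
  h <- run_gait(lib$atlases[[1]], ld)
  .small_gait_cache$h <- h
  .small_gait_cache$loading <- ld
  h
}
small_gait_loading <- function() {
  small_gait_history()
  .small_gait_cache$loading
}
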