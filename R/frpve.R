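# Fibril-reinforced poroviscoelastic (FRPVE) cartilage material.
#
# Total stress decomposition:  sigma_t = sigma_nf + sigma_f - p * I
# with a compressible neo-Hookean nonfibrillar matrix (small-strain moduli
# E_m, nu_m), a tension-only viscoelastic collagen fibril network, and
# interstitial fluid pressure p.
#
# Fibril law (standard-linear-solid arrangement): for tensile fibril
# strain eps > 0,
#   equilibrium spring   sigma_eq(eps) = E_0 * eps + E_eps * eps^2
#   Maxwell branch       d(sigma_ov)/dt = k(eps) * d(eps)/dt
#                                         - (k(eps)/eta) * sigma_ov
#   with k(eps) = E_0 + 2 * E_eps * eps (the tangent of sigma_eq)
#   sigma_f = sigma_eq + sigma_ov
# Backward-Euler discretization:
#   sigma_ov^{n+1} = (sigma_ov^n + k * d_eps) / (1 + k * dt / eta)
# eta -> 0 removes the overstress (purely elastic law); constant strain
# relaxes monotonically to sigma_eq. Compressed fibrils (eps <= 0) carry no
# stress and their overstress resets.
#
# Fibril architecture: primary fibrils follow a Benninghoff arcade — along
# the surface split-line direction superficially, bending continuously to
# the surface normal at the bone interface — plus 13 fixed quasi-uniform
# secondary orientations. Primary fibrils are denser than secondary by a
# configurable ratio.

#' FRPVE material parameters
#'
#' Default parameter sets for femoral and tibial cartilage: nonfibrillar
#' matrix modulus `e_m` (MPa), initial fibril network modulus `e_0` (MPa),
#' strain-dependent fibril network modulus `e_eps` (MPa), matrix Poisson
#' ratio `nu_m`, fibril viscoelastic damping `eta` (MPa s), permeability
#' `k_perm` (in units of 1e-15 m^4/(N s); converted to mm^4/(N s)
#' internally), and the depth profile of the fluid fraction
#' `n_f(h_z) = nf_surface - nf_slope * h_z`.
#'
#' @param tissue `"tibial"` or `"femoral"` preset.
#' @param e_m,e_0,e_eps,nu_m,eta,k_perm,nf_surface,nf_slope Overrides of the
#'   preset values.
#' @param n_secondary Number of secondary fibril orientations (fixed set).
#' @param primary_density_ratio Fibril density of each primary bundle
#'   relative to one secondary bundle. Default 3: denser primary fibrils,
#'   following the convention of the FRPVE literature.
#' @return An `frpve_params` list. `$k_perm_mm` holds the permeability in
#'   mm^4/(N s).
#' @examples
#' frpve_params("tibial")
#' @export
frpve_params <- function(tissue = c("tibial", "femoral"),
                         e_m = NULL, e_0 = NULL, e_eps = NULL, nu_m = NULL,
                         eta = NULL, k_perm = NULL,
                         nf_surface = 0.8, nf_slope = 0.15,
                         n_secondary = 13L, primary_density_ratio = 3) {
  tissue <- match.arg(tissue)
  def <- if (tissue == "femoral")
    list(e_m = 0.215, e_0 = 0.92, e_eps = 150, nu_m = 0.15,
         eta = 1062, k_perm = 6)
  else
    list(e_m = 0.106, e_0 = 0.18, e_eps = 23.06, nu_m = 0.15,
         eta = 1062, k_perm = 18)
  p <- list(tissue = tissue,
            e_m = e_m %||% def$e_m, e_0 = e_0 %||% def$e_0,
            e_eps = e_eps %||% def$e_eps, nu_m = nu_m %||% def$nu_m,
            eta = eta %||% def$eta, k_perm = k_perm %||% def$k_perm,
            nf_surface = nf_surface, nf_slope = nf_slope,
            n_secondary = as.integer(n_secondary),
            primary_density_ratio = primary_density_ratio)
  if (p$e_m <= 0 || p$e_0 < 0 || p$e_eps < 0)
    stop("moduli must be positive", call. = FALSE)
  if (p$nu_m < 0 || p$nu_m >= 0.5)
    stop("nu_m must lie in [0, 0.5)", call. = FALSE)
  if (p$k_perm <= 0) stop("permeability must be positive", call. = FALSE)
  if (p$eta < 0) stop("eta must be non-negative", call. = FALSE)
  nf <- p$nf_surface - p$nf_slope * c(0, 1)
  if (any(nf <= 0) || any(nf >= 1))
    stop("fluid fraction must stay in (0, 1) over the depth", call. = FALSE)
  # 1e-15 m^4/(N s) = 1e-3 mm^4/(N s)
  p$k_perm_mm <- p$k_perm * 1e-3
  class(p) <- "frpve_params"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.frpve_params <- function(x, ...) {
  cat(sprintf(paste0("FRPVE parameters (%s cartilage):\n",
                     "  E_m = %.3f MPa, E_0 = %.3f MPa, E_eps = %.2f MPa, ",
                     "nu_m = %.2f\n  eta = %.0f MPa s, k = %.0f x 1e-15 ",
                     "m^4/(N s), n_f = %.2f - %.2f h_z\n"),
              x$tissue, x$e_m, x$e_0, x$e_eps, x$nu_m, x$eta, x$k_perm,
              x$nf_surface, x$nf_slope))
  invisible(x)
}

#' Load FRPVE parameters from a material configuration YAML
#'
#' The file must contain `femoral` and/or `tibial` blocks with the fields
#' of [frpve_params()]. The packaged default is at
#' `system.file("extdata", "materials.yaml", package = "cartatlas")`.
#'
#' @param path YAML path.
#' @return Named list of `frpve_params` (one per tissue block).
#' @export
read_material_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  for (tissue in intersect(names(cfg), c("femoral", "tibial"))) {
    b <- cfg[[tissue]]
    out[[tissue]] <- frpve_params(
      tissue, e_m = b$e_m, e_0 = b$e_0, e_eps = b$e_eps, nu_m = b$nu_m,
      eta = b$eta, k_perm = b$k_perm,
      nf_surface = b$nf_surface %||% 0.8, nf_slope = b$nf_slope %||% 0.15)
  }
  if (!length(out)) stop("no femoral/tibial block in ", path, call. = FALSE)
  out
}

#' Depth-dependent fluid fraction
#'
#' `n_f(h_z) = nf_surface - nf_slope * h_z`, by default `0.8 - 0.15 h_z`:
#' most fluid at the articular surface, decreasing linearly with depth.
#'
#' @param h_z Normalized depth in `[0, 1]` (0 = articular surface,
#'   1 = bone interface). Vectorized.
#' @param params An [frpve_params()] (defaults used if omitted).
#' @return Fluid volume fraction(s) in (0, 1).
#' @examples
#' fluid_fraction(c(0, 0.5, 1))
#' @export
fluid_fraction <- function(h_z, params = frpve_params()) {
  if (any(h_z < 0 | h_z > 1))
    stop("h_z must lie in [0, 1]", call. = FALSE)
  params$nf_surface - params$nf_slope * h_z
}

#' Primary fibril directions of the Benninghoff arcade
#'
#' Returns the two primary fibril directions at normalized depth `h_z`:
#' at the surface (`h_z = 0`) they run along the split line (one along
#' `+split_line`, one along `-split_line`); at the bone interface
#' (`h_z = 1`) both align with the surface normal; at intermediate depths
#' the directions blend continuously (normalized linear interpolation),
#' producing the arcade bend.
#'
#' @param h_z Normalized depth in `[0, 1]`.
#' @param split_line Unit vector tangent to the articular surface.
#' @param surface_normal Unit vector normal to the articular surface
#'   (pointing from surface into the tissue or out of it; only the axis
#'   matters). Must be orthogonal to `split_line` within `tol`.
#' @param tol Orthogonality/normality tolerance. Default `1e-6`.
#' @return A 2 x 3 matrix of unit row vectors.
#' @examples
#' primary_fibril_directions(0, c(1, 0, 0), c(0, 0, 1))
#' @export
primary_fibril_directions <- function(h_z, split_line, surface_normal,
                                      tol = 1e-6) {
  if (h_z < 0 || h_z > 1) stop("h_z must lie in [0, 1]", call. = FALSE)
  s <- as.numeric(split_line); n <- as.numeric(surface_normal)
  if (abs(sqrt(sum(s^2)) - 1) > tol || abs(sqrt(sum(n^2)) - 1) > tol)
    stop("split_line and surface_normal must be unit vectors", call. = FALSE)
  if (abs(sum(s * n)) > tol)
    stop("split_line must be orthogonal to surface_normal", call. = FALSE)
  d1 <- (1 - h_z) * s + h_z * n
  d2 <- (1 - h_z) * (-s) + h_z * n
  d1 <- d1 / sqrt(sum(d1^2))
  d2 <- d2 / sqrt(sum(d2^2))
  rbind(d1, d2, deparse.level = 0)
}

#' The 13 secondary fibril orientations
#'
#' A fixed, deterministic, quasi-uniform set of 13 unit directions on the
#' hemisphere (spherical Fibonacci lattice), standing in for the randomly
#' oriented secondary fibrils. No two directions are parallel.
#'
#' @return A 13 x 3 matrix of unit row vectors.
#' @export
secondary_fibril_directions <- function() {
  n <- 13L
  i <- seq_len(n)
  z <- (i - 0.5) / n                     # upper hemisphere only
  rho <- sqrt(1 - z^2)
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (i - 1)
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Tension-only viscoelastic fibril stress update
#'
#' One backward-Euler step of the fibril law documented in this file's
#' header: equilibrium spring `E_0 eps + E_eps eps^2` in parallel with a
#' Maxwell branch (tangent spring stiffness `E_0 + 2 E_eps eps`, damper
#' `eta`). Fibrils carry tension only: for `eps_f <= 0` the stress is zero
#' and the viscous overstress resets.
#'
#' @param eps_f Fibril strain at the end of the step (dimensionless).
#' @param state Internal state from the previous step: list with
#'   `eps_prev` and `sigma_ov` (use [fibril_state0()] to initialize).
#' @param dt Time step (s), > 0.
#' @param params An [frpve_params()].
#' @return List `stress` (MPa) and `state` (updated internal state).
#' @examples
#' st <- fibril_state0()
#' fibril_stress_update(0.05, st, dt = 1, params = frpve_params("tibial"))
#' @export
fibril_stress_update <- function(eps_f, state, dt, params) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (eps_f <= 0)
    return(list(stress = 0, state = list(eps_prev = eps_f, sigma_ov = 0)))
  k <- params$e_0 + 2 * params$e_eps * eps_f
  d_eps <- eps_f - max(state$eps_prev, 0)
  sigma_ov <- if (params$eta <= 0) 0 else
    (state$sigma_ov + k * d_eps) / (1 + k * dt / params$eta)
  sigma_eq <- params$e_0 * eps_f + params$e_eps * eps_f^2
  # tension-only also holds during viscous unloading
  list(stress = max(sigma_eq + sigma_ov, 0),
       state = list(eps_prev = eps_f, sigma_ov = sigma_ov))
}

#' @rdname fibril_stress_update
#' @export
fibril_state0 <- function() list(eps_prev = 0, sigma_ov = 0)

#' Equilibrium fibril stress of the adopted law
#' @param eps_f Fibril strain.
#' @param params An [frpve_params()].
#' @return `E_0 eps + E_eps eps^2` for tensile strain, else 0.
#' @export
fibril_equilibrium_stress <- function(eps_f, params) {
  ifelse(eps_f > 0, params$e_0 * eps_f + params$e_eps * eps_f^2, 0)
}

#' Nonfibrillar matrix stress (compressible neo-Hookean)
#'
#' Effective (Cauchy) stress of a compressible neo-Hookean solid with
#' small-strain moduli `(E_m, nu_m)`:
#' `sigma = mu/J (B - I) + lambda ln(J)/J I`, where `F = I + eps` is built
#' from the (small) symmetric strain tensor, `B = F F'`, `J = det F`. At
#' infinitesimal strain this reduces to linear isotropic elasticity.
#'
#' @param strain Symmetric 3 x 3 strain tensor.
#' @param params An [frpve_params()].
#' @return Symmetric 3 x 3 stress tensor (MPa).
#' @export
nonfibrillar_stress <- function(strain, params) {
  strain <- as.matrix(strain)
  if (max(abs(strain - t(strain))) > 1e-8)
    stop("strain must be symmetric", call. = FALSE)
  lam <- lame_lambda(params$e_m, params$nu_m)
  mu <- lame_mu(params$e_m, params$nu_m)
  F <- diag(3) + strain
  J <- det(F)
  if (J <= 0) stop("non-positive volume ratio", call. = FALSE)
  B <- F %*% F
  (mu * (B - diag(3)) + lam * log(J) * diag(3)) / J
}

lame_lambda <- function(E, nu) E * nu / ((1 + nu) * (1 - 2 * nu))
lame_mu <- function(E, nu) E / (2 * (1 + nu))

#' Material point state for the total-stress kernel
#'
#' @param strain Symmetric 3 x 3 strain tensor.
#' @param pore_pressure Interstitial fluid pressure p (MPa).
#' @param h_z Normalized depth in `[0, 1]`.
#' @param split_line,surface_normal Orthonormal surface frame vectors.
#' @param fibril_states Optional list of per-orientation internal states
#'   ([fibril_state0()] each); length 2 + n_secondary. Default: virgin.
#' @param secondary_dirs Optional replacement for the fixed secondary
#'   orientation set (e.g. a rotated copy); rows must be unit vectors.
#' @return A `material_point_state` list.
#' @export
material_point_state <- function(strain, pore_pressure = 0, h_z = 0,
                                 split_line = c(1, 0, 0),
                                 surface_normal = c(0, 0, 1),
                                 fibril_states = NULL,
                                 secondary_dirs = NULL) {
  structure(list(strain = as.matrix(strain), pore_pressure = pore_pressure,
                 h_z = h_z, split_line = as.numeric(split_line),
                 surface_normal = as.numeric(surface_normal),
                 fibril_states = fibril_states,
                 secondary_dirs = secondary_dirs),
            class = "material_point_state")
}

# fibril weights: 2 primary bundles at `ratio` density each, n secondary
# at unit density; normalized to sum 1
fibril_weights <- function(params) {
  r <- params$primary_density_ratio
  ns <- params$n_secondary
  tot <- 2 * r + ns
  c(rep(r / tot, 2L), rep(1 / tot, ns))
}

#' Total FRPVE stress at a material point
#'
#' Evaluates `sigma_t = sigma_nf + sigma_f - p I`: neo-Hookean matrix
#' stress, plus the sum over primary (arcade) and secondary fibril bundles
#' of their scalar tension-only viscoelastic stresses projected as
#' `sigma_i (d_i x d_i)` weighted by bundle density, minus the pore
#' pressure times the identity.
#'
#' @param state A [material_point_state()].
#' @param params An [frpve_params()].
#' @param dt Time step for the viscoelastic fibril update (s).
#' @return List: `stress` (3 x 3, MPa), `components` (list `nonfibrillar`,
#'   `fibril`, `pressure`), `fibril_states` (updated), `fibril_strains`
#'   (per-orientation scalar strains).
#' @export
total_stress <- function(state, params, dt = 1) {
  stopifnot(inherits(state, "material_point_state"))
  sec <- state$secondary_dirs %||%
    secondary_fibril_directions()[seq_len(params$n_secondary), ,
                                  drop = FALSE]
  dirs <- rbind(
    primary_fibril_directions(state$h_z, state$split_line,
                              state$surface_normal),
    sec)
  w <- fibril_weights(params)
  states <- state$fibril_states
  if (is.null(states))
    states <- replicate(nrow(dirs), fibril_state0(), simplify = FALSE)
  sig_f <- matrix(0, 3, 3)
  eps_f_all <- numeric(nrow(dirs))
  new_states <- vector("list", nrow(dirs))
  for (i in seq_len(nrow(dirs))) {
    d <- dirs[i, ]
    eps_f <- drop(d %*% state$strain %*% d)
    eps_f_all[i] <- eps_f
    upd <- fibril_stress_update(eps_f, states[[i]], dt, params)
    new_states[[i]] <- upd$state
    sig_f <- sig_f + w[i] * upd$stress * tcrossprod(d)
  }
  sig_nf <- nonfibrillar_stress(state$strain, params)
  press <- -state$pore_pressure * diag(3)
  list(stress = sig_nf + sig_f + press,
       components = list(nonfibrillar = sig_nf, fibril = sig_f,
                         pressure = press),
       fibril_states = new_states, fibril_strains = eps_f_all)
}
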