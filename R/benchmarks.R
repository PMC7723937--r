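# Verification benchmarks: one-dimensional consolidation.

#' Closed-form Terzaghi consolidation pore pressure
#'
#' Series solution for a laterally confined poroelastic column of height
#' `H`, drained at the top, sealed at the bottom, under a step total stress
#' `p0` applied at t = 0:
#' \deqn{p(z_d, t) = \sum_{m=0}^{\infty} \frac{4 p_0}{(2m+1)\pi}
#'   \sin\!\Big(\frac{(2m+1)\pi z_d}{2H}\Big)
#'   \exp\!\Big(-\frac{(2m+1)^2\pi^2}{4} T_v\Big)}
#' with depth `z_d` measured from the drained surface,
#' `T_v = c_v t / H^2` and consolidation coefficient
#' `c_v = k (lambda + 2 mu)`.
#'
#' @param z_d Depth(s) below the drained surface (mm).
#' @param t Time (s).
#' @param p0 Applied step stress (MPa).
#' @param c_v Consolidation coefficient (mm^2/s).
#' @param height Column height H (mm).
#' @param n_terms Series terms. Default 200.
#' @return Pore pressure(s), MPa.
#' @export
terzaghi_pressure <- function(z_d, t, p0, c_v, height, n_terms = 200L) {
  tv <- c_v * t / height^2
  m <- seq_len(n_terms) - 1L
  fac <- (2 * m + 1)
  out <- numeric(length(z_d))
  for (i in seq_along(z_d)) {
    out[i] <- sum(4 * p0 / (fac * pi) * sin(fac * pi * z_d[i] / (2 * height)) *
                    exp(-fac^2 * pi^2 / 4 * tv))
  }
  out
}

#' Consolidation coefficient of the nonfibrillar poroelastic limit
#' @param params An [frpve_params()].
#' @return `k (lambda + 2 mu)` in mm^2/s.
#' @export
consolidation_coefficient <- function(params) {
  params$k_perm_mm * (lame_lambda(params$e_m, params$nu_m) +
                        2 * lame_mu(params$e_m, params$nu_m))
}

#' Build a 1-D consolidation column problem
#'
#' A 1 x 1 x `n_elem` element column of unit cross-section, laterally
#' confined (zero normal displacement on the side faces), fixed at the
#' bottom, drained at the top only, with a step compressive traction
#' applied to the top face. Fibrils are disabled so the response is the
#' nonfibrillar poroelastic limit verified against
#' [terzaghi_pressure()].
#'
#' @param n_elem Elements through the height.
#' @param height Column height (mm). Default 1.
#' @param params An [frpve_params()]. Default tibial.
#' @param load_mpa Step traction magnitude (MPa, compressive).
#' @param times Time grid (s); default 60 log-spaced points spanning
#'   `T_v` from about 1e-3 to 1.5.
#' @param drained_top If `FALSE`, the top is sealed too (fully undrained
#'   column).
#' @param confined If `FALSE`, the side faces are left free (uniaxial
#'   stress column, used for undrained-limit checks).
#' @return An [fe_problem()].
#' @export
consolidation_column_problem <- function(n_elem = 20L, height = 1,
                                         params = frpve_params("tibial"),
                                         load_mpa = 0.01, times = NULL,
                                         drained_top = TRUE,
                                         confined = TRUE) {
  mesh <- hex_grid_mesh(1L, 1L, n_elem, lx = height / 4, ly = height / 4,
                        lz = height)
  if (is.null(times)) {
    cv <- consolidation_coefficient(params)
    t_char <- height^2 / cv
    times <- exp(seq(log(1e-3 * t_char), log(1.5 * t_char),
                     length.out = 60L))
  }
  dirichlet <- list(list(nodes = mesh$node_sets$zmin, dof = 3L, value = 0))
  if (confined) {
    dirichlet <- c(dirichlet, list(
      list(nodes = seq_len(nrow(mesh$nodes)), dof = 1L, value = 0),
      list(nodes = seq_len(nrow(mesh$nodes)), dof = 2L, value = 0)))
  } else {
    # symmetry rollers: uniform lateral expansion stays representable
    dirichlet <- c(dirichlet, list(
      list(nodes = mesh$node_sets$xmin, dof = 1L, value = 0),
      list(nodes = mesh$node_sets$ymin, dof = 2L, value = 0)))
  }
  fe_problem(mesh, params, fibrils_on = FALSE,
             dirichlet = dirichlet,
             drained_nodes = if (drained_top) mesh$node_sets$zmax
             else integer(),
             traction = list(nodes = mesh$node_sets$zmax,
                             pressure = rep(load_mpa, length(times))),
             time_grid = times)
}
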