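# Mixed displacement / pore-pressure poroelastic solver for hexahedral
# cartilage meshes with the FRPVE effective stress.
#
# Formulation (geometrically linear, Biot coefficient 1, incompressible
# constituents):
#   momentum:      div(sigma_eff) - grad p + t = 0
#   mass balance:  d/dt(div u) - div(k grad p) = 0
# discretized with equal-order trilinear u/p hexahedra (2x2x2 quadrature),
# backward-Euler time stepping and a Brezzi-Pitkaranta pressure-Laplacian
# stabilization (coefficient stab * h_e^2 / (lambda + 2 mu)) that controls
# the spurious pressure modes of the equal-order pair in the undrained
# limit. Each step solves
#   [ K   -Q  ] [du]   [ r_u ]
#   [ Q'  dtH+S ] [dp] = [ r_p ]
# by Newton iteration with a sparse LU factorization; K carries the
# neo-Hookean matrix tangent plus rank-one tension-only fibril tangents and
# any active contact penalty terms. Contact with the rigid femoral condyle
# is force-controlled through one extra unknown (the condyle height) whose
# residual balances the prescribed axial force.

#' Define a poroelastic finite-element problem
#'
#' @param mesh A [hex_mesh()].
#' @param params An [frpve_params()] applied to all elements.
#' @param fibrils_on If `FALSE`, the fibril network is disabled (nonfibrillar
#'   poroelastic limit, used for verification against closed-form
#'   consolidation solutions).
#' @param split_line_field m x 3 unit vectors (per element). Default +x.
#' @param dirichlet List of displacement constraints, each
#'   `list(nodes =, dof =, value = 0)` with `dof` in 1:3 (x,y,z).
#' @param drained_nodes Node indices with p = 0 (free-draining boundary).
#' @param traction Optional distributed load on the top (z+) faces of a node
#'   set: `list(nodes =, pressure =)` where `pressure` is a vector (MPa, one
#'   per time step, positive = compressive, applied along -z).
#' @param contact Optional rigid-condyle contact:
#'   `list(nodes =, force =, penalty =, condyle =, seal_contact = TRUE)`
#'   where `force` is the prescribed axial force per step (N),
#'   `penalty` in MPa/mm, and `condyle` a list with `radius` and per-step
#'   `center` (n_steps x 3 matrix or fixed xyz).
#' @param time_grid Strictly increasing times (s); the state starts from
#'   rest at t = 0.
#' @param surface_z,bottom_z z-coordinates of the articular surface and
#'   bone interface used for the normalized depth; default mesh z-range.
#' @param stab Stabilization coefficient (dimensionless). Default 0.25.
#' @param newton_tol Relative force residual tolerance. Default 1e-6.
#' @param newton_maxit Maximum Newton iterations per step. Default 40.
#' @return An `fe_problem` list.
#' @export
fe_problem <- function(mesh, params, fibrils_on = TRUE,
                       split_line_field = NULL,
                       dirichlet = list(), drained_nodes = integer(),
                       traction = NULL, contact = NULL,
                       time_grid, surface_z = NULL, bottom_z = NULL,
                       stab = 0.25, newton_tol = 1e-6, newton_maxit = 40L) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(params, "frpve_params"))
  if (any(diff(time_grid) <= 0) || any(time_grid <= 0))
    stop("time_grid must be strictly increasing and positive", call. = FALSE)
  if (is.null(split_line_field))
    split_line_field <- matrix(rep(c(1, 0, 0), each = nrow(mesh$elems)),
                               ncol = 3L)
  if (is.null(surface_z)) surface_z <- max(mesh$nodes[, 3])
  if (is.null(bottom_z)) bottom_z <- min(mesh$nodes[, 3])
  structure(list(mesh = mesh, params = params, fibrils_on = fibrils_on,
                 split_line_field = split_line_field,
                 dirichlet = dirichlet, drained_nodes = drained_nodes,
                 traction = traction, contact = contact,
                 time_grid = time_grid, surface_z = surface_z,
                 bottom_z = bottom_z, stab = stab,
                 newton_tol = newton_tol, newton_maxit = newton_maxit),
            class = "fe_problem")
}

# --- precomputation -------------------------------------------------------

fe_precompute <- function(prob) {
  mesh <- prob$mesh
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  gp <- hex_gauss()
  shp <- lapply(seq_len(8L), function(g)
    hex_shape(gp$points[g, 1], gp$points[g, 2], gp$points[g, 3]))
  ngp <- 8L * m
  w <- numeric(ngp)
  gpx <- matrix(0, ngp, 3L)
  elem_of_gp <- rep(seq_len(m), each = 8L)

  nB <- 0L; cap <- ngp * 24L * 3L
  Bi <- integer(cap); Bj <- integer(cap); Bx <- numeric(cap)
  Qi <- integer(0); Qj <- integer(0); Qx <- numeric(0)
  qi <- integer(ngp * 24L * 8L); qj <- integer(ngp * 24L * 8L)
  qx <- numeric(ngp * 24L * 8L); nq <- 0L
  hi <- integer(ngp * 64L); hj <- integer(ngp * 64L)
  hx <- numeric(ngp * 64L); sx <- numeric(ngp * 64L); nh <- 0L
  npi <- integer(ngp * 8L); npj <- integer(ngp * 8L)
  npx <- numeric(ngp * 8L); nn <- 0L

  lam <- lame_lambda(prob$params$e_m, prob$params$nu_m)
  mu <- lame_mu(prob$params$e_m, prob$params$nu_m)
  stab_scale <- prob$stab / (lam + 2 * mu)

  elem_vol <- numeric(m)
  for (e in seq_len(m)) {
    conn <- mesh$elems[e, ]
    X <- mesh$nodes[conn, , drop = FALSE]
    for (g in seq_len(8L)) {
      ig <- 8L * (e - 1L) + g
      J <- t(shp[[g]]$dN) %*% X
      dJ <- det(J)
      if (dJ <= 0) stop("non-positive Jacobian in element ", e, call. = FALSE)
      dNdx <- shp[[g]]$dN %*% solve(J)     # 8 x 3
      w[ig] <- dJ * gp$weights[g]
      elem_vol[e] <- elem_vol[e] + w[ig]
      gpx[ig, ] <- colSums(shp[[g]]$N * X)
      r0 <- 6L * (ig - 1L)
      for (a in seq_len(8L)) {
        cols <- 3L * (conn[a] - 1L) + 1:3
        # rows 1..3: normal strains; 4..6: engineering shears
        add <- rbind(c(r0 + 1L, cols[1], dNdx[a, 1]),
                     c(r0 + 2L, cols[2], dNdx[a, 2]),
                     c(r0 + 3L, cols[3], dNdx[a, 3]),
                     c(r0 + 4L, cols[1], dNdx[a, 2]),
                     c(r0 + 4L, cols[2], dNdx[a, 1]),
                     c(r0 + 5L, cols[1], dNdx[a, 3]),
                     c(r0 + 5L, cols[3], dNdx[a, 1]),
                     c(r0 + 6L, cols[2], dNdx[a, 3]),
                     c(r0 + 6L, cols[3], dNdx[a, 2]))
        idx <- nB + seq_len(nrow(add))
        Bi[idx] <- add[, 1]; Bj[idx] <- add[, 2]; Bx[idx] <- add[, 3]
        nB <- nB + nrow(add)
      }
      # coupling Q and pressure operators
      N <- shp[[g]]$N
      for (a in seq_len(8L)) for (d in 1:3) {
        rows <- 3L * (conn[a] - 1L) + d
        idx <- nq + seq_len(8L)
        qi[idx] <- rows; qj[idx] <- conn
        qx[idx] <- dNdx[a, d] * N * w[ig]
        nq <- nq + 8L
      }
      GG <- dNdx %*% t(dNdx) * w[ig]       # 8 x 8 grad-grad
      idx <- nh + seq_len(64L)
      hi[idx] <- rep(conn, times = 8L)
      hj[idx] <- rep(conn, each = 8L)
      hx[idx] <- as.vector(GG)
      sx[idx] <- as.vector(GG)             # scaled per element below
      nh <- nh + 64L
      idx <- nn + seq_len(8L)
      npi[idx] <- ig; npj[idx] <- conn; npx[idx] <- N
      nn <- nn + 8L
    }
  }
  # element-wise stabilization scale h_e^2
  h2 <- (elem_vol)^(2 / 3)
  sx[seq_len(nh)] <- sx[seq_len(nh)] *
    rep(h2[elem_of_gp], each = 64L)[seq_len(nh)] * stab_scale

  Bglob <- Matrix::sparseMatrix(i = Bi[1:nB], j = Bj[1:nB], x = Bx[1:nB],
                                dims = c(6L * ngp, 3L * n))
  Q <- Matrix::sparseMatrix(i = qi[1:nq], j = qj[1:nq], x = qx[1:nq],
                            dims = c(3L * n, n))
  H <- Matrix::sparseMatrix(i = hi[1:nh], j = hj[1:nh],
                            x = hx[1:nh] * prob$params$k_perm_mm,
                            dims = c(n, n))
  S <- Matrix::sparseMatrix(i = hi[1:nh], j = hj[1:nh], x = sx[1:nh],
                            dims = c(n, n))
  Np <- Matrix::sparseMatrix(i = npi[1:nn], j = npj[1:nn], x = npx[1:nn],
                             dims = c(ngp, n))

  # block-diagonal tangent sparsity pattern (36 entries per GP)
  di <- rep(6L * (seq_len(ngp) - 1L), each = 36L) + rep(rep(1:6, times = 6L), ngp)
  dj <- rep(6L * (seq_len(ngp) - 1L), each = 36L) + rep(rep(1:6, each = 6L), ngp)

  # fibril geometry per GP
  span <- prob$surface_z - prob$bottom_z
  h_z <- pmin(pmax((prob$surface_z - gpx[, 3]) / span, 0), 1)
  nd <- 2L + prob$params$n_secondary
  sec <- secondary_fibril_directions()[seq_len(prob$params$n_secondary), ,
                                       drop = FALSE]
  dirs <- array(0, c(ngp, nd, 3L))
  for (ig in seq_len(ngp)) {
    s <- prob$split_line_field[elem_of_gp[ig], ]
    s <- s - sum(s * c(0, 0, 1)) * c(0, 0, 1)      # project tangent to surface
    s <- s / sqrt(sum(s^2))
    pd <- primary_fibril_directions(h_z[ig], s, c(0, 0, 1))
    dirs[ig, 1:2, ] <- pd
    dirs[ig, 3:nd, ] <- sec
  }
  A_list <- vector("list", nd); M_list <- vector("list", nd)
  for (j in seq_len(nd)) {
    d <- dirs[, j, , drop = TRUE]
    if (is.null(dim(d))) d <- matrix(d, 1L)
    A_list[[j]] <- cbind(d[, 1]^2, d[, 2]^2, d[, 3]^2,
                         2 * d[, 1] * d[, 2], 2 * d[, 1] * d[, 3],
                         2 * d[, 2] * d[, 3])
    M_list[[j]] <- cbind(d[, 1]^2, d[, 2]^2, d[, 3]^2,
                         d[, 1] * d[, 2], d[, 1] * d[, 3],
                         d[, 2] * d[, 3])
  }
  # component-stacked views over all directions: Acomp[[c]] is ngp x nd
  Acomp <- lapply(1:6, function(cc)
    do.call(cbind, lapply(A_list, function(A) A[, cc])))
  Mcomp <- lapply(1:6, function(cc)
    do.call(cbind, lapply(M_list, function(M) M[, cc])))
  list(n = n, m = m, ngp = ngp, w = w, gpx = gpx, elem_of_gp = elem_of_gp,
       Bglob = Bglob, Q = Q, H = H, S = S, Np = Np, di = di, dj = dj,
       h_z = h_z, nd = nd, A_list = A_list, M_list = M_list,
       Acomp = Acomp, Mcomp = Mcomp,
       lam = lam, mu = mu, elem_vol = elem_vol)
}

# linear isotropic tangent in Voigt (engineering shear) form
elastic_D <- function(lam, mu) {
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# --- vectorized material evaluation --------------------------------------
# eps: 6 x ngp Voigt strains (engineering shears); states: list of
# eps_prev, sig_ov (ngp x nd). Returns effective stress (6 x ngp), tangent
# blocks (ngp x 36, row-major per GP? stored column-of-block order matching
# di/dj pattern), updated states, per-GP max tensile fibril strain.
frpve_eval <- function(eps, states, dt, params, pre, fibrils_on,
                       want_tangent = TRUE) {
  ngp <- pre$ngp
  lam <- pre$lam; mu <- pre$mu
  e11 <- eps[1, ]; e22 <- eps[2, ]; e33 <- eps[3, ]
  F12 <- eps[4, ] / 2; F13 <- eps[5, ] / 2; F23 <- eps[6, ] / 2
  F11 <- 1 + e11; F22 <- 1 + e22; F33 <- 1 + e33
  B11 <- F11^2 + F12^2 + F13^2
  B22 <- F12^2 + F22^2 + F23^2
  B33 <- F13^2 + F23^2 + F33^2
  B12 <- F11 * F12 + F12 * F22 + F13 * F23
  B13 <- F11 * F13 + F12 * F23 + F13 * F33
  B23 <- F12 * F13 + F22 * F23 + F23 * F33
  J <- F11 * (F22 * F33 - F23^2) - F12 * (F12 * F33 - F23 * F13) +
    F13 * (F12 * F23 - F22 * F13)
  if (any(J <= 0)) stop("element inversion (J <= 0)", call. = FALSE)
  lnJ <- log(J)
  sig <- rbind((mu * (B11 - 1) + lam * lnJ) / J,
               (mu * (B22 - 1) + lam * lnJ) / J,
               (mu * (B33 - 1) + lam * lnJ) / J,
               mu * B12 / J, mu * B13 / J, mu * B23 / J)

  Dvals <- NULL
  if (want_tangent) {
    # consistent compressible neo-Hookean spatial tangent, per GP:
    # D = (lam/J) 1x1 + 2 (mu - lam lnJ)/J I_sym  (Voigt, engineering shear)
    Dvals <- matrix(0, 36L, ngp)
    l_J <- lam / J
    m_J <- (mu - lam * lnJ) / J
    for (r in 1:3) for (cc in 1:3)
      Dvals[(cc - 1L) * 6L + r, ] <- l_J + if (r == cc) 2 * m_J else 0
    for (r in 4:6) Dvals[(r - 1L) * 6L + r, ] <- m_J
  }

  nd <- pre$nd
  new_eps_prev <- matrix(0, pre$ngp, nd)
  new_sig_ov <- matrix(0, pre$ngp, nd)
  fib_max <- numeric(pre$ngp)
  if (fibrils_on) {
    wts <- fibril_weights(params)
    wrow <- rep(wts, each = pre$ngp)
    # C1 regularization of the tension-only switch: the effective fibril
    # strain ramps in smoothly over eps_reg so the residual stays
    # continuously differentiable (Newton-friendly); above eps_reg the law
    # is the exact one shifted by eps_reg/2
    eps_reg <- 2e-3
    # fibril strains for every orientation at once (ngp x nd)
    EF <- pre$Acomp[[1]] * eps[1, ] + pre$Acomp[[2]] * eps[2, ] +
      pre$Acomp[[3]] * eps[3, ] + pre$Acomp[[4]] * eps[4, ] +
      pre$Acomp[[5]] * eps[5, ] + pre$Acomp[[6]] * eps[6, ]
    fib_max <- do.call(pmax, c(as.data.frame(EF), list(0)))
    pos <- EF > 0
    blend <- pos & (EF < eps_reg)
    full <- pos & !blend
    ef <- (EF - eps_reg / 2) * full + (EF * EF / (2 * eps_reg)) * blend
    new_eps_prev <- ef
    k <- params$e_0 + 2 * params$e_eps * ef
    d_eps <- ef - pmax(states$eps_prev, 0)
    if (params$eta > 0) {
      fac <- 1 / (1 + k * dt / params$eta)
      sov <- (states$sig_ov + k * d_eps) * fac
    } else {
      fac <- 0 * ef; sov <- 0 * ef
    }
    seq_ <- params$e_0 * ef + params$e_eps * ef * ef
    raw <- seq_ + sov
    # tension-only also during viscous unloading: total stress >= 0,
    # C1-blended over sig_reg (MPa) for Newton stability
    sig_reg <- 1e-3
    tot <- ifelse(raw <= 0, 0,
                  ifelse(raw < sig_reg, raw * raw / (2 * sig_reg),
                         raw - sig_reg / 2))
    sf <- tot * wrow * pos
    new_sig_ov <- sov * pos
    for (cc in 1:6)
      sig[cc, ] <- sig[cc, ] + rowSums(pre$Mcomp[[cc]] * sf)
    if (want_tangent) {
      dd <- blend * (EF / eps_reg) + full
      dd2 <- pmin(pmax(raw / sig_reg, 0), 1)
      # d sigma_f / d eps_f: equilibrium tangent k plus overstress branch
      # fac * (k + 2 E_eps d_eps) from the backward-Euler update, chained
      # through the regularization slopes dd and dd2
      gt <- pos * dd2 * wrow * dd *
        (k + fac * (k + 2 * params$e_eps * d_eps))
      for (r in 1:6) {
        gtM <- pre$Mcomp[[r]] * gt
        for (cc in 1:6) {
          Dvals[(cc - 1L) * 6L + r, ] <- Dvals[(cc - 1L) * 6L + r, ] +
            rowSums(gtM * pre$Acomp[[cc]])
        }
      }
    }
  }
  list(sig = sig, Dvals = Dvals,
       states = list(eps_prev = new_eps_prev, sig_ov = new_sig_ov),
       fibril_strain = fib_max)
}

# --- contact helpers ------------------------------------------------------

sphere_gap_terms <- function(nodes_xy, node_z, u_z, center, radius) {
  rho2 <- (nodes_xy[, 1] - center[1])^2 + (nodes_xy[, 2] - center[2])^2
  inside <- rho2 < (0.999 * radius)^2
  zs <- rep(Inf, length(node_z))
  zs[inside] <- center[3] - sqrt(radius^2 - rho2[inside])
  delta <- node_z + u_z - zs
  delta[!inside] <- -Inf
  delta
}

#' Evaluate rigid-surface penalty contact for a deformed state
#'
#' Computes, for the contact-candidate surface nodes of a mesh in a given
#' displacement state, the penetration against a rigid spherical
#' counter-surface, the resulting penalty tractions (compression only) and
#' per-node contact flags.
#'
#' @param mesh A [hex_mesh()] with a `contact_surface` node set.
#' @param u Nodal displacement matrix (n x 3, mm), or `NULL` for the
#'   reference state.
#' @param condyle List `radius` (mm), `center` (xyz, mm).
#' @param penalty Penalty stiffness (MPa/mm), > 0.
#' @return List: `nodes` (candidate node ids), `flags` (logical), `gap`
#'   (penetration, mm, positive where contacting), `traction` (MPa,
#'   compressive, per node), `force` (N, per node) and `total_force` (N).
#' @export
contact_step <- function(mesh, u = NULL, condyle, penalty) {
  if (penalty <= 0) stop("penalty must be positive", call. = FALSE)
  cs <- mesh$node_sets$contact_surface
  if (is.null(cs)) stop("mesh lacks a contact_surface set", call. = FALSE)
  sf <- surface_face_areas(mesh, cs)
  A <- sf$nodal_area[cs]
  uz <- if (is.null(u)) rep(0, length(cs)) else u[cs, 3]
  delta <- sphere_gap_terms(mesh$nodes[cs, 1:2, drop = FALSE],
                            mesh$nodes[cs, 3], uz,
                            condyle$center, condyle$radius)
  act <- is.finite(delta) & delta > 0
  gap <- ifelse(act, delta, 0)
  traction <- penalty * gap
  force <- traction * A
  list(nodes = cs, flags = act, gap = gap, traction = traction,
       force = force, total_force = sum(force))
}

# --- the solver -----------------------------------------------------------

#' Solve a poroelastic finite-element problem
#'
#' Implicit backward-Euler time marching of the coupled
#' displacement/pore-pressure system with the FRPVE effective stress,
#' Newton iteration at every step, optional distributed traction and
#' force-controlled rigid-condyle penalty contact.
#'
#' @param problem An [fe_problem()].
#' @param store_fields If `FALSE`, only nodal fields are kept (no
#'   per-integration-point tensors); saves memory.
#' @param verbose Print per-step convergence lines.
#' @return A `field_history` list: `time`, `U` (steps x nodes x 3, mm),
#'   `P` (steps x nodes, MPa), `stress` (steps x ngp x 6 total stress,
#'   Voigt 11,22,33,12,13,23, MPa), `strain` (same layout), `fibril_strain`
#'   (steps x ngp, max tensile strain over fibril orientations),
#'   `contact_flags` (steps x n_surface_nodes or NULL), `gp` metadata
#'   (coordinates, element of each point, weights), `condyle_z` (per-step
#'   condyle height when contact is active).
#' @export
solve_fe <- function(problem, store_fields = TRUE, verbose = FALSE) {
  stopifnot(inherits(problem, "fe_problem"))
  mesh <- problem$mesh
  pre <- fe_precompute(problem)
  n <- pre$n; ngp <- pre$ngp
  nu_dof <- 3L * n
  times <- problem$time_grid
  nsteps <- length(times)

  # displacement Dirichlet mask
  fixed_u <- rep(FALSE, nu_dof)
  for (bc in problem$dirichlet)
    fixed_u[3L * (bc$nodes - 1L) + bc$dof] <- TRUE
  free_u <- which(!fixed_u)

  # traction load vector pattern (unit surface pressure along -z)
  trac_f <- NULL
  if (!is.null(problem$traction)) {
    sf <- surface_face_areas(mesh, problem$traction$nodes)
    trac_f <- numeric(nu_dof)
    nz <- which(sf$nodal_area > 0)
    trac_f[3L * (nz - 1L) + 3L] <- -sf$nodal_area[nz]
  }

  # contact setup
  has_contact <- !is.null(problem$contact)
  if (has_contact) {
    ct <- problem$contact
    cs <- ct$nodes
    sfc <- surface_face_areas(mesh, cs)
    Acs <- sfc$nodal_area[cs]
    pen <- ct$penalty
    seal <- isTRUE(ct$seal_contact %||% TRUE)
    centers <- ct$condyle$center
    if (is.null(dim(centers)))
      centers <- matrix(rep(centers, each = nsteps), nsteps)
    radius <- ct$condyle$radius
    cs_zdof <- 3L * (cs - 1L) + 3L
    cs_xy <- mesh$nodes[cs, 1:2, drop = FALSE]
    cs_z <- mesh$nodes[cs, 3]
  }

  w6 <- rep(pre$w, each = 6L)
  w36 <- rep(pre$w, each = 36L)
  thickness <- max(problem$surface_z - problem$bottom_z, 1e-6)
  dmax <- 0.25 * thickness
  delta_r <- 0.005 * thickness        # contact regularization gap width
  # overall load scale of the schedule (for stagnation acceptance)
  ref_abs <- max(if (has_contact) max(abs(ct$force)) else 0,
                 if (!is.null(trac_f))
                   max(abs(problem$traction$pressure)) * sum(abs(trac_f))
                 else 0, 1e-6)

  # Inner Newton solve for one (sub)increment at a FIXED condyle height zc
  # (displacement-controlled contact); returns the converged state and the
  # total contact force, or NULL on failure.
  newton_increment <- function(u0, p0, states0, dt, trac_p, center, zc,
                               free_p, fixed_p, u_init = NULL,
                               p_init = NULL) {
    u <- u_init %||% u0; p <- p_init %||% p0
    f_ext0 <- numeric(nu_dof)
    if (!is.null(trac_f)) f_ext0 <- f_ext0 + trac_f * trac_p
    iu <- seq_along(free_u); ip <- length(free_u) + seq_along(free_p)
    want_contact <- has_contact && !is.na(zc)
    last_du <- NULL; last_dp <- 0; last_dzc <- 0
    res_accept <- Inf
    backtracks <- 0L
    act <- NULL; Fc_tot <- 0
    res_hist <- numeric(0)
    damp <- 1
    best <- NULL; best_rel <- Inf; best_abs <- Inf
    A_fact <- NULL; act_key <- NULL; res_last_it <- Inf
    for (iter in seq_len(problem$newton_maxit)) {
      mat <- NULL
      for (retry in 1:6) {
        eps <- matrix(as.numeric(pre$Bglob %*% u), 6L, ngp)
        mat <- tryCatch(frpve_eval(eps, states0, dt, problem$params, pre,
                                   problem$fibrils_on,
                                   want_tangent = FALSE),
                        error = function(e) NULL)
        if (!is.null(mat)) break
        if (is.null(last_du)) return(NULL)   # inversion from the start
        u <- u - 0.5 * last_du
        p[free_p] <- p[free_p] - 0.5 * last_dp
        last_du <- 0.5 * last_du; last_dp <- 0.5 * last_dp
      }
      if (is.null(mat)) return(NULL)
      f_int <- as.numeric(Matrix::crossprod(pre$Bglob,
                                            as.numeric(mat$sig) * w6))
      f_ext <- f_ext0
      if (want_contact) {
        delta <- sphere_gap_terms(cs_xy, cs_z, u[cs_zdof],
                                  c(center[1], center[2], zc), radius)
        act <- is.finite(delta) & delta > 0
        # C1-regularized penalty: traction ramps in quadratically over
        # delta_r so the contact residual is continuously differentiable
        d <- ifelse(act, delta, 0)
        tr <- ifelse(d < delta_r, pen * d * d / (2 * delta_r),
                     pen * (d - delta_r / 2))
        kc <- pen * pmin(d / delta_r, 1)
        fc <- -Acs * tr
        f_ext[cs_zdof] <- f_ext[cs_zdof] + fc
        Fc_tot <- -sum(fc)
      }
      r_u <- f_ext - f_int + as.numeric(pre$Q %*% p)
      r_p <- -(as.numeric(Matrix::crossprod(pre$Q, u - u0)) +
                 dt * as.numeric(pre$H %*% p) +
                 as.numeric(pre$S %*% (p - p0)))
      ref <- max(sum(abs(f_ext)), 1e-6)
      res_u <- sqrt(sum(r_u[free_u]^2))
      res_p <- sqrt(sum(r_p[free_p]^2))
      vol_ref <- max(sqrt(sum(as.numeric(Matrix::crossprod(pre$Q, u))^2)),
                     1e-8)
      ok_u <- res_u < problem$newton_tol * ref
      ok_p <- res_p < 1e-8 * max(1, vol_ref)
      if (verbose)
        message(sprintf("    iter %d: |r_u| %.3e |r_p| %.3e Fc %.3f",
                        iter, res_u, res_p, Fc_tot))
      flags <- if (has_contact) {
        if (want_contact) act else rep(FALSE, length(cs))
      } else NULL
      cand <- list(u = u, p = p, states = mat$states, eps = eps,
                   mat = mat, flags = flags, force = Fc_tot)
      if (ok_u && ok_p) return(cand)
      if (ok_p && res_u / ref < best_rel) {
        best <- cand; best_rel <- res_u / ref; best_abs <- res_u
      }
      # merit backtracking (divergent steps)
      if (!is.null(last_du) && res_u > 1.2 * res_accept &&
          backtracks < 4L) {
        u <- u - 0.5 * last_du
        p[free_p] <- p[free_p] - 0.5 * last_dp
        last_du <- 0.5 * last_du; last_dp <- 0.5 * last_dp
        backtracks <- backtracks + 1L
        next
      }
      res_accept <- res_u
      backtracks <- 0L
      # period-2 limit cycle (a nonsmooth tension/contact switch flipping
      # each iteration): damp subsequent increments to land on the kink
      res_hist <- c(res_hist, res_u)
      nh <- length(res_hist)
      if (nh >= 3L &&
          abs(res_hist[nh] - res_hist[nh - 2L]) < 0.05 * res_hist[nh] &&
          res_hist[nh] > 0.5 * res_hist[nh - 1L]) {
        damp <- max(damp * 0.5, 1 / 128)
      } else if (damp < 1) damp <- min(1, 2 * damp)
      # plateaued cycle with a near-balanced state: accept early
      if (nh >= 12L && !is.null(best) && best_rel < 2e-2 &&
          (best_rel < 1e-3 || best_abs < 1e-3 * ref_abs) &&
          max(res_hist[(nh - 5L):nh]) < 3 * min(res_hist[(nh - 5L):nh]))
        return(best)

      # modified Newton: rebuild and refactor the tangent only on the
      # first iteration, when convergence stalls, or when the contact
      # active set changes
      key <- if (want_contact) which(act) else integer()
      refresh <- is.null(A_fact) || res_u > 0.5 * res_last_it ||
        !identical(key, act_key)
      res_last_it <- res_u
      if (refresh) {
        tan_eval <- frpve_eval(eps, states0, dt, problem$params, pre,
                               problem$fibrils_on, want_tangent = TRUE)
        Dsp <- Matrix::sparseMatrix(i = pre$di, j = pre$dj,
                                    x = as.numeric(tan_eval$Dvals) * w36,
                                    dims = c(6L * ngp, 6L * ngp))
        K <- Matrix::crossprod(pre$Bglob, Dsp %*% pre$Bglob)
        if (want_contact && any(act)) {
          K <- K + Matrix::sparseMatrix(i = cs_zdof[act],
                                        j = cs_zdof[act],
                                        x = (kc * Acs)[act],
                                        dims = c(nu_dof, nu_dof))
        }
        App <- dt * pre$H + pre$S
        A <- rbind(cbind(K[free_u, free_u, drop = FALSE],
                         -pre$Q[free_u, free_p, drop = FALSE]),
                   cbind(Matrix::t(pre$Q)[free_p, free_u, drop = FALSE],
                         App[free_p, free_p, drop = FALSE]))
        A_fact <- tryCatch(Matrix::lu(A),
                           error = function(e)
                             stop("singular system (check constraints ",
                                  "remove all rigid-body modes): ",
                                  conditionMessage(e), call. = FALSE))
        act_key <- key
      }
      rhs <- c(r_u[free_u], r_p[free_p])
      dx <- tryCatch(as.numeric(Matrix::solve(A_fact, rhs)),
                     error = function(e)
                       stop("singular system (check constraints remove ",
                            "all rigid-body modes): ",
                            conditionMessage(e), call. = FALSE))
      mx <- max(abs(dx[iu]))
      sc <- damp * (if (mx > dmax) dmax / mx else 1)
      du_full <- numeric(nu_dof)
      du_full[free_u] <- sc * dx[iu]
      u <- u + du_full
      last_dp <- sc * dx[ip]
      p[free_p] <- p[free_p] + last_dp
      p[fixed_p] <- 0
      last_du <- du_full
    }
    # stagnation acceptance: a nonsmooth tension/contact switch can trap
    # the iteration in a small limit cycle around the solution; accept the
    # best iterate if its force imbalance is below 1e-3 of the current
    # load or 1e-4 of the schedule's peak load
    if (!is.null(best) && best_rel < 2e-2 &&
        (best_rel < 1e-3 || best_abs < 1e-3 * ref_abs)) return(best)
    NULL
  }

  # Outer loop for force-controlled contact: secant/bisection on the
  # condyle height until the total contact force matches the target.
  # slope_mem / F_mem remember the local force-height slope across steps
  # so the first trial height usually lands within tolerance.
  slope_mem <- NA_real_; F_mem <- NA_real_
  solve_contact_increment <- function(u0, p0, states0, dt, trac_p,
                                      F_target, center, zc_warm,
                                      free_p, fixed_p) {
    rho2 <- (cs_xy[, 1] - center[1])^2 + (cs_xy[, 2] - center[2])^2
    inside <- rho2 < (0.999 * radius)^2
    if (!any(inside)) stop("condyle does not cover the mesh", call. = FALSE)
    seat <- function(uz, dbar) {
      reach <- (cs_z + uz)[inside] + sqrt(radius^2 - rho2[inside])
      max(reach) - dbar
    }
    ftol <- max(1e-3 * F_target, 1e-3)
    zc_a <- if (!is.na(zc_warm)) {
      if (!is.na(slope_mem) && !is.na(F_mem) && abs(slope_mem) > 1e-8) {
        dz0 <- (F_target - F_mem) / slope_mem
        zc_warm + sign(dz0) * min(abs(dz0), 0.1 * thickness)
      } else zc_warm
    } else seat(u0[cs_zdof], F_target / (pen * sum(Acs)))
    res_a <- newton_increment(u0, p0, states0, dt, trac_p, center, zc_a,
                              free_p, fixed_p)
    if (is.null(res_a)) return(NULL)
    if (abs(res_a$force - F_target) <= ftol) {
      F_mem <<- res_a$force
      return(c(res_a, list(zc = zc_a)))
    }
    # second point: shift by an estimate of the needed extra penetration
    slope0 <- pen * sum(Acs[inside])
    dz <- -(F_target - res_a$force) / slope0
    dz <- sign(dz) * min(abs(dz), 0.05 * thickness)
    if (dz == 0) dz <- -0.01 * thickness
    zc_b <- zc_a + dz
    res_b <- newton_increment(u0, p0, states0, dt, trac_p, center, zc_b,
                              free_p, fixed_p, res_a$u, res_a$p)
    if (is.null(res_b)) return(NULL)
    # bracket bookkeeping on g(zc) = F(zc) - F_target (decreasing in zc)
    lo <- NA_real_; hi <- NA_real_     # zc with g >= 0 (lo) and g <= 0 (hi)
    note <- function(zc, g) {
      if (g >= 0 && (is.na(lo) || zc > lo)) lo <<- zc
      if (g <= 0 && (is.na(hi) || zc < hi)) hi <<- zc
    }
    note(zc_a, res_a$force - F_target)
    note(zc_b, res_b$force - F_target)
    for (it in seq_len(30L)) {
      g_a <- res_a$force - F_target; g_b <- res_b$force - F_target
      if (verbose)
        message(sprintf("  outer %d: zc %.5f F %.3f (target %.3f)", it,
                        zc_b, res_b$force, F_target))
      if (abs(g_b) <= ftol) {
        if (abs(zc_b - zc_a) > 1e-12)
          slope_mem <<- (res_b$force - res_a$force) / (zc_b - zc_a)
        F_mem <<- res_b$force
        return(c(res_b, list(zc = zc_b)))
      }
      zc_c <- if (abs(g_b - g_a) > 1e-12)
        zc_b - g_b * (zc_b - zc_a) / (g_b - g_a)
      else zc_b - sign(g_b) * 0.05 * thickness
      if (!is.na(lo) && !is.na(hi)) {      # keep inside the bracket
        if (zc_c <= min(lo, hi) || zc_c >= max(lo, hi))
          zc_c <- (lo + hi) / 2
      }
      step_cap <- 0.1 * thickness
      if (abs(zc_c - zc_b) > step_cap)
        zc_c <- zc_b + sign(zc_c - zc_b) * step_cap
      res_c <- newton_increment(u0, p0, states0, dt, trac_p, center, zc_c,
                                free_p, fixed_p, res_b$u, res_b$p)
      if (is.null(res_c)) return(NULL)
      note(zc_c, res_c$force - F_target)
      zc_a <- zc_b; res_a <- res_b
      zc_b <- zc_c; res_b <- res_c
    }
    NULL
  }

  u <- numeric(nu_dof); p <- numeric(n)
  states <- list(eps_prev = matrix(0, ngp, pre$nd),
                 sig_ov = matrix(0, ngp, pre$nd))
  U <- array(0, c(nsteps, n, 3L)); P <- matrix(0, nsteps, n)
  stress_h <- if (store_fields) array(0, c(nsteps, ngp, 6L)) else NULL
  strain_h <- if (store_fields) array(0, c(nsteps, ngp, 6L)) else NULL
  fib_h <- if (store_fields) matrix(0, nsteps, ngp) else NULL
  flags_h <- if (has_contact) matrix(FALSE, nsteps, length(cs)) else NULL
  condyle_z <- rep(NA_real_, nsteps)
  contact_force <- rep(NA_real_, nsteps)
  prev_flags <- if (has_contact) rep(FALSE, length(cs)) else NULL

  t_prev <- 0
  trac_prev <- 0; F_prev <- 0
  center_prev <- if (has_contact) centers[1, ] else c(0, 0, 0)
  zc_warm <- NA_real_
  for (step in seq_len(nsteps)) {
    dt_full <- times[step] - t_prev
    t_prev <- times[step]
    trac_now <- if (!is.null(trac_f)) problem$traction$pressure[step] else 0
    F_now <- if (has_contact) ct$force[step] else 0
    center_now <- if (has_contact) centers[step, ] else c(0, 0, 0)

    # drained set for this step (contact patch of the previous step seals)
    drained <- problem$drained_nodes
    if (has_contact && seal) drained <- setdiff(drained, cs[prev_flags])
    fixed_p <- rep(FALSE, n); fixed_p[drained] <- TRUE
    free_p <- which(!fixed_p)

    # adaptive sub-incrementation of the step's load/time
    frac_done <- 0; frac <- 1
    flags_step <- prev_flags
    eps_conv <- NULL; mat_conv <- NULL
    repeat {
      f1 <- frac_done + frac
      trac_t <- trac_prev + f1 * (trac_now - trac_prev)
      F_t <- F_prev + f1 * (F_now - F_prev)
      cen_t <- center_prev + f1 * (center_now - center_prev)
      res <- if (has_contact && F_t > 0)
        solve_contact_increment(u, p, states, dt_full * frac, trac_t,
                                F_t, cen_t, zc_warm, free_p, fixed_p)
      else
        newton_increment(u, p, states, dt_full * frac, trac_t, cen_t,
                         NA_real_, free_p, fixed_p)
      if (!is.null(res)) {
        u <- res$u; p <- res$p; states <- res$states
        if (!is.null(res$zc)) zc_warm <- res$zc
        force_step <- res$force
        flags_step <- res$flags
        eps_conv <- res$eps; mat_conv <- res$mat
        frac_done <- f1
        if (frac_done >= 1 - 1e-12) break
        frac <- min(2 * frac, 1 - frac_done)
      } else {
        frac <- frac / 2
        if (frac < 1 / 64)
          stop(sprintf(
            "Newton failed to converge at step %d (t = %.4g s) even with load sub-incrementation",
            step, times[step]), call. = FALSE)
      }
    }
    if (verbose)
      message(sprintf("step %d converged (t = %.4g s)", step, times[step]))

    trac_prev <- trac_now; F_prev <- F_now; center_prev <- center_now
    U[step, , ] <- matrix(u, n, 3L, byrow = TRUE)
    P[step, ] <- p
    if (store_fields) {
      # eps_conv / mat_conv correspond to the converged u and the
      # previous-substep internal state (no double update)
      p_gp <- as.numeric(pre$Np %*% p)
      sig_tot <- mat_conv$sig
      sig_tot[1:3, ] <- sig_tot[1:3, ] - rep(p_gp, each = 3L)
      stress_h[step, , ] <- t(sig_tot)
      strain_h[step, , ] <- t(eps_conv)
      fib_h[step, ] <- mat_conv$fibril_strain
    }
    if (has_contact) {
      prev_flags <- flags_step %||% rep(FALSE, length(cs))
      flags_h[step, ] <- prev_flags
      condyle_z[step] <- zc_warm
      contact_force[step] <- force_step
    }
  }

  structure(list(time = times, U = U, P = P, stress = stress_h,
                 strain = strain_h, fibril_strain = fib_h,
                 contact_flags = flags_h,
                 contact_nodes = if (has_contact) cs else NULL,
                 condyle_z = condyle_z, contact_force = contact_force,
                 mesh = mesh,
                 gp = list(x = pre$gpx, elem = pre$elem_of_gp, w = pre$w,
                           h_z = pre$h_z)),
            class = "field_history")
}

#' @export
print.field_history <- function(x, ...) {
  cat(sprintf("Field history: %d steps, %d nodes, %d integration points\n",
              length(x$time), dim(x$U)[2], length(x$gp$w)))
  invisible(x)
}
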