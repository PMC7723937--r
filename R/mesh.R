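# Hexahedral mesh container and structured-grid generator.
#
# Meshes are lists with:
#   nodes     n x 3 numeric matrix (mm)
#   elems     m x 8 integer matrix, 1-based node indices, VTK hexahedron
#             corner ordering: (-,-,-),(+,-,-),(+,+,-),(-,+,-) then the
#             z+ face in the same cycle
#   node_sets named list of integer vectors
# On disk (atlas JSON / VTK) connectivity is 0-based; in R it is 1-based.

#' Construct a hexahedral mesh object
#'
#' @param nodes Numeric n x 3 matrix of coordinates (mm).
#' @param elems Integer m x 8 matrix of 1-based node indices in VTK
#'   hexahedron ordering.
#' @param node_sets Named list of integer node-index vectors.
#' @return A `hex_mesh` object.
#' @export
hex_mesh <- function(nodes, elems, node_sets = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must be n x 3", call. = FALSE)
  if (ncol(elems) != 8L) stop("elems must be m x 8", call. = FALSE)
  if (min(elems) < 1L || max(elems) > nrow(nodes))
    stop("element connectivity indices out of range", call. = FALSE)
  for (s in node_sets)
    if (length(s) && (min(s) < 1L || max(s) > nrow(nodes)))
      stop("node set index out of range", call. = FALSE)
  structure(list(nodes = nodes, elems = elems, node_sets = node_sets),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("Hexahedral mesh: %d nodes, %d elements, sets: %s\n",
              nrow(x$nodes), nrow(x$elems),
              paste(names(x$node_sets), collapse = ", ")))
  invisible(x)
}

#' Structured hexahedral grid on a box
#'
#' Builds an `nx * ny * nz` element grid spanning
#' `[x0, x0+lx] x [y0, y0+ly] x [z0, z0+lz]`, with standard face node sets
#' (`xmin`, `xmax`, `ymin`, `ymax`, `zmin`, `zmax`).
#'
#' @param nx,ny,nz Element counts per axis.
#' @param lx,ly,lz Box edge lengths (mm).
#' @param x0,y0,z0 Box corner (mm).
#' @return A [hex_mesh()].
#' @export
hex_grid_mesh <- function(nx, ny, nz, lx, ly, lz, x0 = 0, y0 = 0, z0 = 0) {
  xs <- x0 + seq(0, lx, length.out = nx + 1L)
  ys <- y0 + seq(0, ly, length.out = ny + 1L)
  zs <- z0 + seq(0, lz, length.out = nz + 1L)
  # node index (i,j,k) -> linear, i fastest
  nid <- function(i, j, k) i + (nx + 1L) * (j - 1L) + (nx + 1L) * (ny + 1L) * (k - 1L)
  grid <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
  nodes <- as.matrix(grid)
  dimnames(nodes) <- NULL
  elems <- matrix(0L, nx * ny * nz, 8L)
  e <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    e <- e + 1L
    elems[e, ] <- c(nid(i, j, k),     nid(i + 1L, j, k),
                    nid(i + 1L, j + 1L, k), nid(i, j + 1L, k),
                    nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                    nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))
  }
  tol <- 1e-9 * max(lx, ly, lz)
  sets <- list(
    xmin = which(abs(nodes[, 1] - xs[1]) < tol),
    xmax = which(abs(nodes[, 1] - xs[nx + 1L]) < tol),
    ymin = which(abs(nodes[, 2] - ys[1]) < tol),
    ymax = which(abs(nodes[, 2] - ys[ny + 1L]) < tol),
    zmin = which(abs(nodes[, 3] - zs[1]) < tol),
    zmax = which(abs(nodes[, 3] - zs[nz + 1L]) < tol))
  hex_mesh(nodes, elems, sets)
}

# Gauss 2x2x2 points/weights in natural coordinates
hex_gauss <- function() {
  g <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
  dimnames(pts) <- NULL
  list(points = pts, weights = rep(1, 8))
}

# corner signs matching hex node ordering
hex_corner_signs <- function() {
  rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
        c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
}

# shape functions and natural-coordinate gradients at (xi, eta, zeta)
hex_shape <- function(xi, eta, zeta) {
  s <- hex_corner_signs()
  N <- (1 + s[, 1] * xi) * (1 + s[, 2] * eta) * (1 + s[, 3] * zeta) / 8
  dN <- cbind(
    s[, 1] * (1 + s[, 2] * eta) * (1 + s[, 3] * zeta),
    s[, 2] * (1 + s[, 1] * xi) * (1 + s[, 3] * zeta),
    s[, 3] * (1 + s[, 1] * xi) * (1 + s[, 2] * eta)) / 8
  list(N = N, dN = dN)
}

#' Isoparametric Jacobian determinants of a hexahedral mesh
#'
#' Evaluates det(J) at the 2x2x2 Gauss points of every element. Positive
#' determinants everywhere indicate valid (non-inverted) elements.
#'
#' @param mesh A [hex_mesh()].
#' @return An m x 8 matrix of determinants (mm^3 per natural volume).
#' @export
mesh_jacobians <- function(mesh) {
  gp <- hex_gauss()
  m <- nrow(mesh$elems)
  out <- matrix(NA_real_, m, 8L)
  shp <- lapply(seq_len(8L), function(g)
    hex_shape(gp$points[g, 1], gp$points[g, 2], gp$points[g, 3]))
  for (e in seq_len(m)) {
    X <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    for (g in seq_len(8L)) {
      J <- t(shp[[g]]$dN) %*% X
      out[e, g] <- det(J)
    }
  }
  out
}

# areas of the z+ face of each element in a set (two-triangle rule),
# plus nodal tributary areas over the given surface node set
surface_face_areas <- function(mesh, surface_nodes) {
  in_surf <- rep(FALSE, nrow(mesh$nodes))
  in_surf[surface_nodes] <- TRUE
  top <- mesh$elems[, 5:8, drop = FALSE]     # z+ face nodes
  on_surf <- rowSums(matrix(in_surf[top], ncol = 4L)) == 4L
  elems <- which(on_surf)
  area <- numeric(length(elems))
  nodal <- numeric(nrow(mesh$nodes))
  tri_area <- function(a, b, c) {
    v <- cross3(b - a, c - a)
    0.5 * sqrt(sum(v^2))
  }
  for (i in seq_along(elems)) {
    f <- top[elems[i], ]
    P <- mesh$nodes[f, , drop = FALSE]
    A <- tri_area(P[1, ], P[2, ], P[3, ]) + tri_area(P[1, ], P[3, ], P[4, ])
    area[i] <- A
    nodal[f] <- nodal[f] + A / 4
  }
  list(elems = elems, face_nodes = top[elems, , drop = FALSE],
       areas = area, nodal_area = nodal)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
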