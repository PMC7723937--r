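# Mesh and atlas serialization.
#
# Meshes travel as legacy ASCII VTK unstructured grids (cell type 12,
# hexahedron); written by hand since no installed R package reads or writes
# unstructured VTK. Atlas metadata travels as JSON with 0-based node-set
# indices (connectivity inside the VTK file is 0-based by format).

#' Write a hexahedral mesh as legacy ASCII VTK
#'
#' @param mesh A [hex_mesh()]. Node sets are not stored in the VTK file;
#'   use [write_atlas()] for the full atlas container.
#' @param path Output `.vtk` path.
#' @param title Dataset title line.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, title = "cartatlas mesh") {
  stopifnot(inherits(mesh, "hex_mesh"))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(format(mesh$nodes, digits = 17, trim = TRUE,
                          scientific = FALSE), 1L, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", m, 9L * m), con)
  writeLines(apply(cbind(8L, mesh$elems - 1L), 1L, paste, collapse = " "), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("12", m), con)
  invisible(path)
}

#' Read a legacy ASCII VTK hexahedral mesh
#'
#' Minimal reader for the files produced by [write_vtk()] (POINTS + CELLS
#' with hexahedra only).
#'
#' @param path `.vtk` file path.
#' @return A [hex_mesh()] (without node sets).
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- scan(text = lines[(ip + 1L):(ip + n)], quiet = TRUE)
  nodes <- matrix(pts, n, 3L, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cl <- scan(text = lines[(ic + 1L):(ic + m)], quiet = TRUE)
  cl <- matrix(cl, m, 9L, byrow = TRUE)
  if (any(cl[, 1] != 8L)) stop("only hexahedral cells supported", call. = FALSE)
  hex_mesh(nodes, cl[, 2:9, drop = FALSE] + 1L)
}

#' Write a template atlas to a directory
#'
#' Creates `mesh.vtk` plus `atlas.json` (id, dimensions, meniscus fraction,
#' condyle, 0-based node sets, split-line field).
#'
#' @param atlas A [template_atlas()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "template_atlas"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vtk(atlas$mesh, file.path(dir, "mesh.vtk"), atlas$atlas_id)
  meta <- list(
    atlas_id = atlas$atlas_id,
    dims = as.list(unclass(atlas$dims)),
    meniscus_fraction = atlas$meniscus_fraction,
    condyle = atlas$condyle,
    node_sets = lapply(atlas$mesh$node_sets, function(s) as.integer(s - 1L)),
    split_line_field = unname(apply(atlas$split_line_field, 1L, c,
                                    simplify = FALSE)))
  jsonlite::write_json(meta, file.path(dir, "atlas.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a template atlas from a directory
#' @param dir Directory written by [write_atlas()].
#' @return A [template_atlas()].
#' @export
read_atlas <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "atlas.json"),
                              simplifyVector = TRUE)
  mesh <- read_vtk(file.path(dir, "mesh.vtk"))
  sets <- lapply(meta$node_sets, function(s) as.integer(s) + 1L)
  mesh <- hex_mesh(mesh$nodes, mesh$elems, sets)
  slf <- meta$split_line_field
  if (is.list(slf)) slf <- do.call(rbind, slf)
  template_atlas(meta$atlas_id, mesh, as_anat_dims(meta$dims),
                 meta$meniscus_fraction, slf,
                 list(radius = meta$condyle$radius,
                      center = as.numeric(meta$condyle$center)))
}

#' Write an atlas library (one subdirectory per template plus an index)
#' @param library An [atlas_library()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_atlas_library <- function(library, dir) {
  stopifnot(inherits(library, "atlas_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(library$atlases, function(a) a$atlas_id, "")
  for (a in library$atlases) write_atlas(a, file.path(dir, a$atlas_id))
  jsonlite::write_json(list(atlases = ids),
                       file.path(dir, "library.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read an atlas library directory
#' @param dir Directory written by [write_atlas_library()].
#' @return An [atlas_library()].
#' @export
read_atlas_library <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "library.json"),
                             simplifyVector = TRUE)
  atlas_library(lapply(idx$atlases, function(id)
    read_atlas(file.path(dir, id))))
}

#' Save / load a simulated field history
#'
#' Field histories are multi-gigabyte-unfriendly nested arrays; they are
#' stored in R's native serialization.
#'
#' @param history A `field_history` from [solve_fe()] or [run_gait()].
#' @param path `.rds` path.
#' @return `path` (save) or the history (load).
#' @export
save_history <- function(history, path) {
  saveRDS(history, path)
  invisible(path)
}

#' @rdname save_history
#' @export
load_history <- function(path) readRDS(path)
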