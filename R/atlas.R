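#' Template atlas: a mesh plus its anatomical dimensions
#'
#' A template atlas couples a hexahedral cartilage mesh of the medial
#' tibial compartment with the anatomical dimensions of the knee it was
#' built from, the fraction of compartment load carried by the meniscus,
#' a per-element split-line direction field, and the parameters of the
#' rigid femoral condyle counter-surface used for contact.
#'
#' @param atlas_id Character identifier (unique within a library).
#' @param mesh A [hex_mesh()] with node sets `tibial_cartilage`,
#'   `tibial_bottom` and `contact_surface` (a `femoral_cartilage` set may be
#'   present when a femoral layer is meshed).
#' @param dims [anat_dims()] of the template knee.
#' @param meniscus_fraction Fraction of compartment load carried by the
#'   meniscus, in `[0, 1)`.
#' @param split_line_field m x 3 matrix of per-element unit vectors
#'   (superficial collagen split-line directions). Default: anterior-
#'   posterior (+x) for every element.
#' @param condyle Optional list describing the rigid femoral counter-surface:
#'   `radius` (mm) and `center` (xyz, mm). When `NULL` a sphere is placed
#'   over the mesh centroid with radius `8 * ap_medial` (a conforming, nearly flat surface emulating meniscus-supported cartilage-on-cartilage contact).
#' @return A `template_atlas` object.
#' @export
template_atlas <- function(atlas_id, mesh, dims, meniscus_fraction = 0,
                           split_line_field = NULL, condyle = NULL) {
  stopifnot(inherits(mesh, "hex_mesh"))
  dims <- as_anat_dims(dims)
  if (!is.character(atlas_id) || length(atlas_id) != 1L)
    stop("atlas_id must be a single string", call. = FALSE)
  if (meniscus_fraction < 0 || meniscus_fraction >= 1)
    stop("meniscus_fraction must lie in [0, 1)", call. = FALSE)
  need <- c("tibial_cartilage", "tibial_bottom", "contact_surface")
  miss <- setdiff(need, names(mesh$node_sets))
  if (length(miss))
    stop("mesh lacks node sets: ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- nrow(mesh$elems)
  if (is.null(split_line_field))
    split_line_field <- matrix(rep(c(1, 0, 0), each = m), m, 3L)
  split_line_field <- as.matrix(split_line_field)
  if (nrow(split_line_field) != m || ncol(split_line_field) != 3L)
    stop("split_line_field must be m x 3", call. = FALSE)
  nrm <- sqrt(rowSums(split_line_field^2))
  if (any(nrm < 1e-12)) stop("zero split-line vector", call. = FALSE)
  split_line_field <- split_line_field / nrm
  if (is.null(condyle)) {
    cs <- mesh$node_sets$contact_surface
    ctr <- colMeans(mesh$nodes[cs, , drop = FALSE])
    r <- 8 * dims[["ap_medial"]]
    condyle <- list(radius = r, center = c(ctr[1], ctr[2], max(mesh$nodes[cs, 3]) + r))
  }
  structure(list(atlas_id = atlas_id, mesh = mesh, dims = dims,
                 meniscus_fraction = meniscus_fraction,
                 split_line_field = split_line_field, condyle = condyle),
            class = "template_atlas")
}

#' @export
print.template_atlas <- function(x, ...) {
  cat(sprintf("Template atlas '%s': %d nodes, %d elements, meniscus fraction %.3f\n",
              x$atlas_id, nrow(x$mesh$nodes), nrow(x$mesh$elems),
              x$meniscus_fraction))
  print(x$dims)
  invisible(x)
}

#' Atlas library
#'
#' An ordered collection of [template_atlas()] objects with unique ids.
#' Order matters: RMSE ties in [match_template()] are broken by library
#' position.
#'
#' @param atlases List of `template_atlas` objects.
#' @return An `atlas_library` object.
#' @export
atlas_library <- function(atlases) {
  if (!length(atlases)) stop("atlas library must be non-empty", call. = FALSE)
  if (!all(vapply(atlases, inherits, TRUE, "template_atlas")))
    stop("all entries must be template_atlas objects", call. = FALSE)
  ids <- vapply(atlases, function(a) a$atlas_id, "")
  if (anyDuplicated(ids)) stop("atlas ids must be unique", call. = FALSE)
  structure(list(atlases = atlases), class = "atlas_library")
}

#' @export
print.atlas_library <- function(x, ...) {
  cat(sprintf("Atlas library with %d templates: %s\n", length(x$atlases),
              paste(vapply(x$atlases, function(a) a$atlas_id, ""),
                    collapse = ", ")))
  invisible(x)
}

#' Mean meniscus support fraction of a library
#' @param library An [atlas_library()].
#' @return Mean of the per-template meniscus fractions.
#' @export
library_meniscus_fraction <- function(library) {
  stopifnot(inherits(library, "atlas_library"))
  mean(vapply(library$atlases, function(a) a$meniscus_fraction, 0))
}

#' Rank atlas templates by normalized-dimension RMSE
#'
#' Compares a subject's normalized dimensions against every template in the
#' library and ranks templates by root mean square error over the five
#' normalized fields. Because both subject and template have ML normalized
#' to 1, the ML term contributes exactly zero. The first row is the
#' selected template; ties keep library order.
#'
#' @param subject Subject dimensions: [anat_dims()] or [normalize_dimensions()]
#'   output (raw dimensions are normalized internally).
#' @param library An [atlas_library()].
#' @return A data.frame `atlas_id`, `rmse`, sorted ascending by `rmse`.
#' @examples
#' lib <- gen_atlas_library(fixture_spec(seed = 1, n_atlases = 3))
#' match_template(anat_dims(80, 53, 62, 3.8, 5.4), lib)
#' @export
match_template <- function(subject, library) {
  stopifnot(inherits(library, "atlas_library"))
  sn <- if (inherits(subject, "norm_dims")) subject else
    normalize_dimensions(subject)
  sv <- unclass(sn)
  rmse <- vapply(library$atlases, function(a) {
    av <- unclass(normalize_dimensions(a$dims))
    sqrt(mean((sv - av)^2))
  }, 0)
  ids <- vapply(library$atlases, function(a) a$atlas_id, "")
  ord <- order(rmse)                       # stable: preserves library order on ties
  data.frame(atlas_id = ids[ord], rmse = rmse[ord],
             stringsAsFactors = FALSE)
}

#' Scale a template atlas to a subject's dimensions
#'
#' Applies the axis-aligned affine map
#' `x' = origin + diag(sx, sy, sz) (x - origin)` to every node, with
#' `sx = subject$ap_medial / atlas$dims$ap_medial` (anterior-posterior),
#' `sy = subject$ml / atlas$dims$ml` (medial-lateral) and
#' `sz = subject$jsw_medial / atlas$dims$jsw_medial` (thickness). Only the
#' medial dimensions govern scaling because only the medial compartment is
#' meshed; the lateral dimensions enter template matching only (set
#' `use_lateral = TRUE` to average medial and lateral ratios instead).
#' Connectivity, node sets and meniscus fraction are unchanged; the
#' split-line field is re-normalized to unit length.
#'
#' @param atlas A [template_atlas()].
#' @param subject [anat_dims()] of the subject.
#' @param origin Scaling origin (xyz, mm). Default: centroid of the
#'   `contact_surface` node set.
#' @param use_lateral If `TRUE`, use the mean of medial and lateral ratios
#'   for the x and z scale factors.
#' @return A `template_atlas` with transformed nodes and `dims` replaced by
#'   the subject's dimensions.
#' @export
scale_template <- function(atlas, subject, origin = NULL,
                           use_lateral = FALSE) {
  stopifnot(inherits(atlas, "template_atlas"))
  subject <- as_anat_dims(subject)
  ad <- atlas$dims
  sx <- subject[["ap_medial"]] / ad[["ap_medial"]]
  sz <- subject[["jsw_medial"]] / ad[["jsw_medial"]]
  if (use_lateral) {
    sx <- mean(c(sx, subject[["ap_lateral"]] / ad[["ap_lateral"]]))
    sz <- mean(c(sz, subject[["jsw_lateral"]] / ad[["jsw_lateral"]]))
  }
  sy <- subject[["ml"]] / ad[["ml"]]
  s <- c(sx, sy, sz)
  if (any(!is.finite(s)) || any(s <= 0))
    stop("scale factors must be positive and finite", call. = FALSE)
  mesh <- atlas$mesh
  if (is.null(origin)) {
    cs <- mesh$node_sets$contact_surface
    origin <- colMeans(mesh$nodes[cs, , drop = FALSE])
  }
  origin <- as.numeric(origin)
  nodes <- sweep(sweep(mesh$nodes, 2L, origin), 2L, s, `*`)
  nodes <- sweep(nodes, 2L, origin, `+`)
  new_mesh <- hex_mesh(nodes, mesh$elems, mesh$node_sets)
  slf <- sweep(atlas$split_line_field, 2L, s, `*`)
  slf <- slf / sqrt(rowSums(slf^2))
  condyle <- atlas$condyle
  condyle$center <- origin + s * (condyle$center - origin)
  condyle$radius <- condyle$radius * sx    # AP curvature governs contact
  out <- template_atlas(atlas$atlas_id, new_mesh, subject,
                        atlas$meniscus_fraction, slf, condyle)
  out
}

#' Measure anatomical dimensions from a template atlas
#'
#' Inverts the generator convention of [gen_atlas_library()]: the tibial
#' mesh footprint spans the full AP medial length in x and half the ML
#' length in y (medial plateau), and the tibial layer is half the medial
#' joint space width in z (the femoral cartilage carries the other half).
#' Lateral dimensions are carried as attributes, scaled by the stored
#' lateral-to-medial ratios.
#'
#' @param atlas A [template_atlas()].
#' @return An [anat_dims()] estimate.
#' @export
measure_dimensions <- function(atlas) {
  nd <- atlas$mesh$nodes[atlas$mesh$node_sets$tibial_cartilage, , drop = FALSE]
  ap <- diff(range(nd[, 1]))
  ml <- 2 * diff(range(nd[, 2]))
  jsw <- 2 * diff(range(nd[, 3]))
  r_ap <- atlas$dims[["ap_lateral"]] / atlas$dims[["ap_medial"]]
  r_jsw <- atlas$dims[["jsw_lateral"]] / atlas$dims[["jsw_medial"]]
  anat_dims(ml, ap, ap * r_ap, jsw, jsw * r_jsw)
}
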