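# Reduction of a simulated field history to the five mechanical response
# parameters over stance: maximum principal stress, maximum and minimum
# principal strain, fibril strain and pore pressure, each as the peak and
# the contact-area-averaged value on the medial tibial contact.

#' Principal values of a symmetric 3 x 3 tensor
#'
#' @param tensor Symmetric 3 x 3 matrix.
#' @param tol Symmetry tolerance (max absolute off-diagonal mismatch).
#' @return Numeric length-3 vector of eigenvalues, sorted descending.
#' @examples
#' principal_values(diag(c(3, 1, 2)))
#' @export
principal_values <- function(tensor, tol = 1e-8) {
  tensor <- as.matrix(tensor)
  if (max(abs(tensor - t(tensor))) > tol * max(1, max(abs(tensor))))
    stop("tensor is not symmetric", call. = FALSE)
  sort(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

voigt_to_tensor <- function(v, engineering_shear = FALSE) {
  s <- if (engineering_shear) 0.5 else 1
  matrix(c(v[1], s * v[4], s * v[5],
           s * v[4], v[2], s * v[6],
           s * v[5], s * v[6], v[3]), 3, 3)
}

response_params <- c("max_principal_stress", "max_principal_strain",
                     "min_principal_strain", "fibril_strain",
                     "pore_pressure")

#' Summarize a field history into stance trajectories
#'
#' At every stored frame, the contact region is the set of elements having
#' at least one flagged contact node; values are taken at the integration
#' points of those elements. For each of the five parameters the function
#' reports the peak (signed extremum in the physically adverse direction:
#' maximum for tensile stress/strain, fibril strain and pore pressure,
#' minimum for compressive strain) and the contact-area-averaged value
#' (element top-face-area-weighted mean of element-mean integration-point
#' values). Frames with an empty contact region yield `NA` with a warning.
#'
#' @param history A `field_history` from [run_gait()] (must contain stored
#'   tensor fields and contact flags).
#' @return A `stance_trajectories` data.frame: `stance_pct` plus columns
#'   `<parameter>_peak` and `<parameter>_mean` for the five parameters.
#'   Stress and pressure in MPa, strains dimensionless.
#' @export
summarize_history <- function(history) {
  stopifnot(inherits(history, "field_history"))
  if (is.null(history$stress))
    stop("history lacks stored tensor fields", call. = FALSE)
  if (is.null(history$contact_flags))
    stop("history lacks contact flags", call. = FALSE)
  nsteps <- length(history$time)
  mesh <- history$mesh
  cs <- history$contact_nodes
  sf <- surface_face_areas(mesh, mesh$node_sets$contact_surface)
  # map element -> top-face area (0 if not a surface element)
  elem_area <- numeric(nrow(mesh$elems))
  elem_area[sf$elems] <- sf$areas
  stance <- history$stance_pct %||% (history$time / max(history$time) * 100)

  out <- data.frame(stance_pct = stance)
  for (p in response_params) {
    out[[paste0(p, "_peak")]] <- NA_real_
    out[[paste0(p, "_mean")]] <- NA_real_
  }
  empty_frames <- 0L
  for (k in seq_len(nsteps)) {
    flagged <- cs[history$contact_flags[k, ]]
    if (!length(flagged)) { empty_frames <- empty_frames + 1L; next }
    inset <- rep(FALSE, nrow(mesh$nodes)); inset[flagged] <- TRUE
    touch <- which(rowSums(matrix(inset[mesh$elems], ncol = 8L)) > 0L)
    gps <- which(history$gp$elem %in% touch)
    if (!length(gps)) { empty_frames <- empty_frames + 1L; next }

    nv <- length(gps)
    vals <- matrix(NA_real_, nv, 5L)
    for (i in seq_len(nv)) {
      g <- gps[i]
      sig <- voigt_to_tensor(history$stress[k, g, ])
      eps <- voigt_to_tensor(history$strain[k, g, ],
                             engineering_shear = TRUE)
      ps <- principal_values(sig)
      pe <- principal_values(eps)
      vals[i, 1:4] <- c(ps[1], pe[1], pe[3], history$fibril_strain[k, g])
    }
    vals[, 5] <- gp_pressure(history, k, gps)

    # element means and area weights
    ge <- history$gp$elem[gps]
    area_w <- elem_area[ge]
    means <- numeric(5); peaks <- numeric(5)
    for (j in 1:5) {
      em <- tapply(vals[, j], ge, mean)
      ea <- elem_area[as.integer(names(em))]
      if (all(ea == 0)) ea <- rep(1, length(ea))
      means[j] <- sum(em * ea) / sum(ea)
    }
    peaks[1] <- max(vals[, 1]); peaks[2] <- max(vals[, 2])
    peaks[3] <- min(vals[, 3]); peaks[4] <- max(vals[, 4])
    peaks[5] <- max(vals[, 5])
    for (j in 1:5) {
      out[[paste0(response_params[j], "_peak")]][k] <- peaks[j]
      out[[paste0(response_params[j], "_mean")]][k] <- means[j]
    }
  }
  if (empty_frames > 0L)
    warning(empty_frames, " frame(s) had an empty contact region; ",
            "values recorded as NA", call. = FALSE)
  class(out) <- c("stance_trajectories", "data.frame")
  out
}

gp_pressure <- function(history, step, gps) {
  # trilinear interpolation of nodal pressure to integration points:
  # reuse stress bookkeeping (total = effective - p I) to avoid storing Np:
  # p = (tr(effective) - tr(total)) / 3; effective trace = total trace + 3p.
  # The solver stores total stress; recover p from nodal P instead.
  mesh <- history$mesh
  p_node <- history$P[step, ]
  out <- numeric(length(gps))
  gp <- hex_gauss()
  for (i in seq_along(gps)) {
    g <- gps[i]
    e <- history$gp$elem[g]
    gl <- ((g - 1L) %% 8L) + 1L      # GPs are stored in blocks of 8
    shp <- hex_shape(gp$points[gl, 1], gp$points[gl, 2], gp$points[gl, 3])
    out[i] <- sum(shp$N * p_node[mesh$elems[e, ]])
  }
  out
}

#' Write stance trajectories as CSV
#' @param traj A [summarize_history()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  out <- read.csv(path)
  class(out) <- c("stance_trajectories", "data.frame")
  out
}

#' Plot mean +/- SD bands of stance trajectories across subjects
#'
#' @param traj_list List of `stance_trajectories` (one per subject).
#' @param parameter One of `max_principal_stress`, `max_principal_strain`,
#'   `min_principal_strain`, `fibril_strain`, `pore_pressure`.
#' @param kind `"peak"` or `"mean"`.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_trajectories <- function(traj_list, parameter = "max_principal_stress",
                              kind = c("peak", "mean")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  kind <- match.arg(kind)
  col <- paste0(parameter, "_", kind)
  mat <- sapply(traj_list, function(tr) tr[[col]])
  df <- data.frame(stance_pct = traj_list[[1]]$stance_pct,
                   mean = rowMeans(mat, na.rm = TRUE),
                   sd = apply(mat, 1L, sd, na.rm = TRUE))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stance_pct, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Stance [%]", y = col)
}
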