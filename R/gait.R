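#' Generic gait waveform
#'
#' A gait waveform tabulates, over the stance phase (0-100%), the total
#' axial tibiofemoral reaction force in multiples of body weight and the
#' knee flexion angle in degrees. The packaged default
#' ([default_gait_waveform()]) is a representative double-peaked waveform
#' of the kind reported by instrumented-knee gait studies; it is an
#' editable input, not a constant, and users should substitute their own
#' measurements when available.
#'
#' @param df Data frame with columns `stance_pct`, `axial_force_bw`,
#'   `flexion_deg`.
#' @return A `gait_waveform` object (validated data.frame).
#' @export
gait_waveform <- function(df) {
  need <- c("stance_pct", "axial_force_bw", "flexion_deg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[need]
  s <- df$stance_pct
  if (any(diff(s) <= 0))
    stop("stance_pct must be strictly increasing", call. = FALSE)
  if (s[1] != 0 || s[length(s)] != 100)
    stop("stance_pct must span [0, 100]", call. = FALSE)
  if (any(df$axial_force_bw < 0))
    stop("axial_force_bw must be non-negative", call. = FALSE)
  class(df) <- c("gait_waveform", "data.frame")
  df
}

#' @rdname gait_waveform
#' @export
default_gait_waveform <- function() {
  path <- system.file("extdata", "gait_waveform.csv", package = "cartatlas")
  read_gait_waveform(path)
}

#' Read / write a gait waveform CSV
#' @param path CSV with columns `stance_pct,axial_force_bw,flexion_deg`.
#' @return A [gait_waveform()].
#' @export
read_gait_waveform <- function(path) gait_waveform(read.csv(path))

#' @rdname read_gait_waveform
#' @param waveform A [gait_waveform()].
#' @export
write_gait_waveform <- function(waveform, path) {
  write.csv(as.data.frame(waveform), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a gait waveform onto a uniform stance grid
#'
#' Linear interpolation of force and flexion onto `n_points` equally spaced
#' stance percentages; endpoints are preserved exactly.
#'
#' @param waveform A [gait_waveform()].
#' @param n_points Number of grid points (>= 2).
#' @return A [gait_waveform()] on the uniform grid.
#' @export
resample_waveform <- function(waveform, n_points) {
  stopifnot(inherits(waveform, "gait_waveform"))
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  grid <- seq(0, 100, length.out = n_points)
  gait_waveform(data.frame(
    stance_pct = grid,
    axial_force_bw = approx(waveform$stance_pct, waveform$axial_force_bw,
                            grid, rule = 2)$y,
    flexion_deg = approx(waveform$stance_pct, waveform$flexion_deg,
                         grid, rule = 2)$y))
}

#' Build the medial-compartment loading profile
#'
#' Converts a body-weight-normalized gait waveform into the axial force
#' applied to the medial compartment model:
#' `medial_force_n(t) = axial_force_bw(t) * body_mass_kg * g * medial_share *
#' (1 - meniscus_fraction)`.
#' The waveform force is scaled by the subject's body weight, half of it
#' (by default) is attributed to the medial compartment, and the share of
#' load carried by the meniscus is subtracted because the meniscus is not
#' meshed. Flexion is passed through unchanged.
#'
#' @param waveform A [gait_waveform()].
#' @param body_mass_kg Subject body mass (kg), > 0.
#' @param meniscus_fraction Fraction of compartment load carried by the
#'   meniscus, in `[0, 1)`. Typically the mean of the atlas library's
#'   per-template fractions ([library_meniscus_fraction()]).
#' @param medial_share Fraction of the total axial force assigned to the
#'   medial compartment, in `(0, 1]`. Default 0.5.
#' @param g Gravitational acceleration (m/s^2). Default 9.81.
#' @return A `loading_profile` data.frame with columns `stance_pct`,
#'   `medial_force_n`, `flexion_deg` and attributes `body_mass_kg`,
#'   `meniscus_fraction`, `medial_share`.
#' @examples
#' w <- gait_waveform(data.frame(stance_pct = c(0, 100),
#'                               axial_force_bw = c(2, 2),
#'                               flexion_deg = c(0, 0)))
#' build_loading(w, body_mass_kg = 80, meniscus_fraction = 0)
#' @export
build_loading <- function(waveform, body_mass_kg, meniscus_fraction,
                          medial_share = 0.5, g = 9.81) {
  stopifnot(inherits(waveform, "gait_waveform"))
  if (!is.numeric(body_mass_kg) || body_mass_kg <= 0)
    stop("body_mass_kg must be positive", call. = FALSE)
  if (meniscus_fraction < 0 || meniscus_fraction >= 1)
    stop("meniscus_fraction must lie in [0, 1)", call. = FALSE)
  if (medial_share <= 0 || medial_share > 1)
    stop("medial_share must lie in (0, 1]", call. = FALSE)
  out <- data.frame(
    stance_pct = waveform$stance_pct,
    medial_force_n = waveform$axial_force_bw * body_mass_kg * g *
      medial_share * (1 - meniscus_fraction),
    flexion_deg = waveform$flexion_deg)
  attr(out, "body_mass_kg") <- body_mass_kg
  attr(out, "meniscus_fraction") <- meniscus_fraction
  attr(out, "medial_share") <- medial_share
  class(out) <- c("loading_profile", "data.frame")
  out
}

#' Read / write a loading profile as JSON
#' @param profile A [build_loading()] result.
#' @param path JSON path.
#' @return `path` (write) or a `loading_profile` (read).
#' @export
write_loading <- function(profile, path) {
  stopifnot(inherits(profile, "loading_profile"))
  jsonlite::write_json(list(
    stance_pct = profile$stance_pct,
    medial_force_n = profile$medial_force_n,
    flexion_deg = profile$flexion_deg,
    body_mass_kg = attr(profile, "body_mass_kg"),
    meniscus_fraction = attr(profile, "meniscus_fraction"),
    medial_share = attr(profile, "medial_share")), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_loading
#' @export
read_loading <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- data.frame(stance_pct = x$stance_pct,
                    medial_force_n = x$medial_force_n,
                    flexion_deg = x$flexion_deg)
  attr(out, "body_mass_kg") <- x$body_mass_kg
  attr(out, "meniscus_fraction") <- x$meniscus_fraction
  attr(out, "medial_share") <- x$medial_share
  class(out) <- c("loading_profile", "data.frame")
  out
}
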