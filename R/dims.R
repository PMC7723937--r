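#' Anatomical dimensions of one knee
#'
#' Container for the five length measurements used by the atlas-based
#' workflow: maximum medial-lateral length (ML, the clinical transepicondylar
#' axis), maximum anterior-posterior condylar lengths (AP medial, AP
#' lateral), and tibiofemoral joint space widths (JSW medial, JSW lateral).
#' All in millimetres. Only positivity is enforced; no ordering among the
#' dimensions is assumed.
#'
#' @param ml Maximum medial-lateral length (mm).
#' @param ap_medial,ap_lateral Maximum anterior-posterior condylar lengths
#'   (mm).
#' @param jsw_medial,jsw_lateral Tibiofemoral joint space widths (mm),
#'   interpreted as the combined femoral + tibial cartilage thickness of the
#'   compartment.
#' @return An object of class `anat_dims`: a named numeric vector with
#'   fields `ml`, `ap_medial`, `ap_lateral`, `jsw_medial`, `jsw_lateral`.
#' @examples
#' d <- anat_dims(79.84, 52.95, 61.66, 3.82, 5.38)
#' normalize_dimensions(d)
#' @export
anat_dims <- function(ml, ap_medial, ap_lateral, jsw_medial, jsw_lateral) {
  x <- c(ml = ml, ap_medial = ap_medial, ap_lateral = ap_lateral,
         jsw_medial = jsw_medial, jsw_lateral = jsw_lateral)
  if (anyNA(x) || !is.numeric(x) || length(x) != 5L)
    stop("all five dimensions must be finite numbers", call. = FALSE)
  if (any(x <= 0))
    stop("anatomical dimensions must be strictly positive", call. = FALSE)
  class(x) <- "anat_dims"
  x
}

#' @export
print.anat_dims <- function(x, ...) {
  cat("Anatomical dimensions [mm]:\n")
  print(unclass(x), ...)
  invisible(x)
}

dim_fields <- c("ml", "ap_medial", "ap_lateral", "jsw_medial", "jsw_lateral")

as_anat_dims <- function(x) {
  if (inherits(x, "anat_dims")) return(x)
  x <- as.list(x)
  if (!all(dim_fields %in% names(x)))
    stop("need named fields: ", paste(dim_fields, collapse = ", "),
         call. = FALSE)
  do.call(anat_dims, lapply(x[dim_fields], function(v) as.numeric(v[[1]])))
}

#' Normalize anatomical dimensions by the ML length
#'
#' Divides every dimension by the measured ML value, giving a dimensionless
#' shape descriptor in which the ML field is identically 1. Normalization
#' makes knees of different overall size comparable for template matching.
#'
#' @param dims An [anat_dims()] object (or coercible named vector).
#' @return A `norm_dims` object: the same five fields, each divided by `ml`.
#' @examples
#' normalize_dimensions(anat_dims(80, 53, 62, 3.8, 5.4))
#' @export
normalize_dimensions <- function(dims) {
  dims <- as_anat_dims(dims)
  x <- unclass(dims) / dims[["ml"]]
  class(x) <- "norm_dims"
  x
}

#' @export
print.norm_dims <- function(x, ...) {
  cat("Normalized (ML = 1) dimensions:\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Read a subject dimensions table
#'
#' Reads a CSV with header
#' `subject_id,ml,ap_medial,ap_lateral,jsw_medial,jsw_lateral,body_mass_kg`.
#'
#' @param path CSV file path.
#' @return A data.frame with those columns; dimensions validated positive.
#' @export
read_subject_dims <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", dim_fields, "body_mass_kg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  num <- c(dim_fields, "body_mass_kg")
  if (any(!sapply(df[num], is.numeric)) || any(as.matrix(df[num]) <= 0))
    stop("dimensions and body mass must be positive numbers", call. = FALSE)
  df[need]
}

#' Write a subject dimensions table
#' @param df Data frame as returned by [read_subject_dims()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_subject_dims <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
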