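#' PET volume container
#'
#' A `pet_volume` holds a 3D grid of standardized uptake values (SUV,
#' dimensionless) together with its voxel geometry. All image-stage functions
#' in this package consume and produce this class.
#'
#' @param values numeric 3D array of SUV (finite, non-negative).
#' @param spacing numeric length-3 vector of voxel sizes in mm (all > 0).
#' @param origin numeric length-3 vector, physical coordinates of voxel
#'   (1,1,1) in mm. Defaults to the zero origin.
#'
#' @return An object of class `pet_volume`: a list with elements `values`,
#'   `spacing`, `origin`, and `matrix_size` (the per-axis voxel counts).
#' @examples
#' vol <- pet_volume(array(1, dim = c(4, 4, 2)), spacing = c(4.07, 4.07, 3))
#' vol$matrix_size
#' @export
pet_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array", call. = FALSE)
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("SUV values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("SUV values must be non-negative", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive voxel sizes in mm", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 3L)
    stop("'origin' must have length 3", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin,
                 matrix_size = dim(values)),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat("PET volume:", paste(x$matrix_size, collapse = " x "), "voxels,",
      paste(format(x$spacing, digits = 4), collapse = " x "), "mm\n")
  cat("  SUV range:", format(min(x$values), digits = 4), "-",
      format(max(x$values), digits = 4), "\n")
  invisible(x)
}

#' @export
dim.pet_volume <- function(x) x$matrix_size

#' Voxel volume in cm^3
#'
#' @param volume a [pet_volume()].
#' @return Volume of a single voxel in cm^3.
#' @export
voxel_volume_cm3 <- function(volume) {
  stopifnot(inherits(volume, "pet_volume"))
  prod(volume$spacing) / 1000
}

#' Acquisition metadata for SUV conversion
#'
#' Injected dose and body weight needed to convert tissue activity
#' concentration into standardized uptake values.
#'
#' @param injected_dose_mbq injected tracer dose in MBq (> 0).
#' @param body_weight_kg subject body weight in kg (> 0).
#' @param activity_units label for the raw voxel units; only `"kBq/mL"` is
#'   supported.
#' @return An object of class `acquisition_meta`.
#' @examples
#' acquisition_meta(362.6, 70)
#' @export
acquisition_meta <- function(injected_dose_mbq, body_weight_kg,
                             activity_units = "kBq/mL") {
  if (!is.numeric(injected_dose_mbq) || length(injected_dose_mbq) != 1L ||
      !is.finite(injected_dose_mbq) || injected_dose_mbq <= 0)
    stop("invalid metadata: injected dose must be a positive MBq value",
         call. = FALSE)
  if (!is.numeric(body_weight_kg) || length(body_weight_kg) != 1L ||
      !is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("invalid metadata: body weight must be a positive kg value",
         call. = FALSE)
  activity_units <- match.arg(activity_units, "kBq/mL")
  structure(list(injected_dose_mbq = injected_dose_mbq,
                 body_weight_kg = body_weight_kg,
                 activity_units = activity_units),
            class = "acquisition_meta")
}

#' Convert activity concentration to SUV
#'
#' The body-weight SUV is the ratio between the tissue activity concentration
#' (kBq/mL) and the injected dose per body weight (kBq/g). With the dose in
#' MBq and the weight in kg the two unit conversions cancel, so numerically
#' `suv = activity / (dose_MBq / weight_kg)`.
#'
#' @param activity numeric vector or array of activity concentration in
#'   kBq/mL (non-negative).
#' @param meta an [acquisition_meta()].
#' @return SUV values with the same shape as `activity`.
#' @examples
#' compute_suv(5.18, acquisition_meta(5.18 * 70, 70))   # uniform tracer -> 1
#' compute_suv(18.13, acquisition_meta(362.6, 70))      # 3.5
#' @export
compute_suv <- function(activity, meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  if (any(activity < 0, na.rm = TRUE))
    stop("activity concentration must be non-negative", call. = FALSE)
  activity / (meta$injected_dose_mbq / meta$body_weight_kg)
}

#' Read a PET volume from NIfTI
#'
#' Reads a 3D NIfTI image (.nii or .nii.gz) into a [pet_volume()]. Voxel
#' spacing is taken from the header. When the stored voxels are raw activity
#' concentration (`input_units = "kBq_per_mL"`), acquisition metadata must be
#' supplied and the volume is converted to SUV; when they are already SUV the
#' values pass through unchanged. The unit declaration is mandatory: the
#' function never guesses.
#'
#' @param path path to a NIfTI file.
#' @param input_units `"suv"` (default) or `"kBq_per_mL"`.
#' @param meta an [acquisition_meta()], required when
#'   `input_units = "kBq_per_mL"`.
#' @return A [pet_volume()] in SUV units.
#' @seealso [write_pet_volume()]
#' @export
load_pet_volume <- function(path, input_units = c("suv", "kBq_per_mL"),
                            meta = NULL) {
  input_units <- match.arg(input_units)
  if (!file.exists(path))
    stop("PET volume file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  values <- as.array(img)
  values <- array(as.numeric(values), dim = dim(values))  # drop NIfTI attrs
  if (length(dim(values)) == 4L && dim(values)[4] == 1L)
    values <- array(values, dim = dim(values)[1:3])
  if (length(dim(values)) != 3L)
    stop("expected a 3D volume in ", path, call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  if (input_units == "kBq_per_mL") {
    if (is.null(meta))
      stop("voxels are raw activity (kBq/mL): acquisition metadata required ",
           "for SUV conversion", call. = FALSE)
    values <- compute_suv(values, meta)
  }
  pet_volume(values, spacing = spacing)
}

#' Write a PET volume (or mask) to NIfTI
#'
#' @param volume a [pet_volume()] or a `tumor_mask`.
#' @param path output file path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_pet_volume <- function(volume, path) {
  if (inherits(volume, "tumor_mask")) {
    arr <- array(as.integer(volume$mask), dim = dim(volume$mask))
    spacing <- volume$spacing
  } else {
    stopifnot(inherits(volume, "pet_volume"))
    arr <- volume$values
    spacing <- volume$spacing
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
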