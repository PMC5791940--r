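#' Segment a tumor by fixed SUV isocontour
#'
#' Thresholds the volume at a fixed SUV (inclusive, default 3.5) and keeps the
#' 26-connected component of supra-threshold voxels containing the seed. If
#' the seed voxel itself is below threshold, the nearest supra-threshold voxel
#' within `seed_radius` voxels (Euclidean, in voxel units) is used instead.
#'
#' @param volume a [pet_volume()].
#' @param seed integer length-3 voxel index (1-based) inside the grid.
#' @param threshold SUV isocontour value; voxels with SUV >= threshold are
#'   candidate tumor.
#' @param seed_radius maximum voxel distance searched for a supra-threshold
#'   voxel when the seed is below threshold.
#' @return An object of class `tumor_mask`: list with `mask` (logical 3D
#'   array), `seed`, `threshold`, and `spacing` (copied from the volume).
#' @examples
#' vol <- pet_volume(array(4, dim = c(3, 3, 3)), spacing = c(4, 4, 4))
#' m <- segment_tumor(vol, seed = c(2, 2, 2))
#' sum(m$mask)  # whole grid
#' @export
segment_tumor <- function(volume, seed, threshold = 3.5, seed_radius = 3) {
  stopifnot(inherits(volume, "pet_volume"))
  seed <- as.integer(seed)
  dm <- dim(volume$values)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > dm))
    stop("seed voxel index out of grid bounds", call. = FALSE)
  supra <- volume$values >= threshold
  if (!any(supra))
    stop("EmptySegmentation: no voxel reaches SUV ", threshold, call. = FALSE)
  if (!supra[seed[1], seed[2], seed[3]]) {
    cand <- which(supra, arr.ind = TRUE)
    dist2 <- colSums((t(cand) - seed)^2)
    j <- which.min(dist2)
    if (dist2[j] > seed_radius^2)
      stop("EmptySegmentation: no voxel >= SUV ", threshold,
           " within ", seed_radius, " voxels of the seed", call. = FALSE)
    seed <- as.integer(cand[j, ])
  }
  comp <- connected_components_3d(supra)
  mask <- comp == comp[seed[1], seed[2], seed[3]]
  structure(list(mask = mask, seed = seed, threshold = threshold,
                 spacing = volume$spacing),
            class = "tumor_mask")
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat("Tumor mask:", sum(x$mask), "voxels at SUV >=", x$threshold, "\n")
  invisible(x)
}

#' Conventional SUV parameters of a segmented tumor
#'
#' Computes SUVmax, SUVaverage and metabolic volume (MV) over the mask, and
#' categorizes MV at a fixed cutoff (default 45 cm^3).
#'
#' @param volume a [pet_volume()].
#' @param mask a `tumor_mask` from [segment_tumor()] (or a logical array
#'   aligned to the volume).
#' @param mv_cutoff_cm3 cutoff in cm^3 for the binary MV category.
#' @return A list of class `conventional_params` with `suv_max`,
#'   `suv_average`, `metabolic_volume` (cm^3) and `mv_category`
#'   (`"above"`/`"below"` the cutoff; inclusive below).
#' @export
conventional_params <- function(volume, mask, mv_cutoff_cm3 = 45) {
  stopifnot(inherits(volume, "pet_volume"))
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  if (!any(m)) stop("empty mask", call. = FALSE)
  vals <- volume$values[m]
  mv <- sum(m) * voxel_volume_cm3(volume)
  structure(list(
    suv_max = max(vals),
    suv_average = mean(vals),
    metabolic_volume = mv,
    mv_category = if (mv > mv_cutoff_cm3) "above" else "below",
    mv_cutoff_cm3 = mv_cutoff_cm3
  ), class = "conventional_params")
}

#' Quantize a segmented tumor to L gray levels
#'
#' Rescales the SUVs inside the mask to integer gray levels 1..L relative to
#' the in-mask minimum and maximum:
#' `level(v) = min(L, 1 + floor(L * (SUV(v) - vmin) / (vmax - vmin)))`.
#' A constant-SUV region maps entirely to level 1. Voxels outside the mask
#' are coded 0. The recoding is monotone in SUV and invariant to affine
#' rescaling of the in-mask values.
#'
#' @param volume a [pet_volume()].
#' @param mask a `tumor_mask` or logical array.
#' @param levels number of gray levels L (default 64).
#' @return An object of class `quantized_volume`: list with `levels`
#'   (integer 3D array), `L`, `vmin`, `vmax`, and `spacing`.
#' @export
quantize <- function(volume, mask, levels = 64L) {
  stopifnot(inherits(volume, "pet_volume"))
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  if (!any(m)) stop("empty mask", call. = FALSE)
  L <- as.integer(levels)
  stopifnot(L >= 1L)
  vals <- volume$values[m]
  vmin <- min(vals)
  vmax <- max(vals)
  lev <- array(0L, dim = dim(volume$values))
  if (vmax > vmin) {
    lev[m] <- pmin(L, 1L + as.integer(floor(L * (vals - vmin) / (vmax - vmin))))
  } else {
    lev[m] <- 1L
  }
  structure(list(levels = lev, L = L, vmin = vmin, vmax = vmax,
                 spacing = volume$spacing),
            class = "quantized_volume")
}

#' @export
print.quantized_volume <- function(x, ...) {
  inmask <- x$levels[x$levels > 0L]
  cat("Quantized tumor:", length(inmask), "voxels,", x$L, "gray levels",
      sprintf("(SUV %.3g-%.3g)\n", x$vmin, x$vmax))
  invisible(x)
}
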