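#' Construct an image volume
#'
#' An `image_volume` is a 3D scalar grid of intensities on the Hounsfield-unit
#' scale together with its voxel spacing (mm) and world origin (mm). World
#' coordinates follow `origin + (index - 1) * spacing` with 1-based voxel
#' indices.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing Numeric length-3, voxel spacing in mm along (x, y, z);
#'   all components must be positive.
#' @param origin Numeric length-3, world coordinates (mm) of the first voxel.
#' @return An object of class `image_volume`: a list with elements `data`,
#'   `spacing` and `origin`.
#' @export
#' @examples
#' vol <- image_volume(array(rnorm(8 * 8 * 4), dim = c(8, 8, 4)))
#' dim(vol$data)
image_volume <- function(data, spacing = c(1, 1, 2), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive finite numbers (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("volume intensities must all be finite", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Construct a lesion mask
#'
#' A `lesion_mask` is a binary 3D array co-registered with an
#' [image_volume()] (same grid, spacing and origin), tagged with the lesion's
#' identity and timepoint.
#'
#' @param data 3D array coercible to logical; `TRUE`/1 marks lesion voxels.
#' @param spacing,origin Grid geometry, as in [image_volume()].
#' @param patient_id,lesion_id Identifiers (coerced to character).
#' @param timepoint `"baseline"` or `"evaluation"`.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(data, spacing = c(1, 1, 2), origin = c(0, 0, 0),
                        patient_id = NA_character_, lesion_id = NA_character_,
                        timepoint = "baseline") {
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    stop("mask `data` must be a 3D array", call. = FALSE)
  }
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1, TRUE, FALSE))) {
    stop("mask values must be exactly binary (0/1); binarize explicitly first",
         call. = FALSE)
  }
  timepoint <- match.arg(timepoint, c("baseline", "evaluation"))
  structure(
    list(data = array(as.logical(data), dim = dim(data)),
         spacing = as.numeric(spacing), origin = as.numeric(origin),
         patient_id = as.character(patient_id),
         lesion_id = as.character(lesion_id),
         timepoint = timepoint),
    class = "lesion_mask"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels @ (%g, %g, %g) mm, range [%.1f, %.1f]\n",
              paste(dim(x$data), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s/%s [%s] %d voxels on %s grid @ (%g, %g, %g) mm\n",
              x$patient_id, x$lesion_id, x$timepoint, sum(x$data),
              paste(dim(x$data), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# voxel volume in mm^3
voxel_volume_mm3 <- function(spacing) prod(spacing)

stopifnot_same_grid <- function(vol, mask) {
  if (!identical(dim(vol$data), dim(mask$data))) {
    stop("image and mask grids do not align: dims ",
         paste(dim(vol$data), collapse = "x"), " vs ",
         paste(dim(mask$data), collapse = "x"), call. = FALSE)
  }
  if (max(abs(vol$spacing - mask$spacing)) > 1e-6) {
    stop("image and mask voxel spacings differ", call. = FALSE)
  }
  invisible(TRUE)
}

# Bounding box of a logical array, expanded by `margin` voxels and clipped to
# the grid. Returns list of index vectors (ix, iy, iz).
mask_bbox <- function(mask_data, margin = 0L) {
  stopifnot(any(mask_data))
  dims <- dim(mask_data)
  w <- which(mask_data)
  ijk <- arrayInd(w, dims)
  lapply(1:3, function(a) {
    lo <- max(1L, min(ijk[, a]) - margin)
    hi <- min(dims[a], max(ijk[, a]) + margin)
    lo:hi
  })
}

# Crop an image/mask pair to the mask bounding box plus margin.
crop_to_mask <- function(vol_data, mask_data, margin = 2L) {
  bb <- mask_bbox(mask_data, margin)
  list(vol = vol_data[bb[[1]], bb[[2]], bb[[3]], drop = FALSE],
       mask = mask_data[bb[[1]], bb[[2]], bb[[3]], drop = FALSE])
}
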