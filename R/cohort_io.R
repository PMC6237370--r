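#' Load and validate a cohort manifest
#'
#' The manifest is a CSV with one row per lesion per timepoint and columns
#' `patient_id, lesion_id, timepoint, image_path, mask_path`. Lesions are
#' matched across timepoints by `(patient_id, lesion_id)`; a baseline row with
#' no evaluation counterpart encodes lesion disappearance (complete response).
#'
#' Relative `image_path`/`mask_path` entries are resolved against the
#' manifest's own directory.
#'
#' @param path Path to the manifest CSV.
#' @param check_paths If `TRUE` (default), error when a referenced file is
#'   missing.
#' @return A tibble with the five manifest columns plus
#'   `absent_at_evaluation` (logical, set on baseline rows whose lesion has no
#'   evaluation row).
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) {
    stop("manifest not found: ", path, call. = FALSE)
  }
  man <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("patient_id", "lesion_id", "timepoint", "image_path", "mask_path")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols) > 0) {
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  man <- man |>
    dplyr::mutate(dplyr::across(c("patient_id", "lesion_id", "timepoint"), as.character))

  bad_tp <- setdiff(unique(man$timepoint), c("baseline", "evaluation"))
  if (length(bad_tp) > 0) {
    stop("unknown timepoint value(s): ", paste(bad_tp, collapse = ", "),
         "; expected 'baseline' or 'evaluation'", call. = FALSE)
  }

  dup <- man |>
    dplyr::count(.data$patient_id, .data$lesion_id, .data$timepoint) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (patient_id, lesion_id, timepoint) row(s), e.g. ",
         dup$patient_id[1], "/", dup$lesion_id[1], "/", dup$timepoint[1],
         call. = FALSE)
  }

  keys <- function(tp) {
    m <- man[man$timepoint == tp, ]
    paste(m$patient_id, m$lesion_id, sep = "\r")
  }
  orphans <- setdiff(keys("evaluation"), keys("baseline"))
  if (length(orphans) > 0) {
    stop("evaluation row(s) without a baseline counterpart: ",
         gsub("\r", "/", orphans[1]), call. = FALSE)
  }

  root <- dirname(normalizePath(path, mustWork = TRUE))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(root, p))
  man$image_path <- resolve(man$image_path)
  man$mask_path <- resolve(man$mask_path)
  if (check_paths) {
    missing_files <- setdiff(c(man$image_path, man$mask_path), "") |>
      Filter(f = function(p) !file.exists(p), x = _)
    if (length(missing_files) > 0) {
      stop("manifest references missing file(s), e.g. ", missing_files[1],
           call. = FALSE)
    }
  }

  eval_keys <- keys("evaluation")
  man |>
    dplyr::mutate(absent_at_evaluation = .data$timepoint == "baseline" &
                    !(paste(.data$patient_id, .data$lesion_id, sep = "\r") %in% eval_keys)) |>
    dplyr::arrange(.data$patient_id, .data$lesion_id, .data$timepoint) |>
    tibble::as_tibble()
}

#' Read / write image volumes and lesion masks (NIfTI)
#'
#' `read_volume()` reads a NIfTI file into an [image_volume()], taking voxel
#' spacing and origin from the header. `read_mask()` reads a mask on the same
#' grid as `reference` and binarizes it at > 0.5 (fractional values arise from
#' interpolated masks). `write_volume()`/`write_mask()` are the inverses.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param reference An [image_volume()] whose grid the mask must match.
#' @param patient_id,lesion_id,timepoint Identity attached to the mask.
#' @return `read_volume()` an `image_volume`; `read_mask()` a `lesion_mask`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # drop RNifti header attributes
  image_volume(arr, spacing = sp, origin = xf[1:3, 4])
}

#' @rdname read_volume
#' @export
read_mask <- function(path, reference = NULL,
                      patient_id = NA_character_, lesion_id = NA_character_,
                      timepoint = "baseline") {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (!is.null(reference)) {
    if (!identical(dim(arr), dim(reference$data))) {
      stop("mask grid ", paste(dim(arr), collapse = "x"),
           " does not match reference grid ",
           paste(dim(reference$data), collapse = "x"), call. = FALSE)
    }
    if (max(abs(sp - reference$spacing)) > 1e-4) {
      stop("mask voxel spacing does not match reference", call. = FALSE)
    }
  }
  lesion_mask(array(arr > 0.5, dim = dim(arr)), spacing = sp,
              origin = xf[1:3, 4], patient_id = patient_id,
              lesion_id = lesion_id, timepoint = timepoint)
}

#' @rdname read_volume
#' @param vol An [image_volume()] to write.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @param mask A [lesion_mask()] to write.
#' @export
write_mask <- function(mask, path) {
  vol <- image_volume(array(as.numeric(mask$data), dim = dim(mask$data)),
                      spacing = mask$spacing, origin = mask$origin)
  write_volume(vol, path)
}

#' Resample an image/mask pair to the analysis grid
#'
#' Resamples the image with trilinear interpolation to the target voxel
#' spacing (default 1 x 1 x 2 mm, the standard analysis grid for
#' contrast-enhanced abdominal CT in this pipeline). The mask is resampled
#' with the same trilinear interpolation and then thresholded at 0.5, which
#' preserves sub-voxel boundary position better than nearest-neighbour
#' while keeping the result binary and deterministic.
#'
#' @param vol An [image_volume()].
#' @param mask A [lesion_mask()] on the same grid, or `NULL`.
#' @param target_spacing Numeric length-3, target spacing in mm.
#' @return A list with elements `vol` and `mask` on the common target grid
#'   (`mask` is `NULL` if it was `NULL`).
#' @export
resample_to_grid <- function(vol, mask = NULL, target_spacing = c(1, 1, 2)) {
  target_spacing <- as.numeric(target_spacing)
  stopifnot(length(target_spacing) == 3, all(target_spacing > 0))
  if (!is.null(mask)) stopifnot_same_grid(vol, mask)

  if (max(abs(vol$spacing - target_spacing)) < 1e-9) {
    return(list(vol = vol, mask = mask))
  }

  new_data <- trilinear_resample(vol$data, vol$spacing, target_spacing)
  out_vol <- image_volume(new_data, spacing = target_spacing, origin = vol$origin)
  out_mask <- NULL
  if (!is.null(mask)) {
    frac <- trilinear_resample(array(as.numeric(mask$data), dim = dim(mask$data)),
                               vol$spacing, target_spacing)
    out_mask <- lesion_mask(array(frac > 0.5, dim = dim(frac)),
                            spacing = target_spacing, origin = mask$origin,
                            patient_id = mask$patient_id,
                            lesion_id = mask$lesion_id,
                            timepoint = mask$timepoint)
  }
  list(vol = out_vol, mask = out_mask)
}

# Trilinear resampling on a voxel-centre grid. Output voxel i (1-based) sits
# at continuous input index 1 + (i-1)*sp_out/sp_in; indices are clamped to the
# grid so single-voxel-thick axes degrade to edge replication instead of
# failing.
trilinear_resample <- function(data, spacing_in, spacing_out) {
  dims <- dim(data)
  extent <- (dims - 1) * spacing_in
  dims_out <- pmax(1L, as.integer(round(extent / spacing_out)) + 1L)

  # continuous (1-based) input coordinates per output axis, clamped
  coord <- lapply(1:3, function(a) {
    x <- 1 + (seq_len(dims_out[a]) - 1) * spacing_out[a] / spacing_in[a]
    pmin(pmax(x, 1), dims[a])
  })
  lo <- lapply(1:3, function(a) pmin(floor(coord[[a]]), dims[a] - (dims[a] > 1)))
  fr <- lapply(1:3, function(a) coord[[a]] - lo[[a]])
  hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1, dims[a]))
  lo <- lapply(lo, as.integer); hi <- lapply(hi, as.integer)

  out <- array(0, dim = dims_out)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wx <- if (cx == 0) 1 - fr[[1]] else fr[[1]]
    wy <- if (cy == 0) 1 - fr[[2]] else fr[[2]]
    wz <- if (cz == 0) 1 - fr[[3]] else fr[[3]]
    ix <- if (cx == 0) lo[[1]] else hi[[1]]
    iy <- if (cy == 0) lo[[2]] else hi[[2]]
    iz <- if (cz == 0) lo[[3]] else hi[[3]]
    block <- data[ix, iy, iz, drop = FALSE]
    w <- outer(outer(wx, wy), wz)
    dim(w) <- dims_out
    out <- out + w * block
  }
  out
}
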