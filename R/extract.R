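#' Extract the radiomics feature vector for lesions
#'
#' Computes the catalog-defined radiomics feature vector for every baseline
#' lesion of a cohort manifest. Each lesion's image and mask are read,
#' resampled to the analysis grid (trilinear image interpolation, mask
#' thresholded at 0.5), and the feature vector is computed on the resampled
#' grid. First-order and texture features are computed on the original image
#' and, for wavelet-channel entries, on the eight stationary wavelet
#' sub-bands; shape features are computed from the mask alone. Grey levels
#' are discretized per channel with equal-width bins over the in-mask range.
#'
#' @param manifest A manifest tibble from [load_manifest()] (or a path to a
#'   manifest CSV).
#' @param catalog A feature catalog tibble ([default_catalog()] by default).
#' @param n_bins Grey levels for discretization (default: catalog attribute,
#'   32 for the default catalog).
#' @param wavelet Wavelet filter name (default: catalog attribute).
#' @param target_spacing Analysis grid spacing in mm, default (1, 1, 2).
#' @param resample If `FALSE`, volumes are assumed to already be on the
#'   analysis grid and are not resampled.
#' @return A tibble with `patient_id`, `lesion_id`, then one column per
#'   catalog feature, one row per baseline lesion, in catalog order.
#' @export
extract_features <- function(manifest, catalog = default_catalog(),
                             n_bins = NULL, wavelet = NULL,
                             target_spacing = c(1, 1, 2), resample = TRUE) {
  if (is.character(manifest) && length(manifest) == 1) {
    manifest <- load_manifest(manifest)
  }
  n_bins <- n_bins %||% attr(catalog, "n_bins") %||% 32
  wavelet <- wavelet %||% attr(catalog, "wavelet") %||% "coif1"

  base <- manifest |> dplyr::filter(.data$timepoint == "baseline")
  rows <- purrr::pmap(
    list(base$patient_id, base$lesion_id, base$image_path, base$mask_path),
    function(pid, lid, ipath, mpath) {
      vol <- read_volume(ipath)
      mask <- read_mask(mpath, reference = vol, patient_id = pid,
                        lesion_id = lid, timepoint = "baseline")
      if (resample) {
        rs <- resample_to_grid(vol, mask, target_spacing)
        vol <- rs$vol; mask <- rs$mask
      }
      fv <- extract_lesion_features(vol, mask, catalog = catalog,
                                    n_bins = n_bins, wavelet = wavelet)
      tibble::tibble(patient_id = pid, lesion_id = lid, !!!as.list(fv))
    }
  )
  out <- dplyr::bind_rows(rows)
  attr(out, "catalog_version") <- attr(catalog, "catalog_version")
  attr(out, "n_bins") <- n_bins
  attr(out, "wavelet") <- wavelet
  out
}

#' Extract the feature vector for a single lesion
#'
#' @param vol An [image_volume()] on the analysis grid.
#' @param mask A [lesion_mask()] on the same grid; must be non-empty.
#' @inheritParams extract_features
#' @return Named numeric vector in catalog order; all values finite.
#' @export
extract_lesion_features <- function(vol, mask, catalog = default_catalog(),
                                    n_bins = 32, wavelet = "coif1") {
  stopifnot_same_grid(vol, mask)
  if (!any(mask$data)) stop("empty ROI: mask has no foreground voxels", call. = FALSE)
  spacing <- vol$spacing

  # crop once with a margin covering the wavelet filter support
  pad <- wavelet_filters(wavelet)$length
  cr <- crop_to_mask(vol$data, mask$data, margin = pad)

  channels_needed <- unique(catalog$channel)
  wav_needed <- setdiff(channels_needed, "original")
  bands <- if (length(wav_needed) > 0) wavelet_bands(cr$vol, wavelet) else list()

  # per (channel, family) feature cache
  cache <- new.env(parent = emptyenv())
  channel_data <- function(ch) if (ch == "original") cr$vol else bands[[ch]]

  family_values <- function(ch, fam) {
    key <- paste(ch, fam, sep = ".")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- switch(fam,
      Stats = first_order_from_values(channel_data(ch)[cr$mask]),
      Shape = shape_features(cr$mask, spacing),
      {
        droi <- droi_for(ch)
        switch(fam,
          GLCM = glcm_features(compute_glcm(droi)),
          GLRLM = glrlm_features(compute_glrlm(droi)),
          GLSZM = glszm_features(compute_glszm(droi)),
          GLDZM = gldzm_features(compute_gldzm(droi)),
          NGLDM = ngldm_features(compute_ngldm(droi)),
          NGTDM = ngtdm_features(compute_ngtdm(droi)),
          stop("unknown feature family: ", fam, call. = FALSE)
        )
      }
    )
    cache[[key]] <- val
    val
  }

  droi_for <- function(ch) {
    key <- paste0(ch, ".droi")
    if (is.null(cache[[key]])) {
      # tighten to a 1-voxel margin: texture matrices only look 1 voxel out
      tight <- crop_to_mask(channel_data(ch), cr$mask, margin = 1L)
      cache[[key]] <- discretize(tight$vol, tight$mask, n_bins = n_bins)
    }
    cache[[key]]
  }

  vals <- numeric(nrow(catalog))
  for (r in seq_len(nrow(catalog))) {
    fam <- catalog$family[r]
    fv <- family_values(catalog$channel[r], fam)
    vals[r] <- fv[[paste0(fam, "_", catalog$feature[r])]]
  }
  names(vals) <- catalog$name

  bad <- !is.finite(vals)
  if (any(bad)) {
    stop("non-finite feature value(s): ",
         paste(utils::head(names(vals)[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  vals
}

#' Write / read a feature table CSV
#'
#' One row per lesion: `patient_id`, `lesion_id`, then catalog-ordered
#' feature columns.
#'
#' @param features Feature tibble from [extract_features()].
#' @param path Output CSV path.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE) |>
    dplyr::mutate(dplyr::across(c("patient_id", "lesion_id"), as.character))
}
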