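#' Voxel-count lesion volume
#'
#' Volume of a lesion mask in mL: foreground voxel count times voxel volume.
#'
#' @param mask A [lesion_mask()] or 3D logical array.
#' @param spacing Voxel spacing in mm (taken from a `lesion_mask`).
#' @return Volume in mL.
#' @export
lesion_volume <- function(mask, spacing = NULL) {
  if (inherits(mask, "lesion_mask")) {
    if (is.null(spacing)) spacing <- mask$spacing
    m <- mask$data
  } else {
    m <- as.array(mask)
    if (is.null(spacing)) stop("`spacing` required for a bare array mask", call. = FALSE)
  }
  sum(m) * voxel_volume_mm3(spacing) / 1000
}

#' Assign per-lesion response labels from paired volumes
#'
#' Computes the signed percent volume change between baseline and evaluation
#' and assigns the two binary outcome labels: `label_pr` (responding lesion,
#' volume decrease of strictly more than 65%, the volume-equivalent of a
#' RECIST 30% diameter decrease) and `label_cr` (complete response, lesion no
#' longer detectable, i.e. evaluation volume 0). CR lesions are by
#' construction a subset of PR lesions.
#'
#' @param volumes A data frame with columns `patient_id`, `lesion_id`,
#'   `volume_baseline_ml` and `volume_evaluation_ml` (0 or `NA` for a lesion
#'   absent at evaluation).
#' @param pr_threshold Percent volume decrease that defines a responding
#'   lesion; the decrease must be strictly greater (default 65).
#' @return A tibble with the input identity columns plus `pct_change`,
#'   `label_pr`, `label_cr`.
#' @export
assign_labels <- function(volumes, pr_threshold = 65) {
  stopifnot(all(c("patient_id", "lesion_id", "volume_baseline_ml",
                  "volume_evaluation_ml") %in% names(volumes)))
  v0 <- volumes$volume_baseline_ml
  v1 <- volumes$volume_evaluation_ml
  v1[is.na(v1)] <- 0
  if (any(!is.finite(v0)) || any(v0 <= 0)) {
    stop("every lesion must have a positive baseline volume", call. = FALSE)
  }
  if (any(v1 < 0)) stop("evaluation volumes must be >= 0", call. = FALSE)
  pct <- 100 * (v1 - v0) / v0
  volumes |>
    dplyr::mutate(volume_evaluation_ml = v1,
                  pct_change = pct,
                  label_pr = pct < -pr_threshold,
                  label_cr = v1 == 0) |>
    tibble::as_tibble()
}

#' Label lesion response from a cohort manifest
#'
#' End-to-end labeling: reads each lesion's baseline and evaluation masks,
#' resamples them to the analysis grid, computes voxel-count volumes, and
#' assigns PR/CR labels with [assign_labels()]. A lesion with no evaluation
#' row in the manifest is treated as disappeared (evaluation volume 0), as is
#' an empty evaluation mask.
#'
#' @param manifest Manifest tibble from [load_manifest()] or a CSV path.
#' @param target_spacing Analysis grid spacing (mm).
#' @param resample If `FALSE`, masks are used at their native grid.
#' @return Tibble: `patient_id`, `lesion_id`, `volume_baseline_ml`,
#'   `volume_evaluation_ml`, `pct_change`, `label_pr`, `label_cr`.
#' @export
label_responses <- function(manifest, target_spacing = c(1, 1, 2),
                            resample = TRUE) {
  if (is.character(manifest) && length(manifest) == 1) {
    manifest <- load_manifest(manifest)
  }
  vol_of <- function(ipath, mpath, pid, lid, tp) {
    vol <- read_volume(ipath)
    mask <- read_mask(mpath, reference = vol, patient_id = pid,
                      lesion_id = lid, timepoint = tp)
    if (resample) mask <- resample_to_grid(vol, mask, target_spacing)$mask
    lesion_volume(mask)
  }
  base <- manifest |> dplyr::filter(.data$timepoint == "baseline")
  ev <- manifest |> dplyr::filter(.data$timepoint == "evaluation")

  v0 <- purrr::pmap_dbl(
    list(base$image_path, base$mask_path, base$patient_id, base$lesion_id),
    function(i, m, p, l) vol_of(i, m, p, l, "baseline"))
  key <- function(d) paste(d$patient_id, d$lesion_id, sep = "\r")
  v1 <- rep(0, nrow(base))
  if (nrow(ev) > 0) {
    v1e <- purrr::pmap_dbl(
      list(ev$image_path, ev$mask_path, ev$patient_id, ev$lesion_id),
      function(i, m, p, l) vol_of(i, m, p, l, "evaluation"))
    v1[match(key(ev), key(base))] <- v1e
  }
  assign_labels(tibble::tibble(patient_id = base$patient_id,
                               lesion_id = base$lesion_id,
                               volume_baseline_ml = v0,
                               volume_evaluation_ml = v1))
}

#' RECIST-equivalent volume threshold
#'
#' Converts a fractional diameter decrease into the equivalent percent volume
#' decrease for a sphere-like lesion: `100 * (1 - (1 - f)^3)`. A RECIST
#' partial-response diameter decrease of 30% corresponds to a 65.7% volume
#' decrease, which motivates the 65% volume cut-off used for PR labeling.
#'
#' @param diameter_decrease_fraction Fractional diameter decrease in (0, 1)
#'   (0 and 1 allowed as limits).
#' @return Percent volume decrease.
#' @export
#' @examples
#' recist_equivalent_volume_threshold(0.30)  # 65.7
recist_equivalent_volume_threshold <- function(diameter_decrease_fraction) {
  f <- diameter_decrease_fraction
  stopifnot(all(f >= 0), all(f <= 1))
  100 * (1 - (1 - f)^3)
}

#' Cohort-level response summary
#'
#' Totals and per-patient tabulation of lesion response (the content of a
#' per-patient waterfall summary): lesion counts, PR and CR counts and
#' fractions overall and per patient.
#'
#' @param outcomes Outcome tibble from [assign_labels()] /
#'   [label_responses()].
#' @return A list with `totals` (one-row tibble: `n_lesions`, `n_pr`, `n_cr`,
#'   `frac_pr`, `frac_cr`) and `per_patient` (tibble with per-patient counts
#'   and median percent change).
#' @export
cohort_response_summary <- function(outcomes) {
  stopifnot(nrow(outcomes) > 0)
  totals <- tibble::tibble(
    n_lesions = nrow(outcomes),
    n_pr = sum(outcomes$label_pr),
    n_cr = sum(outcomes$label_cr),
    frac_pr = mean(outcomes$label_pr),
    frac_cr = mean(outcomes$label_cr)
  )
  per_patient <- outcomes |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_lesions = dplyr::n(),
                     n_pr = sum(.data$label_pr),
                     n_cr = sum(.data$label_cr),
                     median_pct_change = stats::median(.data$pct_change),
                     .groups = "drop")
  list(totals = totals, per_patient = per_patient)
}
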