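#' Discretize ROI intensities into grey levels
#'
#' Equal-width binning of in-mask intensities between the ROI minimum and
#' maximum into `n_bins` levels (1..n_bins). Binning is ROI-relative and
#' applied independently per image channel, which makes all downstream texture
#' features invariant to global intensity shifts. A constant ROI maps to the
#' single level 1.
#'
#' @param vol An [image_volume()] or a 3D numeric array.
#' @param mask A [lesion_mask()] or a 3D logical array of the same shape.
#' @param n_bins Number of grey levels (default 32; must be >= 2).
#' @return A `discretized_roi`: list with `levels` (3D integer array, `NA`
#'   outside the mask), `n_levels`, and `range` (in-mask min/max intensity).
#' @export
discretize <- function(vol, mask, n_bins = 32) {
  data <- if (inherits(vol, "image_volume")) vol$data else as.array(vol)
  m <- if (inherits(mask, "lesion_mask")) mask$data else as.array(mask)
  stopifnot(identical(dim(data), dim(m)))
  if (!any(m)) stop("empty ROI: mask has no foreground voxels", call. = FALSE)
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)

  vals <- data[m]
  lo <- min(vals); hi <- max(vals)
  lv <- array(NA_integer_, dim = dim(data))
  if (hi - lo <= 0) {
    lv[m] <- 1L
    n_levels <- 1L
  } else {
    g <- pmin(as.integer(floor(n_bins * (vals - lo) / (hi - lo))) + 1L, n_bins)
    lv[m] <- g
    n_levels <- as.integer(n_bins)
  }
  structure(list(levels = lv, n_levels = n_levels, range = c(lo, hi)),
            class = "discretized_roi")
}

#' First-order intensity statistics of a lesion ROI
#'
#' The seven first-order grey-level statistics used by the default feature
#' catalog: mean, standard deviation, variance, root mean square, 10th and
#' 90th percentile, and interquartile range. Variance is the population
#' variance (denominator n); percentiles use linear interpolation between
#' closest ranks.
#'
#' @param vol An [image_volume()] or 3D numeric array.
#' @param mask A [lesion_mask()] or 3D logical array; must be non-empty.
#' @return Named numeric vector of length 7 with names
#'   `Stats_mean, Stats_std, Stats_var, Stats_rms, Stats_p10, Stats_p90,
#'   Stats_iqr`.
#' @export
first_order_features <- function(vol, mask) {
  data <- if (inherits(vol, "image_volume")) vol$data else as.array(vol)
  m <- if (inherits(mask, "lesion_mask")) mask$data else as.array(mask)
  if (!any(m)) stop("empty ROI: mask has no foreground voxels", call. = FALSE)
  first_order_from_values(data[m])
}

first_order_from_values <- function(x) {
  n <- length(x)
  mu <- mean(x)
  v <- sum((x - mu)^2) / n
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  c(Stats_mean = mu,
    Stats_std = sqrt(v),
    Stats_var = v,
    Stats_rms = sqrt(mean(x^2)),
    Stats_p10 = q[1],
    Stats_p90 = q[4],
    Stats_iqr = q[3] - q[2])
}
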