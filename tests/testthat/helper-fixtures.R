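# Fixtures built in code; no binary files.

# Digital ball mask of radius r_mm on an isotropic-in-plane grid.
make_ball_mask <- function(r_mm, spacing = c(1, 1, 2), margin_mm = 4) {
  dims <- as.integer(ceiling(2 * (r_mm + margin_mm) / spacing))
  ctr <- (dims - 1) * spacing / 2
  q <- outer(outer(((seq_len(dims[1]) - 1) * spacing[1] - ctr[1])^2,
                   ((seq_len(dims[2]) - 1) * spacing[2] - ctr[2])^2, `+`),
             ((seq_len(dims[3]) - 1) * spacing[3] - ctr[3])^2, `+`)
  array(q <= r_mm^2, dims)
}

# Noisy textured lesion on its ball mask; returns image_volume + lesion_mask.
make_test_lesion <- function(r_mm = 8, spacing = c(1, 1, 2), seed = 1,
                             base = 60, sd = 15) {
  set.seed(seed)
  m <- make_ball_mask(r_mm, spacing)
  img <- array(stats::rnorm(length(m), base, sd), dim(m))
  list(vol = lesionrad::image_volume(img, spacing),
       mask = lesionrad::lesion_mask(m, spacing))
}

# Random small discretized ROI for oracle comparisons.
random_droi <- function(dims = c(4, 4, 4), n_levels = 4, p_mask = 0.8,
                        seed = 1) {
  set.seed(seed)
  m <- array(stats::runif(prod(dims)) < p_mask, dims)
  if (!any(m)) m[1, 1, 1] <- TRUE
  lv <- array(NA_integer_, dims)
  lv[m] <- sample.int(n_levels, sum(m), replace = TRUE)
  structure(list(levels = lv, n_levels = as.integer(n_levels),
                 range = c(0, 1)), class = "discretized_roi")
}

# Reduced synthetic cohort configuration used across the heavier tests:
# 8 patients with 1-6 small lesions each on compact grids.
reduced_cohort_config <- function(seed, delta = 2 * log(2), ...) {
  lesionrad::synthetic_config(
    n_patients = 8, lesion_median = 3, lesion_sdlog = 0.5,
    lesions_min = 1, lesions_max = 6,
    volume_range_ml = c(0.3, 6),
    grid_max = c(64, 64, 32),
    delta = delta, seed = seed, ...)
}

# Generate a reduced cohort in a temp dir, extract features and labels.
reduced_cohort_data <- function(seed, delta = 2 * log(2), ...) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  gen <- lesionrad::generate_cohort(reduced_cohort_config(seed, delta, ...), dir)
  features <- lesionrad::extract_features(gen$manifest)
  outcomes <- lesionrad::label_responses(gen$manifest)
  list(manifest = gen$manifest, truth = gen$truth,
       features = features, outcomes = outcomes)
}
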