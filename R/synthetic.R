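#' Configuration for the synthetic cohort generator
#'
#' Defines the cohort geometry and the generative model for synthetic
#' paired-timepoint CT cohorts with known per-lesion response. Defaults
#' emulate the study cohort this pipeline targets: 18 patients, a median of
#' 10 (range 1-42) lesions per patient, baseline lesion volumes spanning
#' about 0.06-195 cm^3 (drawn log-uniform to cover the three-decade range),
#' a 51% responding-lesion (PR) rate and a 47% complete-response rate among
#' responders.
#'
#' Lesions are ellipsoids with a smooth random surface perturbation; in-mask
#' intensity is a base Hounsfield level plus a Gaussian random field whose
#' correlation length depends on response class, plus white noise. The class
#' texture difference is controlled by `delta`: responders get correlation
#' length `corr_length_base * exp(-delta / 2)` mm, non-responders
#' `corr_length_base * exp(+delta / 2)` mm, so `delta = 0` makes the classes
#' exactly exchangeable at baseline. The default `delta = 2 * log(2)` gives
#' 2 mm vs 8 mm.
#'
#' @param n_patients Number of patients.
#' @param lesion_median,lesion_sdlog,lesions_min,lesions_max Per-patient
#'   lesion count: `round(rlnorm(log(lesion_median), lesion_sdlog))` clamped
#'   to `[lesions_min, lesions_max]`.
#' @param volume_range_ml Baseline volume range (mL), log-uniform.
#' @param grid_max Maximum per-lesion grid (voxels); each lesion is rendered
#'   on its own grid sized to the lesion plus margin, capped here.
#' @param spacing Voxel spacing (mm) of the emitted volumes.
#' @param base_hu,background_hu,noise_sd,texture_amplitude Intensity model
#'   (HU): lesion base level, background level, white-noise sd, and the sd
#'   of the class-dependent texture field.
#' @param corr_length_base Texture correlation length scale (mm).
#' @param delta Class texture separation (see above); 0 = null cohort.
#' @param p_pr Probability a lesion responds (> 65% volume decrease).
#' @param p_cr_given_pr Probability a responding lesion disappears.
#' @param size_coupled_cr If `TRUE`, CR probability is coupled to lesion
#'   size (smaller lesions more likely to disappear), with the marginal
#'   CR-given-PR rate held at `p_cr_given_pr`.
#' @param size_coupling_gamma Strength of the size coupling (volume
#'   exponent).
#' @param pct_change_pr,pct_change_nr Percent-volume-change ranges (uniform)
#'   for responding (non-CR) and non-responding lesions.
#' @param seed Master seed; every random draw derives from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 18,
                             lesion_median = 10, lesion_sdlog = 0.8,
                             lesions_min = 1, lesions_max = 42,
                             volume_range_ml = c(0.06, 195),
                             grid_max = c(128, 128, 64),
                             spacing = c(1, 1, 2),
                             base_hu = 60, background_hu = 30,
                             noise_sd = 5, texture_amplitude = 25,
                             corr_length_base = 4,
                             delta = 2 * log(2),
                             p_pr = 0.51, p_cr_given_pr = 0.47,
                             size_coupled_cr = FALSE,
                             size_coupling_gamma = 0.8,
                             pct_change_pr = c(-97, -70),
                             pct_change_nr = c(-55, 50),
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(p_pr >= 0, p_pr <= 1, p_cr_given_pr >= 0, p_cr_given_pr <= 1,
            all(volume_range_ml > 0), delta >= 0,
            pct_change_pr[2] < -65, pct_change_nr[1] > -65)
  structure(cfg, class = "synthetic_config")
}

#' Draw the cohort plan (no rendering)
#'
#' Draws patients, lesion counts, baseline volumes, response classes and
#' volume changes — everything except voxel data. Used internally by
#' [generate_cohort()]; exposed because cohort-shape properties can be
#' checked cheaply on the plan alone.
#'
#' @param cfg A [synthetic_config()].
#' @return Tibble, one row per lesion, with generating parameters including
#'   a per-lesion rendering seed.
#' @export
draw_cohort_plan <- function(cfg) {
  set.seed(as.integer(cfg$seed))
  rows <- list()
  len_pr <- cfg$corr_length_base * exp(-cfg$delta / 2)
  len_nr <- cfg$corr_length_base * exp(cfg$delta / 2)
  for (p in seq_len(cfg$n_patients)) {
    n_les <- round(stats::rlnorm(1, log(cfg$lesion_median), cfg$lesion_sdlog))
    n_les <- min(max(n_les, cfg$lesions_min), cfg$lesions_max)
    lr <- log(cfg$volume_range_ml)
    v0 <- exp(stats::runif(n_les, lr[1], lr[2]))
    is_pr <- stats::runif(n_les) < cfg$p_pr
    rows[[p]] <- tibble::tibble(
      patient_id = sprintf("P%02d", p),
      lesion_id = sprintf("L%02d", seq_len(n_les)),
      v0_target_ml = v0,
      class_pr = is_pr
    )
  }
  plan <- dplyr::bind_rows(rows)

  # CR assignment among responders, optionally size-coupled
  plan$class_cr <- FALSE
  pr_idx <- which(plan$class_pr)
  if (length(pr_idx) > 0 && cfg$p_cr_given_pr > 0) {
    if (cfg$size_coupled_cr) {
      w <- plan$v0_target_ml[pr_idx]^(-cfg$size_coupling_gamma)
      # scale so the mean CR probability equals p_cr_given_pr
      f <- function(cc) mean(pmin(cc * w, 1)) - cfg$p_cr_given_pr
      cc <- stats::uniroot(f, c(1e-9, 1e9), tol = 1e-10)$root
      p_cr <- pmin(cc * w, 1)
    } else {
      p_cr <- rep(cfg$p_cr_given_pr, length(pr_idx))
    }
    plan$class_cr[pr_idx] <- stats::runif(length(pr_idx)) < p_cr
  }

  n <- nrow(plan)
  pct <- numeric(n)
  pr_noncr <- plan$class_pr & !plan$class_cr
  pct[pr_noncr] <- stats::runif(sum(pr_noncr), cfg$pct_change_pr[1],
                                cfg$pct_change_pr[2])
  pct[!plan$class_pr] <- stats::runif(sum(!plan$class_pr),
                                      cfg$pct_change_nr[1],
                                      cfg$pct_change_nr[2])
  pct[plan$class_cr] <- -100
  plan$pct_change_true <- pct
  plan$corr_length_mm <- ifelse(plan$class_pr, len_pr, len_nr)
  plan$lesion_seed <- sample.int(.Machine$integer.max - 1L, n)
  # scalar generator parameters repeated per row so the truth table is
  # self-contained for regeneration
  plan$spacing_x <- cfg$spacing[1]; plan$spacing_y <- cfg$spacing[2]
  plan$spacing_z <- cfg$spacing[3]
  plan$base_hu <- cfg$base_hu; plan$background_hu <- cfg$background_hu
  plan$noise_sd <- cfg$noise_sd; plan$texture_amplitude <- cfg$texture_amplitude
  plan$grid_max_x <- cfg$grid_max[1]; plan$grid_max_y <- cfg$grid_max[2]
  plan$grid_max_z <- cfg$grid_max[3]
  plan
}

#' Generate a synthetic paired-timepoint cohort on disk
#'
#' Renders every lesion of the cohort plan as a NIfTI image/mask pair at
#' baseline and (for lesions that do not disappear) at evaluation, writes a
#' cohort manifest `cohort.csv` and ground-truth table `truth.csv`, and
#' returns both. Rendering is fully seeded: the same config produces
#' byte-identical volumes.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return List with `manifest` (validated, as from [load_manifest()]),
#'   `truth` (the plan with per-lesion parameters) and `dir`.
#' @export
generate_cohort <- function(cfg, dir) {
  truth <- draw_cohort_plan(cfg)
  write_cohort_files(truth, dir)
}

#' Re-render a cohort from its ground truth
#'
#' Rebuilds all NIfTI files from a `truth.csv` table; output is
#' byte-identical to the original generation because every lesion carries
#' its own rendering seed.
#'
#' @param truth Truth tibble from [generate_cohort()] (or `truth.csv` path).
#' @param dir Output directory.
#' @return As [generate_cohort()].
#' @export
regenerate_from_truth <- function(truth, dir) {
  if (is.character(truth) && length(truth) == 1) {
    truth <- readr::read_csv(truth, show_col_types = FALSE, progress = FALSE)
  }
  if (!"lesion_seed" %in% names(truth) || any(is.na(truth$lesion_seed))) {
    stop("truth table must carry per-lesion seeds", call. = FALSE)
  }
  write_cohort_files(tibble::as_tibble(truth), dir)
}

write_cohort_files <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man_rows <- vector("list", nrow(truth))
  for (r in seq_len(nrow(truth))) {
    tr <- truth[r, ]
    spacing <- c(tr$spacing_x, tr$spacing_y, tr$spacing_z)
    grid_max <- c(tr$grid_max_x, tr$grid_max_y, tr$grid_max_z)
    les <- render_lesion(tr, spacing, grid_max)
    stem <- sprintf("%s_%s", tr$patient_id, tr$lesion_id)
    paths <- list(
      img0 = sprintf("%s_baseline_img.nii.gz", stem),
      msk0 = sprintf("%s_baseline_mask.nii.gz", stem),
      img1 = sprintf("%s_evaluation_img.nii.gz", stem),
      msk1 = sprintf("%s_evaluation_mask.nii.gz", stem)
    )
    write_volume(les$vol0, file.path(dir, paths$img0))
    write_mask(les$mask0, file.path(dir, paths$msk0))
    rows <- tibble::tibble(patient_id = tr$patient_id,
                           lesion_id = tr$lesion_id,
                           timepoint = "baseline",
                           image_path = paths$img0, mask_path = paths$msk0)
    if (!tr$class_cr) {
      write_volume(les$vol1, file.path(dir, paths$img1))
      write_mask(les$mask1, file.path(dir, paths$msk1))
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        patient_id = tr$patient_id, lesion_id = tr$lesion_id,
        timepoint = "evaluation",
        image_path = paths$img1, mask_path = paths$msk1))
    }
    man_rows[[r]] <- rows
  }
  man <- dplyr::bind_rows(man_rows)
  man_path <- file.path(dir, "cohort.csv")
  readr::write_csv(man, man_path)
  readr::write_csv(truth, file.path(dir, "truth.csv"))
  list(manifest = load_manifest(man_path), truth = truth, dir = dir)
}

# Render one lesion at both timepoints on its own grid.
render_lesion <- function(tr, spacing, grid_max) {
  set.seed(as.integer(tr$lesion_seed))
  v0_mm3 <- tr$v0_target_ml * 1000
  r_eq <- (3 * v0_mm3 / (4 * pi))^(1 / 3)

  # randomized ellipsoid axes with preserved volume
  ax <- stats::runif(3, 0.75, 1.3)
  ax <- ax / prod(ax)^(1 / 3)
  radii <- r_eq * ax

  margin_mm <- 8
  dims <- pmin(grid_max,
               pmax(8L, as.integer(ceiling(2 * (radii + margin_mm) / spacing))))
  if (any(2 * radii > dims * spacing)) {
    stop("lesion larger than the maximum rendering grid; increase grid_max",
         call. = FALSE)
  }
  centre <- (dims - 1) * spacing / 2

  # voxel-centre coordinate grids (mm)
  cx <- (seq_len(dims[1]) - 1) * spacing[1]
  cy <- (seq_len(dims[2]) - 1) * spacing[2]
  cz <- (seq_len(dims[3]) - 1) * spacing[3]
  QX <- ((cx - centre[1]))^2
  QY <- ((cy - centre[2]))^2
  QZ <- ((cz - centre[3]))^2

  quad <- function(rs) {
    outer(outer(QX / rs[1]^2, QY / rs[2]^2, `+`), QZ / rs[3]^2, `+`)
  }

  # smooth surface perturbation and texture fields (shared across timepoints)
  perturb <- gaussian_random_field(dims, spacing, corr_length = 5)
  texture <- gaussian_random_field(dims, spacing,
                                   corr_length = tr$corr_length_mm)
  noise0 <- array(stats::rnorm(prod(dims), 0, tr$noise_sd), dims)
  noise1 <- array(stats::rnorm(prod(dims), 0, tr$noise_sd), dims)

  make_mask <- function(scale) {
    q <- quad(radii * scale)
    m <- q + 0.12 * perturb * q <= 1  # perturbation scaled by q: smooth boundary wobble
    if (!any(m)) {
      ic <- pmax(1L, as.integer(round(centre / spacing)) + 1L)
      m[ic[1], ic[2], ic[3]] <- TRUE
    }
    m
  }

  mask0 <- make_mask(1)
  img0 <- tr$background_hu + noise0
  img0[mask0] <- tr$base_hu + tr$texture_amplitude * texture[mask0] +
    noise0[mask0]

  vol0 <- image_volume(img0, spacing = spacing)
  m0 <- lesion_mask(mask0, spacing = spacing, patient_id = tr$patient_id,
                    lesion_id = tr$lesion_id, timepoint = "baseline")
  out <- list(vol0 = vol0, mask0 = m0)

  if (!tr$class_cr) {
    scale1 <- (1 + tr$pct_change_true / 100)^(1 / 3)
    mask1 <- make_mask(scale1)
    img1 <- tr$background_hu + noise1
    img1[mask1] <- tr$base_hu + tr$texture_amplitude * texture[mask1] +
      noise1[mask1]
    out$vol1 <- image_volume(img1, spacing = spacing)
    out$mask1 <- lesion_mask(mask1, spacing = spacing,
                             patient_id = tr$patient_id,
                             lesion_id = tr$lesion_id,
                             timepoint = "evaluation")
  }
  out
}

#' Gaussian random field with given correlation length
#'
#' White Gaussian noise smoothed with a separable Gaussian kernel whose
#' standard deviation along each axis is `corr_length` mm (converted to
#' voxels via the spacing), then standardized to zero mean and unit
#' variance over the grid.
#'
#' @param dims Grid dimensions (3 integers).
#' @param spacing Voxel spacing (mm).
#' @param corr_length Correlation length (mm).
#' @return 3D array with sd 1.
#' @export
gaussian_random_field <- function(dims, spacing, corr_length) {
  z <- array(stats::rnorm(prod(dims)), dims)
  sig_vox <- corr_length / spacing
  for (ax in 1:3) {
    s <- sig_vox[ax]
    if (s < 0.3) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    z <- conv_axis_kernel(z, k, ax)
  }
  sd_z <- stats::sd(z)
  if (sd_z > 0) z <- (z - mean(z)) / sd_z
  z
}

# Gaussian smoothing along one axis with symmetric boundary handling
# (odd-length kernel, zero phase).
conv_axis_kernel <- function(a, k, ax) {
  dims <- dim(a)
  n <- dims[ax]
  L <- length(k)
  half <- (L - 1L) %/% 2L
  idx <- reflect_index(seq.int(1 - half, n + half), n)
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  mat <- matrix(ap, nrow = dp[1])
  padded <- mat[idx, , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(mat))
  for (j in seq_len(L)) {
    out <- out + k[j] * padded[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  dim(out) <- dp
  aperm(out, order(perm))
}
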