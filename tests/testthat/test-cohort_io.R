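write_manifest_csv <- function(rows, dir) {
  path <- file.path(dir, "cohort.csv")
  readr::write_csv(rows, path)
  path
}

dummy_files <- function(dir, n) {
  # manifest validation only needs the files to exist
  paths <- file.path(dir, sprintf("f%02d.nii.gz", seq_len(n)))
  vol <- image_volume(array(0, c(2, 2, 2)))
  for (p in paths) write_volume(vol, p)
  basename(paths)
}

test_that("manifest loading validates schema and pairs lesions across timepoints", {
  dir <- withr::local_tempdir()
  f <- dummy_files(dir, 8)
  rows <- tidyr::expand_grid(patient_id = c("P1", "P2"),
                             lesion_id = c("L1", "L2"),
                             timepoint = c("baseline", "evaluation"))
  rows$image_path <- f
  rows$mask_path <- f
  man <- load_manifest(write_manifest_csv(rows, dir))
  expect_equal(nrow(man), 8)
  expect_equal(sum(man$timepoint == "baseline"), 4)
  expect_false(any(man$absent_at_evaluation))

  # a baseline-only lesion is flagged as absent at evaluation
  rows2 <- rows[!(rows$lesion_id == "L2" & rows$patient_id == "P1" &
                    rows$timepoint == "evaluation"), ]
  man2 <- load_manifest(write_manifest_csv(rows2, dir))
  flagged <- man2[man2$absent_at_evaluation, ]
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$lesion_id, "L2")
  expect_equal(flagged$patient_id, "P1")
})

test_that("manifest integrity errors: missing column, duplicates, orphan evaluation", {
  dir <- withr::local_tempdir()
  f <- dummy_files(dir, 2)
  base <- tibble::tibble(patient_id = "P1", lesion_id = "L1",
                         timepoint = "baseline",
                         image_path = f[1], mask_path = f[2])

  expect_error(load_manifest(write_manifest_csv(base[, -2], dir)),
               "missing required column")
  expect_error(load_manifest(write_manifest_csv(rbind(base, base), dir)),
               "duplicate")
  orphan <- base; orphan$timepoint <- "evaluation"
  expect_error(load_manifest(write_manifest_csv(orphan, dir)),
               "without a baseline")
  badtp <- base; badtp$timepoint <- "followup"
  expect_error(load_manifest(write_manifest_csv(badtp, dir)),
               "timepoint")
})

test_that("NIfTI round trip preserves data, spacing and origin", {
  dir <- withr::local_tempdir()
  set.seed(7)
  vol <- image_volume(array(rnorm(64^2 * 8), c(64, 64, 8)),
                      spacing = c(0.7, 0.7, 5), origin = c(-10, 4, 22.5))
  p <- file.path(dir, "v.nii.gz")
  write_volume(vol, p)
  back <- read_volume(p)
  expect_equal(back$data, vol$data, tolerance = 1e-6)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)
})

test_that("mask reading binarizes at 0.5 and enforces grid alignment", {
  dir <- withr::local_tempdir()
  ref <- image_volume(array(0, c(4, 4, 4)))
  frac <- image_volume(array(c(0, 0.2, 0.500001, 0.9), c(4, 4, 4)))
  p <- file.path(dir, "m.nii.gz")
  write_volume(frac, p)
  m <- read_mask(p, reference = ref)
  expect_equal(as.vector(m$data[1:4, 1, 1]), c(FALSE, FALSE, TRUE, TRUE))

  wrong <- image_volume(array(0, c(5, 4, 4)))
  expect_error(read_mask(p, reference = wrong), "does not match")
})

test_that("resampling is identity on the target grid and exact on constants", {
  vol <- image_volume(array(rnorm(16^3), c(16, 16, 16)), spacing = c(1, 1, 2))
  out <- resample_to_grid(vol, target_spacing = c(1, 1, 2))
  expect_identical(out$vol$data, vol$data)

  const <- image_volume(array(42, c(20, 20, 6)), spacing = c(0.7, 0.7, 5))
  rc <- resample_to_grid(const, target_spacing = c(1, 1, 2))
  expect_equal(rc$vol$spacing, c(1, 1, 2))
  expect_true(all(abs(rc$vol$data - 42) < 1e-12))
})

test_that("resampled sphere mask volume is within 5% of the analytic volume", {
  sp_in <- c(0.8, 0.8, 3)
  m <- make_ball_mask(20, spacing = sp_in, margin_mm = 6)
  vol <- image_volume(array(0, dim(m)), spacing = sp_in)
  mask <- lesion_mask(m, spacing = sp_in)
  out <- resample_to_grid(vol, mask, target_spacing = c(1, 1, 2))
  v_analytic <- 4 / 3 * pi * 20^3
  v_before <- sum(m) * prod(sp_in)
  v_after <- sum(out$mask$data) * 2
  expect_lt(abs(v_after - v_analytic) / v_analytic, 0.05)
  # voxel-count volume approximately conserved across resampling
  expect_lt(abs(v_after - v_before) / v_before, 0.05)
})

test_that("single-voxel-thick axes are resampled by edge clamping, not failure", {
  thin <- image_volume(array(seq_len(12), c(4, 3, 1)), spacing = c(2, 2, 2))
  out <- resample_to_grid(thin, target_spacing = c(1, 1, 2))
  expect_equal(dim(out$vol$data)[3], 1)
  expect_true(all(is.finite(out$vol$data)))
})
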