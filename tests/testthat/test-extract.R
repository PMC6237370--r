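test_that("default catalog has 370 uniquely named entries split 7/19/65/279", {
  cat <- default_catalog()
  expect_equal(nrow(cat), 370)
  expect_false(anyDuplicated(cat$name) > 0)
  counts <- catalog_group_counts(cat)
  expect_equal(counts$n[counts$group == "first_order"], 7L)
  expect_equal(counts$n[counts$group == "shape"], 19L)
  expect_equal(counts$n[counts$group == "texture"], 65L)
  expect_equal(counts$n[counts$group == "wavelet"], 279L)
})

test_that("the catalog contains every top-importance feature name", {
  nm <- default_catalog()$name
  required <- c("Wavelet_LHH_GLCM_correl1", "GLCM_clusShade",
                "Wavelet_LHH_Stats_rms", "Wavelet_LLL_GLCM_clusShade",
                "Wavelet_LHH_Stats_std", "Wavelet_LHH_Stats_p90",
                "Wavelet_LHH_GLCM_infoCorr1", "Wavelet_LHH_Stats_var",
                "Wavelet_HHH_GLCM_infoCorr1", "Wavelet_HHH_Stats_p10",
                "Wavelet_HHH_GLDZM_LDE", "Wavelet_HHH_GLDZM_SDE",
                "Wavelet_HHH_GLDZM_DZNN", "Wavelet_HHH_GLDZM_DZV",
                "Wavelet_HHL_Stats_p10", "GLSZM_ZP",
                "Wavelet_HHH_NGTDM_coarseness", "Wavelet_HHH_Stats_iqr",
                "Wavelet_HHL_Stats_iqr")
  expect_true(all(required %in% nm))
})

test_that("extraction returns a finite vector in catalog order for any lesion", {
  les <- make_test_lesion(r_mm = 7, seed = 2)
  fv <- extract_lesion_features(les$vol, les$mask)
  expect_length(fv, 370)
  expect_identical(names(fv), default_catalog()$name)
  expect_true(all(is.finite(fv)))
})

test_that("degenerate ROIs (1-2 voxels, constant intensity) still yield finite vectors", {
  m <- array(FALSE, c(8, 8, 6)); m[4, 4, 3] <- TRUE
  vol <- image_volume(array(50, c(8, 8, 6)))
  fv1 <- extract_lesion_features(vol, lesion_mask(m))
  expect_true(all(is.finite(fv1)))

  m[5, 4, 3] <- TRUE
  fv2 <- extract_lesion_features(vol, lesion_mask(m))
  expect_true(all(is.finite(fv2)))

  expect_error(extract_lesion_features(vol, lesion_mask(array(FALSE, c(8, 8, 6)))),
               "empty ROI")
})

test_that("intensity shift moves location statistics by +c and nothing else", {
  les <- make_test_lesion(r_mm = 6, seed = 8)
  shift <- 250
  vol2 <- image_volume(les$vol$data + shift, les$vol$spacing)
  f1 <- extract_lesion_features(les$vol, les$mask)
  f2 <- extract_lesion_features(vol2, les$mask)
  loc <- c("Stats_mean", "Stats_p10", "Stats_p90")
  expect_equal(f2[loc], f1[loc] + shift, tolerance = 1e-9)
  spread <- c("Stats_std", "Stats_var", "Stats_iqr")
  expect_equal(f2[spread], f1[spread], tolerance = 1e-9)
  # discretized texture features on the original channel are shift-invariant
  tex <- default_catalog()
  tex_names <- tex$name[tex$channel == "original" &
                          !tex$family %in% c("Stats", "Shape")]
  expect_equal(f2[tex_names], f1[tex_names], tolerance = 1e-9)
})

test_that("swapping x and y axes leaves direction-averaged features unchanged", {
  les <- make_test_lesion(r_mm = 6, seed = 12, sd = 12)
  sw_vol <- image_volume(aperm(les$vol$data, c(2, 1, 3)), les$vol$spacing)
  sw_mask <- lesion_mask(aperm(les$mask$data, c(2, 1, 3)), les$mask$spacing)
  f1 <- extract_lesion_features(les$vol, les$mask)
  f2 <- extract_lesion_features(sw_vol, sw_mask)
  # texture features on the original channel average over symmetric directions
  keep <- default_catalog()
  orig_tex <- keep$name[keep$channel == "original" & keep$family != "Shape"]
  expect_equal(f2[orig_tex], f1[orig_tex], tolerance = 1e-9)
  expect_equal(f2[["Shape_volume_ml"]], f1[["Shape_volume_ml"]], tolerance = 1e-9)
})

test_that("extract_features processes a manifest into a lesion-by-feature tibble", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_patients = 2, lesion_median = 2, lesion_sdlog = 0.3,
                          lesions_min = 1, lesions_max = 3,
                          volume_range_ml = c(0.3, 2),
                          grid_max = c(48, 48, 24), seed = 31)
  gen <- generate_cohort(cfg, dir)
  ft <- extract_features(gen$manifest)
  n_base <- sum(gen$manifest$timepoint == "baseline")
  expect_equal(nrow(ft), n_base)
  expect_equal(ncol(ft), 372)  # ids + 370 features
  expect_identical(names(ft)[1:2], c("patient_id", "lesion_id"))
  expect_true(all(vapply(ft[, -(1:2)], function(x) all(is.finite(x)), logical(1))))

  # round trip through CSV
  p <- file.path(dir, "features.csv")
  write_features(ft, p)
  back <- read_features(p)
  expect_equal(as.data.frame(back), as.data.frame(ft), tolerance = 1e-12,
               ignore_attr = TRUE)
})
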