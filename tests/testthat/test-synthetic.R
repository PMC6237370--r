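test_that("cohort plan reproduces the target cohort geometry at defaults", {
  meds <- vapply(1:12, function(s) {
    plan <- draw_cohort_plan(synthetic_config(seed = s))
    stats::median(as.numeric(table(plan$patient_id)))
  }, numeric(1))
  # median lesions per patient targets 10
  expect_gte(mean(meds), 7)
  expect_lte(mean(meds), 13)

  plan <- draw_cohort_plan(synthetic_config(seed = 1))
  counts <- table(plan$patient_id)
  expect_equal(length(counts), 18)
  expect_true(all(counts >= 1 & counts <= 42))
  expect_true(all(plan$v0_target_ml >= 0.06 & plan$v0_target_ml <= 195))
  # CR implies PR in the generative classes too
  expect_true(all(plan$class_pr[plan$class_cr]))
})

test_that("emitted PR and CR fractions converge to the configured rates", {
  plans <- dplyr::bind_rows(lapply(1:6, function(s)
    draw_cohort_plan(synthetic_config(seed = 200 + s))))
  n <- nrow(plans)
  p_hat <- mean(plans$class_pr)
  expect_lt(abs(p_hat - 0.51), 4 * sqrt(0.51 * 0.49 / n))
  cr_given_pr <- mean(plans$class_cr[plans$class_pr])
  n_pr <- sum(plans$class_pr)
  expect_lt(abs(cr_given_pr - 0.47), 4 * sqrt(0.47 * 0.53 / n_pr))
})

test_that("delta = 0 makes class texture parameters identical", {
  plan <- draw_cohort_plan(reduced_cohort_config(seed = 3, delta = 0))
  expect_equal(length(unique(plan$corr_length_mm)), 1L)
  plan2 <- draw_cohort_plan(reduced_cohort_config(seed = 3, delta = 2 * log(2)))
  expect_setequal(round(unique(plan2$corr_length_mm), 6), c(2, 8))
})

test_that("size-coupled CR keeps the marginal rate but favours small lesions", {
  cfg <- synthetic_config(n_patients = 40, seed = 17, size_coupled_cr = TRUE)
  plan <- draw_cohort_plan(cfg)
  pr <- plan[plan$class_pr, ]
  rate <- mean(pr$class_cr)
  expect_lt(abs(rate - 0.47), 4 * sqrt(0.47 * 0.53 / nrow(pr)))
  expect_lt(median(pr$v0_target_ml[pr$class_cr]),
            median(pr$v0_target_ml[!pr$class_cr]))
})

test_that("generation is reproducible: same truth -> identical files, new seed -> different", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  dir3 <- withr::local_tempdir()
  cfg <- synthetic_config(n_patients = 2, lesion_median = 2, lesion_sdlog = 0.3,
                          lesions_min = 1, lesions_max = 3,
                          volume_range_ml = c(0.3, 2),
                          grid_max = c(48, 48, 24), seed = 8)
  gen1 <- generate_cohort(cfg, dir1)
  gen2 <- regenerate_from_truth(gen1$truth, dir2)
  h <- function(d) tools::md5sum(sort(list.files(d, pattern = "nii", full.names = TRUE)))
  expect_identical(unname(h(dir1)), unname(h(dir2)))

  cfg3 <- synthetic_config(n_patients = 2, lesion_median = 2, lesion_sdlog = 0.3,
                           lesions_min = 1, lesions_max = 3,
                           volume_range_ml = c(0.3, 2),
                           grid_max = c(48, 48, 24), seed = 9)
  gen3 <- generate_cohort(cfg3, dir3)
  expect_false(identical(unname(h(dir1)), unname(h(dir3))))

  # truth without seeds cannot be regenerated
  expect_error(regenerate_from_truth(dplyr::select(gen1$truth, -lesion_seed), dir2),
               "seed")
})

test_that("emitted mask volumes track the drawn target volumes", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_patients = 3, lesion_median = 3, lesion_sdlog = 0.3,
                          lesions_min = 2, lesions_max = 4,
                          volume_range_ml = c(0.5, 8),
                          grid_max = c(64, 64, 32), seed = 23)
  gen <- generate_cohort(cfg, dir)
  base <- gen$manifest[gen$manifest$timepoint == "baseline", ]
  v_mask <- vapply(seq_len(nrow(base)), function(i) {
    lesion_volume(read_mask(base$mask_path[i]))
  }, numeric(1))
  key <- paste(base$patient_id, base$lesion_id)
  v_target <- gen$truth$v0_target_ml[match(key, paste(gen$truth$patient_id,
                                                      gen$truth$lesion_id))]
  # voxelization + surface perturbation: volumes agree within 25%
  expect_true(all(abs(v_mask - v_target) / v_target < 0.25))
  expect_gt(cor(v_mask, v_target), 0.99)
})

test_that("downstream labels recover the generative classes", {
  dat <- reduced_cohort_data(seed = 41, delta = 0)
  truth <- dat$truth
  out <- dat$outcomes
  key <- paste(out$patient_id, out$lesion_id)
  tr <- truth[match(key, paste(truth$patient_id, truth$lesion_id)), ]
  expect_equal(out$label_cr, tr$class_cr)
  # PR recovery tolerates voxelization noise near the threshold
  expect_gt(mean(out$label_pr == tr$class_pr), 0.9)
})

test_that("the texture field has the configured correlation structure", {
  set.seed(99)
  dims <- c(48, 48, 24); sp <- c(1, 1, 2)
  short <- gaussian_random_field(dims, sp, corr_length = 1)
  long <- gaussian_random_field(dims, sp, corr_length = 8)
  lag1 <- function(z) cor(as.vector(z[-1, , ]), as.vector(z[-dim(z)[1], , ]))
  expect_equal(sd(short), 1, tolerance = 1e-6)
  expect_equal(sd(long), 1, tolerance = 1e-6)
  expect_gt(lag1(long), lag1(short))
  expect_gt(lag1(long), 0.9)
})
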