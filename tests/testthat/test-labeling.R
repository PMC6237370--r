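test_that("voxel-count volume converts to mL; 500 voxels at (1,1,2) mm = 1 mL", {
  m <- array(FALSE, c(10, 10, 10)); m[which(seq_len(1000) <= 500)] <- TRUE
  expect_equal(lesion_volume(m, spacing = c(1, 1, 2)), 1.0)
  expect_equal(lesion_volume(array(FALSE, c(4, 4, 4)), spacing = c(1, 1, 2)), 0)
})

test_that("a digital ball of r = 36 mm reaches the cohort's upper volume scale", {
  m <- make_ball_mask(36, spacing = c(1, 1, 2), margin_mm = 3)
  v <- lesion_volume(m, spacing = c(1, 1, 2))
  expect_lt(abs(v - 4 / 3 * pi * 36^3 / 1000) / v, 0.05)  # ~195 mL
})

test_that("PR/CR labels follow the strict 65% rule and the subset invariant", {
  vols <- tibble::tibble(
    patient_id = "P1", lesion_id = c("a", "b", "c", "d"),
    volume_baseline_ml = 10,
    volume_evaluation_ml = c(3.4, 0, 3.5, 12))
  out <- assign_labels(vols)
  expect_equal(out$pct_change, c(-66, -100, -65, 20))
  expect_equal(out$label_pr, c(TRUE, TRUE, FALSE, FALSE))  # -65% exactly is NOT PR
  expect_equal(out$label_cr, c(FALSE, TRUE, FALSE, FALSE))
  expect_true(all(out$label_pr[out$label_cr]))  # CR subset of PR

  expect_error(assign_labels(dplyr::mutate(vols, volume_baseline_ml = 0)),
               "positive baseline")
})

test_that("labels are scale-invariant in volume units", {
  set.seed(2)
  vols <- tibble::tibble(patient_id = "P", lesion_id = as.character(1:50),
                         volume_baseline_ml = runif(50, 0.1, 50),
                         volume_evaluation_ml = runif(50, 0, 50))
  a <- assign_labels(vols)
  b <- assign_labels(dplyr::mutate(vols,
                                   volume_baseline_ml = volume_baseline_ml * 17,
                                   volume_evaluation_ml = volume_evaluation_ml * 17))
  expect_equal(a$label_pr, b$label_pr)
  expect_equal(a$label_cr, b$label_cr)
})

test_that("RECIST diameter-volume equivalence: 30% diameter -> 65.7% volume", {
  expect_equal(recist_equivalent_volume_threshold(0.30), 100 * (1 - 0.7^3))
  expect_equal(floor(recist_equivalent_volume_threshold(0.30)), 65)
  expect_equal(recist_equivalent_volume_threshold(0), 0)
  expect_equal(recist_equivalent_volume_threshold(1), 100)
  # strictly increasing
  f <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(recist_equivalent_volume_threshold(f)) > 0))
})

test_that("cohort summary counts PR and CR per the worked example", {
  out <- assign_labels(tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P2"), lesion_id = as.character(1:4),
    volume_baseline_ml = 10,
    volume_evaluation_ml = c(0, 3, 9, 12)))
  s <- cohort_response_summary(out)
  expect_equal(s$totals$n_lesions, 4)
  expect_equal(s$totals$n_pr, 2)
  expect_equal(s$totals$n_cr, 1)
  expect_equal(nrow(s$per_patient), 2)

  none <- assign_labels(tibble::tibble(
    patient_id = "P1", lesion_id = as.character(1:3),
    volume_baseline_ml = 5, volume_evaluation_ml = 5))
  s0 <- cohort_response_summary(none)
  expect_equal(s0$totals$n_pr, 0)
  expect_equal(s0$totals$n_cr, 0)
})

test_that("label_responses reads a cohort end to end: absence means CR", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_patients = 3, lesion_median = 3, lesion_sdlog = 0.4,
                          lesions_min = 2, lesions_max = 4,
                          volume_range_ml = c(0.5, 4),
                          grid_max = c(48, 48, 24), seed = 5)
  gen <- generate_cohort(cfg, dir)
  out <- label_responses(gen$manifest)
  expect_equal(nrow(out), sum(gen$manifest$timepoint == "baseline"))
  # manifest absence <-> CR label <-> zero evaluation volume
  absent <- gen$manifest$absent_at_evaluation[gen$manifest$timepoint == "baseline"]
  key_m <- paste(gen$manifest$patient_id[gen$manifest$timepoint == "baseline"],
                 gen$manifest$lesion_id[gen$manifest$timepoint == "baseline"])
  key_o <- paste(out$patient_id, out$lesion_id)
  expect_equal(out$label_cr[match(key_m, key_o)], absent)
  expect_true(all(out$volume_evaluation_ml[out$label_cr] == 0))
  expect_true(all(out$label_pr[out$label_cr]))
})
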