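test_that("LOPO folds partition lesions by patient with disjoint train/test", {
  ids <- c("B", "B", "A", "A", "A", "C")
  folds <- build_lopo_folds(ids)
  expect_equal(nrow(folds), 3)
  expect_equal(folds$patient_id, c("A", "B", "C"))
  expect_equal(lengths(folds$test_idx), c(3L, 2L, 1L))
  expect_equal(lengths(folds$train_idx), c(3L, 4L, 5L))
  # union of test sets covers every lesion exactly once
  expect_setequal(unlist(folds$test_idx), seq_along(ids))
  for (k in seq_len(nrow(folds))) {
    expect_length(intersect(ids[folds$train_idx[[k]]], ids[folds$test_idx[[k]]]), 0)
  }
  expect_error(build_lopo_folds(rep("A", 5)), "at least 2 patients")
})

test_that("pooled AUC equals brute-force pair counting, including ties", {
  expect_equal(auc_mann_whitney(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(auc_mann_whitney(c(0.6, 0.4, 0.6, 0.4), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  set.seed(10)
  for (i in 1:20) {
    n <- 50
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # tie-rich
    labels <- runif(n) < 0.4
    if (length(unique(labels)) < 2) next
    expect_equal(auc_mann_whitney(scores, labels),
                 oracle_auc_paircount(scores, labels), tolerance = 1e-12)
  }
  expect_error(auc_mann_whitney(c(1, 2), c(TRUE, TRUE)), "AUC undefined")
})

test_that("pooled ROC curve starts at (0,0), ends at (1,1), and CI brackets the AUC", {
  set.seed(3)
  scores <- c(rnorm(30, 1), rnorm(40, 0))
  labels <- rep(c(TRUE, FALSE), c(30, 40))
  r <- pooled_validation_roc(scores, labels)
  expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
  expect_equal(dplyr::last(r$curve$fpr), 1); expect_equal(dplyr::last(r$curve$tpr), 1)
  expect_true(all(diff(r$curve$fpr) >= 0)); expect_true(all(diff(r$curve$tpr) >= 0))
  expect_lte(r$ci_lower, r$auc); expect_gte(r$ci_upper, r$auc)
  b <- pooled_validation_roc(scores, labels, ci_method = "bootstrap")
  expect_equal(b$auc, r$auc)
  expect_lt(abs(b$ci_lower - r$ci_lower), 0.1)
})

make_sep_cohort <- function(n_patients = 8, per = 6, d = 5, sep = 3, seed = 1) {
  set.seed(seed)
  n <- n_patients * per
  y <- rep(c(TRUE, FALSE), length.out = n)
  x <- matrix(rnorm(n * d), n, d) + sep * y
  features <- tibble::as_tibble(as.data.frame(x)) |>
    rlang::set_names(paste0("f", seq_len(d))) |>
    dplyr::mutate(patient_id = rep(sprintf("P%02d", seq_len(n_patients)), each = per),
                  lesion_id = sprintf("L%03d", seq_len(n)), .before = 1)
  outcomes <- tibble::tibble(patient_id = features$patient_id,
                             lesion_id = features$lesion_id,
                             volume_baseline_ml = runif(n, 0.5, 5),
                             label_pr = y, label_cr = y)
  list(features = features, outcomes = outcomes)
}

test_that("well-separated classes give near-perfect training and validation AUC", {
  ch <- make_sep_cohort(seed = 42)
  fit <- fit_lopo(ch$features, ch$outcomes, task = "pr", seed = 7)
  expect_gt(min(fit$folds$train_auc), 0.95)
  expect_gt(fit$pooled$auc, 0.95)
  expect_equal(nrow(fit$predictions), nrow(ch$features))
  g <- glance(fit)
  expect_equal(g$n_patients, 8)
  expect_s3_class(tidy(fit), "tbl_df")
})

test_that("the LOPO run is bit-reproducible under a fixed seed and varies across seeds", {
  ch <- make_sep_cohort(sep = 1, seed = 9)
  f1 <- fit_lopo(ch$features, ch$outcomes, task = "pr", seed = 11)
  f2 <- fit_lopo(ch$features, ch$outcomes, task = "pr", seed = 11)
  expect_identical(f1$predictions$oof_score, f2$predictions$oof_score)
  expect_identical(f1$pooled$auc, f2$pooled$auc)
  f3 <- fit_lopo(ch$features, ch$outcomes, task = "pr", seed = 12)
  expect_false(identical(f1$predictions$oof_score, f3$predictions$oof_score))
})

test_that("permuted labels give chance-level out-of-bag AUC (null calibration)", {
  ch <- make_sep_cohort(n_patients = 6, per = 8, sep = 0, seed = 2)
  aucs <- vapply(1:20, function(i) {
    set.seed(100 + i)
    y <- sample(ch$outcomes$label_pr)
    fit <- train_rf(as.matrix(ch$features[, -(1:2)]), y, seed = 100 + i)
    fit$train_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("a planted perfectly informative feature is ranked first by Gini importance", {
  ch <- make_sep_cohort(sep = 0, seed = 33)
  ch$features$planted <- as.numeric(ch$outcomes$label_pr) + rnorm(nrow(ch$features), 0, 0.05)
  fit <- fit_lopo(ch$features, ch$outcomes, task = "pr", seed = 3)
  imp <- aggregate_importance(fit, ch$features, ch$outcomes)
  expect_equal(imp$feature[1], "planted")
  expect_equal(nrow(imp), ncol(ch$features) - 2)
  expect_equal(sum(imp$top), min(10, nrow(imp)))
  expect_setequal(imp$rank, seq_len(nrow(imp)))
})

test_that("feature-volume correlation flags exact dependence and spares noise", {
  set.seed(8)
  n <- 196
  vols <- runif(n, 0.06, 50)
  features <- tibble::tibble(patient_id = rep("P1", n),
                             lesion_id = as.character(seq_len(n)),
                             exact = 2 * vols,
                             noise = rnorm(n),
                             flat = rep(1, n))
  cors <- feature_volume_correlation(features, vols)
  expect_equal(cors$r_volume[cors$feature == "exact"], 1, tolerance = 1e-12)
  expect_true(cors$significant[cors$feature == "exact"])
  expect_false(cors$significant[cors$feature == "noise"])
  # zero-variance feature reported as r = 0, p = 1
  expect_equal(cors$r_volume[cors$feature == "flat"], 0)
  expect_equal(cors$p_volume[cors$feature == "flat"], 1)
})

test_that("null features give ~1e-4 significance rate at the p < 1e-4 cutoff", {
  set.seed(19)
  n <- 196; p <- 400
  vols <- runif(n, 0.1, 20)
  x <- matrix(rnorm(n * p), n, p)
  features <- tibble::as_tibble(as.data.frame(x)) |>
    dplyr::mutate(patient_id = "P", lesion_id = as.character(seq_len(n)),
                  .before = 1)
  cors <- feature_volume_correlation(features, vols)
  # expected 0.04 significant features; observing >= 3 has prob < 1e-5
  expect_lt(sum(cors$significant), 3)
})

test_that("degenerate single-class training folds produce flagged constant scores", {
  ch <- make_sep_cohort(n_patients = 3, per = 2, sep = 0, seed = 4)
  # make patient P01 carry all positives: others' training sets lack a class
  ch$outcomes$label_pr <- ch$outcomes$patient_id == "P01"
  ch$outcomes$label_cr <- ch$outcomes$label_pr
  fit <- fit_lopo(ch$features, ch$outcomes, task = "pr", seed = 5)
  expect_true(fit$folds$degenerate[fit$folds$patient_id == "P01"])
  expect_true(all(!is.na(fit$predictions$oof_score)))
})
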