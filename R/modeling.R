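#' Leave-one-patient-out fold plan
#'
#' One fold per patient: all of that patient's lesions form the validation
#' set, every other patient's lesions the training set. Fold order is
#' deterministic (sorted patient id).
#'
#' @param patient_ids Character vector, one entry per lesion.
#' @return Tibble with columns `fold`, `patient_id` and list-columns
#'   `train_idx`, `test_idx` (row indices into the lesion table).
#' @export
build_lopo_folds <- function(patient_ids) {
  patient_ids <- as.character(patient_ids)
  pats <- sort(unique(patient_ids))
  if (length(pats) < 2) stop("need at least 2 patients for LOPO", call. = FALSE)
  tibble::tibble(
    fold = seq_along(pats),
    patient_id = pats,
    train_idx = lapply(pats, function(p) which(patient_ids != p)),
    test_idx = lapply(pats, function(p) which(patient_ids == p))
  )
}

#' Train one random forest fold
#'
#' Fits a 150-tree random forest with terminal node size 1 (the settings
#' used throughout this pipeline) and returns out-of-bag vote scores, a
#' training AUC and per-feature Gini importances. The training AUC is
#' computed from out-of-bag votes by default; resubstitution AUC of a
#' node-size-1 forest is essentially 1 and carries no information.
#' A single-class training set yields a degenerate constant-score model,
#' flagged in the output.
#'
#' @param x Numeric feature matrix (rows = lesions).
#' @param y Logical or 0/1 outcome vector.
#' @param n_trees,node_size Forest size and minimum terminal node size.
#' @param seed Integer seed; the fit is deterministic given it.
#' @param training_auc `"oob"` (default) or `"resubstitution"`.
#' @return List: `model`, `train_auc`, `train_scores` (OOB vote fractions),
#'   `importance` (named numeric), `degenerate` (logical).
#' @export
train_rf <- function(x, y, n_trees = 150, node_size = 1, seed = 1,
                     training_auc = c("oob", "resubstitution")) {
  training_auc <- match.arg(training_auc)
  y <- as.logical(y)
  x <- as.matrix(x)
  if (length(unique(y)) < 2) {
    const <- as.numeric(y[1])
    return(list(model = NULL, train_auc = NA_real_,
                train_scores = rep(const, length(y)),
                importance = stats::setNames(rep(0, ncol(x)), colnames(x)),
                degenerate = TRUE))
  }
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = x, y = yf, ntree = n_trees,
                                   nodesize = node_size, importance = FALSE)
  oob <- rf$votes[, "pos"]
  # a sample that ends up in every bootstrap has no out-of-bag vote: score it
  # at the uninformative 0.5 rather than propagating NaN
  oob[!is.finite(oob)] <- 0.5
  tr_auc <- if (training_auc == "oob") {
    auc_mann_whitney(oob, y)
  } else {
    auc_mann_whitney(stats::predict(rf, x, type = "prob")[, "pos"], y)
  }
  list(model = rf, train_auc = tr_auc, train_scores = as.numeric(oob),
       importance = rf$importance[, "MeanDecreaseGini"],
       degenerate = FALSE)
}

#' Empirical AUC by the Mann-Whitney statistic
#'
#' Probability that a positive lesion outscores a negative one, ties counted
#' one half; computed from midranks.
#'
#' @param scores Numeric prediction scores.
#' @param labels Logical or 0/1 outcomes.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Pooled validation ROC with confidence interval
#'
#' Pools out-of-fold scores over all lesions, computes the empirical ROC
#' curve and AUC, and a 95% confidence interval (DeLong by default,
#' seeded bootstrap as an alternative).
#'
#' @param scores Pooled out-of-fold scores, one per lesion.
#' @param labels Outcomes, one per lesion.
#' @param ci_method `"delong"` (default) or `"bootstrap"` (2000 resamples).
#' @param boot_seed Seed for the bootstrap CI.
#' @return List: `curve` (tibble `threshold`, `fpr`, `tpr`), `auc`,
#'   `ci_lower`, `ci_upper`, `ci_method`.
#' @export
pooled_validation_roc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                                  boot_seed = 1L) {
  ci_method <- match.arg(ci_method)
  labels <- as.logical(labels)
  auc <- auc_mann_whitney(scores, labels)  # errors on one-class input

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  curve <- tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr)

  proc <- pROC::roc(response = labels, predictor = scores,
                    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- if (ci_method == "delong") {
    suppressWarnings(pROC::ci.auc(proc, method = "delong"))
  } else {
    set.seed(as.integer(boot_seed))
    suppressWarnings(pROC::ci.auc(proc, method = "bootstrap",
                                  boot.n = 2000, progress = "none"))
  }
  list(curve = curve, auc = auc,
       ci_lower = as.numeric(ci[1]), ci_upper = as.numeric(ci[3]),
       ci_method = ci_method)
}

#' Leave-one-patient-out random-forest evaluation
#'
#' The pipeline's model evaluation: for each patient, a random forest
#' (default 150 trees, node size 1) is trained on all other patients'
#' lesions and scored on the held-out patient's lesions; the out-of-fold
#' scores of all lesions are pooled into one validation ROC/AUC with a 95%
#' confidence interval, and per-fold Gini importances are kept for
#' aggregation. Scores are the fraction of trees voting positive. With the
#' same seed and inputs the whole run is reproducible; per-fold seeds are
#' derived deterministically from the master seed.
#'
#' @param features Feature tibble from [extract_features()]:
#'   `patient_id`, `lesion_id`, then numeric feature columns.
#' @param outcomes Outcome tibble from [label_responses()] /
#'   [assign_labels()].
#' @param task `"pr"` or `"cr"`: which label column to predict.
#' @param n_trees,node_size Forest settings.
#' @param seed Master seed.
#' @param ci_method Confidence-interval method, see
#'   [pooled_validation_roc()].
#' @param training_auc See [train_rf()].
#' @return A `lopo_result` object; see [tidy.lopo_result()],
#'   [glance.lopo_result()], [autoplot.lopo_result()],
#'   [aggregate_importance()].
#' @export
fit_lopo <- function(features, outcomes, task = c("pr", "cr"),
                     n_trees = 150, node_size = 1, seed = 1,
                     ci_method = c("delong", "bootstrap"),
                     training_auc = c("oob", "resubstitution")) {
  task <- match.arg(task)
  ci_method <- match.arg(ci_method)
  training_auc <- match.arg(training_auc)

  label_col <- paste0("label_", task)
  stopifnot(label_col %in% names(outcomes))
  dat <- features |>
    dplyr::inner_join(outcomes |>
                        dplyr::select("patient_id", "lesion_id",
                                      dplyr::all_of(label_col)),
                      by = c("patient_id", "lesion_id"))
  if (nrow(dat) != nrow(features)) {
    stop("features and outcomes do not cover the same lesions", call. = FALSE)
  }
  y <- dat[[label_col]]
  if (length(unique(y)) < 2) {
    stop("task '", task, "' has a single class over the whole cohort", call. = FALSE)
  }
  feat_cols <- setdiff(names(features), c("patient_id", "lesion_id"))
  x <- as.matrix(dat[, feat_cols])

  folds <- build_lopo_folds(dat$patient_id)
  oof <- rep(NA_real_, nrow(dat))
  fold_rows <- vector("list", nrow(folds))
  importances <- matrix(NA_real_, nrow = length(feat_cols), ncol = nrow(folds),
                        dimnames = list(feat_cols, folds$patient_id))
  train_curves <- vector("list", nrow(folds))

  for (k in seq_len(nrow(folds))) {
    tr <- folds$train_idx[[k]]; te <- folds$test_idx[[k]]
    stopifnot(length(intersect(dat$patient_id[tr], dat$patient_id[te])) == 0)
    fold_seed <- as.integer(seed) + 7919L * k
    fit <- train_rf(x[tr, , drop = FALSE], y[tr], n_trees = n_trees,
                    node_size = node_size, seed = fold_seed,
                    training_auc = training_auc)
    if (fit$degenerate) {
      oof[te] <- fit$train_scores[1]
    } else {
      oof[te] <- stats::predict(fit$model, x[te, , drop = FALSE],
                                type = "prob")[, "pos"]
    }
    importances[, k] <- fit$importance
    train_curves[[k]] <- list(scores = fit$train_scores, labels = y[tr])
    fold_rows[[k]] <- tibble::tibble(
      fold = k, patient_id = folds$patient_id[k],
      n_train = length(tr), n_test = length(te),
      train_auc = fit$train_auc, degenerate = fit$degenerate,
      seed = fold_seed)
  }

  pooled <- pooled_validation_roc(oof, y, ci_method = ci_method,
                                  boot_seed = as.integer(seed))
  structure(list(
    task = toupper(task),
    folds = dplyr::bind_rows(fold_rows),
    predictions = tibble::tibble(patient_id = dat$patient_id,
                                 lesion_id = dat$lesion_id,
                                 label = y, oof_score = oof),
    pooled = pooled,
    importance = importances,
    train_curves = train_curves,
    settings = list(n_trees = n_trees, node_size = node_size, seed = seed,
                    ci_method = ci_method, training_auc = training_auc)
  ), class = "lopo_result")
}

#' @export
print.lopo_result <- function(x, ...) {
  cat(sprintf("<lopo_result> task %s: %d folds, %d lesions\n", x$task,
              nrow(x$folds), nrow(x$predictions)))
  cat(sprintf("  training AUC (mean over folds): %.3f (range %.3f-%.3f)\n",
              mean(x$folds$train_auc, na.rm = TRUE),
              min(x$folds$train_auc, na.rm = TRUE),
              max(x$folds$train_auc, na.rm = TRUE)))
  cat(sprintf("  pooled validation AUC: %.3f (95%% CI %.3f-%.3f, %s)\n",
              x$pooled$auc, x$pooled$ci_lower, x$pooled$ci_upper,
              x$pooled$ci_method))
  invisible(x)
}

#' Aggregate feature importance across folds
#'
#' Mean decrease in Gini impurity per feature averaged over the per-fold
#' forests, ranked in descending order, optionally joined with each
#' feature's Pearson correlation against baseline lesion volume (the
#' volume-confounding audit).
#'
#' @param fit A `lopo_result` from [fit_lopo()].
#' @param features Feature tibble (needed for volume correlations).
#' @param outcomes Outcome tibble with `volume_baseline_ml` (idem).
#' @param top_k Number of top features to mark (default 10).
#' @return Tibble: `feature`, `mean_gini`, `rank`, `top` and, when volumes
#'   are supplied, `r_volume`, `p_volume`, `significant` (p < 1e-4).
#' @export
aggregate_importance <- function(fit, features = NULL, outcomes = NULL,
                                 top_k = 10) {
  mg <- rowMeans(fit$importance, na.rm = TRUE)
  out <- tibble::tibble(feature = names(mg), mean_gini = as.numeric(mg)) |>
    dplyr::arrange(dplyr::desc(.data$mean_gini)) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  top = .data$rank <= top_k)
  if (!is.null(features) && !is.null(outcomes)) {
    cors <- feature_volume_correlation(features, outcomes)
    out <- out |> dplyr::left_join(cors, by = "feature")
  }
  out
}

#' Pearson correlation of every feature with baseline lesion volume
#'
#' Audits how much each radiomics feature simply restates lesion size:
#' two-sided Pearson correlation of each feature column with the baseline
#' volume, flagged significant at p < 0.0001. Zero-variance features are
#' reported as r = 0 with p = 1.
#'
#' @param features Feature tibble ([extract_features()]).
#' @param outcomes Tibble with `patient_id`, `lesion_id`,
#'   `volume_baseline_ml` (or a numeric volume vector aligned with
#'   `features` rows).
#' @param alpha Significance level on the p-value (default 1e-4).
#' @return Tibble: `feature`, `r_volume`, `p_volume`, `significant`.
#' @export
feature_volume_correlation <- function(features, outcomes, alpha = 1e-4) {
  if (is.numeric(outcomes)) {
    vol <- outcomes
    stopifnot(length(vol) == nrow(features))
  } else {
    m <- features |>
      dplyr::select("patient_id", "lesion_id") |>
      dplyr::left_join(outcomes |>
                         dplyr::select("patient_id", "lesion_id",
                                       "volume_baseline_ml"),
                       by = c("patient_id", "lesion_id"))
    vol <- m$volume_baseline_ml
  }
  if (length(vol) < 3) stop("need at least 3 lesions", call. = FALSE)
  feat_cols <- setdiff(names(features), c("patient_id", "lesion_id"))
  res <- lapply(feat_cols, function(f) {
    x <- features[[f]]
    if (stats::sd(x) == 0 || stats::sd(vol) == 0) {
      return(c(r = 0, p = 1))
    }
    ct <- stats::cor.test(x, vol, method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  res <- do.call(rbind, res)
  tibble::tibble(feature = feat_cols,
                 r_volume = res[, "r"],
                 p_volume = res[, "p"],
                 significant = res[, "p"] < alpha)
}

#' Permutation-null pooled AUC
#'
#' Repeats the LOPO evaluation with lesion labels randomly permuted; the
#' resulting pooled AUCs calibrate the null distribution (they should centre
#' on 0.5).
#'
#' @param features,outcomes,task,n_trees,node_size As in [fit_lopo()].
#' @param n_perm Number of permutations.
#' @param seed Master seed (controls both permutations and forests).
#' @return Numeric vector of pooled validation AUCs, length `n_perm`.
#' @export
lopo_permutation_null <- function(features, outcomes, task = "pr",
                                  n_perm = 20, seed = 1,
                                  n_trees = 150, node_size = 1) {
  label_col <- paste0("label_", task)
  vapply(seq_len(n_perm), function(i) {
    perm_seed <- as.integer(seed) + 104729L * i
    set.seed(perm_seed)
    out_p <- outcomes
    out_p[[label_col]] <- sample(out_p[[label_col]])
    fit <- fit_lopo(features, out_p, task = task, n_trees = n_trees,
                    node_size = node_size, seed = perm_seed)
    fit$pooled$auc
  }, numeric(1))
}
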