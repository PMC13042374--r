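# Feature assembly and the gradient-boosted classifier with repeated
# 10-fold nested cross-validation.

DIFF_FEATURES <- c("diff_size", "diff_ccca", "diff_ctcc", "diff_nucleosome",
                   "diff_methylation")
GENOMEWIDE_FEATURES <- c("gw_methylation", "gw_size", "gw_motif",
                         "gw_copy_number")

#' Names of the classifier features
#'
#' The base model uses the 96 mutation-profile frequencies plus the five
#' Mut-vs-Wt contrasts (101 features); the extended model appends four
#' supplied genome-wide summary columns (methylation, fragment size, end
#' motif, copy number; 105 features).
#'
#' @param mode `"freesv"` (101 features) or `"freesv_plus"` (105).
#' @return Character vector of feature names in canonical order.
#' @export
feature_names <- function(mode = c("freesv", "freesv_plus")) {
  mode <- match.arg(mode)
  nm <- c(sbs96_contexts(), DIFF_FEATURES)
  if (mode == "freesv_plus") nm <- c(nm, GENOMEWIDE_FEATURES)
  nm
}

#' Assemble per-sample feature vectors
#'
#' Joins each sample's 96-context mutation-profile frequencies with its
#' Diff-* contrasts (and, for the extended mode, the four supplied
#' genome-wide features) into the ordered feature row the classifier
#' consumes. Undefined Diff entries stay `NA` here; they are imputed with
#' training-fold medians inside cross-validation.
#'
#' @param profiles Named list of profile tibbles ([build_profile()]), one
#'   per sample.
#' @param diffs Tibble with `sample_id` and the five Diff columns
#'   (`diff_size`, `diff_ccca`, `diff_ctcc`, `diff_nucleosome`,
#'   `diff_methylation`).
#' @param mode `"freesv"` or `"freesv_plus"`.
#' @param genomewide Tibble (`sample_id` + four numeric columns), required
#'   iff `mode = "freesv_plus"`. Columns are consumed as opaque numeric
#'   summaries.
#' @param labels Optional tibble (`sample_id`, `label` in
#'   \{"control","cancer"\}).
#' @return Tibble: `sample_id`, optional `label`, then 101 or 105 named
#'   feature columns.
#' @export
assemble_features <- function(profiles, diffs, mode = c("freesv", "freesv_plus"),
                              genomewide = NULL, labels = NULL) {
  mode <- match.arg(mode)
  if (mode == "freesv_plus" && is.null(genomewide)) {
    stop("freesv_plus mode requires the genome-wide feature table")
  }
  diffs <- tibble::as_tibble(diffs)
  prof_tbl <- purrr::imap(profiles, function(p, id) {
    row <- as.list(stats::setNames(p$frequency, p$context))
    tibble::as_tibble(c(list(sample_id = id), row))
  }) %>% dplyr::bind_rows()
  out <- dplyr::left_join(prof_tbl,
                          diffs[, c("sample_id", DIFF_FEATURES)],
                          by = "sample_id")
  if (mode == "freesv_plus") {
    gw <- tibble::as_tibble(genomewide)
    gw_cols <- setdiff(names(gw), "sample_id")
    if (length(gw_cols) != 4) {
      stop("genome-wide table must carry exactly four feature columns")
    }
    gw <- gw[, c("sample_id", gw_cols)]
    names(gw) <- c("sample_id", GENOMEWIDE_FEATURES)
    out <- dplyr::left_join(out, gw, by = "sample_id")
  }
  if (!is.null(labels)) {
    out <- dplyr::left_join(out, tibble::as_tibble(labels), by = "sample_id")
    out <- dplyr::select(out, "sample_id", "label", dplyr::everything())
  }
  nm <- feature_names(mode)
  stopifnot(all(nm %in% names(out)))
  dplyr::select(out, dplyr::any_of(c("sample_id", "label")),
                dplyr::all_of(nm))
}

#' Default gradient-boosting tuning grid
#'
#' Trees 50-500, interaction depth 1-3, learning rate 0.01 or 0.1; the
#' inner resampling picks the AUC-maximising combination. The compact
#' default keeps repeated nested cross-validation tractable.
#'
#' @param nrounds,max_depth,eta Candidate values.
#' @return Tibble grid of hyperparameter combinations.
#' @export
default_tuning_grid <- function(nrounds = c(50, 150), max_depth = c(1, 2, 3),
                                eta = c(0.1)) {
  tidyr::expand_grid(nrounds = nrounds, max_depth = max_depth, eta = eta)
}

# median imputation fit on training rows only
impute_medians <- function(x, medians = NULL) {
  if (is.null(medians)) {
    medians <- apply(x, 2, stats::median, na.rm = TRUE)
    medians[is.na(medians)] <- 0
  }
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- medians[j]
  }
  list(x = x, medians = medians)
}

fit_gbdt <- function(x, y, params, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(
      objective = "binary:logistic",
      max_depth = params$max_depth,
      eta = params$eta,
      nthread = 1,
      subsample = 1, colsample_bytree = 1,
      seed = seed
    ),
    data = dtrain, nrounds = params$nrounds, verbose = 0
  )
}

predict_gbdt <- function(model, x) {
  stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1))
}

# rank-statistic AUC (Mann-Whitney)
rank_auc <- function(scores, labels01) {
  n1 <- sum(labels01 == 1)
  n0 <- sum(labels01 == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(labels01, k, seed) {
  idx <- integer(length(labels01))
  set.seed(seed)
  for (cl in unique(labels01)) {
    members <- which(labels01 == cl)
    members <- sample(members)
    idx[members] <- rep_len(seq_len(k), length(members))
  }
  idx
}

# inner tuning: k-fold CV over the grid, pick max mean AUC
tune_gbdt <- function(x, y, grid, inner_folds, seed) {
  fold <- stratified_folds(y, inner_folds, seed)
  aucs <- vapply(seq_len(nrow(grid)), function(g) {
    fold_auc <- vapply(seq_len(inner_folds), function(f) {
      tr <- fold != f
      if (sum(!tr) == 0 || length(unique(y[tr])) < 2) return(NA_real_)
      imp <- impute_medians(x[tr, , drop = FALSE])
      te <- impute_medians(x[!tr, , drop = FALSE], imp$medians)
      m <- fit_gbdt(imp$x, y[tr], grid[g, ], seed + g)
      p <- predict_gbdt(m, te$x)
      rank_auc(p, y[!tr])
    }, numeric(1))
    mean(fold_auc, na.rm = TRUE)
  }, numeric(1))
  grid[which.max(aucs), ]
}

labels_to01 <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels))
  lv <- c("control", "cancer")
  if (!all(labels %in% lv)) {
    stop("labels must be 'control'/'cancer' (cancer is the positive class)")
  }
  as.integer(labels == "cancer")
}

feature_matrix <- function(features) {
  x <- as.matrix(dplyr::select(features,
                               -dplyr::any_of(c("sample_id", "label"))))
  storage.mode(x) <- "double"
  rownames(x) <- features$sample_id
  x
}

#' Repeated nested cross-validation of the gradient-boosted classifier
#'
#' Per repeat, samples are split into `folds` stratified subsets; each
#' subset is scored by a model tuned (inner `inner_folds`-fold resampling
#' over `tuning_grid`, maximizing AUC) and trained on the remaining
#' subsets, so no sample is ever scored by a model that saw it. Scores are
#' averaged over repeats to give one prediction score per sample. Fold
#' seeds are derived deterministically from the master seed.
#'
#' @param features Feature tibble from [assemble_features()] (with
#'   `sample_id`), or a numeric matrix.
#' @param labels Character (`"control"`/`"cancer"`) or 0/1 vector aligned
#'   with the rows.
#' @param folds Outer folds (default 10).
#' @param repeats Number of repeats of the whole procedure (default 100).
#' @param seed Master seed.
#' @param tuning_grid Hyperparameter grid (see [default_tuning_grid()]).
#' @param inner_folds Inner resampling folds for tuning (default 5).
#' @return A `cv_result`: `scores` tibble (`sample_id`, `label`, `score`),
#'   `fold_assignments` matrix (samples x repeats), `auc`, `seed`.
#' @export
nested_cv <- function(features, labels, folds = 10, repeats = 100,
                      seed = 1L, tuning_grid = default_tuning_grid(),
                      inner_folds = 5) {
  x <- if (is.matrix(features)) features else feature_matrix(features)
  y <- labels_to01(labels)
  stopifnot(length(y) == nrow(x), folds >= 2)
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  score_sum <- numeric(nrow(x))
  fold_assign <- matrix(NA_integer_, nrow(x), repeats)
  for (r in seq_len(repeats)) {
    rseed <- derive_seed(seed, 7919L * r)
    fold <- stratified_folds(y, folds, rseed)
    fold_assign[, r] <- fold
    pred <- numeric(nrow(x))
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (sum(tr) == 0 || sum(!tr) == 0) next
      best <- tune_gbdt(x[tr, , drop = FALSE], y[tr], tuning_grid,
                        inner_folds, derive_seed(rseed, f))
      imp <- impute_medians(x[tr, , drop = FALSE])
      te <- impute_medians(x[!tr, , drop = FALSE], imp$medians)
      m <- fit_gbdt(imp$x, y[tr], best, derive_seed(rseed, 1000L + f))
      pred[!tr] <- predict_gbdt(m, te$x)
    }
    score_sum <- score_sum + pred
  }
  scores <- score_sum / repeats
  res <- structure(list(
    scores = tibble::tibble(
      sample_id = if (is.null(rownames(x))) as.character(seq_len(nrow(x))) else rownames(x),
      label = y,
      score = scores
    ),
    fold_assignments = fold_assign,
    auc = rank_auc(scores, y),
    folds = folds, repeats = repeats, seed = seed
  ), class = "cv_result")
  res
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$folds, "-fold x ", x$repeats, " repeats, ",
      nrow(x$scores), " samples, AUC ", format(x$auc, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' @rdname nested_cv
#' @param x A `cv_result`.
#' @param ... Unused.
#' @export
tidy.cv_result <- function(x, ...) x$scores

#' @rdname nested_cv
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, folds = x$folds, repeats = x$repeats,
                 n = nrow(x$scores))
}

#' Train on one cohort, score another
#'
#' Tunes (inner resampling on the training group only) and fits a single
#' gradient-boosted model on all training samples, then scores the held-out
#' test samples. Sample identifiers must not overlap between groups.
#'
#' @param train_features,test_features Feature tibbles or matrices.
#' @param train_labels Labels for the training rows.
#' @param seed Integer seed.
#' @param tuning_grid Hyperparameter grid.
#' @param inner_folds Inner resampling folds.
#' @return Tibble (`sample_id`, `score`).
#' @export
train_apply <- function(train_features, train_labels, test_features,
                        seed = 1L, tuning_grid = default_tuning_grid(),
                        inner_folds = 5) {
  xtr <- if (is.matrix(train_features)) train_features else feature_matrix(train_features)
  xte <- if (is.matrix(test_features)) test_features else feature_matrix(test_features)
  if (length(intersect(rownames(xtr), rownames(xte))) > 0) {
    stop("training and testing groups share sample ids")
  }
  y <- labels_to01(train_labels)
  best <- tune_gbdt(xtr, y, tuning_grid, inner_folds, derive_seed(seed, 1L))
  imp <- impute_medians(xtr)
  te <- impute_medians(xte, imp$medians)
  m <- fit_gbdt(imp$x, y, best, derive_seed(seed, 2L))
  tibble::tibble(
    sample_id = if (is.null(rownames(xte))) as.character(seq_len(nrow(xte))) else rownames(xte),
    score = as.numeric(predict_gbdt(m, te$x))
  )
}

#' ROC report: AUC, and sensitivity at a fixed specificity
#'
#' AUC is the Mann-Whitney rank statistic; its p-value tests AUC = 0.5 by a
#' Z-test with the Hanley-McNeil variance. The decision threshold is the
#' smallest score cutoff achieving at least `target_specificity` on the
#' negative class; sensitivity at that cutoff is reported with an exact
#' Clopper-Pearson 95% binomial confidence interval.
#'
#' @param scores Numeric prediction scores (higher = more cancer-like).
#' @param labels `"control"`/`"cancer"` or 0/1 vector.
#' @param target_specificity Specificity to fix (default 0.99).
#' @return A `diagnostic_report` with `auc`, `auc_p`, `threshold`,
#'   `n_cancer`, `n_detected`, `sensitivity` (percent), `ci_low`, `ci_high`
#'   (percent).
#' @export
roc_report <- function(scores, labels, target_specificity = 0.99) {
  y <- labels_to01(labels)
  if (sum(y == 1) == 0 || sum(y == 0) == 0) {
    stop("both classes must be present")
  }
  auc <- rank_auc(scores, y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  # Hanley-McNeil variance of the AUC estimator
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n0 - 1) * (q2 - auc^2)) / (n1 * n0)
  z <- (auc - 0.5) / sqrt(max(v, .Machine$double.eps))
  auc_p <- 2 * stats::pnorm(-abs(z))

  # smallest cutoff (score >= cutoff called positive) with specificity
  # >= target on controls
  ctrl <- sort(scores[y == 0])
  cand <- sort(unique(c(scores, max(scores) + 1)))
  spec <- vapply(cand, function(t) mean(ctrl < t), numeric(1))
  ok <- cand[spec >= target_specificity]
  threshold <- min(ok)
  detected <- sum(scores[y == 1] >= threshold)
  ci <- stats::binom.test(detected, n1)$conf.int
  structure(list(
    auc = auc, auc_p = auc_p, threshold = threshold,
    target_specificity = target_specificity,
    n_cancer = n1, n_control = n0, n_detected = detected,
    sensitivity = 100 * detected / n1,
    ci_low = 100 * ci[1], ci_high = 100 * ci[2]
  ), class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("<diagnostic_report> AUC ", format(x$auc, digits = 4),
      " (p ", format(x$auc_p, digits = 3), ")\n",
      "sensitivity at ", 100 * x$target_specificity, "% specificity: ",
      x$n_detected, "/", x$n_cancer, " = ",
      sprintf("%.1f%%", x$sensitivity),
      sprintf(" (95%% CI %.1f-%.1f%%)", x$ci_low, x$ci_high), "\n",
      sep = "")
  invisible(x)
}

#' @rdname roc_report
#' @param x A `diagnostic_report`.
#' @param ... Unused.
#' @export
tidy.diagnostic_report <- function(x, ...) {
  tibble::tibble(
    metric = c("auc", "sensitivity", "ci_low", "ci_high"),
    value = c(x$auc, x$sensitivity, x$ci_low, x$ci_high)
  )
}

#' @rdname roc_report
#' @export
glance.diagnostic_report <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, auc_p = x$auc_p, threshold = x$threshold,
    target_specificity = x$target_specificity,
    n_cancer = x$n_cancer, n_control = x$n_control,
    n_detected = x$n_detected, sensitivity = x$sensitivity,
    ci_low = x$ci_low, ci_high = x$ci_high
  )
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' @param k Successes.
#' @param n Trials.
#' @param conf Confidence level (default 0.95).
#' @return Tibble (`estimate`, `low`, `high`) as fractions.
#' @export
exact_binomial_ci <- function(k, n, conf = 0.95) {
  ci <- stats::binom.test(k, n, conf.level = conf)$conf.int
  tibble::tibble(estimate = k / n, low = ci[1], high = ci[2])
}
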