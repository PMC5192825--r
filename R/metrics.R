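#' Balanced accuracy
#'
#' The average of the true-positive rate and the true-negative rate; robust
#' to class imbalance (an all-positive predictor scores 0.5 regardless of
#' the class ratio).
#'
#' @param truth binary 0/1 truth labels (both classes present).
#' @param predicted binary 0/1 predicted labels.
#' @return numeric scalar in \[0, 1\].
#' @export
balanced_accuracy <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  stopifnot(length(truth) == length(predicted),
            all(truth %in% 0:1), all(predicted %in% 0:1))
  if (length(unique(truth)) < 2L)
    stop("both classes must be present in the truth labels", call. = FALSE)
  tpr <- sum(predicted == 1 & truth == 1) / sum(truth == 1)
  tnr <- sum(predicted == 0 & truth == 0) / sum(truth == 0)
  (tpr + tnr) / 2
}

#' Area under the ROC curve
#'
#' Rank-based (pairwise-concordance) AUROC: the probability that a random
#' positive sample scores above a random negative one, with ties credited
#' 0.5. Identical to the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`, and to trapezoidal integration of the ROC curve.
#'
#' @param scores real-valued ranking scores (e.g. ensemble confidences).
#' @param truth binary 0/1 truth labels (both classes present).
#' @return numeric scalar in \[0, 1\].
#' @export
auroc <- function(scores, truth) {
  truth <- as.integer(truth)
  stopifnot(length(scores) == length(truth), all(truth %in% 0:1))
  if (length(unique(truth)) < 2L)
    stop("both classes must be present in the truth labels", call. = FALSE)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  r <- rank(scores)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-based evaluation report
#'
#' @param truth binary truth labels.
#' @param predicted binary predicted labels.
#' @param scores optional ranking scores for AUROC.
#' @return list of class `evo_report`: confusion counts, TPR, TNR, BAC and
#'   (when scores are given) AUROC.
#' @export
evaluate_predictions <- function(truth, predicted, scores = NULL) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  tp <- sum(predicted == 1 & truth == 1)
  fn <- sum(predicted == 0 & truth == 1)
  tn <- sum(predicted == 0 & truth == 0)
  fp <- sum(predicted == 1 & truth == 0)
  out <- list(TP = tp, FP = fp, TN = tn, FN = fn,
              n_pos = tp + fn, n_neg = tn + fp,
              TPR = tp / (tp + fn), TNR = tn / (tn + fp),
              BAC = balanced_accuracy(truth, predicted),
              AUROC = if (!is.null(scores)) auroc(scores, truth) else NA_real_)
  class(out) <- "evo_report"
  out
}

#' Repeated train/test evaluation of the pipeline
#'
#' For each repeat, a class-stratified random split holds out
#' `test_fraction` of the samples; the z transform and the statistical
#' weights are fitted on the training side only (no information leak), the
#' ensemble is trained there, and BAC/AUROC are measured on the held-out
#' side. Reported as per-repeat values plus mean and standard error.
#'
#' @param matrix an unnormalized [labeled_matrix()].
#' @param meta feature metadata (see [assemble_weights()]).
#' @param conservation gene-rate table (see [assemble_weights()]).
#' @param config an [evo_config()].
#' @param mode weighting mode: `"e+s"` composite, `"e"` evolutionary only,
#'   `"s"` statistical only, `"0"` unweighted.
#' @param n_repeats number of random splits (default 10).
#' @param test_fraction held-out fraction (default 0.2).
#' @param seed master seed; split k uses the k-th derived seed, so two
#'   modes run with the same master seed see identical splits.
#' @return object of class `evo_cv_report`: `folds` data.frame (BAC, AUROC,
#'   complexity per repeat), `mean_BAC`, `se_BAC`, `mean_AUROC`, `se_AUROC`,
#'   `mean_complexity`.
#' @export
cross_validate <- function(matrix, meta, conservation, config = evo_config(),
                           mode = c("e+s", "e", "s", "0"), n_repeats = 10L,
                           test_fraction = 0.2, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "labeled_matrix"), !matrix$z_scored)
  seeds <- derive_seeds(seed, 2L * n_repeats)
  folds <- data.frame(repeat_ = seq_len(n_repeats), BAC = NA_real_,
                      AUROC = NA_real_, complexity = NA_real_)
  for (k in seq_len(n_repeats)) {
    split <- stratified_split(matrix$labels, test_fraction,
                              seed = seeds[2 * k - 1])
    train <- subset_samples(matrix, split$train)
    ztrain <- z_normalize(train)
    weights <- mode_weights(ztrain, meta, conservation, mode)
    model <- train_ensemble(ztrain, weights, config, seed = seeds[2 * k])
    pred <- predict(model, matrix$values[split$test, , drop = FALSE])
    truth <- matrix$labels[split$test]
    folds$BAC[k] <- balanced_accuracy(truth, pred$label)
    folds$AUROC[k] <- auroc(pred$confidence, truth)
    folds$complexity[k] <- model_complexity(model)
  }
  se <- function(v) stats::sd(v) / sqrt(length(v))
  structure(list(folds = folds, mode = mode,
                 mean_BAC = mean(folds$BAC), se_BAC = se(folds$BAC),
                 mean_AUROC = mean(folds$AUROC), se_AUROC = se(folds$AUROC),
                 mean_complexity = mean(folds$complexity),
                 n_repeats = n_repeats, test_fraction = test_fraction),
            class = "evo_cv_report")
}

#' @export
print.evo_cv_report <- function(x, ...) {
  cat(sprintf(paste0("cross-validation (mode %s, %d repeats): BAC %.3f ",
                     "(SE %.3f), AUROC %.3f (SE %.3f), %.1f features/",
                     "submodel\n"),
              x$mode, x$n_repeats, x$mean_BAC, x$se_BAC, x$mean_AUROC,
              x$se_AUROC, x$mean_complexity))
  invisible(x)
}

# class-stratified train/test split; degenerate draws cannot occur because
# each class is split proportionally (>= 1 test, >= 2 train enforced)
#' @keywords internal
stratified_split <- function(labels, test_fraction, seed = NULL) {
  with_seed(seed, {
    test <- unlist(lapply(c(0L, 1L), function(cl) {
      ids <- names(labels)[labels == cl]
      n_test <- max(1L, round(test_fraction * length(ids)))
      if (length(ids) - n_test < 2L)
        stop("class ", cl, " too small for a ", test_fraction, " split",
             call. = FALSE)
      sample(ids, n_test)
    }))
    list(train = setdiff(names(labels), test), test = test)
  })
}

# weight-set for one comparison mode, fitted on training data only
#' @keywords internal
mode_weights <- function(ztrain, meta, conservation, mode) {
  meta <- meta[match(colnames(ztrain$values), meta$feature_id), , drop = FALSE]
  if (anyNA(meta$feature_id))
    stop("feature metadata does not cover the matrix", call. = FALSE)
  if (mode == "0") return(uniform_weights(meta))
  ws <- statistical_weights(ztrain)
  scales <- switch(mode, "e+s" = c(1, 1), "e" = c(1, 0), "s" = c(0, 1))
  assemble_weights(conservation, meta, ws,
                   we_scale = scales[1], ws_scale = scales[2])
}

#' Compare weighting modes with matched splits
#'
#' Runs [cross_validate()] once per requested mode with the same master
#' seed, so every mode sees identical train/test splits and matched
#' ensemble seeds; the modes differ only in the weights used during feature
#' selection.
#'
#' @inheritParams cross_validate
#' @param modes subset of `c("e+s", "e", "s", "0")`.
#' @return named list of `evo_cv_report` objects plus a `summary`
#'   data.frame (class `evo_comparison`).
#' @export
compare_models <- function(matrix, meta, conservation, config = evo_config(),
                           modes = c("e+s", "e", "s", "0"), n_repeats = 10L,
                           test_fraction = 0.2, seed = NULL) {
  modes <- match.arg(modes, several.ok = TRUE)
  reports <- lapply(modes, function(md)
    cross_validate(matrix, meta, conservation, config, mode = md,
                   n_repeats = n_repeats, test_fraction = test_fraction,
                   seed = seed))
  names(reports) <- modes
  summary <- data.frame(
    mode = modes,
    BAC = vapply(reports, `[[`, numeric(1), "mean_BAC"),
    se_BAC = vapply(reports, `[[`, numeric(1), "se_BAC"),
    AUROC = vapply(reports, `[[`, numeric(1), "mean_AUROC"),
    se_AUROC = vapply(reports, `[[`, numeric(1), "se_AUROC"),
    complexity = vapply(reports, `[[`, numeric(1), "mean_complexity"),
    row.names = NULL)
  structure(list(reports = reports, summary = summary),
            class = "evo_comparison")
}

#' @export
print.evo_comparison <- function(x, ...) {
  print(x$summary, digits = 3)
  invisible(x)
}

#' Paired t test between two cross-validation reports
#'
#' Compares per-fold metric values of two reports run with matched splits
#' (same master seed).
#'
#' @param report1,report2 `evo_cv_report` objects with equal `n_repeats`.
#' @param metric `"BAC"`, `"AUROC"`, or `"complexity"`.
#' @return an `htest` from [stats::t.test()] (paired).
#' @export
paired_fold_test <- function(report1, report2,
                             metric = c("BAC", "AUROC", "complexity")) {
  metric <- match.arg(metric)
  stopifnot(nrow(report1$folds) == nrow(report2$folds))
  stats::t.test(report1$folds[[metric]], report2$folds[[metric]],
                paired = TRUE)
}
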