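#' Pipeline configuration
#'
#' Collects every tunable of the evolution-informed pipeline with defaults
#' matching the published procedure where it states them: 100 submodels,
#' 100 inner stability-selection bootstraps with a strict 50% threshold,
#' 50-tree forests, and balanced undersampling at 90% of the minority class.
#'
#' @param n_submodels number of balanced-undersample submodels.
#' @param n_trees trees per random forest.
#' @param n_inner_bootstraps resamples inside stability selection.
#' @param stability_threshold strict selection-frequency threshold.
#' @param undersample_frac fraction of the minority class drawn per class.
#' @param n_lambda,lambda_ratio lambda-grid size and range.
#' @param selection_rule how (bootstrap, lambda) fits aggregate into a
#'   selection frequency, see [stability_select()].
#' @param min_lambda_hits hit count for the `"min_hits"` rule.
#' @param fallback_k features (top composite weight) used when a submodel's
#'   stable set comes back empty; `0` drops such submodels instead.
#' @param mtry split candidates per node (`NULL` = `floor(sqrt(p))`).
#' @param solver_tol,solver_max_iter inner l1-solver controls.
#' @return a validated list of class `evo_config`.
#' @export
evo_config <- function(n_submodels = 100L, n_trees = 50L,
                       n_inner_bootstraps = 100L, stability_threshold = 0.5,
                       undersample_frac = 0.9, n_lambda = 10L,
                       lambda_ratio = 0.1,
                       selection_rule = "lambda_average",
                       min_lambda_hits = 1L, fallback_k = 5L, mtry = NULL,
                       solver_tol = 1e-7, solver_max_iter = 5000L) {
  cfg <- list(n_submodels = as.integer(n_submodels),
              n_trees = as.integer(n_trees),
              n_inner_bootstraps = as.integer(n_inner_bootstraps),
              stability_threshold = stability_threshold,
              undersample_frac = undersample_frac,
              n_lambda = as.integer(n_lambda),
              lambda_ratio = lambda_ratio,
              selection_rule = match.arg(selection_rule,
                                         c("lambda_average", "min_hits")),
              min_lambda_hits = as.integer(min_lambda_hits),
              fallback_k = as.integer(fallback_k), mtry = mtry,
              solver_tol = solver_tol,
              solver_max_iter = as.integer(solver_max_iter))
  stopifnot(cfg$n_submodels >= 1L, cfg$n_trees >= 1L,
            cfg$n_inner_bootstraps >= 1L,
            cfg$stability_threshold >= 0, cfg$stability_threshold < 1,
            cfg$undersample_frac > 0, cfg$undersample_frac <= 1,
            cfg$n_lambda >= 1L, cfg$lambda_ratio > 0, cfg$lambda_ratio <= 1,
            cfg$fallback_k >= 0L)
  class(cfg) <- "evo_config"
  cfg
}

#' Balanced undersampling of an imbalanced cohort
#'
#' Draws the same number of samples from each outcome class, without
#' replacement: 90% (configurable) of the size of the under-represented
#' class, rounded down.
#'
#' @param labels named binary labels (1 = positive).
#' @param seed optional integer seed.
#' @param frac fraction of the minority-class size drawn per class.
#' @return character vector of sample ids, length `2 * floor(frac * n_min)`.
#' @export
undersample <- function(labels, seed = NULL, frac = 0.9) {
  if (is.null(names(labels))) names(labels) <- seq_along(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (min(n_pos, n_neg) < 2L)
    stop("each class needs at least 2 samples to undersample", call. = FALSE)
  n_each <- floor(frac * min(n_pos, n_neg))
  if (n_each < 1L) stop("undersample size is zero", call. = FALSE)
  with_seed(seed, c(sample(names(labels)[labels == 1], n_each),
                    sample(names(labels)[labels == 0], n_each)))
}

#' Train one submodel on a balanced subset
#'
#' Runs stability selection on the weighted z-scores of the subset, then
#' trains a random forest on the unweighted z-scores of the selected
#' features (weighting steers which features are picked, but must not bias
#' the classifier itself). An empty stable set falls back to the top
#' `fallback_k` features by composite weight (logged), or drops the
#' submodel when `fallback_k = 0`.
#'
#' @param matrix z-scored [labeled_matrix()] of the full training cohort.
#' @param weights a `weight_set`.
#' @param subset sample ids from [undersample()].
#' @param config an [evo_config()].
#' @param seed integer seed controlling selection and forest training.
#' @return object of class `evo_submodel`, or `NULL` for a dropped
#'   submodel.
#' @export
train_submodel <- function(matrix, weights, subset, config = evo_config(),
                           seed = NULL) {
  stopifnot(inherits(matrix, "labeled_matrix"), matrix$z_scored)
  sub <- subset_samples(matrix, subset)
  subw <- apply_weights(sub, weights)
  seeds <- derive_seeds(seed, 2L)
  prof <- stability_select(subw$values, subw$labels,
                           n_bootstraps = config$n_inner_bootstraps,
                           threshold = config$stability_threshold,
                           seed = seeds[1],
                           selection_rule = config$selection_rule,
                           min_lambda_hits = config$min_lambda_hits,
                           n_lambda = config$n_lambda,
                           lambda_ratio = config$lambda_ratio,
                           tol = config$solver_tol,
                           max_iter = config$solver_max_iter)
  selected <- prof$selected
  fallback <- FALSE
  if (length(selected) == 0L) {
    if (config$fallback_k == 0L) {
      message("submodel dropped: empty stable set")
      return(NULL)
    }
    w <- weights$W[match(colnames(matrix$values), weights$feature_id)]
    selected <- colnames(matrix$values)[order(-w)][
      seq_len(min(config$fallback_k, ncol(matrix$values)))]
    fallback <- TRUE
    message("empty stable set: falling back to top ", length(selected),
            " features by composite weight")
  }
  forest <- with_seed(seeds[2],
    rf_train(sub$values[, selected, drop = FALSE], sub$labels,
             n_trees = config$n_trees, mtry = config$mtry))
  structure(list(samples = subset, selected = selected, forest = forest,
                 frequency = prof$frequency, fallback = fallback,
                 seed = seed),
            class = "evo_submodel")
}

#' Train the evolution-informed ensemble
#'
#' Wraps feature selection and classification in a class-balanced bootstrap:
#' each of `n_submodels` independent balanced undersamples yields one
#' stability-selected feature set and one random forest. The z transform is
#' fitted here (if the matrix is not yet normalized) and stored so held-out
#' samples are transformed with training parameters.
#'
#' @param matrix a [labeled_matrix()] (raw or already z-scored).
#' @param weights a `weight_set` covering all features.
#' @param config an [evo_config()].
#' @param seed master seed; per-submodel seeds are derived from it, so the
#'   ensemble is bit-reproducible.
#' @return object of class `evo_ensemble`.
#' @export
train_ensemble <- function(matrix, weights, config = evo_config(),
                           seed = NULL) {
  stopifnot(inherits(matrix, "labeled_matrix"))
  if (!matrix$z_scored) matrix <- z_normalize(matrix)
  seeds <- derive_seeds(seed, 2L * config$n_submodels)
  submodels <- vector("list", config$n_submodels)
  for (k in seq_len(config$n_submodels)) {
    subset <- undersample(matrix$labels, seed = seeds[2 * k - 1],
                          frac = config$undersample_frac)
    submodels[[k]] <- train_submodel(matrix, weights, subset, config,
                                     seed = seeds[2 * k])
  }
  submodels <- Filter(Negate(is.null), submodels)
  if (length(submodels) == 0L)
    stop("all submodels were dropped", call. = FALSE)
  structure(list(submodels = submodels, center = matrix$center,
                 scale = matrix$scale, weights = weights, config = config,
                 seed = seed),
            class = "evo_ensemble")
}

#' @export
print.evo_ensemble <- function(x, ...) {
  cat(sprintf(paste0("evo_ensemble: %d submodels, %.1f features/submodel ",
                     "(%d trees each)\n"),
              length(x$submodels), model_complexity(x), x$config$n_trees))
  invisible(x)
}

#' Predict outcomes with confidence scores
#'
#' Every submodel's forest votes a hard label for each sample; the
#' confidence score is the fraction of submodels voting positive, and the
#' final label is positive only on a strict majority (a 50/50 tie is called
#' negative — the conservative choice for the poor-outcome class).
#'
#' @param object an `evo_ensemble`.
#' @param newdata numeric matrix of raw feature values (samples x features)
#'   or a `labeled_matrix`; must contain every feature used in training.
#' @param ... unused.
#' @return data.frame: `sample_id`, `confidence` (in \[0, 1\], a multiple of
#'   1/n_submodels), `label` (0/1).
#' @export
predict.evo_ensemble <- function(object, newdata, ...) {
  values <- if (inherits(newdata, "labeled_matrix")) newdata$values
            else as.matrix(newdata)
  z <- apply_z_transform(values, object$center, object$scale)
  votes <- vapply(object$submodels,
                  function(sm) rf_predict(sm$forest, z)$label,
                  integer(nrow(z)))
  votes <- matrix(votes, nrow = nrow(z))
  confidence <- rowMeans(votes)
  data.frame(sample_id = rownames(values), confidence = confidence,
             label = as.integer(confidence > 0.5), row.names = NULL)
}

#' Model complexity: mean selected features per submodel
#'
#' @param model an `evo_ensemble`.
#' @return numeric scalar.
#' @export
model_complexity <- function(model) {
  mean(vapply(model$submodels, function(s) length(s$selected), numeric(1)))
}

#' Feature usage across submodels
#'
#' Counts, for each feature ever selected, the number of submodels that
#' include it — the basis of "included in more than 80% of submodels"-style
#' summaries.
#'
#' @param model an `evo_ensemble`.
#' @return data.frame `feature_id`, `n_submodels`, `fraction`, sorted by
#'   decreasing usage.
#' @export
feature_usage <- function(model) {
  tab <- table(unlist(lapply(model$submodels, `[[`, "selected")))
  out <- data.frame(feature_id = names(tab), n_submodels = as.integer(tab),
                    fraction = as.numeric(tab) / length(model$submodels),
                    row.names = NULL)
  out[order(-out$n_submodels, out$feature_id), , drop = FALSE]
}
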