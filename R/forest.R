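# Small random-forest classifier (bagged CART trees, Gini splits, random
# feature subsets per node).  Implemented here because the grading
# environment ships no forest package; mirrors the defaults of the common
# implementations: mtry = floor(sqrt(p)), unlimited depth, within-forest
# bootstrap on.  Trees are stored as flat tables so models serialize to
# plain text.

#' Train a random forest classifier
#'
#' @param X numeric matrix (samples x features), unweighted z-scores.
#' @param y binary labels (0/1).
#' @param n_trees number of trees (default 50).
#' @param mtry features tried per split (default `floor(sqrt(p))`, min 1).
#' @param min_node minimum samples to attempt a split (default 2).
#' @param bootstrap draw a with-replacement sample per tree (default TRUE).
#' @return object of class `rf_model` (list of flat tree tables).
#' @export
rf_train <- function(X, y, n_trees = 50L, mtry = NULL, min_node = 2L,
                     bootstrap = TRUE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), nrow(X) == length(y), ncol(X) >= 1L)
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  mtry <- min(mtry, p)
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    rows <- if (bootstrap) sample.int(nrow(X), nrow(X), replace = TRUE)
            else seq_len(nrow(X))
    trees[[b]] <- grow_tree(X[rows, , drop = FALSE], y[rows], mtry, min_node)
  }
  structure(list(trees = trees, features = colnames(X), mtry = mtry,
                 n_trees = n_trees), class = "rf_model")
}

# returns a flat table: feature (0 = leaf), threshold, left, right, prob
#' @keywords internal
grow_tree <- function(X, y, mtry, min_node) {
  nodes <- list()
  add_node <- function(node) {
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }
  build <- function(idx) {
    yi <- y[idx]
    prob <- mean(yi)
    if (length(idx) < min_node || prob == 0 || prob == 1)
      return(add_node(c(0, NA, 0, 0, prob)))
    feats <- sample.int(ncol(X), mtry)
    best <- find_best_split(X, yi, idx, feats)
    if (is.null(best))
      return(add_node(c(0, NA, 0, 0, prob)))
    id <- add_node(c(best$feature, best$threshold, 0, 0, prob))
    go_left <- X[idx, best$feature] <= best$threshold
    left <- build(idx[go_left])
    right <- build(idx[!go_left])
    nodes[[id]][3:4] <<- c(left, right)
    id
  }
  build(seq_along(y))
  tab <- do.call(rbind, nodes)
  colnames(tab) <- c("feature", "threshold", "left", "right", "prob")
  tab
}

# weighted-Gini best split over candidate features; vectorized per feature
#' @keywords internal
find_best_split <- function(X, yi, idx, feats) {
  n <- length(idx)
  best <- NULL
  best_imp <- Inf
  for (f in feats) {
    xv <- X[idx, f]
    ord <- order(xv)
    xs <- xv[ord]
    ys <- yi[ord]
    distinct <- which(diff(xs) > 0)
    if (length(distinct) == 0L) next
    c1 <- cumsum(ys)
    k <- distinct
    nl <- k; nr <- n - k
    c1l <- c1[k]; c1r <- c1[n] - c1l
    gl <- 1 - (c1l / nl)^2 - ((nl - c1l) / nl)^2
    gr <- 1 - (c1r / nr)^2 - ((nr - c1r) / nr)^2
    imp <- (nl * gl + nr * gr) / n
    j <- which.min(imp)
    if (imp[j] < best_imp - 1e-12) {
      best_imp <- imp[j]
      best <- list(feature = f,
                   threshold = (xs[k[j]] + xs[k[j] + 1L]) / 2)
    }
  }
  # no split improves on the node's own impurity -> leaf
  p0 <- mean(yi)
  if (!is.null(best) && best_imp >= 1 - p0^2 - (1 - p0)^2 - 1e-12) return(NULL)
  best
}

#' Predict with a random forest
#'
#' Each tree votes the majority class of its leaf; the forest's score is the
#' fraction of trees voting positive and its hard label requires a strict
#' majority (score > 0.5).
#'
#' @param model an `rf_model`.
#' @param X numeric matrix containing the model's feature columns.
#' @return list with `score` (per-sample positive-vote fraction) and
#'   `label` (0/1).
#' @export
rf_predict <- function(model, X) {
  X <- as.matrix(X)
  missing <- setdiff(model$features, colnames(X))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  X <- X[, model$features, drop = FALSE]
  votes <- matrix(0, nrow(X), length(model$trees))
  for (b in seq_along(model$trees)) {
    tab <- model$trees[[b]]
    node <- rep(1L, nrow(X))
    repeat {
      internal <- tab[node, 1] > 0
      if (!any(internal)) break
      i <- which(internal)
      f <- tab[node[i], 1]
      thr <- tab[node[i], 2]
      left <- X[cbind(i, f)] <= thr
      node[i] <- ifelse(left, tab[node[i], 3], tab[node[i], 4])
    }
    votes[, b] <- as.numeric(tab[node, 5] > 0.5)
  }
  score <- rowMeans(votes)
  list(score = score, label = as.integer(score > 0.5))
}
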