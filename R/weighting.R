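#' Construct a labeled sample-by-feature matrix
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature ids).
#' @param labels binary outcome per sample: 1 = positive/poor outcome,
#'   0 = good outcome. Recycled names must match `rownames(values)`.
#' @return an object of class `labeled_matrix`.
#' @export
labeled_matrix <- function(values, labels) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != nrow(values))
    stop("labels must have one entry per sample", call. = FALSE)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1 with no missing values", call. = FALSE)
  if (anyNA(values))
    stop("missing feature values are not supported; remove or impute ",
         "affected samples upstream", call. = FALSE)
  names(labels) <- rownames(values)
  structure(list(values = values, labels = labels, z_scored = FALSE,
                 center = NULL, scale = NULL),
            class = "labeled_matrix")
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf("labeled_matrix: %d samples x %d features (%d positive)%s\n",
              nrow(x$values), ncol(x$values), sum(x$labels),
              if (x$z_scored) ", z-scored" else ""))
  invisible(x)
}

#' @keywords internal
subset_samples <- function(matrix, ids) {
  out <- matrix
  out$values <- matrix$values[ids, , drop = FALSE]
  out$labels <- matrix$labels[ids]
  out
}

#' Per-feature statistical weights from two-sample t tests
#'
#' Each feature is tested between the two outcome classes with a two-sided
#' two-sample t test (classic Student's pooled-variance test by default;
#' Welch available). The statistical weight is the negative logarithm of the
#' p-value, `WS = -log10(p)`, with p floored at `p_floor` to keep weights
#' finite under underflow.
#'
#' @param matrix a [labeled_matrix()] (weighting not yet applied).
#' @param log_base base of the negative logarithm (default 10).
#' @param var_equal `TRUE` for the pooled-variance Student's test (default),
#'   `FALSE` for Welch.
#' @param p_floor lower floor applied to p-values (default 1e-300).
#' @return data.frame with columns `feature_id`, `t`, `df`, `p`, `WS`.
#' @export
statistical_weights <- function(matrix, log_base = 10, var_equal = TRUE,
                                p_floor = 1e-300) {
  stopifnot(inherits(matrix, "labeled_matrix"))
  y <- matrix$labels
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < 2L || n0 < 2L)
    stop("each outcome class needs at least 2 samples (have ", n1, "/", n0,
         ")", call. = FALSE)
  X1 <- matrix$values[y == 1L, , drop = FALSE]
  X0 <- matrix$values[y == 0L, , drop = FALSE]
  m1 <- colMeans(X1); m0 <- colMeans(X0)
  v1 <- apply(X1, 2, stats::var); v0 <- apply(X0, 2, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  tstat <- (m1 - m0) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- !is.finite(tstat)
  if (any(degenerate)) {
    # zero pooled variance: identical values -> no association (p = 1);
    # separated constants -> maximal association (p at the floor)
    p[degenerate] <- ifelse(abs(m1[degenerate] - m0[degenerate]) < 1e-12,
                            1, p_floor)
    tstat[degenerate] <- ifelse(p[degenerate] == 1, 0,
                                sign(m1[degenerate] - m0[degenerate]) * Inf)
    warning(sum(degenerate), " zero-variance feature(s); p-value set by ",
            "mean-difference rule", call. = FALSE)
  }
  p <- pmax(p, p_floor)
  data.frame(feature_id = colnames(matrix$values), t = tstat, df = df,
             p = p, WS = -log(p, base = log_base), row.names = NULL)
}

#' Z-score normalization with stored transform parameters
#'
#' Centers and scales every feature to mean 0, standard deviation 1 (sample
#' sd, n-1 denominator) on the given samples. The per-feature means and sds
#' are retained on the returned object so held-out samples can be
#' transformed with the training parameters. Zero-variance features carry no
#' information and are dropped with a warning.
#'
#' @param matrix an unnormalized [labeled_matrix()].
#' @return a z-scored `labeled_matrix` with `center` and `scale` set.
#' @export
z_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "labeled_matrix"))
  if (matrix$z_scored) stop("matrix is already z-scored", call. = FALSE)
  ctr <- colMeans(matrix$values)
  scl <- apply(matrix$values, 2, stats::sd)
  keep <- scl > 0
  if (!any(keep)) stop("all features have zero variance", call. = FALSE)
  if (!all(keep))
    warning("dropping ", sum(!keep), " zero-variance feature(s): ",
            paste(head(colnames(matrix$values)[!keep], 5), collapse = ", "),
            call. = FALSE)
  out <- matrix
  out$values <- scale(matrix$values[, keep, drop = FALSE],
                      center = ctr[keep], scale = scl[keep])
  attr(out$values, "scaled:center") <- NULL
  attr(out$values, "scaled:scale") <- NULL
  out$z_scored <- TRUE
  out$center <- ctr[keep]
  out$scale <- scl[keep]
  out
}

#' Apply a stored z transform to new samples
#'
#' @param values numeric matrix of raw feature values (samples x features);
#'   must contain every feature of the stored transform.
#' @param center,scale named per-feature parameters from [z_normalize()].
#' @return z-scored matrix restricted to the transform's features.
#' @export
apply_z_transform <- function(values, center, scale) {
  missing <- setdiff(names(center), colnames(values))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  v <- values[, names(center), drop = FALSE]
  sweep(sweep(v, 2, center, "-"), 2, scale, "/")
}

#' Assemble composite feature weights
#'
#' Molecular features inherit the evolutionary weight `WE = 1/R` of their
#' linked gene. Clinical covariates have no meaningful conservation score;
#' because clinical features tend to carry high predictive value, they are
#' assigned the maximum WE observed among the molecular features. The
#' composite weight is the (optionally rescaled) sum `W = WE + WS`.
#'
#' @param conservation data.frame of gene rates ([gene_rate()] rows) with
#'   columns `gene_id`, `WE`.
#' @param meta feature metadata: data.frame with `feature_id`,
#'   `kind` (`"molecular"` or `"clinical"`), `gene_id` (NA for clinical).
#' @param ws data.frame from [statistical_weights()] (or any frame with
#'   `feature_id`, `WS`).
#' @param we_scale,ws_scale global rescaling factors (default 1); setting one
#'   to 0 yields the evolutionary-only / statistical-only weight variants.
#' @return a `weight_set` data.frame: `feature_id`, `kind`, `WE`, `WS`, `W`.
#' @export
assemble_weights <- function(conservation, meta, ws,
                             we_scale = 1, ws_scale = 1) {
  stopifnot(all(c("feature_id", "kind") %in% names(meta)),
            all(c("feature_id", "WS") %in% names(ws)))
  if (!all(meta$kind %in% c("molecular", "clinical")))
    stop("feature kind must be 'molecular' or 'clinical'", call. = FALSE)
  mol <- meta$kind == "molecular"
  if (!any(mol))
    stop("no molecular features: clinical max-WE rule undefined",
         call. = FALSE)
  if (any(mol & (is.na(meta$gene_id) | !nzchar(meta$gene_id))))
    stop("molecular feature(s) without a gene link", call. = FALSE)
  we_gene <- conservation$WE[match(meta$gene_id, conservation$gene_id)]
  if (any(mol & !is.finite(we_gene)))
    stop("molecular feature(s) link to genes without a finite WE: ",
         paste(head(meta$feature_id[mol & !is.finite(we_gene)], 5),
               collapse = ", "), call. = FALSE)
  WE <- ifelse(mol, we_gene, max(we_gene[mol]))
  WS <- ws$WS[match(meta$feature_id, ws$feature_id)]
  if (anyNA(WS))
    stop("missing statistical weight for: ",
         paste(head(meta$feature_id[is.na(WS)], 5), collapse = ", "),
         call. = FALSE)
  if (any(WS < 0)) stop("negative statistical weight", call. = FALSE)
  out <- data.frame(feature_id = meta$feature_id, kind = meta$kind,
                    WE = we_scale * WE, WS = ws_scale * WS,
                    W = we_scale * WE + ws_scale * WS, row.names = NULL)
  class(out) <- c("weight_set", "data.frame")
  out
}

#' Uniform (unweighted) weight set
#'
#' All composite weights equal 1 — the unweighted reference model, to which
#' the weighted pipeline provably collapses when every weight is equal.
#'
#' @param meta feature metadata (see [assemble_weights()]).
#' @return a `weight_set` with `W = 1` for every feature.
#' @export
uniform_weights <- function(meta) {
  out <- data.frame(feature_id = meta$feature_id, kind = meta$kind,
                    WE = NA_real_, WS = NA_real_, W = 1, row.names = NULL)
  class(out) <- c("weight_set", "data.frame")
  out
}

#' Multiply a z-scored matrix by composite feature weights
#'
#' Produces the weighted feature matrix `fw[i, j] = W_i * f[i, j]` that is
#' subjected to sparse feature selection; the original matrix is untouched
#' (classification later uses the unweighted values).
#'
#' @param matrix a z-scored [labeled_matrix()].
#' @param weights a `weight_set` covering every feature of `matrix`.
#' @return a `labeled_matrix` with weighted values (attribute
#'   `weighted = TRUE`).
#' @export
apply_weights <- function(matrix, weights) {
  stopifnot(inherits(matrix, "labeled_matrix"))
  if (!matrix$z_scored)
    stop("matrix must be z-scored before weighting", call. = FALSE)
  w <- weights$W[match(colnames(matrix$values), weights$feature_id)]
  if (anyNA(w))
    stop("missing weight for feature(s): ",
         paste(head(setdiff(colnames(matrix$values), weights$feature_id), 5),
               collapse = ", "), call. = FALSE)
  out <- matrix
  out$values <- sweep(matrix$values, 2, w, "*")
  attr(out, "weighted") <- TRUE
  out
}
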