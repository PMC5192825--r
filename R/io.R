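#' Read a sample-by-feature table with a binary outcome column
#'
#' Accepts CSV or TSV (by file extension) with a header, one sample-id
#' column and one binary label column; every other column must be numeric.
#' Labels accept `1`/`0` and the synonyms `poor`/`good` (poor outcome is
#' the positive class).
#'
#' @param path file path (`.csv` comma-separated, otherwise tab-separated).
#' @param label_column name of the outcome column (default `"outcome"`).
#' @param id_column name of the sample-id column (default `"sample_id"`).
#' @return a [labeled_matrix()].
#' @export
read_feature_table <- function(path, label_column = "outcome",
                               id_column = "sample_id") {
  df <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    utils::read.csv(path, check.names = FALSE, colClasses = "character")
  else utils::read.delim(path, check.names = FALSE, colClasses = "character")
  for (col in c(id_column, label_column))
    if (!col %in% names(df))
      stop("missing column '", col, "' in ", path, call. = FALSE)
  ids <- df[[id_column]]
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  raw <- df[[label_column]]
  labels <- ifelse(raw %in% c("1", "poor"), 1L,
                   ifelse(raw %in% c("0", "good"), 0L, NA_integer_))
  if (anyNA(labels))
    stop("non-binary label value '", raw[which(is.na(labels))[1]],
         "' for sample '", ids[which(is.na(labels))[1]], "'", call. = FALSE)
  feats <- setdiff(names(df), c(id_column, label_column))
  values <- matrix(NA_real_, nrow(df), length(feats),
                   dimnames = list(ids, feats))
  for (f in feats) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    bad <- which(is.na(v) & !is.na(df[[f]]) & nzchar(df[[f]]))
    if (length(bad) || anyNA(v))
      stop("non-numeric value in column '", f, "', row ",
           if (length(bad)) bad[1] else which(is.na(v))[1], call. = FALSE)
    values[, f] <- v
  }
  labeled_matrix(values, labels)
}

#' Write a sample-by-feature table
#'
#' @param matrix a [labeled_matrix()].
#' @param path output path (`.csv` or `.tsv`).
#' @param label_column,id_column column names to use.
#' @export
write_feature_table <- function(matrix, path, label_column = "outcome",
                                id_column = "sample_id") {
  df <- data.frame(matrix$values, check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(matrix$values),
                                         matrix$labels),
                              c(id_column, label_column)), df)
  utils::write.table(df, path, sep = if (grepl("\\.csv$", path)) "," else "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Read/write feature metadata (feature_id, kind, gene_id)
#' @param path TSV path.
#' @return data.frame.
#' @export
read_feature_meta <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("feature_id", "kind", "gene_id")
  if (!all(need %in% names(df)))
    stop("metadata must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df$gene_id[!nzchar(df$gene_id)] <- NA_character_
  df
}

#' Write a generic TSV table (rates, weights, stability profiles)
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a TSV table written by [write_tsv_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) utils::read.delim(path)

#' Save an ensemble model as a plain-text archive
#'
#' Writes a versioned directory: `manifest.json` (config, weights,
#' z-transform parameters, seed) and `submodels.json` (selected features
#' and flat forest tables per submodel). Everything is plain JSON at full
#' precision, so a load round-trips the model exactly.
#'
#' @param model an `evo_ensemble`.
#' @param dir output directory (created if needed).
#' @export
save_ensemble <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format = "evoinform-ensemble", version = 1L,
                   config = unclass(model$config), seed = model$seed,
                   center = as.list(model$center),
                   scale = as.list(model$scale),
                   weights = model$weights)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  subs <- lapply(model$submodels, function(sm) {
    list(samples = sm$samples, selected = sm$selected,
         fallback = sm$fallback, seed = sm$seed,
         frequency = as.list(sm$frequency),
         features = sm$forest$features, mtry = sm$forest$mtry,
         trees = lapply(sm$forest$trees, function(t)
           as.data.frame(t)))
  })
  jsonlite::write_json(subs, file.path(dir, "submodels.json"),
                       digits = NA, null = "null")
  invisible(dir)
}

#' Load an ensemble model saved by [save_ensemble()]
#'
#' @param dir model directory.
#' @return an `evo_ensemble`.
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (!identical(manifest$format, "evoinform-ensemble"))
    stop("not an evoinform model directory: ", dir, call. = FALSE)
  subs <- jsonlite::fromJSON(file.path(dir, "submodels.json"),
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  cfg <- do.call(evo_config, manifest$config[setdiff(names(manifest$config),
                                                     "mtry")])
  cfg$mtry <- manifest$config$mtry
  weights <- as.data.frame(
    lapply(as.data.frame(do.call(rbind, lapply(manifest$weights, as.data.frame)),
                         stringsAsFactors = FALSE), unlist))
  class(weights) <- c("weight_set", "data.frame")
  submodels <- lapply(subs, function(sm) {
    forest <- structure(list(
      trees = lapply(sm$trees, function(t) {
        tab <- do.call(rbind, lapply(t, function(row)
          vapply(row[c("feature", "threshold", "left", "right", "prob")],
                 function(v) if (is.null(v)) NA_real_ else as.numeric(v),
                 numeric(1))))
        colnames(tab) <- c("feature", "threshold", "left", "right", "prob")
        tab
      }),
      features = unlist(sm$features), mtry = sm$mtry,
      n_trees = length(sm$trees)), class = "rf_model")
    structure(list(samples = unlist(sm$samples),
                   selected = unlist(sm$selected),
                   forest = forest,
                   frequency = unlist(sm$frequency),
                   fallback = isTRUE(sm$fallback), seed = sm$seed),
              class = "evo_submodel")
  })
  structure(list(submodels = submodels,
                 center = unlist(manifest$center),
                 scale = unlist(manifest$scale),
                 weights = weights, config = cfg, seed = manifest$seed),
            class = "evo_ensemble")
}
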