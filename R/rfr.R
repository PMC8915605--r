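# Random-forest QSPR regression of log S0 on a combined descriptor table.

#' Build a combined descriptor table for random-forest modeling
#'
#' Assembles the feature matrix: melting point plus the five Abraham
#' descriptors from the compound records, joined with any precomputed 2D
#' structural descriptors supplied as a data frame or CSV (matched by
#' `id`). Columns that are zero for every compound carry no information
#' for tree splits and are dropped with a message; a feature name
#' colliding with a base feature is an error. When no 2D descriptor
#' table is supplied the model falls back to the reduced
#' mp-plus-Abraham feature set with a warning.
#'
#' @param records a `compound_table` with `mp` and Abraham descriptor
#'   columns.
#' @param descriptors optional data frame or CSV path with an `id`
#'   column and numeric 2D descriptor columns.
#' @return numeric matrix (rows = compounds, named columns = features)
#'   with attributes `provenance` (per-column origin) and `dropped`
#'   (all-zero columns removed).
#' @export
build_descriptor_table <- function(records, descriptors = NULL) {
  base_feats <- c("mp", ABRAHAM_FIELDS)
  missing_f <- setdiff(base_feats, names(records))
  if (length(missing_f) > 0) {
    stop("records lack required feature column(s): ",
         paste(missing_f, collapse = ", "))
  }
  X <- as.matrix(as.data.frame(records)[, base_feats, drop = FALSE])
  rownames(X) <- records$id
  provenance <- setNames(rep("record", length(base_feats)), base_feats)

  if (is.null(descriptors)) {
    warning("no 2D descriptor table supplied; using the reduced ",
            "mp + Abraham feature set", call. = FALSE)
  } else {
    if (is.character(descriptors)) {
      descriptors <- read.csv(descriptors, stringsAsFactors = FALSE)
    }
    if (!"id" %in% names(descriptors)) stop("descriptors need an 'id' column")
    extra <- setdiff(names(descriptors), "id")
    clash <- intersect(extra, colnames(X))
    if (length(clash) > 0) {
      stop("feature-name collision: ", paste(clash, collapse = ", "))
    }
    idx <- match(records$id, descriptors$id)
    if (any(is.na(idx))) {
      stop("descriptor table lacks rows for: ",
           paste(records$id[is.na(idx)][1:min(3, sum(is.na(idx)))],
                 collapse = ", "))
    }
    M <- as.matrix(descriptors[idx, extra, drop = FALSE])
    if (!is.numeric(M)) stop("descriptor columns must be numeric")
    X <- cbind(X, M)
    provenance <- c(provenance, setNames(rep("descriptor_table",
                                             length(extra)), extra))
  }
  if (any(!is.finite(X))) stop("all features must be finite")
  zero_cols <- colnames(X)[apply(X == 0, 2, all)]
  if (length(zero_cols) > 0) {
    message("dropping all-zero feature column(s): ",
            paste(zero_cols, collapse = ", "))
    X <- X[, setdiff(colnames(X), zero_cols), drop = FALSE]
    provenance <- provenance[colnames(X)]
  }
  attr(X, "provenance") <- provenance
  attr(X, "dropped") <- zero_cols
  X
}

#' Train a random-forest solubility model
#'
#' Random 70/30 train/validation split at the given seed, then a
#' [randomForest::randomForest()] ensemble on the training rows. The
#' classic defaults are adopted: 500 trees, `p/3` candidate features per
#' split, unlimited depth. Feature importance (mean decrease in node
#' impurity) is reported normalized to sum 1, in descending order.
#'
#' @param features feature matrix from [build_descriptor_table()].
#' @param targets observed log S0, one per feature row.
#' @param split training fraction (default 0.7).
#' @param seed seed controlling both the split and the forest.
#' @param ntree number of trees (default 500).
#' @param mtry candidate features per split; default `max(1, p/3)`.
#' @return list of class `rfr_model`: `forest`, `features`
#'   (column names), `importance`, `train_index`, `metrics_train`,
#'   `metrics_validation`, `seed`.
#' @export
train_rfr <- function(features, targets, split = 0.7, seed = 1,
                      ntree = 500, mtry = NULL) {
  features <- as.matrix(features)
  if (nrow(features) != length(targets)) {
    stop("features and targets must have matching rows")
  }
  if (nrow(features) < 50) stop("need at least 50 rows to train")
  if (is.null(mtry)) mtry <- max(1, floor(ncol(features) / 3))
  set.seed(seed)
  n <- nrow(features)
  train_idx <- sort(sample.int(n, size = floor(split * n)))
  forest <- randomForest::randomForest(
    x = features[train_idx, , drop = FALSE], y = targets[train_idx],
    ntree = ntree, mtry = mtry, importance = FALSE)
  pred_tr <- predict(forest, features[train_idx, , drop = FALSE])
  val_idx <- setdiff(seq_len(n), train_idx)
  pred_val <- predict(forest, features[val_idx, , drop = FALSE])
  imp <- randomForest::importance(forest, type = 2)[, 1]
  imp <- sort(imp / sum(imp), decreasing = TRUE)
  structure(list(forest = forest, features = colnames(features),
                 importance = imp, train_index = train_idx, seed = seed,
                 metrics_train = evaluate_predictions(targets[train_idx],
                                                      pred_tr),
                 metrics_validation = evaluate_predictions(targets[val_idx],
                                                           pred_val)),
            class = "rfr_model")
}

#' @export
print.rfr_model <- function(x, ...) {
  cat(sprintf("random forest (%d trees, %d features)\n",
              x$forest$ntree, length(x$features)))
  cat("  train:      "); print(x$metrics_train)
  cat("  validation: "); print(x$metrics_validation)
  invisible(x)
}

#' Predict log S0 with a trained random-forest model
#'
#' @param model an [train_rfr()] result.
#' @param features feature matrix containing at least the model's
#'   feature columns (extra columns are ignored).
#' @return per-row ensemble-mean predicted log S0.
#' @export
predict_rfr <- function(model, features) {
  stopifnot(inherits(model, "rfr_model"))
  features <- as.matrix(features)
  missing_f <- setdiff(model$features, colnames(features))
  if (length(missing_f) > 0) {
    stop("missing feature(s): ", paste(missing_f, collapse = ", "))
  }
  unname(predict(model$forest, features[, model$features, drop = FALSE]))
}
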