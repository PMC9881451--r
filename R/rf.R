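# Random-forest harness shared by the small-variant and SV classifiers:
# 1:1 class balancing, stratified 75/25 splitting, grid search, training
# (ranger, seeded, single-threaded for reproducibility) and evaluation.

#' Random-forest hyperparameters
#'
#' @param features_per_split number of candidate features per split (mtry).
#' @param num_trees number of trees (ntree).
#' @param min_node_size minimal terminal node size (nodesize).
#' @param seed RNG seed used when fitting.
#' @return list of class `rf_hyperparams`.
#' @export
rf_hyperparams <- function(features_per_split = 8, num_trees = 1000,
                           min_node_size = 5, seed = 42) {
  stopifnot(features_per_split >= 1, num_trees >= 1, min_node_size >= 1)
  structure(list(features_per_split = as.integer(features_per_split),
                 num_trees = as.integer(num_trees),
                 min_node_size = as.integer(min_node_size),
                 seed = as.integer(seed)),
            class = "rf_hyperparams")
}

#' Default hyperparameters for the small-variant models
#'
#' The grid-search optimum for the point-mutation models:
#' mtry 8, 1000 trees, node size 5.
#' @param seed RNG seed.
#' @return `rf_hyperparams`.
#' @export
snv_default_hyperparams <- function(seed = 42) {
  rf_hyperparams(8, 1000, 5, seed)
}

#' Default hyperparameters for the SV models
#'
#' The SV classifiers use stock random-forest settings: mtry 4, 400 trees,
#' node size 1.
#' @param seed RNG seed.
#' @return `rf_hyperparams`.
#' @export
sv_default_hyperparams <- function(seed = 42) {
  rf_hyperparams(4, 400, 1, seed)
}

#' Default grid for hyperparameter search
#'
#' Spans mtry {2, 4, 8} x trees {400, 1000} x node size {1, 5}, covering
#' both the small-variant optimum (8/1000/5) and the stock SV settings
#' (4/400/1).
#' @param seed RNG seed shared by all grid points.
#' @return list of `rf_hyperparams`.
#' @export
default_rf_grid <- function(seed = 42) {
  g <- expand.grid(mtry = c(2, 4, 8), trees = c(400, 1000), node = c(1, 5))
  lapply(seq_len(nrow(g)),
         function(i) rf_hyperparams(g$mtry[i], g$trees[i], g$node[i], seed))
}

#' Down-sample the majority class to a 1:1 ratio
#'
#' Somatic:germline classes are balanced to the minority-class count by
#' uniform sampling without replacement; deterministic under a fixed seed.
#'
#' @param labeled data.frame with a `label` column in {somatic, germline}.
#' @param seed RNG seed.
#' @return balanced data.frame (original row order within class preserved).
#' @export
balance_one_to_one <- function(labeled, seed = 42) {
  for (cls in c("somatic", "germline")) {
    if (!any(labeled$label == cls)) {
      stop(sprintf("cannot balance: class '%s' absent", cls))
    }
  }
  idx <- split(seq_len(nrow(labeled)), labeled$label)
  m <- min(lengths(idx))
  keep <- unlist(lapply(idx, function(ii) {
    if (length(ii) == m) ii else sort(withr::with_seed(seed, sample(ii, m)))
  }), use.names = FALSE)
  out <- labeled[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified train/test split
#'
#' Splits by label with `train_fraction` (default 0.75, i.e. 75% training /
#' 25% held-out evaluation) within each stratum; train and test are disjoint
#' and exhaustive.
#'
#' @param records labeled data.frame.
#' @param train_fraction fraction per stratum assigned to training.
#' @param seed RNG seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_train_test <- function(records, train_fraction = 0.75, seed = 42) {
  stopifnot(train_fraction > 0, train_fraction < 1, nrow(records) >= 4)
  idx <- split(seq_len(nrow(records)), records$label)
  small <- names(idx)[lengths(idx) < 2]
  if (length(small) > 0) {
    stop(sprintf("stratum '%s' has fewer than 2 records", small[1]))
  }
  train_idx <- unlist(lapply(seq_along(idx), function(k) {
    ii <- idx[[k]]
    n_tr <- round(train_fraction * length(ii))
    n_tr <- min(max(n_tr, 1), length(ii) - 1)
    withr::with_seed(seed + k, sample(ii, n_tr))
  }), use.names = FALSE)
  train_idx <- sort(train_idx)
  list(train = records[train_idx, , drop = FALSE],
       test = records[setdiff(seq_len(nrow(records)), train_idx), , drop = FALSE])
}

#' Train a somatic-vs-germline random forest
#'
#' Fits a probability forest (ranger) on the given feature columns; single
#' threaded and seeded so that repeated runs give identical predictions.
#' Per-feature impurity importances are reported in rank order.
#'
#' @param train labeled feature data.frame (balanced upstream).
#' @param features character vector of feature column names.
#' @param hp `rf_hyperparams`.
#' @return object of class `tos_rf` with elements `model`, `features`, `hp`,
#'   `importance` (named, sorted decreasing).
#' @export
train_rf <- function(train, features, hp = snv_default_hyperparams()) {
  if (nrow(train) == 0) stop("cannot train on zero records")
  stopifnot(all(features %in% names(train)),
            hp$features_per_split <= length(features))
  x <- train[, features, drop = FALSE]
  stopifnot(all(vapply(x, function(col) all(is.finite(col)), logical(1))))
  y <- factor(train$label, levels = c("germline", "somatic"))
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = hp$num_trees,
    mtry = hp$features_per_split,
    min.node.size = hp$min_node_size,
    probability = TRUE,
    importance = "impurity",
    seed = hp$seed,
    num.threads = 1,
    respect.unordered.factors = "order"
  )
  structure(list(model = fit, features = features, hp = hp,
                 importance = sort(fit$variable.importance, decreasing = TRUE)),
            class = "tos_rf")
}

#' @export
print.tos_rf <- function(x, ...) {
  cat("<tos_rf>", length(x$features), "features,",
      x$hp$num_trees, "trees (mtry", paste0(x$hp$features_per_split, ","),
      "node size", paste0(x$hp$min_node_size, ")\n"))
  cat("top importances:", paste(utils::head(names(x$importance), 5), collapse = ", "),
      "\n")
  invisible(x)
}

#' Somatic class probability for a feature table
#'
#' @param model a `tos_rf`.
#' @param newdata feature data.frame.
#' @return numeric vector of somatic probabilities between 0 and 1.
#' @export
predict_somatic_prob <- function(model, newdata) {
  if (nrow(newdata) == 0) return(numeric(0))
  p <- stats::predict(model$model, data = newdata[, model$features, drop = FALSE],
                      num.threads = 1)$predictions
  as.numeric(p[, "somatic"])
}

#' Confusion-count evaluation report
#'
#' @param tp,fp,fn,tn confusion counts (somatic = positive class).
#' @return list of class `evaluation_report` with precision = tp/(tp+fp),
#'   recall = tp/(tp+fn), accuracy = (tp+tn)/total.
#' @export
evaluation_report <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn > 0)
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    accuracy = (tp + tn) / (tp + fp + fn + tn)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("tp %d fp %d fn %d tn %d | precision %.4f recall %.4f accuracy %.4f\n",
              x$tp, x$fp, x$fn, x$tn, x$precision, x$recall, x$accuracy))
  invisible(x)
}

#' Evaluate a model on a labeled test set
#'
#' Classification at probability threshold 0.5, somatic as the positive
#' class.
#'
#' @param model a `tos_rf`.
#' @param test labeled feature data.frame.
#' @param threshold somatic probability cutoff.
#' @return an `evaluation_report`.
#' @export
evaluate_model <- function(model, test, threshold = 0.5) {
  if (nrow(test) == 0) stop("cannot evaluate on an empty test set")
  prob <- predict_somatic_prob(model, test)
  pred <- prob >= threshold
  truth <- test$label == "somatic"
  evaluation_report(tp = sum(pred & truth), fp = sum(pred & !truth),
                    fn = sum(!pred & truth), tn = sum(!pred & !truth))
}

#' Grid search over random-forest hyperparameters
#'
#' Selects the grid point maximizing mean cross-validated accuracy on the
#' training set (stratified folds). Ties are broken towards the cheaper /
#' more regularized model: fewer trees, then larger minimal node size, then
#' smaller mtry. Deterministic under a fixed seed.
#'
#' @param train labeled feature data.frame.
#' @param features feature column names.
#' @param grid list of `rf_hyperparams` (non-empty).
#' @param cv_folds number of folds.
#' @param seed fold-assignment seed.
#' @return list with `best` (`rf_hyperparams`), `cv_accuracy` of the best
#'   point, and `table` of all grid points with their mean CV accuracies.
#' @export
grid_search_rf <- function(train, features, grid = default_rf_grid(),
                           cv_folds = 5, seed = 42) {
  stopifnot(length(grid) > 0)
  y <- train$label
  folds <- integer(nrow(train))
  for (cls in unique(y)) {
    ii <- which(y == cls)
    folds[ii] <- withr::with_seed(seed, sample(rep_len(seq_len(cv_folds), length(ii))))
  }
  for (f in seq_len(cv_folds)) {
    if (length(unique(y[folds == f])) < 2 || length(unique(y[folds != f])) < 2) {
      stop(sprintf("cross-validation fold %d contains a single class", f))
    }
  }
  acc <- vapply(grid, function(hp) {
    mean(vapply(seq_len(cv_folds), function(f) {
      m <- train_rf(train[folds != f, , drop = FALSE], features, hp)
      evaluate_model(m, train[folds == f, , drop = FALSE])$accuracy
    }, numeric(1)))
  }, numeric(1))
  ord <- order(-acc,
               vapply(grid, `[[`, integer(1), "num_trees"),
               -vapply(grid, `[[`, integer(1), "min_node_size"),
               vapply(grid, `[[`, integer(1), "features_per_split"))
  tab <- data.frame(
    features_per_split = vapply(grid, `[[`, integer(1), "features_per_split"),
    num_trees = vapply(grid, `[[`, integer(1), "num_trees"),
    min_node_size = vapply(grid, `[[`, integer(1), "min_node_size"),
    cv_accuracy = acc
  )
  list(best = grid[[ord[1]]], cv_accuracy = acc[ord[1]], table = tab)
}

#' Classify a cohort of tumor-only samples
#'
#' Applies the SNV model to SNV records and the indel model to the rest;
#' every variant receives a somatic probability and a class, and a summary
#' table reports per-sample counts. The record count is never changed.
#'
#' @param models list with elements `snv` and `indel` (`tos_rf` objects).
#' @param samples named list of small-variant data.frames (one per sample).
#' @param rs a `resource_set` for feature extraction.
#' @param threshold somatic probability cutoff.
#' @return list with `classified` (named list of data.frames gaining
#'   `somatic_prob` and `rf_class`) and `summary` (per-sample counts).
#' @export
classify_cohort <- function(models, samples, rs, threshold = 0.5) {
  classified <- lapply(samples, function(v) {
    if (nrow(v) == 0) {
      v$somatic_prob <- numeric(0)
      v$rf_class <- character(0)
      return(v)
    }
    feats <- extract_snv_features(v, rs)
    prob <- numeric(nrow(v))
    snv_rows <- v$vclass == "SNV"
    if (any(snv_rows)) {
      prob[snv_rows] <- predict_somatic_prob(models$snv, feats[snv_rows, , drop = FALSE])
    }
    if (any(!snv_rows)) {
      prob[!snv_rows] <- predict_somatic_prob(models$indel, feats[!snv_rows, , drop = FALSE])
    }
    v$somatic_prob <- prob
    v$rf_class <- ifelse(prob >= threshold, "somatic", "germline")
    v
  })
  summary <- data.frame(
    sample = names(samples),
    n = vapply(classified, nrow, integer(1)),
    n_somatic = vapply(classified, function(v) sum(v$rf_class == "somatic"), integer(1)),
    n_germline = vapply(classified, function(v) sum(v$rf_class == "germline"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(classified = classified, summary = summary)
}
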