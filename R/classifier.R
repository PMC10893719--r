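#' Stratified train/test split
#'
#' Splits samples 3:1 (by default) within each class: per class,
#' `round(ratio * n_class)` training members, with at least one member left
#' in the test set. Seeded and deterministic.
#'
#' @param sample_ids sample identifiers
#' @param labels class labels aligned to `sample_ids`
#' @param ratio training fraction in (0, 1)
#' @param seed integer RNG seed
#' @return list(train = ids, test = ids)
#' @export
split_train_test <- function(sample_ids, labels, ratio = 0.75, seed = 1L) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  tab <- table(labels)
  if (any(tab < 2)) stop("every class needs >= 2 members")
  set.seed(seed)
  train <- character(0)
  for (cl in names(tab)) {
    ids <- sample_ids[labels == cl]
    n_tr <- round(ratio * length(ids))
    n_tr <- min(n_tr, length(ids) - 1L)   # at least one test member
    n_tr <- max(n_tr, 1L)
    train <- c(train, sample(ids, n_tr))
  }
  list(train = train, test = setdiff(sample_ids, train))
}

# OOB error of one forest fit; seeded so every grid point is reproducible
fit_forest <- function(x, y, mtry, ntree, seed) {
  set.seed(seed)
  randomForest::randomForest(x = x, y = y, mtry = mtry, ntree = ntree)
}

oob_error <- function(model) {
  unname(model$err.rate[nrow(model$err.rate), "OOB"])
}

#' Grid-tune a random forest on out-of-bag error
#'
#' Fits a forest at every (mtry, ntree) grid point on the training data
#' (features = the global DEG set), records the OOB error, and selects the
#' minimizer; ties go to the smaller ntree, then the smaller mtry. Grid
#' points with mtry exceeding the feature count are skipped with a warning.
#' Default grids cover the mtry = 9 / ntree = 400 operating point used in
#' the study.
#'
#' @param x sample x feature training matrix
#' @param y factor of training labels
#' @param mtry_grid candidate mtry values (default sqrt(p), p/10, p/5, 9)
#' @param ntree_grid candidate ntree values (default 100..500 step 100)
#' @param seed integer RNG seed
#' @return list(model, mtry, ntree, oob_error, grid = full results table)
#' @export
tune_forest <- function(x, y, mtry_grid = NULL, ntree_grid = seq(100, 500, 100),
                        seed = 1L) {
  y <- factor(y)
  p <- ncol(x)
  if (is.null(mtry_grid)) {
    mtry_grid <- unique(pmax(1L, c(floor(sqrt(p)), floor(p / 10),
                                   floor(p / 5), 9L)))
  }
  if (length(mtry_grid) == 0 || length(ntree_grid) == 0) stop("empty grid")
  bad <- mtry_grid > p
  if (any(bad)) {
    warning(sprintf("skipping mtry > %d: %s", p,
                    paste(mtry_grid[bad], collapse = ", ")), call. = FALSE)
    mtry_grid <- mtry_grid[!bad]
    if (length(mtry_grid) == 0) stop("no valid mtry values")
  }
  grid <- expand.grid(mtry = sort(mtry_grid), ntree = sort(ntree_grid))
  grid$oob <- NA_real_
  for (i in seq_len(nrow(grid))) {
    fit <- fit_forest(x, y, grid$mtry[i], grid$ntree[i],
                      seed = stage_seed(seed, paste0("rf", i)))
    grid$oob[i] <- oob_error(fit)
  }
  best <- grid[order(grid$oob, grid$ntree, grid$mtry), ][1, ]
  model <- fit_forest(x, y, best$mtry, best$ntree,
                      seed = stage_seed(seed, "rf_final"))
  list(model = model, mtry = best$mtry, ntree = best$ntree,
       oob_error = oob_error(model), grid = grid)
}

#' One-vs-rest AUC from scores (Mann-Whitney convention)
#'
#' Rank-based AUC; tied scores contribute 1/2 per pair.
#' @param scores numeric scores, higher = more positive
#' @param positive logical vector marking the positive class
#' @return AUC in [0, 1]
#' @export
rank_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)   # midranks handle ties at 1/2 weight
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a subtype classifier on held-out samples
#'
#' Accuracy plus one-vs-rest AUCs computed from the forest's class vote
#' fractions; macro AUC is the unweighted mean over classes with defined
#' AUC. Classes absent from the test set yield NA AUC with a warning.
#'
#' @param model a fitted randomForest
#' @param x_test sample x feature test matrix
#' @param y_test true test labels
#' @return list(accuracy, per_class_auc, macro_auc, confusion, votes)
#' @export
evaluate_classifier <- function(model, x_test, y_test) {
  if (nrow(x_test) == 0) stop("empty test set")
  y_test <- factor(y_test, levels = levels(model$y))
  votes <- stats::predict(model, x_test, type = "prob")
  pred <- factor(colnames(votes)[max.col(votes, ties.method = "first")],
                 levels = levels(model$y))
  accuracy <- mean(pred == y_test)
  per_class_auc <- vapply(levels(y_test), function(cl) {
    pos <- y_test == cl
    if (!any(pos)) return(NA_real_)
    rank_auc(votes[, cl], pos)
  }, 0)
  if (anyNA(per_class_auc)) {
    warning("class absent from test set; macro AUC over defined classes",
            call. = FALSE)
  }
  list(accuracy = accuracy, per_class_auc = per_class_auc,
       macro_auc = mean(per_class_auc, na.rm = TRUE),
       confusion = table(truth = y_test, predicted = pred),
       votes = votes)
}

#' Stratified k-fold cross-validated accuracy
#'
#' Per fold, the full grid tuning of [tune_forest()] is rerun on the other
#' folds and accuracy is measured on the held-out fold; returns the mean
#' over folds.
#'
#' @param x sample x feature matrix
#' @param y labels
#' @param folds number of folds (every class needs >= folds members)
#' @param mtry_grid,ntree_grid grids passed to [tune_forest()]
#' @param seed integer RNG seed
#' @return list(cv_accuracy, fold_accuracy, fold_assignment)
#' @export
cross_validate <- function(x, y, folds = 5, mtry_grid = NULL,
                           ntree_grid = seq(100, 500, 100), seed = 1L) {
  y <- factor(y)
  if (any(table(y) < folds)) stop("every class needs >= folds members")
  set.seed(stage_seed(seed, "cvfolds"))
  fold_of <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold_of != f
    fit <- tune_forest(x[tr, , drop = FALSE], y[tr],
                       mtry_grid = mtry_grid, ntree_grid = ntree_grid,
                       seed = stage_seed(seed, paste0("cv", f)))
    ev <- evaluate_classifier(fit$model, x[!tr, , drop = FALSE], y[!tr])
    ev$accuracy
  }, 0)
  list(cv_accuracy = mean(acc), fold_accuracy = acc, fold_assignment = fold_of)
}

#' Predict the subtype of single samples
#'
#' The single-sample contract: each prediction uses one sample's expression
#' vector over the model's feature list only.
#'
#' @param model fitted randomForest from [tune_forest()]
#' @param expr gene x sample matrix containing the model's features
#' @return data.frame: sample_id, predicted, plus one vote-fraction column
#'   per subtype
#' @export
predict_subtype <- function(model, expr) {
  feats <- rownames(model$importance)
  missing <- setdiff(feats, rownames(expr))
  if (length(missing)) {
    stop(sprintf("expression matrix lacks model features: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  x <- t(expr[feats, , drop = FALSE])
  votes <- stats::predict(model, x, type = "prob")
  pred <- colnames(votes)[max.col(votes, ties.method = "first")]
  data.frame(sample_id = rownames(x), predicted = pred, votes,
             stringsAsFactors = FALSE, row.names = NULL, check.names = FALSE)
}
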