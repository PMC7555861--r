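#' Label peaks TRUE/FALSE against a reference end annotation
#'
#' A peak is labeled `TRUE` (authentic end) when its dominant position lies
#' within `tolerance` bp of a same-strand reference end — emulating
#' labeling against curated TSS / polyadenylation-site catalogs — and
#' `FALSE` otherwise.
#'
#' @param peaks A peak tibble from [call_peaks()].
#' @param reference_ends A data frame of reference ends with `chrom`, `pos`
#'   (or `start`), `strand`, and optionally `end_type` (matched when present
#'   in both).
#' @param tolerance Matching window in bp (default 50).
#' @return A tibble `peak_id`, `label` (logical), `nearest_ref_dist`.
#' @export
label_peaks <- function(peaks, reference_ends, tolerance = 50L) {
  stopifnot(all(c("chrom", "strand") %in% names(reference_ends)))
  refs <- as_tibble(reference_ends)
  if (!("pos" %in% names(refs))) {
    # a peak table used as reference contributes its dominant position
    refs$pos <- if ("dominant_pos" %in% names(refs)) refs$dominant_pos else refs$start
  }
  match_type <- "end_type" %in% names(refs) && "end_type" %in% names(peaks)
  key_p <- paste(peaks$chrom, peaks$strand,
                 if (match_type) peaks$end_type else "", sep = "\r")
  key_r <- paste(refs$chrom, refs$strand,
                 if (match_type) refs$end_type else "", sep = "\r")
  dist <- rep(Inf, nrow(peaks))
  for (k in unique(key_p)) {
    rp <- sort(refs$pos[key_r == k])
    if (length(rp) == 0L) next
    idx <- which(key_p == k)
    q <- peaks$dominant_pos[idx]
    lo <- findInterval(q, rp)
    d_lo <- ifelse(lo >= 1L, q - rp[pmax(lo, 1L)], Inf)
    d_hi <- ifelse(lo < length(rp), rp[pmin(lo + 1L, length(rp))] - q, Inf)
    dist[idx] <- pmin(abs(d_lo), abs(d_hi))
  }
  tibble(peak_id = peaks$peak_id, label = dist <= tolerance,
         nearest_ref_dist = dist)
}

#' Training protocol for end classifiers
#'
#' The model-fitting protocol: a stratified 70/30 train/test split,
#' five-fold cross-validation on the training split for hyperparameter
#' selection, and a two-round (coarse, then fine) grid search per
#' algorithm.
#'
#' @param train_fraction Fraction of peaks used for training (default 0.7).
#' @param cv_folds Cross-validation folds (default 5).
#' @param algorithms Algorithms to train: subset of `"LR"` (ridge logistic
#'   regression), `"RF"` (random forest), `"SVM"` (RBF-kernel SVM), `"KNN"`.
#' @param seed Integer seed controlling the split, fold assignment and
#'   stochastic fits; identical seed and data give identical models.
#' @return A `training_protocol` list.
#' @export
training_protocol <- function(train_fraction = 0.7, cv_folds = 5L,
                              algorithms = c("LR", "RF", "SVM", "KNN"),
                              seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, cv_folds >= 2)
  algorithms <- match.arg(algorithms, c("LR", "RF", "SVM", "KNN"),
                          several.ok = TRUE)
  structure(
    list(train_fraction = train_fraction, cv_folds = as.integer(cv_folds),
         algorithms = algorithms, seed = as.integer(seed)),
    class = "training_protocol"
  )
}

#' Train end classifiers with cross-validated two-round grid search
#'
#' For each requested algorithm: a coarse hyperparameter grid is scored by
#' stratified k-fold cross-validated accuracy on the training split, a fine
#' grid is laid around the best coarse point and scored the same way, and
#' the winning hyperparameters are refit on the whole training split. Test
#' accuracy on the held-out split is recorded per model.
#'
#' @param features An `rcat_features` matrix from [assemble_features()].
#' @param labels Logical vector (or `label_peaks()` output) aligned with the
#'   feature rows; `TRUE` = authentic end. Both classes must be present.
#' @param protocol A [training_protocol()].
#' @return A named list of `end_classifier` objects (one per algorithm), of
#'   class `end_classifier_set`, carrying the test split indices as
#'   attributes.
#' @export
train_end_classifiers <- function(features, labels,
                                  protocol = training_protocol()) {
  xy <- check_training_input(features, labels)
  x <- xy$x; y <- xy$y
  set.seed(protocol$seed)
  train_idx <- stratified_sample(y, protocol$train_fraction)
  folds <- stratified_folds(y[train_idx], protocol$cv_folds)

  models <- lapply(protocol$algorithms, function(alg) {
    fit_with_grid_search(alg, x[train_idx, , drop = FALSE], y[train_idx],
                         folds, protocol, contract = contract_of(features))
  })
  names(models) <- protocol$algorithms
  for (alg in protocol$algorithms) {
    pred <- predict(models[[alg]], x[-train_idx, , drop = FALSE],
                    .raw_matrix = TRUE)
    models[[alg]]$metrics <- classifier_metrics(y[-train_idx] == "TRUE",
                                                pred == "TRUE")
  }
  structure(models, class = "end_classifier_set",
            train_idx = train_idx, seed = protocol$seed)
}

check_training_input <- function(features, labels) {
  if (is.data.frame(labels)) {
    stopifnot("label" %in% names(labels))
    labels <- labels$label[match(features$peak_id, labels$peak_id)]
  }
  stopifnot(length(labels) == nrow(features), !anyNA(labels))
  if (length(unique(labels)) < 2L) {
    stop("training data contain a single class; both TRUE and FALSE peaks are required")
  }
  x <- as.matrix(features[, setdiff(names(features), "peak_id"), drop = FALSE])
  rownames(x) <- features$peak_id
  y <- factor(ifelse(labels, "TRUE", "FALSE"), levels = c("FALSE", "TRUE"))
  list(x = x, y = y)
}

contract_of <- function(features) {
  list(columns = setdiff(names(features), "peak_id"),
       groups = feature_groups(features),
       normalization = feature_normalization(features),
       end_type = attr(features, "end_type"))
}

stratified_sample <- function(y, fraction) {
  idx <- unlist(lapply(split(seq_along(y), y), function(i)
    sample(i, max(1L, round(length(i) * fraction)))))
  sort(unname(idx))
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in levels(y)) {
    i <- which(y == cls)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

# ---- grids ------------------------------------------------------------------

coarse_grid <- function(alg, p) {
  switch(alg,
    RF = expand.grid(mtry = unique(pmax(1L, c(floor(sqrt(p)), floor(p / 4), floor(p / 2)))),
                     nodesize = c(1L, 5L)),
    SVM = expand.grid(cost = 10^(-1:2), gamma = 10^(-3:-1)),
    KNN = data.frame(k = c(1L, 3L, 5L, 9L, 15L)),
    LR = data.frame(lambda = 10^seq(-4, 1, by = 1))
  )
}

fine_grid <- function(alg, best, p) {
  switch(alg,
    RF = expand.grid(
      mtry = unique(pmax(1L, pmin(p, best$mtry + c(-round(best$mtry / 2), 0L, round(best$mtry / 2))))),
      nodesize = unique(pmax(1L, best$nodesize + c(-2L, 0L, 2L)))
    ),
    SVM = expand.grid(cost = best$cost * c(1 / 3, 1, 3),
                      gamma = best$gamma * c(1 / 3, 1, 3)),
    KNN = data.frame(k = unique(pmax(1L, best$k + c(-2L, 0L, 2L)))),
    LR = data.frame(lambda = best$lambda * 10^seq(-0.5, 0.5, by = 0.25))
  )
}

fit_one <- function(alg, x, y, hyper, seed) {
  set.seed(seed)
  switch(alg,
    RF = randomForest::randomForest(x, y, ntree = 200L,
                                    mtry = hyper$mtry,
                                    nodesize = hyper$nodesize),
    SVM = e1071::svm(x, y, kernel = "radial", cost = hyper$cost,
                     gamma = hyper$gamma, probability = TRUE),
    KNN = list(x = x, y = y, k = hyper$k),   # lazy learner: store the data
    LR = glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = hyper$lambda)
  )
}

predict_one <- function(alg, model, x, seed) {
  set.seed(seed)
  switch(alg,
    RF = predict(model, x),
    SVM = predict(model, x),
    KNN = class::knn(model$x, x, model$y, k = model$k, prob = TRUE),
    LR = {
      p <- predict(model, x, type = "response")[, 1]
      factor(ifelse(p >= 0.5, "TRUE", "FALSE"), levels = c("FALSE", "TRUE"))
    }
  )
}

cv_score <- function(alg, x, y, hyper, folds, seed) {
  accs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    m <- fit_one(alg, x[tr, , drop = FALSE], y[tr], hyper, seed + f)
    pred <- predict_one(alg, m, x[!tr, , drop = FALSE], seed + f)
    mean(pred == y[!tr])
  }, double(1))
  mean(accs)
}

fit_with_grid_search <- function(alg, x, y, folds, protocol, contract) {
  p <- ncol(x)
  score_grid <- function(grid) {
    grid$cv_acc <- vapply(seq_len(nrow(grid)), function(i)
      cv_score(alg, x, y, grid[i, , drop = FALSE], folds, protocol$seed),
      double(1))
    grid
  }
  g1 <- score_grid(coarse_grid(alg, p))
  best1 <- g1[which.max(g1$cv_acc), , drop = FALSE]
  g2 <- score_grid(fine_grid(alg, best1, p))
  best2 <- g2[which.max(g2$cv_acc), , drop = FALSE]
  hyper <- best2[, setdiff(names(best2), "cv_acc"), drop = FALSE]
  model <- fit_one(alg, x, y, hyper, protocol$seed)
  structure(
    list(algorithm = alg, model = model,
         hyperparameters = as.list(hyper),
         cv_results = as_tibble(rbind(cbind(round = 1L, g1),
                                      cbind(round = 2L, g2))),
         cv_acc = best2$cv_acc,
         metrics = NULL, contract = contract, protocol = protocol),
    class = "end_classifier"
  )
}

# ---- prediction & evaluation ------------------------------------------------

#' Predict authentic vs false ends for a peak feature matrix
#'
#' @param object An `end_classifier`.
#' @param newdata An `rcat_features` matrix built on the model's feature
#'   contract (same columns; use the stored normalization via
#'   `assemble_features(..., normalization = object$contract$normalization)`).
#'   A matrix whose columns differ from the contract is refused.
#' @param type `"class"` for TRUE/FALSE calls, `"prob"` for the probability
#'   of the TRUE class.
#' @param .raw_matrix Internal: `newdata` is already a numeric matrix.
#' @param ... Unused.
#' @return A logical vector (`type = "class"`) or numeric probabilities.
#' @export
predict.end_classifier <- function(object, newdata, type = c("class", "prob"),
                                   .raw_matrix = FALSE, ...) {
  type <- match.arg(type)
  if (.raw_matrix) {
    x <- newdata
  } else {
    cols <- setdiff(names(newdata), "peak_id")
    if (!identical(cols, object$contract$columns)) {
      stop("feature columns do not match the model's feature contract")
    }
    x <- as.matrix(newdata[, cols, drop = FALSE])
  }
  seed <- object$protocol$seed
  if (type == "class") {
    pred <- predict_one(object$algorithm, object$model, x, seed)
    if (.raw_matrix) return(pred)
    return(pred == "TRUE")
  }
  set.seed(seed)
  switch(object$algorithm,
    RF = predict(object$model, x, type = "prob")[, "TRUE"],
    SVM = {
      p <- predict(object$model, x, probability = TRUE)
      attr(p, "probabilities")[, "TRUE"]
    },
    KNN = {
      pred <- class::knn(object$model$x, x, object$model$y,
                         k = object$model$k, prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "TRUE", win, 1 - win)
    },
    LR = predict(object$model, x, type = "response")[, 1]
  )
}

#' Confusion-matrix metrics with accuracy
#'
#' Accuracy is `(TP + TN) / (TP + TN + FP + FN)`, with `TRUE` (authentic
#' end) as the positive class.
#'
#' @param truth Logical ground-truth labels.
#' @param predicted Logical predicted labels.
#' @return A one-row tibble `TP`, `TN`, `FP`, `FN`, `acc`.
#' @export
classifier_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  tp <- sum(truth & predicted); tn <- sum(!truth & !predicted)
  fp <- sum(!truth & predicted); fn <- sum(truth & !predicted)
  tibble(TP = tp, TN = tn, FP = fp, FN = fn,
         acc = (tp + tn) / max(tp + tn + fp + fn, 1L))
}

#' Evaluate a classifier on a labeled peak set
#'
#' @param model An `end_classifier`.
#' @param features An `rcat_features` matrix matching the model's contract.
#' @param labels Logical labels (or `label_peaks()` output) for the rows.
#' @return A one-row metrics tibble (see [classifier_metrics()]).
#' @export
evaluate_classifier <- function(model, features, labels) {
  if (is.data.frame(labels)) {
    labels <- labels$label[match(features$peak_id, labels$peak_id)]
  }
  pred <- predict(model, features, type = "class")
  classifier_metrics(labels, pred)
}

#' Evaluate a trained model on another dataset without refitting
#'
#' Cross-cell-type / cross-dataset transfer: the model trained on one
#' dataset scores another one, with the feature contract (column names and
#' groups) enforced; the new features must be assembled with the training
#' normalization.
#'
#' @inheritParams evaluate_classifier
#' @return A one-row metrics tibble.
#' @export
cross_dataset_transfer <- function(model, features, labels) {
  grp <- feature_groups(features)
  if (!is.null(grp) && !identical(grp, model$contract$groups)) {
    stop("feature groups do not match the model's feature contract")
  }
  evaluate_classifier(model, features, labels)
}

#' Feature-group ablation
#'
#' Retrains the classifier with one feature group removed at a time (same
#' protocol, split and folds) and reports the accuracy drop per group — the
#' contribution of that group to classification. The drop is measured on
#' the cross-validated accuracy of the selected hyperparameters
#' (fold-averaged over the training split), which is a much smoother
#' importance estimate than the 30% held-out set; the held-out accuracies
#' are reported alongside.
#'
#' @param features An `rcat_features` matrix.
#' @param labels Logical labels (or `label_peaks()` output).
#' @param protocol A [training_protocol()].
#' @param algorithm Which algorithm to ablate (default `"RF"`).
#' @param groups Feature groups to remove, default all groups present.
#' @return A tibble `group`, `cv_acc_full`, `cv_acc_without`, `drop`
#'   (cross-validated), plus held-out `acc_full`, `acc_without`.
#' @export
ablate_groups <- function(features, labels, protocol = training_protocol(),
                          algorithm = "RF", groups = NULL) {
  grp_map <- feature_groups(features)
  groups <- groups %||% unique(grp_map)
  proto <- training_protocol(protocol$train_fraction, protocol$cv_folds,
                             algorithms = algorithm, seed = protocol$seed)
  full <- train_end_classifiers(features, labels, proto)[[algorithm]]
  res <- map(groups, function(g) {
    keep <- names(grp_map)[grp_map != g]
    sub <- features[, c("peak_id", keep)]
    attr(sub, "groups") <- grp_map[keep]
    attr(sub, "normalization") <- feature_normalization(features)[keep]
    attr(sub, "end_type") <- attr(features, "end_type")
    m <- train_end_classifiers(sub, labels, proto)[[algorithm]]
    tibble(group = g,
           cv_acc_full = full$cv_acc, cv_acc_without = m$cv_acc,
           drop = full$cv_acc - m$cv_acc,
           acc_full = full$metrics$acc, acc_without = m$metrics$acc)
  })
  dplyr::bind_rows(res)
}

#' Filter a peak set with a trained end classifier
#'
#' Retains peaks predicted to be authentic ends, attaching the model's
#' TRUE-class probability where the algorithm provides one.
#'
#' @param model An `end_classifier`.
#' @param peaks The peak tibble the features were built from.
#' @param features The matching `rcat_features` matrix.
#' @return The retained subset of `peaks` with a `prob_true` column.
#' @export
filter_peaks <- function(model, peaks, features) {
  stopifnot(identical(peaks$peak_id, features$peak_id))
  keep <- predict(model, features, type = "class")
  prob <- predict(model, features, type = "prob")
  out <- peaks[keep, , drop = FALSE]
  out$prob_true <- prob[keep]
  out
}

#' @export
print.end_classifier <- function(x, ...) {
  cat("<end_classifier:", x$algorithm, "> ",
      paste(names(x$hyperparameters),
            unlist(x$hyperparameters), sep = "=", collapse = ", "), "\n")
  if (!is.null(x$metrics)) {
    cat("  test accuracy:", sprintf("%.3f", x$metrics$acc), "\n")
  }
  invisible(x)
}

#' @export
print.end_classifier_set <- function(x, ...) {
  cat("<end_classifier_set> algorithms:", paste(names(x), collapse = ", "), "\n")
  for (m in x) print(m)
  invisible(x)
}
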