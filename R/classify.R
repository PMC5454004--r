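# Screening classifiers and the cross-validation harness.
#
# One fitting function, fxs_fit(), covers the five learners of the
# screening framework (logistic regression, naive Bayes, AdaBoost, decision
# tree, random forest). Feature normalization (per-feature z-score from the
# TRAINING data) and optional information-gain feature selection happen
# inside the fit, so cross_validate() is leakage-free by construction:
# every fold refits normalization and selection on its own training part.
#
# Standard learners are delegated (stats::glm, e1071::naiveBayes,
# rpart, randomForest); discrete AdaBoost over depth-1 rpart stumps is
# implemented here.

fxs_algorithms <- c("logistic_regression", "naive_bayes", "adaboost",
                    "decision_tree", "random_forest")
fxs_algorithm_aliases <- c(lr = "logistic_regression", nb = "naive_bayes",
                           dt = "decision_tree", rf = "random_forest",
                           adaboost = "adaboost")

#' Classifier specification
#'
#' @param algorithm one of `"logistic_regression"`, `"naive_bayes"`,
#'   `"adaboost"`, `"decision_tree"`, `"random_forest"` (short aliases
#'   `lr`, `nb`, `dt`, `rf` are accepted).
#' @param hyperparameters named list; unspecified entries take the recorded
#'   defaults (random forest: 500 trees, `sqrt(p)` features per split;
#'   AdaBoost: 50 depth-1 stumps; decision tree: rpart with Gini impurity;
#'   logistic regression: `maxit = 50`).
#' @param seed integer seed recorded in all outputs.
#' @return `fxs_model_spec` list.
#' @export
model_spec <- function(algorithm = "random_forest", hyperparameters = list(),
                       seed = 1L) {
  if (algorithm %in% names(fxs_algorithm_aliases)) {
    algorithm <- unname(fxs_algorithm_aliases[algorithm])
  }
  if (!algorithm %in% fxs_algorithms) {
    stop("unknown algorithm: ", algorithm, " (expected one of ",
         paste(fxs_algorithms, collapse = ", "), ")")
  }
  defaults <- switch(algorithm,
    random_forest = list(ntree = 500L, mtry = NULL),
    adaboost = list(n_stumps = 50L),
    decision_tree = list(minsplit = 20L, cp = 0.01),
    logistic_regression = list(maxit = 50L),
    naive_bayes = list(laplace = 0))
  structure(list(algorithm = algorithm,
                 hyperparameters = modifyList(defaults, hyperparameters),
                 seed = as.integer(seed)),
            class = "fxs_model_spec")
}

as_binary_factor <- function(y, positive = NULL) {
  y <- as.character(y)
  lv <- sort(unique(y))
  if (length(lv) != 2L) stop("labels must contain exactly two classes")
  positive <- resolve_positive(y, positive)
  if (!positive %in% lv) stop("positive class '", positive, "' not in labels")
  factor(y, levels = c(setdiff(lv, positive), positive))
}

#' Fit a screening classifier
#'
#' The single fitting entry point of the package. Features are z-scored
#' with training statistics (stored in the fit and re-applied by
#' `predict()`); zero-variance features are dropped; with `select = TRUE`
#' an information-gain ranking ([rank_features()]) is computed on the
#' training data and only positive-gain features (the "optimized profile")
#' are kept — if no feature passes the MDL criterion the full set is
#' retained.
#'
#' @param x data frame or matrix of numeric features (samples in rows), or
#'   a formula.
#' @param y binary labels (ignored for the formula method).
#' @param spec an [model_spec()].
#' @param select run information-gain feature selection on the training
#'   data (default FALSE).
#' @param positive positive-class label (default `"carrier"` when present).
#' @param seed seed for stochastic learners (default from `spec`).
#' @param ids optional participant ids of the training samples, recorded so
#'   that [evaluate_independent()] can verify train/test disjointness.
#' @param ... passed on to methods.
#' @return `fxs_model` with `predict()`, `print()` and (for logistic
#'   regression) `coef()` methods.
#' @export
#' @examples
#' x <- data.frame(a = c(rnorm(20), rnorm(20, 3)), b = rnorm(40))
#' y <- rep(c("comparison", "carrier"), each = 20)
#' fit <- fxs_fit(x, y, model_spec("decision_tree"))
#' table(predict(fit, x, type = "class"), y)
fxs_fit <- function(x, ...) UseMethod("fxs_fit")

#' @rdname fxs_fit
#' @param data data frame holding the formula variables.
#' @export
fxs_fit.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  fxs_fit.default(mf[-1L], y, ...)
}

#' @rdname fxs_fit
#' @export
fxs_fit.default <- function(x, y, spec = model_spec("random_forest"),
                            select = FALSE, positive = NULL,
                            seed = spec$seed, ids = NULL, ...) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y))
  if (!all(vapply(x, is.numeric, logical(1)))) {
    stop("all features must be numeric")
  }
  y <- as_binary_factor(y, positive)
  positive <- levels(y)[2L]

  selection <- NULL
  features <- names(x)
  if (select) {
    selection <- rank_features(x, y)
    optimized <- attr(selection, "optimized")
    if (length(optimized)) features <- optimized
  }
  xs <- x[features]
  center <- vapply(xs, mean, numeric(1))
  scale_ <- vapply(xs, sd, numeric(1))
  keep <- !is.na(scale_) & scale_ > 0
  if (!any(keep)) stop("no feature with positive variance in the training data")
  features <- features[keep]
  center <- center[keep]
  scale_ <- scale_[keep]
  xn <- sweep(sweep(xs[features], 2, center), 2, scale_, `/`)

  set.seed(seed)
  hp <- spec$hyperparameters
  model <- switch(spec$algorithm,
    logistic_regression = {
      df <- cbind(xn, .y = y)
      suppressWarnings(glm(.y ~ ., data = df, family = binomial(),
                           control = list(maxit = hp$maxit)))
    },
    naive_bayes = e1071::naiveBayes(xn, y, laplace = hp$laplace),
    decision_tree = rpart::rpart(
      .y ~ ., data = cbind(xn, .y = y), method = "class",
      control = rpart::rpart.control(minsplit = hp$minsplit, cp = hp$cp,
                                     xval = 0)),
    random_forest = {
      mtry <- if (is.null(hp$mtry)) max(1L, floor(sqrt(ncol(xn)))) else hp$mtry
      randomForest::randomForest(xn, y, ntree = hp$ntree, mtry = mtry)
    },
    adaboost = fit_adaboost(xn, y, n_stumps = hp$n_stumps))

  structure(list(algorithm = spec$algorithm, spec = spec, model = model,
                 levels = levels(y), positive = positive,
                 features = features, center = center, scale = scale_,
                 selection = selection, ids = ids, seed = seed,
                 n = nrow(x)),
            class = "fxs_model")
}

# ---- discrete AdaBoost over depth-1 rpart stumps -------------------------

fit_adaboost <- function(x, y, n_stumps = 50L) {
  n <- nrow(x)
  ypm <- ifelse(y == levels(y)[2L], 1, -1)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = 1, minsplit = 2, cp = -1, xval = 0)
  df <- cbind(x, .y = y)
  for (m in seq_len(n_stumps)) {
    stump <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                          control = ctrl)
    pred <- ifelse(predict(stump, x, type = "class") == levels(y)[2L], 1, -1)
    err <- sum(w[pred != ypm])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- stump
    alphas <- c(alphas, alpha)
    if (err <= 1e-8) break
    w <- w * exp(-alpha * ypm * pred)
    w <- w / sum(w)
  }
  if (!length(stumps)) {
    # no stump beats chance: fall back to the weighted majority class
    prior <- sum(w[ypm == 1])
    return(structure(list(stumps = list(), alphas = numeric(0),
                          prior = prior, levels = levels(y)),
                     class = "fx_adaboost"))
  }
  structure(list(stumps = stumps, alphas = alphas, levels = levels(y)),
            class = "fx_adaboost")
}

predict_adaboost <- function(object, newdata) {
  if (!length(object$stumps)) {
    return(rep(object$prior, nrow(newdata)))
  }
  f <- rep(0, nrow(newdata))
  for (m in seq_along(object$stumps)) {
    pred <- ifelse(predict(object$stumps[[m]], newdata, type = "class") ==
                     object$levels[2L], 1, -1)
    f <- f + object$alphas[m] * pred
  }
  1 / (1 + exp(-2 * f))
}

# --------------------------------------------------------------------------

#' Predict from a fitted screening classifier
#'
#' @param object an `fxs_model`.
#' @param newdata data frame with (at least) the model's feature columns.
#' @param type `"prob"` for the positive-class (carrier) score in `[0, 1]`,
#'   `"class"` for thresholded labels (score >= 0.5).
#' @param ... unused.
#' @return numeric scores or a factor of predicted labels.
#' @export
predict.fxs_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing)) {
    stop("newdata is missing feature(s): ", paste(missing, collapse = ", "))
  }
  xn <- sweep(sweep(newdata[object$features], 2, object$center),
              2, object$scale, `/`)
  scores <- switch(object$algorithm,
    logistic_regression = suppressWarnings(
      unname(predict(object$model, xn, type = "response"))),
    naive_bayes = unname(predict(object$model, xn, type = "raw")[, object$positive]),
    decision_tree = unname(predict(object$model, xn, type = "prob")[, object$positive]),
    random_forest = unname(predict(object$model, xn, type = "prob")[, object$positive]),
    adaboost = predict_adaboost(object$model, xn))
  if (type == "prob") return(scores)
  factor(ifelse(scores >= 0.5, object$levels[2L], object$levels[1L]),
         levels = object$levels)
}

#' @export
print.fxs_model <- function(x, ...) {
  cat(sprintf("<fxs_model> %s on %d samples, %d feature(s)%s (positive class: %s, seed %d)\n",
              x$algorithm, x$n, length(x$features),
              if (!is.null(x$selection))
                sprintf(" [IG-selected from %d]", nrow(x$selection)) else "",
              x$positive, x$seed))
  invisible(x)
}

#' @export
coef.fxs_model <- function(object, ...) {
  if (object$algorithm != "logistic_regression") {
    stop("coef() is only defined for logistic regression fits")
  }
  stats::coef(object$model)
}

#' Stratified k-fold cross-validation of a screening classifier
#'
#' Samples are split into `k` stratified folds (sizes differ by at most
#' one; the class ratio of every fold is within one sample of the global
#' ratio). For each fold the classifier is fit on the other `k - 1` folds —
#' including normalization and, when `select = TRUE`, information-gain
#' feature selection, both computed on the training part only — and scored
#' on the held-out fold. Pooled out-of-fold scores give a single ROC curve
#' and pooled confusion counts give the summary metrics.
#'
#' @param x feature data frame (samples in rows).
#' @param y binary labels.
#' @param spec an [model_spec()].
#' @param k number of folds (default 10).
#' @param select run feature selection inside each training fold.
#' @param seed seed controlling fold assignment and the per-fold fits; the
#'   same seed reproduces the result exactly.
#' @param positive positive-class label.
#' @return `fxs_cv` list: `folds` (assignment), `scores` (pooled
#'   out-of-fold), `predictions`, `confusion`, `metrics` (incl. `auc`),
#'   `roc`, `per_fold` (confusions and selected features), `spec`, `seed`.
#' @export
cross_validate <- function(x, y, spec = model_spec("random_forest"),
                           k = 10L, select = TRUE, seed = 1L,
                           positive = NULL) {
  x <- as.data.frame(x)
  y <- as_binary_factor(y, positive)
  n <- nrow(x)
  stopifnot(n == length(y), n >= k, k >= 2L)
  counts <- table(y)
  if (min(counts) < k) {
    stop(sprintf("cannot stratify: class '%s' has %d samples for %d folds",
                 names(counts)[which.min(counts)], min(counts), k))
  }
  set.seed(seed)
  folds <- integer(n)
  ptr <- 0L
  for (cls in levels(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- ((seq_along(idx) - 1L + ptr) %% k) + 1L
    ptr <- (ptr + length(idx)) %% k
  }

  scores <- numeric(n)
  predictions <- character(n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- fxs_fit(x[!test, , drop = FALSE], y[!test], spec = spec,
                   select = select, positive = levels(y)[2L],
                   seed = spec$seed + f)
    scores[test] <- predict(fit, x[test, , drop = FALSE], type = "prob")
    predictions[test] <- as.character(predict(fit, x[test, , drop = FALSE],
                                              type = "class"))
    per_fold[[f]] <- list(
      confusion = confusion_from_predictions(y[test], predictions[test],
                                             positive = levels(y)[2L]),
      selected = fit$features)
  }
  confusion <- confusion_from_predictions(y, predictions,
                                          positive = levels(y)[2L])
  roc <- roc_auc(scores, y, positive = levels(y)[2L])
  metrics <- c(metrics_from_confusion(confusion), auc = roc$auc)
  structure(list(folds = folds, scores = scores,
                 predictions = factor(predictions, levels = levels(y)),
                 labels = y, confusion = confusion, metrics = metrics,
                 roc = roc, per_fold = per_fold, spec = spec, k = k,
                 select = select, seed = seed, positive = levels(y)[2L],
                 feature_names = names(x)),
            class = "fxs_cv")
}

#' @export
print.fxs_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<fxs_cv> %s, %d-fold (seed %d, selection %s), n = %d\n",
              x$spec$algorithm, x$k, x$seed, if (x$select) "on" else "off",
              length(x$folds)))
  cat(sprintf("  F1 = %.3f  AUC = %.3f  MCC = %.3f  acc = %.3f  sens = %.3f  spec = %.3f\n",
              m["f1"], m["auc"], m["mcc"], m["accuracy"], m["sensitivity"],
              m["specificity"]))
  invisible(x)
}

#' @export
summary.fxs_cv <- function(object, ...) {
  print(object)
  sel <- table(unlist(lapply(object$per_fold, `[[`, "selected")))
  sel <- sort(sel, decreasing = TRUE)
  cat("  features selected in most folds:\n")
  top <- head(sel, 10L)
  for (i in seq_along(top)) {
    cat(sprintf("    %-34s %d/%d folds\n", names(top)[i], top[[i]], object$k))
  }
  invisible(object)
}

#' @export
plot.fxs_cv <- function(x, ...) {
  plot(x$roc, main = sprintf("%s pooled out-of-fold ROC (AUC = %.3f)",
                             x$spec$algorithm, x$roc$auc), ...)
  invisible(x)
}

#' Evaluate a fitted classifier on an independent sample set
#'
#' @param object a fitted `fxs_model`.
#' @param newdata feature data frame of the held-out participants.
#' @param labels their true labels.
#' @param ids optional participant ids; when both these and the ids stored
#'   in the fit are available, any overlap is an error (the independent set
#'   must be disjoint from the training data).
#' @return `fxs_eval` list: `confusion`, `metrics` (incl. `auc`), `roc`,
#'   `scores`, `predictions`.
#' @export
evaluate_independent <- function(object, newdata, labels, ids = NULL) {
  stopifnot(inherits(object, "fxs_model"))
  if (!is.null(ids) && !is.null(object$ids)) {
    overlap <- intersect(ids, object$ids)
    if (length(overlap)) {
      stop("independent set overlaps the training data: ",
           paste(overlap, collapse = ", "))
    }
  }
  labels <- factor(as.character(labels), levels = object$levels)
  scores <- predict(object, newdata, type = "prob")
  predictions <- predict(object, newdata, type = "class")
  confusion <- confusion_from_predictions(labels, predictions,
                                          positive = object$positive)
  metrics <- metrics_from_confusion(confusion)
  roc <- if (length(unique(labels)) == 2L) {
    roc_auc(scores, labels, positive = object$positive)
  } else NULL
  if (!is.null(roc)) metrics <- c(metrics, auc = roc$auc)
  structure(list(confusion = confusion, metrics = metrics, roc = roc,
                 scores = scores, predictions = predictions, labels = labels,
                 algorithm = object$algorithm),
            class = "fxs_eval")
}

#' @export
print.fxs_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<fxs_eval> %s on independent set (n = %d)\n", x$algorithm,
              length(x$scores)))
  cat(sprintf("  F1 = %.3f  MCC = %.3f  sens = %.3f  spec = %.3f%s\n",
              m["f1"], m["mcc"], m["sensitivity"], m["specificity"],
              if ("auc" %in% names(m)) sprintf("  AUC = %.3f", m["auc"]) else ""))
  invisible(x)
}
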