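# Binary classifiers: SVM-RBF (primary) and tree-ensemble comparators.

#' Specify a classifier
#'
#' Hyperparameters are pinned to explicit numbers (not left to library
#' defaults, which drift across versions) and echoed into the trained
#' model's run log.  The SVM-RBF defaults are regularization constant
#' `cost = 1` and kernel width `gamma = 1 / (n_features * var(X))` — the
#' standard "scale" heuristic, with `var(X)` the variance of the pooled
#' training matrix entries.
#'
#' @param algorithm One of `"svm_rbf"`, `"random_forest"`,
#'   `"gradient_boosting"`, `"extreme_gradient_boosting"`.
#' @param seed Integer seed for the seedable algorithms.
#' @param ... Hyperparameter overrides (see Details in the run log).
#' @return A `model_spec`.
#' @export
model_spec <- function(algorithm = c("svm_rbf", "random_forest",
                                     "gradient_boosting",
                                     "extreme_gradient_boosting"),
                       seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    svm_rbf = list(cost = 1, gamma = "scale"),
    random_forest = list(ntree = 500L, mtry = NULL),
    gradient_boosting = list(nrounds = 100L, eta = 0.1, max_depth = 3L,
                             subsample = 1),
    extreme_gradient_boosting = list(nrounds = 100L, eta = 0.3,
                                     max_depth = 6L, subsample = 1))
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0L) {
    stop("unknown hyperparameter(s) for ", algorithm, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  defaults[names(overrides)] <- overrides
  structure(list(algorithm = algorithm, seed = as.integer(seed),
                 hyperparameters = defaults),
            class = "model_spec")
}

#' Train a binary classifier
#'
#' @param spec A `model_spec`.
#' @param x Numeric feature matrix (scaled/pruned training features).
#' @param y Binary 0/1 label vector; both classes must be present.
#' @return A `trained_model` exposing real-valued decision scores (larger
#'   means more likely binder) via [decision_scores()].  The model records
#'   its feature-name contract and refuses to score matrices whose columns
#'   differ from training.
#' @export
train_classifier <- function(spec, x, y) {
  stopifnot(inherits(spec, "model_spec"), is.matrix(x),
            nrow(x) == length(y))
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) < 2L) {
    stop("y must contain both classes coded 0/1", call. = FALSE)
  }
  hp <- spec$hyperparameters
  fit <- switch(spec$algorithm,
    svm_rbf = {
      gamma <- if (identical(hp$gamma, "scale")) {
        1 / (ncol(x) * stats::var(as.vector(x)))
      } else {
        hp$gamma
      }
      e1071::svm(x, factor(y, levels = c(0L, 1L)), type = "C-classification",
                 kernel = "radial", cost = hp$cost, gamma = gamma,
                 scale = FALSE)
    },
    random_forest = with_seed(spec$seed, {
      mtry <- if (is.null(hp$mtry)) floor(sqrt(ncol(x))) else hp$mtry
      randomForest::randomForest(x, factor(y, levels = c(0L, 1L)),
                                 ntree = hp$ntree, mtry = mtry)
    }),
    gradient_boosting = ,
    extreme_gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1L)
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       eta = hp$eta, max_depth = hp$max_depth,
                                       subsample = hp$subsample,
                                       nthread = 1L, seed = spec$seed),
                         data = dtrain, nrounds = hp$nrounds, verbose = 0)
    })
  score_type <- if (spec$algorithm == "svm_rbf") "decision" else "probability"
  model <- structure(list(spec = spec, fit = fit, features = colnames(x),
                          score_type = score_type, sign = 1,
                          threshold = if (score_type == "decision") 0 else 0.5,
                          run_log = list(algorithm = spec$algorithm,
                                         seed = spec$seed,
                                         hyperparameters = hp,
                                         n_train = nrow(x),
                                         n_features = ncol(x))),
                     class = "trained_model")
  if (score_type == "decision") {
    # e1071 orients decision values by factor-level order; pin the
    # orientation so larger score always means class 1
    sc <- .raw_scores(model, x)
    if (mean(sc[y == 1L]) < mean(sc[y == 0L])) model$sign <- -1
  }
  model
}

.check_contract <- function(model, x) {
  if (!is.matrix(x) || !identical(colnames(x), model$features)) {
    stop("feature matrix does not match the model's feature contract ",
         "(same names, same order required)", call. = FALSE)
  }
}

.raw_scores <- function(model, x) {
  switch(model$score_type,
    decision = {
      p <- stats::predict(model$fit, x, decision.values = TRUE)
      as.numeric(attr(p, "decision.values"))
    },
    probability = {
      if (inherits(model$fit, "randomForest")) {
        stats::predict(model$fit, x, type = "prob")[, "1"]
      } else {
        stats::predict(model$fit, x)
      }
    })
}

#' Decision scores of a trained model
#'
#' @param model A `trained_model`.
#' @param x Feature matrix matching the model's feature contract.
#' @return Numeric vector; larger values mean more likely binder.  For the
#'   SVM these are signed decision-function values; for the probabilistic
#'   comparators, class-1 probabilities.
#' @export
decision_scores <- function(model, x) {
  stopifnot(inherits(model, "trained_model"))
  .check_contract(model, x)
  model$sign * .raw_scores(model, x)
}

#' Predicted 0/1 labels
#'
#' @param model A `trained_model`.
#' @param x Feature matrix.
#' @param threshold Score threshold; defaults to the model's native one
#'   (0 for SVM decision values, 0.5 for probabilities).  A label of 1 is
#'   assigned when `score > threshold`.
#' @return Integer vector of 0/1 labels.
#' @export
predict_labels <- function(model, x, threshold = NULL) {
  if (is.null(threshold)) threshold <- model$threshold
  as.integer(decision_scores(model, x) > threshold)
}
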