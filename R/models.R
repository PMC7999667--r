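.family_defaults <- list(
  gradient_boosted_trees = list(learning_rate = 0.01, n_estimators = 1000L,
                                max_depth = 4L, min_child_weight = 1,
                                gamma = 0, subsample = 0.8),
  rbf_svm = list(C = 1.0, gamma = 0.001),
  random_forest = list(n_estimators = 80L, max_depth = 13L,
                       min_samples_split = 150L, min_samples_leaf = 15L,
                       max_features = 7L, oob_score = TRUE,
                       random_state = 10L),
  knn = list(K = 5L)
)

#' Classifier configuration
#'
#' Builds a configuration for one of the four supported classifier
#' families, with hyperparameter defaults fixed at the values established
#' for ACE-inhibitory peptide classification on 26-dimensional PseAAC
#' features:
#' \itemize{
#'   \item `gradient_boosted_trees`: learning_rate 0.01, n_estimators
#'     1000, max_depth 4, min_child_weight 1, gamma 0, subsample 0.8;
#'   \item `rbf_svm`: RBF kernel, C = 1.0, gamma = 0.001;
#'   \item `random_forest`: n_estimators 80, max_depth 13,
#'     min_samples_split 150, min_samples_leaf 15, max_features 7,
#'     oob_score TRUE, random_state 10;
#'   \item `knn`: K = 5 neighbours.
#' }
#' Overrides are applied on top of the defaults and recorded; unknown
#' hyperparameter names are rejected.
#'
#' @param family one of `"gradient_boosted_trees"`, `"rbf_svm"`,
#'   `"random_forest"`, `"knn"`.
#' @param overrides named list of hyperparameter overrides.
#' @param seed integer seed used by families with training randomness
#'   (boosted trees: subsampling; forest: bootstrap and feature draws);
#'   `NULL` falls back to a per-family default.
#' @return object of class `model_config`.
#' @export
model_config <- function(family = c("gradient_boosted_trees", "rbf_svm",
                                    "random_forest", "knn"),
                         overrides = list(), seed = NULL) {
  family <- match.arg(family)
  defaults <- .family_defaults[[family]]
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "), "; valid keys: ",
         paste(names(defaults), collapse = ", "))
  }
  hp <- utils::modifyList(defaults, overrides)
  structure(list(family = family, hyperparameters = hp,
                 overrides = overrides, seed = seed),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("Model config:", x$family, "\n")
  hp <- vapply(x$hyperparameters, function(v) paste(format(v), collapse = ","), "")
  cat(paste0("  ", names(hp), " = ", hp, collapse = "\n"), "\n")
  invisible(x)
}

#' Fit a classifier on a peptide feature matrix
#'
#' Trains the configured family on an `n x p` feature matrix (typically
#' 26-dimensional PseAAC features) with binary labels.  All families are
#' deterministic given the same data and seed.  The RBF SVM is followed by
#' Platt-style probability calibration (a logistic fit on the training
#' decision values) so that every family emits probabilities comparable
#' under the common 0.5 decision threshold.
#'
#' @param config a [model_config()].
#' @param features numeric matrix, one row per peptide.
#' @param labels integer/logical vector of 1 (positive) / 0 (negative).
#' @param seed optional seed overriding `config$seed` for this fit.
#' @return object of class `fitted_model` carrying the config, the
#'   feature dimension and a training fingerprint.
#' @export
fit_model <- function(config, features, labels, seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) stop("features/labels length mismatch")
  if (nrow(features) < 2L) stop("need at least 2 training instances")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L) {
    stop("training labels contain a single class")
  }
  if (config$family != "gradient_boosted_trees" && anyNA(features)) {
    stop("missing feature values are only supported by ",
         "gradient_boosted_trees")
  }
  hp <- config$hyperparameters
  eff_seed <- seed %||% config$seed %||%
    (if (config$family == "random_forest") hp$random_state else 1L)
  fit <- switch(
    config$family,
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(features, label = labels, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = hp$learning_rate, max_depth = hp$max_depth,
                      min_child_weight = hp$min_child_weight,
                      gamma = hp$gamma, subsample = hp$subsample,
                      nthread = 1, seed = eff_seed),
        data = dtrain, nrounds = hp$n_estimators, verbose = 0)
    },
    rbf_svm = {
      svm_fit <- e1071::svm(features, factor(labels, levels = c(0L, 1L)),
                            kernel = "radial", cost = hp$C,
                            gamma = hp$gamma, scale = FALSE)
      dvm <- attr(predict(svm_fit, features, decision.values = TRUE),
                  "decision.values")
      # libsvm labels the decision column "<first>/<second>"; a positive
      # value votes for <first>.  Flip so larger always means class 1.
      flip <- if (startsWith(colnames(dvm)[1L], "1")) 1 else -1
      platt <- suppressWarnings(
        stats::glm(y ~ dv, family = stats::binomial(),
                   data = data.frame(y = labels,
                                     dv = flip * as.numeric(dvm))))
      list(svm = svm_fit, platt = platt, flip = flip)
    },
    random_forest = {
      ranger::ranger(x = features, y = factor(labels, levels = c(0L, 1L)),
                     num.trees = hp$n_estimators, mtry = hp$max_features,
                     min.node.size = hp$min_samples_split,
                     min.bucket = hp$min_samples_leaf,
                     max.depth = hp$max_depth, probability = TRUE,
                     oob.error = isTRUE(hp$oob_score),
                     seed = eff_seed, num.threads = 1)
    },
    knn = list(x = features, y = labels, K = hp$K)
  )
  structure(list(config = config, family = config$family,
                 feature_dimension = ncol(features),
                 feature_names = colnames(features), seed = eff_seed,
                 fit = fit,
                 training_fingerprint = sprintf(
                   "n%d_p%d_ysum%d_xsum%.6g_seed%d", nrow(features),
                   ncol(features), sum(labels), sum(features), eff_seed)),
            class = "fitted_model")
}

#' Predicted probability of the positive class
#'
#' @param model a `fitted_model`.
#' @param features numeric matrix whose width matches the model's feature
#'   dimension.
#' @return numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "fitted_model"))
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (ncol(features) != model$feature_dimension) {
    stop("feature width ", ncol(features), " does not match model dimension ",
         model$feature_dimension)
  }
  colnames(features) <- model$feature_names
  p <- switch(
    model$family,
    gradient_boosted_trees = {
      predict(model$fit, xgboost::xgb.DMatrix(features, nthread = 1))
    },
    rbf_svm = {
      dv <- as.numeric(attr(predict(model$fit$svm, features,
                                    decision.values = TRUE),
                            "decision.values"))
      as.numeric(predict(model$fit$platt,
                         newdata = data.frame(dv = model$fit$flip * dv),
                         type = "response"))
    },
    random_forest = {
      predict(model$fit, data = features,
              num.threads = 1)$predictions[, "1"]
    },
    knn = {
      knn_positive_fraction(model$fit$x, model$fit$y, features, model$fit$K)
    })
  pmin(1, pmax(0, as.numeric(p)))
}

# k-NN positive-class probability: fraction of positive labels among the K
# nearest training rows (Euclidean distance); ties in distance are broken
# by training input order, which makes the prediction deterministic.
knn_positive_fraction <- function(train_x, train_y, query_x, K) {
  K <- min(K, nrow(train_x))
  apply(query_x, 1L, function(q) {
    d <- sqrt(colSums((t(train_x) - q)^2))
    nn <- order(d)[seq_len(K)]  # order() is stable: ties keep input order
    mean(train_y[nn])
  })
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("Fitted", x$family, "model on", x$feature_dimension, "features",
      sprintf("(fingerprint %s)\n", x$training_fingerprint))
  invisible(x)
}
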