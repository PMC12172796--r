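# Pinned hyperparameter tables. "Default settings" are frozen here so results
# do not drift with library upgrades; lasso gets the raised iteration cap.
.DEFAULT_HYPERPARAMETERS <- list(
  linear = list(),
  lasso = list(nfolds = 5, nlambda = 100, maxit = 1e5, standardize = TRUE,
               lambda = NULL),
  svm = list(kernel = "radial", cost = 1, epsilon = 0.1, gamma = NULL,
             scale = TRUE),
  xgboost = list(nrounds = 100, eta = 0.3, max_depth = 6, subsample = 1,
                 colsample_bytree = 1, min_child_weight = 1, nthread = 1)
)

#' Specify an age-prediction model
#'
#' One uniform fit/predict contract over the model suite. Hyperparameters are
#' pinned to the tables in the package (library defaults, except the lasso
#' iteration cap of 100,000) and are immutable after construction.
#'
#' @param algorithm One of "linear", "lasso", "svm", "xgboost".
#' @param seed Integer seed controlling any internal randomness (lasso CV
#'   folds, boosting subsampling).
#' @param ... Named hyperparameter overrides (must name entries of the pinned
#'   table; e.g. `lambda = 1e9` forces a fully shrunk lasso).
#' @return A `model_spec` object.
#' @export
model_spec <- function(algorithm = c("linear", "lasso", "svm", "xgboost"),
                       seed = 1L, ...) {
  algorithm <- tryCatch(match.arg(algorithm),
                        error = function(e)
                          stop("unsupported algorithm: ",
                               paste(algorithm, collapse = "/"),
                               " (available: linear, lasso, svm, xgboost)",
                               call. = FALSE))
  hp <- .DEFAULT_HYPERPARAMETERS[[algorithm]]
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(hp))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown hyperparameter(s) for ", algorithm, ": ",
           paste(bad, collapse = ", "))
    hp[names(dots)] <- dots
  }
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Fit an age-prediction model
#'
#' Deterministic given `spec$seed`. Plain linear regression is ordinary least
#' squares on the raw features (OLS is scale-equivariant, so no
#' standardization); lasso and SVM standardize internally (training-side
#' parameters are stored in the fit and reused at prediction time); the lasso
#' penalty is chosen by 5-fold internal cross-validation over glmnet's default
#' logarithmic lambda path.
#'
#' @param spec A [model_spec()].
#' @param X Numeric feature matrix (no missing values), columns named.
#' @param y Numeric age vector, `length(y) == nrow(X)`.
#' @return A `fitted_model` holding the learned parameters and the training
#'   feature-column order (predictions refuse matrices in any other order).
#' @export
fit_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  hp <- spec$hyperparameters
  set.seed(spec$seed)
  fit <- switch(spec$algorithm,
    linear = {
      if (nrow(X) < ncol(X) + 1)
        stop("linear regression needs n >= p + 1 (got n = ", nrow(X),
             ", p = ", ncol(X), ")")
      qx <- qr(cbind(`(Intercept)` = 1, X))
      if (qx$rank < ncol(X) + 1) {
        dropped <- setdiff(colnames(X),
                           colnames(qx$qr)[qx$pivot[seq_len(qx$rank)]])
        stop("rank-deficient design; offending column(s): ",
             paste(dropped, collapse = ", "))
      }
      list(coef = qr.coef(qx, y))
    },
    lasso = {
      foldid <- sample(rep_len(seq_len(hp$nfolds), nrow(X)))
      if (!is.null(hp$lambda)) {
        list(fit = glmnet::glmnet(X, y, alpha = 1, lambda = hp$lambda,
                                  maxit = hp$maxit,
                                  standardize = hp$standardize),
             lambda = hp$lambda)
      } else {
        cv <- glmnet::cv.glmnet(X, y, alpha = 1, foldid = foldid,
                                nlambda = hp$nlambda, maxit = hp$maxit,
                                standardize = hp$standardize)
        list(fit = cv$glmnet.fit, lambda = cv$lambda.min)
      }
    },
    svm = {
      gamma <- hp$gamma %||% (1 / ncol(X))
      list(fit = e1071::svm(X, y, type = "eps-regression",
                            kernel = hp$kernel, cost = hp$cost,
                            epsilon = hp$epsilon, gamma = gamma,
                            scale = hp$scale))
    },
    xgboost = {
      dm <- xgboost::xgb.DMatrix(X, label = y, nthread = hp$nthread)
      list(fit = xgboost::xgb.train(
        params = list(objective = "reg:squarederror", eta = hp$eta,
                      max_depth = hp$max_depth, subsample = hp$subsample,
                      colsample_bytree = hp$colsample_bytree,
                      min_child_weight = hp$min_child_weight,
                      nthread = hp$nthread, seed = spec$seed),
        data = dm, nrounds = hp$nrounds, verbose = 0))
    })
  structure(list(spec = spec, fit = fit, feature_names = colnames(X),
                 n_train = nrow(X)),
            class = "fitted_model")
}

#' Predict ages from a fitted model
#'
#' @param model A `fitted_model`.
#' @param X Feature matrix whose columns match the training order exactly.
#' @return Numeric vector of predicted ages, one per row of `X`.
#' @export
predict_ages <- function(model, X) {
  stopifnot(inherits(model, "fitted_model"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (!identical(colnames(X), model$feature_names))
    stop("feature columns do not match the training order")
  if (anyNA(X)) stop("missing values are not allowed")
  out <- switch(model$spec$algorithm,
    linear = as.numeric(cbind(1, X) %*% model$fit$coef),
    lasso = as.numeric(stats::predict(model$fit$fit, newx = X,
                                      s = model$fit$lambda)),
    svm = as.numeric(stats::predict(model$fit$fit, X)),
    xgboost = as.numeric(stats::predict(
      model$fit$fit,
      xgboost::xgb.DMatrix(X,
        nthread = model$spec$hyperparameters$nthread))))
  if (!all(is.finite(out))) stop("non-finite predictions")
  out
}

#' Save / load a fitted model
#'
#' Self-describing single-file serialization: spec (algorithm,
#' hyperparameters, seed), training column order and learned parameters.
#'
#' @param model A `fitted_model`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fitted_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "fitted_model")) stop("not a saved fitted_model")
  model
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$algorithm, "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("fitted_model:", x$spec$algorithm, "on", length(x$feature_names),
      "features,", x$n_train, "training rows\n")
  invisible(x)
}
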