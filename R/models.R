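#' Specify a supervised model
#'
#' Captures the classifier kind, hyperparameters and seed so that training
#' is fully reproducible. Supported kinds and their hyperparameters:
#' \describe{
#'   \item{LR}{L2-regularized (ridge) logistic regression via
#'     \pkg{glmnet}: `lambda` (regularization strength, default `1e-3`),
#'     `maxit` (iteration cap, default `1e5`). Features are assumed
#'     Z-scored, so glmnet's internal standardization is off.}
#'   \item{RF}{Random forest via \pkg{randomForest}: `ntree` (default 500),
#'     `maxnodes` (tree size cap, default `NULL` = unlimited).}
#'   \item{SVM}{Support vector machine with polynomial kernel
#'     `(gamma * <x,y> + bias)^power` via \pkg{e1071}: `power` (default 3),
#'     `bias` (coef0, default 1), `gamma` (default `1/ncol`), `cost`
#'     (default 1).}
#' }
#'
#' @param kind One of `"LR"`, `"RF"`, `"SVM"`.
#' @param ... Hyperparameters overriding the defaults above.
#' @param seed Integer seed used during training (default 1).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("LR", "RF", "SVM"), ..., seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    LR  = list(lambda = 1e-3, maxit = 1e5),
    RF  = list(ntree = 500L, maxnodes = NULL),
    SVM = list(power = 3, bias = 1, gamma = NULL, cost = 1)
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown hyperparameter(s) for ", kind, ": ",
         paste(unknown, collapse = ", "))
  }
  defaults[names(override)] <- override
  structure(list(kind = kind, params = defaults, seed = as.integer(seed)),
            class = "model_spec")
}

# Levels are fixed U < S so confusion matrices always come out in the
# (U, S) order of the report tables.
as_class_factor <- function(labels) {
  factor(as.character(labels), levels = c("U", "S"))
}

#' Train a classifier
#'
#' @param spec A [model_spec()].
#' @param features Numeric matrix (rows = positions, columns = features),
#'   already normalized.
#' @param labels Class label per row (`"U"`/`"S"`); both classes must be
#'   present.
#' @return A fitted model of class `su_model`; pass to [predict()].
#' @export
train_model <- function(spec, features, labels) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(features)
  y <- as_class_factor(labels)
  if (anyNA(y)) stop("labels must be 'U' or 'S'")
  if (nlevels(droplevels(y)) < 2L) {
    stop("training labels contain a single class")
  }
  fit <- with_seed(spec$seed, switch(spec$kind,
    LR = {
      # glmnet needs >= 2 columns; pad single-feature fits with a zero
      # dummy whose coefficient is structurally 0
      xx <- if (ncol(x) == 1L) cbind(x, .dummy = 0) else x
      glmnet::glmnet(xx, y, family = "binomial", alpha = 0,
                     lambda = spec$params$lambda,
                     maxit = spec$params$maxit, standardize = FALSE)
    },
    RF = randomForest::randomForest(
      x, y, ntree = spec$params$ntree,
      maxnodes = spec$params$maxnodes),
    SVM = {
      gamma <- if (is.null(spec$params$gamma)) 1 / ncol(x) else
        spec$params$gamma
      e1071::svm(x, y, kernel = "polynomial",
                 degree = spec$params$power, coef0 = spec$params$bias,
                 gamma = gamma, cost = spec$params$cost, scale = FALSE)
    }
  ))
  structure(list(spec = spec, fit = fit, feature_ids = colnames(x)),
            class = "su_model")
}

#' Predict classes with a fitted model
#'
#' @param object A `su_model` from [train_model()].
#' @param newdata Numeric matrix with the training feature columns.
#' @param ... Unused.
#' @return Factor of predicted classes with levels `U`, `S`.
#' @export
predict.su_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, object$feature_ids, drop = FALSE]
  out <- switch(object$spec$kind,
    LR = {
      xx <- if (ncol(x) == 1L) cbind(x, .dummy = 0) else x
      p <- stats::predict(object$fit, newx = xx, type = "class",
                          s = object$spec$params$lambda)
      factor(drop(p), levels = c("U", "S"))
    },
    RF = stats::predict(object$fit, x),
    SVM = stats::predict(object$fit, x)
  )
  factor(as.character(out), levels = c("U", "S"))
}

#' @export
print.su_model <- function(x, ...) {
  cat("Fitted ", x$spec$kind, " model on ", length(x$feature_ids),
      " features (seed ", x$spec$seed, ")\n", sep = "")
  invisible(x)
}
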