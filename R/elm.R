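#' Extreme learning machine classifier
#'
#' Fits a single-hidden-layer feedforward network in which the input
#' weights and biases are drawn at random and fixed, and only the
#' output weights are learned — in closed form, as the minimum-norm
#' least-squares (Moore-Penrose pseudoinverse) solution
#' `beta = pinv(H) %*% y`, where `H[i, j] = g(w_j . x_i + b_j)` is the
#' hidden-layer output matrix with sigmoid activation
#' `g(u) = 1 / (1 + exp(-u))`. With at least as many hidden neurons as
#' distinct training samples the network can interpolate the training
#' targets to arbitrary precision.
#'
#' Class labels follow the EHG convention: 1 = pregnancy, 2 = labour.
#' The single output neuron regresses the numeric label; predicted
#' scores are thresholded at the midpoint 1.5 (ties go to class 2).
#'
#' @param x Numeric feature matrix (samples x features), or a formula.
#' @param y Numeric/integer label vector in `{1, 2}`; both classes must
#'   be present.
#' @param n_hidden Number of hidden neurons `L` (default 20).
#' @param seed Integer seed for the random input weights
#'   (`Uniform(-1, 1)`) and biases (`Uniform(0, 1)`); the fit is fully
#'   reproducible given `(x, y, n_hidden, seed)`. `NULL` uses the
#'   current RNG stream.
#' @param rcond Singular-value cutoff (relative to the largest) for the
#'   pseudoinverse.
#' @param ... Passed between methods.
#' @return An object of class `elm` with components `input_weights`
#'   (`L x d`), `biases` (`L`), `beta` (`L x 1`), `n_hidden`, `seed`,
#'   `activation`, `fitted.values` (training scores), `y`, and
#'   `feature_names`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 2), 20))
#' y <- rep(c(1, 2), each = 20)
#' fit <- elm(x, y, n_hidden = 20, seed = 7)
#' fit
#' mean(predict(fit, x) == y)
#' @export
elm <- function(x, ...) UseMethod("elm")

#' @rdname elm
#' @param data Data frame holding the variables of the formula.
#' @export
elm.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  fit <- elm.default(X, y, ...)
  fit$call <- match.call()
  fit$terms <- attr(mf, "terms")
  fit
}

#' @rdname elm
#' @export
elm.default <- function(x, y, n_hidden = 20L, seed = NULL, rcond = 1e-12, ...) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stopf("`x` must be a numeric matrix")
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stopf("nrow(x) != length(y)")
  if (nrow(x) < 2L) stopf("need at least 2 training samples")
  if (!all(y %in% c(1, 2))) stopf("labels must be 1 (pregnancy) or 2 (labour)")
  if (length(unique(y)) < 2L) stopf("both classes must be present in `y`")
  n_hidden <- as.integer(n_hidden)
  if (n_hidden < 1L) stopf("`n_hidden` must be >= 1")
  d <- ncol(x)
  w <- with_seed(seed, {
    list(W = matrix(stats::runif(n_hidden * d, -1, 1), nrow = n_hidden),
         b = stats::runif(n_hidden, 0, 1))
  })
  model <- structure(list(input_weights = w$W, biases = w$b, beta = NULL,
                          n_hidden = n_hidden, seed = seed,
                          activation = "sigmoid", rcond = rcond,
                          feature_names = colnames(x),
                          call = match.call()),
                     class = "elm")
  H <- hidden_matrix(x, model)
  model$beta <- pinv_solve(H, y, rcond)
  model$fitted.values <- drop(H %*% model$beta)
  model$y <- y
  model
}

#' Hidden-layer output matrix
#'
#' Evaluates `H[i, j] = g(w_j . x_i + b_j)` for the fixed random hidden
#' layer of an ELM; `g` is the logistic sigmoid, so entries lie in
#' (0, 1).
#'
#' @param x Numeric matrix, samples x features.
#' @param model An [elm()] model (only its hidden layer is used).
#' @return Numeric matrix, samples x `n_hidden`.
#' @export
hidden_matrix <- function(x, model) {
  stopifnot(inherits(model, "elm"))
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$input_weights)) {
    stopf("feature dimension mismatch: x has %d columns, model expects %d",
          ncol(x), ncol(model$input_weights))
  }
  u <- x %*% t(model$input_weights)
  u <- sweep(u, 2L, model$biases, "+")
  1 / (1 + exp(-u))
}

# Minimum-norm least-squares via SVD with relative singular-value cutoff.
pinv_solve <- function(H, y, rcond = 1e-12) {
  s <- svd(H)
  keep <- s$d > rcond * max(s$d)
  dinv <- ifelse(keep, 1 / s$d, 0)
  s$v %*% (dinv * crossprod(s$u, y))
}

#' Predict method for ELM models
#'
#' @param object An [elm()] model.
#' @param newdata Numeric matrix or data frame of features.
#' @param type `"class"` (default) for labels in `{1, 2}`, `"score"`
#'   for the raw network output (used by [roc_curve()]).
#' @param ... Unused.
#' @return Numeric vector of labels or scores. A score of exactly 1.5
#'   is assigned to class 2.
#' @export
predict.elm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (!is.null(object$terms) && is.data.frame(newdata)) {
    X <- stats::model.matrix(stats::delete.response(object$terms), newdata)
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  } else {
    X <- as.matrix(newdata)
  }
  scores <- unname(drop(hidden_matrix(X, object) %*% object$beta))
  if (type == "score") return(scores)
  ifelse(scores < 1.5, 1, 2)
}

#' @export
coef.elm <- function(object, ...) drop(object$beta)

#' @export
fitted.elm <- function(object, ...) object$fitted.values

#' @export
residuals.elm <- function(object, ...) object$y - object$fitted.values

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("<elm> %d hidden neurons (%s), %d features%s\n",
              x$n_hidden, x$activation, ncol(x$input_weights),
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  cat(sprintf("training RMSE: %.4g\n",
              sqrt(mean((x$y - x$fitted.values)^2))))
  invisible(x)
}

#' @export
summary.elm <- function(object, ...) {
  pred <- ifelse(object$fitted.values < 1.5, 1, 2)
  cm <- confusion(object$y, pred)
  out <- list(model = object, train_confusion = cm,
              train_metrics = classification_metrics(cm),
              train_rmse = sqrt(mean((object$y - object$fitted.values)^2)))
  class(out) <- "summary.elm"
  out
}

#' @export
print.summary.elm <- function(x, ...) {
  print(x$model)
  cat("training confusion:\n")
  print(x$train_confusion)
  m <- x$train_metrics
  cat(sprintf("sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%\n",
              m["sensitivity"], m["specificity"], m["accuracy"]))
  invisible(x)
}

#' Serialize / restore an ELM model as JSON
#'
#' @param model An [elm()] model.
#' @param path Destination / source path.
#' @return `path` (write) or an `elm` object (read).
#' @export
write_elm <- function(model, path) {
  stopifnot(inherits(model, "elm"))
  jsonlite::write_json(
    list(input_weights = model$input_weights, biases = model$biases,
         beta = drop(model$beta), n_hidden = model$n_hidden,
         seed = model$seed, activation = model$activation,
         feature_names = model$feature_names),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_elm
#' @export
read_elm <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  iw <- m$input_weights
  if (!is.matrix(iw)) iw <- matrix(iw, nrow = m$n_hidden)
  structure(list(input_weights = iw,
                 biases = m$biases, beta = matrix(m$beta, ncol = 1),
                 n_hidden = m$n_hidden, seed = m$seed,
                 activation = m$activation,
                 feature_names = m$feature_names),
            class = "elm")
}
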