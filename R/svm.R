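#' Train a linear two-class soft-margin SVM
#'
#' Solves the standard primal problem
#' \deqn{\min_{w,b} \tfrac{1}{2}\|w\|^2 + C \sum_i \max(0,\, 1 - y_i (w \cdot x_i + b))}
#' through its dual with a sequential-minimal-optimization solver
#' (maximal-violating-pair selection). No internal rescaling of `X` is
#' performed: the pipeline standardises features upstream, on training data
#' only, and a classifier that silently rescaled would leak that choice.
#'
#' @param X numeric `n x P` matrix.
#' @param y labels: either a numeric +1/-1 vector or a character/factor
#'   vector with exactly two levels (see `positive`).
#' @param cost positive soft-margin cost parameter `C`.
#' @param positive when `y` is character/factor, the label mapped to +1;
#'   defaults to the first label encountered.
#' @param tolerance dual KKT-violation stopping tolerance.
#' @param max_iter iteration cap for the solver.
#' @return An object of class `linear_svm`: `w` (named if `X` has column
#'   names), `b`, `cost`, `class_map` (labels of the +1 and -1 classes) and
#'   the solver iteration count. The decision function is
#'   `decision(x) = w . x + b`.
#' @export
svm_train <- function(X, y, cost = 1, positive = NULL,
                      tolerance = 1e-6, max_iter = 1000000L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || !all(is.finite(X))) stop("X contains NA or non-finite values")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (cost <= 0) stop("cost must be positive")

  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) stop("numeric y must contain only +1 and -1")
    ys <- as.numeric(y)
    class_map <- c(positive = "1", negative = "-1")
  } else {
    y <- as.character(y)
    if (is.null(positive)) positive <- y[1L]
    lev <- unique(y)
    if (length(lev) != 2L) stop("y must contain exactly two classes")
    if (!positive %in% lev) stop("positive label not present in y")
    ys <- ifelse(y == positive, 1, -1)
    class_map <- c(positive = positive, negative = setdiff(lev, positive))
  }
  if (length(unique(ys)) < 2L) stop("both classes must be present in y")

  fit <- .svm_train_cpp(X, ys, cost, tolerance, as.integer(max_iter))
  w <- drop(fit$w)
  names(w) <- colnames(X)
  structure(list(w = w, b = fit$b, cost = cost, class_map = class_map,
                 iterations = fit$iterations),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("linear_svm: %d features, cost C=%g, |w|=%.4g, b=%.4g\n",
              length(x$w), x$cost, sqrt(sum(x$w^2)), x$b))
  cat(sprintf("  classes: +1=%s, -1=%s\n",
              x$class_map[["positive"]], x$class_map[["negative"]]))
  invisible(x)
}

#' Decision values of a linear SVM
#'
#' @param model a [svm_train()] fit.
#' @param X numeric matrix (or single row) with the model's feature count.
#' @return numeric vector `X %*% w + b`.
#' @export
decision_values <- function(model, X) {
  stopifnot(inherits(model, "linear_svm"))
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(X) != length(model$w)) {
    stop("shape error: model has ", length(model$w),
         " features but X has ", ncol(X))
  }
  drop(X %*% model$w + model$b)
}

#' Predict class labels with a linear SVM
#'
#' A decision value of exactly 0 is mapped to the positive class (fixed,
#' documented tie rule, so predictions are deterministic).
#'
#' @param object a [svm_train()] fit.
#' @param X feature matrix.
#' @param ... unused.
#' @return character vector of predicted labels (or "1"/"-1" when the model
#'   was trained on numeric labels).
#' @export
predict.linear_svm <- function(object, X, ...) {
  d <- decision_values(object, X)
  ifelse(d >= 0, object$class_map[["positive"]], object$class_map[["negative"]])
}

#' Rank features by absolute hyperplane coefficient
#'
#' The relevance of feature `j` is `|w_j|`: features with small absolute
#' hyperplane coefficients contribute least to the decision function and are
#' eliminated first.
#'
#' @param model a [svm_train()] fit.
#' @return integer permutation of `1..P` ordering the features from least to
#'   most relevant; ties are broken by ascending feature index.
#' @export
rank_features <- function(model) {
  stopifnot(inherits(model, "linear_svm"))
  order(abs(model$w), seq_along(model$w), method = "radix")
}

#' Primal objective of a linear SVM fit
#'
#' `0.5 * ||w||^2 + C * sum(hinge losses)`; mainly useful for verifying the
#' solver against an independent quadratic-programming solution.
#'
#' @param model a [svm_train()] fit.
#' @param X,y the training data the model was fitted on (`y` as +1/-1).
#' @return the primal objective value.
#' @export
svm_objective <- function(model, X, y) {
  d <- decision_values(model, X)
  0.5 * sum(model$w^2) + model$cost * sum(pmax(0, 1 - y * d))
}
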