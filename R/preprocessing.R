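#' Fit per-feature age/sex covariate models on training data
#'
#' For every feature (region), fits ordinary least squares of the feature on
#' an intercept, age and sex. The corrected data used downstream are the
#' residuals of these regressions, so training residuals are exactly
#' uncorrelated with age and sex. The model is fitted on training subjects
#' only and later applied unchanged to held-out subjects via
#' [residualize()].
#'
#' A rank-deficient design (for instance constant age and constant sex) is
#' handled by the minimum-norm least-squares solution, with a warning.
#'
#' @param X numeric `n x P` training matrix.
#' @param age numeric length-`n` vector, years.
#' @param sex numeric length-`n` 0/1 vector.
#' @return An object of class `covariate_model`: a `3 x P` coefficient
#'   matrix (rows intercept, age, sex).
#' @export
fit_covariate_model <- function(X, age, sex) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(age) != n || length(sex) != n) {
    stop("age and sex must have one entry per row of X")
  }
  D <- cbind(intercept = rep(1, n), age = as.numeric(age), sex = as.numeric(sex))
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("rank-deficient covariate design (rank ", qrD$rank,
            " of 3); using the minimum-norm least-squares solution")
    coef <- MASS::ginv(D) %*% X
  } else {
    coef <- qr.coef(qrD, X)
  }
  dimnames(coef) <- list(c("intercept", "age", "sex"), colnames(X))
  structure(list(coef = coef), class = "covariate_model")
}

#' Remove fitted covariate effects from a data matrix
#'
#' Subtracts the values predicted by a fitted [fit_covariate_model()] from
#' `X`. The model is never refitted here: applying a training-fold model to
#' a held-out subject uses the training coefficients unchanged, which is
#' what keeps the nested cross-validation leak-free.
#'
#' @param model a `covariate_model`.
#' @param X numeric `m x P` matrix (any `m`, including a single subject).
#' @param age,sex covariates of the `m` rows.
#' @return `m x P` matrix of residuals.
#' @export
residualize <- function(model, X, age, sex) {
  stopifnot(inherits(model, "covariate_model"))
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(X) != ncol(model$coef)) {
    stop("shape error: model has ", ncol(model$coef),
         " features but X has ", ncol(X))
  }
  D <- cbind(rep(1, nrow(X)), as.numeric(age), as.numeric(sex))
  X - D %*% model$coef
}

#' Fit a per-feature standardizer on training data
#'
#' Computes per-feature mean and sample standard deviation (n - 1
#' denominator). Features whose sd falls below `tol` are flagged degenerate;
#' [apply_scaler()] maps them to zero rather than dropping them, so feature
#' indexing stays aligned across folds.
#'
#' @param X numeric `n x P` training matrix, `n >= 2`.
#' @param tol degeneracy threshold on the sd.
#' @return An object of class `scaler` with `center`, `scale` and the
#'   logical `degenerate` flag per feature.
#' @export
fit_scaler <- function(X, tol = 1e-10) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("at least 2 training rows required")
  center <- colMeans(X)
  scale <- apply(X, 2L, sd)
  degenerate <- !is.finite(scale) | scale < tol
  structure(list(center = center, scale = scale, degenerate = degenerate),
            class = "scaler")
}

#' Apply a fitted standardizer
#'
#' @param scaler a [fit_scaler()] object (fitted on training data).
#' @param X numeric `m x P` matrix.
#' @return `m x P` matrix: `(X - center) / scale` per feature; degenerate
#'   features are mapped to all zeros.
#' @export
apply_scaler <- function(scaler, X) {
  stopifnot(inherits(scaler, "scaler"))
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(X) != length(scaler$center)) {
    stop("shape error: scaler has ", length(scaler$center),
         " features but X has ", ncol(X))
  }
  s <- ifelse(scaler$degenerate, 1, scaler$scale)
  Z <- sweep(sweep(X, 2L, scaler$center, "-"), 2L, s, "/")
  if (any(scaler$degenerate)) Z[, scaler$degenerate] <- 0
  Z
}
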