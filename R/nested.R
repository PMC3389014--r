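#' Inner leave-one-out accuracy curve under feature elimination
#'
#' For every inner fold, one subject is held out of the (already
#' covariate-corrected and standardised) training data; the SVM is trained
#' on the rest with all features, the features are ranked once by absolute
#' hyperplane coefficient, and the least-relevant feature is then removed
#' one at a time — retraining and predicting the held-out subject at every
#' feature count from `P - 1` down to 1. Accuracies are pooled over folds
#' (total correct / total predictions) at each count, and the chosen feature
#' count `Q` maximises that pooled accuracy. Pooled accuracy has resolution
#' `1/n`, so ties across counts are common; `q_tie` picks among the
#' maximisers (default: the largest count, i.e. keep every feature whose
#' removal does not improve inner accuracy).
#'
#' By default the ranking is computed once per inner fold from the
#' full-feature model and elimination follows that fixed ranking; with
#' `rerank = TRUE` the ranking is recomputed from the current model after
#' every elimination (classic recursive feature elimination).
#'
#' @param X numeric `n x P` matrix, `P >= 2`, already corrected/normalised.
#' @param y +1/-1 numeric labels (or character/factor, see `positive`).
#' @param cost SVM cost parameter `C`.
#' @param rerank recompute the ranking after each elimination?
#' @param include_full also score the full-feature count `P` and allow `Q = P`?
#' @param q_tie tie rule among accuracy-maximising counts: `"max"` (largest
#'   count, the default) or `"min"` (most parsimonious count).
#' @param positive label mapped to +1 when `y` is not numeric.
#' @param tolerance,max_iter solver controls, see [svm_train()].
#' @return An object of class `inner_curve`: `feature_counts` (descending),
#'   `accuracy` (one value per count, same order), `chosen_q`, and
#'   `n_folds_used` (folds whose training subset retained both classes;
#'   others are excluded with a warning).
#' @export
inner_accuracy_curve <- function(X, y, cost = 1, rerank = FALSE,
                                 include_full = FALSE,
                                 q_tie = c("max", "min"), positive = NULL,
                                 tolerance = 1e-6, max_iter = 1000000L) {
  q_tie <- match.arg(q_tie)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  P <- ncol(X)
  if (P < 2L) stop("at least 2 features required")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (!is.numeric(y)) {
    y <- as.character(y)
    if (is.null(positive)) positive <- y[1L]
    y <- ifelse(y == positive, 1, -1)
  }
  if (!all(y %in% c(-1, 1))) stop("labels must reduce to +1/-1")

  correct <- numeric(P - 1L)          # index c = feature count c
  correct_full <- 0
  used <- 0L
  skipped <- 0L
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      skipped <- skipped + 1L
      next
    }
    path <- .rfe_path_cpp(X[-i, , drop = FALSE], ytr, X[i, ],
                          cost, tolerance, as.integer(max_iter), rerank)
    correct <- correct + (path$preds == y[i])
    correct_full <- correct_full + (path$pred_full == y[i])
    used <- used + 1L
  }
  if (skipped > 0L) {
    warning(skipped, " inner fold(s) excluded: training subset lost a class")
  }
  if (used == 0L) stop("no valid inner folds (a class has too few subjects)")

  counts <- (P - 1L):1L
  acc <- correct[counts] / used
  if (include_full) {
    counts <- c(P, counts)
    acc <- c(correct_full / used, acc)
  }
  best <- max(acc)
  maxima <- counts[acc >= best]
  chosen_q <- if (q_tie == "min") min(maxima) else max(maxima)
  structure(list(feature_counts = counts, accuracy = acc,
                 chosen_q = chosen_q, n_folds_used = used),
            class = "inner_curve")
}

#' @export
print.inner_curve <- function(x, ...) {
  cat(sprintf("inner_curve: %d folds, counts %d..%d, best accuracy %.3f at Q=%d\n",
              x$n_folds_used, max(x$feature_counts), min(x$feature_counts),
              max(x$accuracy), x$chosen_q))
  invisible(x)
}

#' Nested leave-one-subject-out SVM feature-elimination classification
#'
#' The full two-level procedure. For every outer fold one subject is held
#' out; on the remaining training subjects the pipeline (a) regresses age
#' and sex out of every feature and standardises the residuals, with
#' parameters fitted on the training fold only; (b) runs the inner
#' leave-one-out elimination loop ([inner_accuracy_curve()]) to choose the
#' feature count `Q`; (c) trains on all features, ranks them by absolute
#' hyperplane coefficient, keeps the `Q` most discriminant and retrains on
#' that subset; (d) transforms the held-out subject with the training-fold
#' covariate model and scaler and predicts its class. The procedure is fully
#' deterministic given the table: there is no randomness at any step.
#'
#' @param table a [feature_table()] with at least 2 subjects per class.
#' @param cost SVM cost parameter `C` (default 1, the customary default of
#'   libSVM front-ends).
#' @param rerank use re-ranking after each elimination instead of the fixed
#'   per-fold ranking (see [inner_accuracy_curve()]).
#' @param correct_covariates regress age and sex out of each feature
#'   (per training fold) before standardising. Disabling this is only
#'   sensible for demonstrating why the correction matters.
#' @param include_full allow the inner loop to choose `Q = P`.
#' @param q_tie tie rule for `Q` among inner-accuracy maximisers, see
#'   [inner_accuracy_curve()].
#' @param tolerance,max_iter solver controls, see [svm_train()].
#' @return An object of class `outer_result`: per-fold entries (held-out
#'   subject, `q_used`, `selected_features` ordered most discriminant first,
#'   predicted and true label, decision value, final weights, the
#'   training-fold covariate coefficients and scaler), plus `n_correct`,
#'   `n_total` and the run settings.
#' @export
run_outer_loocv <- function(table, cost = 1, rerank = FALSE,
                            correct_covariates = TRUE, include_full = FALSE,
                            q_tie = c("max", "min"),
                            tolerance = 1e-6, max_iter = 1000000L) {
  q_tie <- match.arg(q_tie)
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$X)
  if (n < 4L) stop("at least 4 subjects required")
  if (min(table(table$group)) < 2L) stop("at least 2 subjects per class required")
  y <- ft_labels(table)

  folds <- vector("list", n)
  for (k in seq_len(n)) {
    tr <- setdiff(seq_len(n), k)
    Xtr <- table$X[tr, , drop = FALSE]
    ytr <- y[tr]

    cov <- NULL
    R <- Xtr
    if (correct_covariates) {
      cov <- fit_covariate_model(Xtr, table$age[tr], table$sex[tr])
      R <- residualize(cov, Xtr, table$age[tr], table$sex[tr])
    }
    sc <- fit_scaler(R)
    Z <- apply_scaler(sc, R)

    curve <- inner_accuracy_curve(Z, ytr, cost = cost, rerank = rerank,
                                  include_full = include_full, q_tie = q_tie,
                                  tolerance = tolerance, max_iter = max_iter)
    q <- curve$chosen_q
    sel <- .rfe_select_cpp(Z, ytr, cost, tolerance, as.integer(max_iter),
                           rerank, as.integer(q))
    sel_idx <- sel$selected
    w <- as.numeric(sel$w)
    names(w) <- table$region_names[sel_idx]

    x0 <- table$X[k, , drop = FALSE]
    if (correct_covariates) {
      x0 <- residualize(cov, x0, table$age[k], table$sex[k])
    }
    z0 <- apply_scaler(sc, x0)
    dec <- sum(z0[1, sel_idx] * w) + sel$b
    pred <- if (dec >= 0) 1 else -1

    lab <- function(v) {
      if (v > 0) table$positive_class
      else setdiff(unique(table$group), table$positive_class)
    }
    folds[[k]] <- list(
      held_out_subject = table$subject_id[k],
      q_used = as.integer(q),
      selected_features = table$region_names[sel_idx],
      predicted_label = lab(pred),
      true_label = table$group[k],
      correct = pred == y[k],
      decision_value = dec,
      w = w,
      b = sel$b,
      inner_curve = curve,
      covariate_coef = if (correct_covariates) cov$coef else NULL,
      scaler = sc
    )
  }
  n_correct <- sum(vapply(folds, `[[`, logical(1), "correct"))
  structure(list(folds = folds,
                 n_correct = as.integer(n_correct),
                 n_total = n,
                 subject_ids = table$subject_id,
                 region_names = table$region_names,
                 positive_class = table$positive_class,
                 cost = cost, rerank = rerank,
                 correct_covariates = correct_covariates),
            class = "outer_result")
}

#' @export
print.outer_result <- function(x, ...) {
  qs <- vapply(x$folds, `[[`, integer(1), "q_used")
  cat(sprintf("outer_result: %d/%d correct (%.2f%%), per-fold Q in %d..%d\n",
              x$n_correct, x$n_total, 100 * x$n_correct / x$n_total,
              min(qs), max(qs)))
  cons <- consensus_features(x)
  cat(sprintf("  consensus regions (%d): %s\n", length(cons),
              if (length(cons)) paste(cons, collapse = ", ") else "<none>"))
  invisible(x)
}

#' Regions selected in every outer fold
#'
#' The intersection of the per-fold selected feature sets: the regions the
#' classifier relied on in all leave-one-out iterations, i.e. the
#' discriminative-region map. Ordered by mean within-fold rank of the
#' absolute final-model weight (most discriminant first, ties
#' lexicographic). The intersection may be empty; that is a reportable
#' outcome, not an error.
#'
#' @param result an [run_outer_loocv()] result with at least one fold.
#' @return character vector of region names (possibly empty).
#' @export
consensus_features <- function(result) {
  stopifnot(inherits(result, "outer_result"), length(result$folds) >= 1L)
  sets <- lapply(result$folds, `[[`, "selected_features")
  cons <- Reduce(intersect, sets)
  if (!length(cons)) return(character(0))
  mean_rank <- vapply(cons, function(r) {
    mean(vapply(result$folds, function(f) {
      pos <- rank(-abs(f$w), ties.method = "first")
      pos[[match(r, names(f$w))]]
    }, numeric(1)))
  }, numeric(1))
  cons[order(mean_rank, cons, method = "radix")]
}

#' Per-region selection frequency across outer folds
#'
#' @param result an [run_outer_loocv()] result.
#' @return data frame with columns `region` and `frequency` (fraction of
#'   outer folds whose selected set contains the region), sorted by
#'   decreasing frequency then region name. Regions at frequency 1 are the
#'   consensus set.
#' @export
selection_frequencies <- function(result) {
  stopifnot(inherits(result, "outer_result"))
  n <- length(result$folds)
  counts <- integer(length(result$region_names))
  names(counts) <- result$region_names
  for (f in result$folds) {
    counts[f$selected_features] <- counts[f$selected_features] + 1L
  }
  freq <- counts / n
  out <- data.frame(region = names(freq), frequency = as.numeric(freq),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$frequency, out$region, method = "radix"), , drop = FALSE]
}
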