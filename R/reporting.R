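#' Classification accuracy as a percentage
#'
#' @param n_correct,n_total integers, `0 <= n_correct <= n_total`,
#'   `n_total > 0`.
#' @return `100 * n_correct / n_total` rounded to 2 decimals.
#' @export
accuracy_percent <- function(n_correct, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_correct < 0 || n_correct > n_total) {
    stop("n_correct must lie in [0, n_total]")
  }
  round(100 * n_correct / n_total, 2)
}

#' Exact binomial significance of a classifier's accuracy
#'
#' Upper-tail probability `P(X >= n_correct)` for
#' `X ~ Binomial(n_total, chance)`: the probability of doing at least this
#' well by guessing at the stated chance level. Computed exactly (summation
#' of binomial terms, no normal approximation).
#'
#' @param n_correct,n_total integers.
#' @param chance chance-level success probability, in (0, 1). The
#'   conventional two-class value is 0.5; the majority-class proportion is a
#'   stricter alternative null.
#' @return the exact one-sided p-value.
#' @export
binomial_pvalue <- function(n_correct, n_total, chance = 0.5) {
  if (chance <= 0 || chance >= 1) stop("chance must be strictly inside (0, 1)")
  if (n_total <= 0) stop("n_total must be positive")
  if (n_correct < 0 || n_correct > n_total) {
    stop("n_correct must lie in [0, n_total]")
  }
  pbinom(n_correct - 1, n_total, chance, lower.tail = FALSE)
}

# "p<0.001"-style banding next to the exact value
format_pvalue <- function(p) {
  if (p < 0.001) "p<0.001" else if (p < 0.01) "p<0.01"
  else if (p < 0.05) "p<0.05" else sprintf("p=%.3f", p)
}

#' Empirical ROC curve and AUC
#'
#' Sweeps the decision threshold over the distinct score values in
#' descending order; tied scores collapse to a single point. The point list
#' starts at (0, 0) and ends at (1, 1) and is monotone non-decreasing in
#' both coordinates. The AUC is the trapezoid-rule area, which equals the
#' concordant-pair (rank-sum) statistic; it is invariant under any strictly
#' increasing transform of the scores.
#'
#' @param scores numeric vector (larger = more positive-class-like, e.g. SVM
#'   decision values or raw regional volumes).
#' @param labels +1/-1 vector (or logical, `TRUE` = positive); both classes
#'   must be present.
#' @return An object of class `roc_curve`: `points` (data frame `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_points <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, 1, -1)
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1/-1 (or logical)")
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")

  ord <- order(-scores)
  s <- scores[ord]
  l <- labels[ord]
  grp <- cumsum(!duplicated(s))            # distinct-score groups, descending
  tp <- cumsum(l == 1)
  fp <- cumsum(l == -1)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Per-region, per-group distribution summaries and single-region AUC
#'
#' For each requested region: the five-number summary (min, Q1, median, Q3,
#' max; quantiles by linear interpolation, R type 7) of the raw volumes per
#' group — the numbers behind a group boxplot — plus the AUC obtained when
#' the raw volume alone is used as a classification score for the positive
#' class. Regions do not retain their multivariate accuracy in isolation;
#' this summary makes that visible.
#'
#' @param table a [feature_table()].
#' @param regions character vector of region names, a subset of
#'   `table$region_names`.
#' @return data frame with one row per region and group and columns
#'   `region`, `group`, `min`, `q1`, `median`, `q3`, `max`, `auc` (the AUC
#'   repeats across the two group rows of a region).
#' @export
region_summary <- function(table, regions) {
  stopifnot(inherits(table, "feature_table"))
  unknown <- setdiff(regions, table$region_names)
  if (length(unknown)) {
    stop("unknown region(s): ", paste(unknown, collapse = ", "))
  }
  y <- ft_labels(table)
  groups <- unique(table$group)
  rows <- lapply(regions, function(r) {
    v <- table$X[, r]
    auc <- roc_points(v, y)$auc
    do.call(rbind, lapply(groups, function(g) {
      q <- quantile(v[table$group == g], c(0, 0.25, 0.5, 0.75, 1),
                    type = 7, names = FALSE)
      data.frame(region = r, group = g, min = q[1], q1 = q[2], median = q[3],
                 q3 = q[4], max = q[5], auc = auc,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise a nested LOOCV run
#'
#' Collects accuracy, exact binomial significance, per-fold `Q`, consensus
#' regions and selection frequencies, and the ROC over the outer-fold
#' decision values, into a single report object.
#'
#' @param result an [run_outer_loocv()] result.
#' @param chance chance level for the binomial test (default 0.5).
#' @return An object of class `classification_report`.
#' @export
classification_report <- function(result, chance = 0.5) {
  stopifnot(inherits(result, "outer_result"))
  dec <- vapply(result$folds, `[[`, numeric(1), "decision_value")
  truth <- ifelse(vapply(result$folds, `[[`, character(1), "true_label") ==
                    result$positive_class, 1, -1)
  roc <- roc_points(dec, truth)
  structure(list(
    accuracy = result$n_correct / result$n_total,
    accuracy_percent = accuracy_percent(result$n_correct, result$n_total),
    n_correct = result$n_correct,
    n_total = result$n_total,
    chance_level = chance,
    p_value = binomial_pvalue(result$n_correct, result$n_total, chance),
    per_fold_q = vapply(result$folds, `[[`, integer(1), "q_used"),
    consensus_regions = consensus_features(result),
    selection_frequencies = selection_frequencies(result),
    roc = roc,
    positive_class = result$positive_class,
    cost = result$cost,
    rerank = result$rerank,
    correct_covariates = result$correct_covariates
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Leave-one-subject-out accuracy: %.2f%% (%d of %d, %s; exact p = %.3g, chance = %g)\n",
              x$accuracy_percent, x$n_correct, x$n_total,
              format_pvalue(x$p_value), x$p_value, x$chance_level))
  cat(sprintf("Decision-value ROC AUC: %.3f\n", x$roc$auc))
  cat(sprintf("Per-fold Q: %s\n", paste(x$per_fold_q, collapse = " ")))
  cat(sprintf("Consensus regions (selected in every fold, most discriminant first):\n  %s\n",
              if (length(x$consensus_regions))
                paste(x$consensus_regions, collapse = ", ") else "<none>"))
  invisible(x)
}

#' Write a classification report to JSON
#'
#' Serialises the report (accuracy, counts, p-value, chance level, per-fold
#' `Q` and selected features, consensus regions, selection frequencies, ROC
#' points) so a run can be audited or re-rendered without re-computation.
#'
#' @param report a [classification_report()].
#' @param result the [run_outer_loocv()] result it came from (for the
#'   per-fold detail).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, result, path) {
  payload <- list(
    accuracy = report$accuracy,
    accuracy_percent = report$accuracy_percent,
    n_correct = report$n_correct,
    n_total = report$n_total,
    chance_level = report$chance_level,
    p_value = report$p_value,
    p_banded = format_pvalue(report$p_value),
    positive_class = report$positive_class,
    cost = report$cost,
    rerank = report$rerank,
    correct_covariates = report$correct_covariates,
    consensus_regions = report$consensus_regions,
    selection_frequencies = report$selection_frequencies,
    roc = list(auc = report$roc$auc, points = report$roc$points),
    folds = lapply(result$folds, function(f) {
      list(held_out_subject = f$held_out_subject,
           q_used = f$q_used,
           selected_features = f$selected_features,
           predicted_label = f$predicted_label,
           true_label = f$true_label,
           decision_value = f$decision_value)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the per-region selection-frequency table to CSV
#'
#' @param result an [run_outer_loocv()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_selection_frequencies <- function(result, path) {
  utils::write.csv(selection_frequencies(result), path, row.names = FALSE)
  invisible(path)
}
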