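#' Construct a subject-by-region feature table
#'
#' The central data object of the pipeline: an `n` subjects by `P` regions
#' matrix of volumes (mm^3) together with the demographics needed for
#' covariate correction (age in years, sex as a 0/1 indicator) and the group
#' label of every subject.
#'
#' @param X numeric matrix, one row per subject and one column per region;
#'   all cells finite and non-negative.
#' @param subject_id character vector of unique subject identifiers.
#' @param group character or factor vector of per-subject group labels;
#'   exactly two distinct labels across the table.
#' @param age numeric vector, years.
#' @param sex numeric 0/1 indicator vector.
#' @param region_names character vector of unique region names, one per
#'   column of `X`; defaults to `colnames(X)`.
#' @param positive_class label treated as the positive class (+1) by the
#'   classifier; defaults to the first group label in `group`.
#'
#' @return An object of class `feature_table` with elements `X`,
#'   `subject_id`, `group`, `age`, `sex`, `region_names`, `positive_class`.
#' @export
feature_table <- function(X, subject_id, group, age, sex,
                          region_names = colnames(X),
                          positive_class = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  group <- as.character(group)
  if (is.null(region_names)) {
    stop("region names are required (set colnames(X) or pass region_names)")
  }
  region_names <- as.character(region_names)
  if (length(subject_id) != n || length(group) != n ||
      length(age) != n || length(sex) != n) {
    stop("subject_id, group, age and sex must each have one entry per row of X")
  }
  if (anyDuplicated(subject_id)) stop("duplicate subject ids")
  if (length(region_names) != ncol(X)) {
    stop("region_names length does not match ncol(X)")
  }
  if (anyDuplicated(region_names)) stop("duplicate region names")
  if (n < 2L) stop("at least 2 subjects required")
  if (ncol(X) < 2L) stop("at least 2 regions required")
  if (anyNA(X) || !all(is.finite(X))) stop("X contains missing or non-finite cells")
  if (any(X < 0)) stop("volumes must be non-negative")
  if (!all(sex %in% c(0, 1))) stop("sex must be coded 0/1")
  if (anyNA(age) || !all(is.finite(age))) stop("age contains missing values")
  lev <- unique(group)
  if (length(lev) != 2L) stop("exactly two group labels required, got: ",
                              paste(lev, collapse = ", "))
  if (is.null(positive_class)) positive_class <- lev[1L]
  if (!positive_class %in% lev) stop("positive_class not among the group labels")
  dimnames(X) <- list(subject_id, region_names)
  structure(
    list(X = X, subject_id = as.character(subject_id), group = group,
         age = as.numeric(age), sex = as.numeric(sex),
         region_names = region_names, positive_class = positive_class),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(x$group)
  cat(sprintf("feature_table: %d subjects x %d regions\n",
              nrow(x$X), ncol(x$X)))
  cat(sprintf("  groups: %s (positive class: %s)\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              x$positive_class))
  cat(sprintf("  age: %.1f-%.1f yr; sex=1: %d\n",
              min(x$age), max(x$age), sum(x$sex)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$X)

# +1/-1 label vector, +1 for the positive class
ft_labels <- function(table) {
  ifelse(table$group == table$positive_class, 1, -1)
}

#' Write a feature table to the canonical tidy CSV
#'
#' One row per subject: `subject_id, group, age, sex`, then one column per
#' region. Volumes are written with 17 significant digits so that
#' [read_feature_table()] reproduces the matrix bit-identically.
#'
#' @param table a [feature_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  num <- function(v) sprintf("%.17g", v)
  header <- c("subject_id", "group", "age", "sex", table$region_names)
  rows <- vapply(seq_len(nrow(table$X)), function(i) {
    paste(c(table$subject_id[i], table$group[i],
            num(table$age[i]), num(table$sex[i]), num(table$X[i, ])),
          collapse = ",")
  }, character(1))
  writeLines(c(paste(header, collapse = ","), rows), path)
  invisible(path)
}

#' Read a feature table from the canonical tidy CSV
#'
#' @param path CSV written by [write_feature_table()] (or following the same
#'   layout).
#' @param positive_class optional positive-class label; defaults to the first
#'   group label encountered.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, positive_class = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "sex")
  if (!all(need %in% names(df))) {
    stop("feature CSV must contain columns: ", paste(need, collapse = ", "))
  }
  regions <- setdiff(names(df), need)
  X <- as.matrix(df[, regions, drop = FALSE])
  feature_table(X, df$subject_id, df$group, df$age, df$sex,
                region_names = regions, positive_class = positive_class)
}
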