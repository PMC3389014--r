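test_that("a single wide-margin feature wins the inner curve with Q = 1", {
  # feature 1 separates perfectly with a wide margin, feature 2 is tiny noise
  set.seed(20)
  n <- 8
  y <- rep(c(1, -1), 4)
  X <- cbind(3 * y + rnorm(n, 0, 0.05), rnorm(n, 0, 1e-3))
  cur <- inner_accuracy_curve(X, y)
  expect_s3_class(cur, "inner_curve")
  expect_identical(cur$feature_counts, 1L)   # P = 2 scores counts P-1..1
  expect_equal(cur$accuracy, 1.0)
  expect_identical(cur$chosen_q, 1L)
})

test_that("inner accuracies are chance-level under permuted labels", {
  # label-permutation null: mean accuracy at every count ~ 0.5
  set.seed(21)
  n <- 20; P <- 10; n_seeds <- 50
  acc <- matrix(NA_real_, n_seeds, P - 1)
  for (s in seq_len(n_seeds)) {
    X <- matrix(rnorm(n * P), n, P)
    y <- sample(rep(c(1, -1), n / 2))
    cur <- inner_accuracy_curve(X, y)
    acc[s, ] <- cur$accuracy[match(1:(P - 1), cur$feature_counts)]
  }
  means <- colMeans(acc)
  se <- apply(acc, 2, sd) / sqrt(n_seeds)
  expect_true(all(abs(means - 0.5) <= 3 * se))
})

test_that("inner curve matches the naive nested-loop oracle exactly", {
  skip_if_not_installed("e1071")
  set.seed(22)
  for (r in 1:8) {
    n <- sample(6:8, 1)
    P <- sample(3:5, 1)
    X <- matrix(rnorm(n * P), n, P)
    y <- c(1, 1, -1, -1, sample(c(1, -1), n - 4, replace = TRUE))
    for (rerank in c(FALSE, TRUE)) {
      cur <- inner_accuracy_curve(X, y, rerank = rerank)
      orc <- oracle_inner(X, y, rerank = rerank)
      expect_identical(cur$feature_counts, as.integer(orc$counts))
      expect_equal(cur$accuracy, orc$accuracy)
      expect_identical(cur$chosen_q, as.integer(orc$q))
    }
  }
})

test_that("Q tie rules pick the largest (default) or smallest maximiser", {
  set.seed(23)
  X <- matrix(rnorm(12 * 6), 12, 6)
  y <- rep(c(1, -1), 6)
  cmax <- inner_accuracy_curve(X, y, q_tie = "max")
  cmin <- inner_accuracy_curve(X, y, q_tie = "min")
  expect_equal(cmax$accuracy, cmin$accuracy)
  best <- max(cmax$accuracy)
  maxima <- cmax$feature_counts[cmax$accuracy >= best]
  expect_identical(cmax$chosen_q, max(maxima))
  expect_identical(cmin$chosen_q, min(maxima))
})

test_that("inner folds that lose a class are excluded with a warning", {
  set.seed(24)
  X <- matrix(rnorm(5 * 3), 5, 3)
  y <- c(1, -1, -1, -1, -1)       # removing the lone positive kills a fold
  expect_warning(cur <- inner_accuracy_curve(X, y), "lost a class")
  expect_identical(cur$n_folds_used, 4L)
})

test_that("the full outer procedure matches the naive oracle exactly", {
  skip_if_not_installed("e1071")
  for (s in 1:6) {
    tab <- random_small_table(seed = 100 + s)
    res <- suppressWarnings(run_outer_loocv(tab))
    orc <- suppressWarnings(oracle_nested(tab))
    for (k in seq_along(res$folds)) {
      f <- res$folds[[k]]
      expect_identical(f$q_used, as.integer(orc[[k]]$q))
      expect_identical(sort(f$selected_features), orc[[k]]$selected)
      expect_identical(f$predicted_label,
                       if (orc[[k]]$pred > 0) "meditator" else "control")
    }
  }
})

test_that("the outer procedure is deterministic (bitwise-identical reruns)", {
  tab <- random_small_table(seed = 42)
  r1 <- suppressWarnings(run_outer_loocv(tab))
  r2 <- suppressWarnings(run_outer_loocv(tab))
  expect_identical(r1, r2)
})

test_that("per-fold invariants hold: |selected| = Q, counts consistent", {
  tab <- generate_cohort(synthetic_config(n_pos = 6, n_neg = 6, n_regions = 8,
                                          planted_regions = 1:2, seed = 7))
  res <- run_outer_loocv(tab)
  expect_identical(res$n_total, 12L)
  expect_identical(res$n_correct,
                   sum(vapply(res$folds, function(f)
                     f$predicted_label == f$true_label, logical(1))))
  for (f in res$folds) {
    expect_identical(length(f$selected_features), as.integer(f$q_used))
    expect_true(all(f$selected_features %in% tab$region_names))
  }
})

test_that("consensus is the across-fold intersection, most discriminant first", {
  fold <- function(sel, w) list(selected_features = sel,
                                w = stats::setNames(w, sel))
  mk <- function(folds) structure(
    list(folds = folds, region_names = c("A", "B", "C", "D")),
    class = "outer_result")

  r <- mk(list(fold(c("A", "B", "C"), c(3, 2, 1)),
               fold(c("C", "A", "B"), c(5, 4, 1))))
  expect_identical(consensus_features(r), c("A", "C", "B"))

  r2 <- mk(list(fold(c("A", "B"), c(2, 1)), fold(c("A", "C"), c(2, 1))))
  expect_identical(consensus_features(r2), "A")

  r3 <- mk(list(fold("A", 1), fold("B", 1)))
  expect_identical(consensus_features(r3), character(0))

  freq <- selection_frequencies(r2)
  expect_equal(freq$frequency[match(c("A", "B", "C", "D"), freq$region)],
               c(1, 0.5, 0.5, 0))
})

test_that("an age-confounded region is not selected more than in a null", {
  # plant a pure age effect (zero group effect) in region 1 while groups
  # differ in age; residualization should keep its selection frequency at
  # the noise level seen in a matched unconfounded null
  freq1 <- function(cfg) {
    res <- run_outer_loocv(generate_cohort(cfg))
    sf <- selection_frequencies(res)
    sf$frequency[sf$region == "region_001"]
  }
  conf <- sapply(1:4, function(s) freq1(synthetic_config(
    n_pos = 8, n_neg = 8, n_regions = 8, planted_regions = integer(0),
    effect_size = 0, age_mean_pos = 55, age_sd_pos = 6,
    age_mean_neg = 38, age_sd_neg = 6,
    beta_age_fraction = -0.01, beta_sex_fraction = 0, seed = s)))
  null <- sapply(1:4, function(s) freq1(synthetic_config(
    n_pos = 8, n_neg = 8, n_regions = 8, planted_regions = integer(0),
    effect_size = 0, age_mean_pos = 55, age_sd_pos = 6,
    age_mean_neg = 38, age_sd_neg = 6,
    beta_age_fraction = 0, beta_sex_fraction = 0, seed = s)))
  expect_lte(mean(conf), mean(null) + 0.1)
})
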