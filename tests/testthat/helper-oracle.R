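# Independent oracles used to verify the implementation. These deliberately
# share no code with the package: the SVM backend is e1071/libSVM, the
# covariate regression is lm(), and the nested procedure is written as plain
# explicit loops.

# linear SVM (w, b) via e1071/libSVM, decision positive for y = +1
oracle_svm <- function(X, y, cost = 1) {
  f <- factor(ifelse(y > 0, "pos", "neg"), levels = c("pos", "neg"))
  m <- e1071::svm(X, f, kernel = "linear", cost = cost, scale = FALSE,
                  tolerance = 1e-8)
  list(w = drop(t(m$coefs) %*% m$SV), b = -m$rho)
}

oracle_predict <- function(fit, x) {
  if (sum(fit$w * x) + fit$b >= 0) 1 else -1
}

# ascending relevance (least |w| first, ties by index)
oracle_rank <- function(w) order(abs(w), seq_along(w))

# naive inner leave-one-out elimination curve; returns pooled accuracies for
# counts P-1 .. 1 and the chosen Q
oracle_inner <- function(Z, y, cost = 1, rerank = FALSE, q_tie = "max") {
  n <- nrow(Z)
  P <- ncol(Z)
  correct <- rep(0, P - 1)
  used <- 0
  for (i in seq_len(n)) {
    Ztr <- Z[-i, , drop = FALSE]
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) next
    used <- used + 1
    fit <- oracle_svm(Ztr, ytr, cost)
    active <- seq_len(P)
    ord <- oracle_rank(fit$w)      # fixed full-model ranking (original indices)
    removed <- 0
    for (cnt in (P - 1):1) {
      if (rerank) {
        wa <- fit$w               # aligned with current `active`
        pos <- which(abs(wa) == min(abs(wa)))
        pos <- pos[which.min(active[pos])]
        active <- active[-pos]
      } else {
        removed <- removed + 1
        active <- setdiff(active, ord[removed])
      }
      fit <- oracle_svm(Ztr[, active, drop = FALSE], ytr, cost)
      correct[cnt] <- correct[cnt] + (oracle_predict(fit, Z[i, active]) == y[i])
    }
  }
  acc <- correct[(P - 1):1] / used
  counts <- (P - 1):1
  maxima <- counts[acc >= max(acc)]
  q <- if (q_tie == "min") min(maxima) else max(maxima)
  list(counts = counts, accuracy = acc, q = q)
}

# naive full nested procedure over a feature_table-like list; returns per
# outer fold the chosen Q, the selected set (unordered) and the prediction
oracle_nested <- function(tab, cost = 1, rerank = FALSE, q_tie = "max") {
  X <- tab$X
  n <- nrow(X)
  y <- ifelse(tab$group == tab$positive_class, 1, -1)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    tr <- setdiff(seq_len(n), k)
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]

    # covariate residualization via lm(), per feature
    resid_tr <- matrix(0, length(tr), ncol(X))
    x0 <- numeric(ncol(X))
    for (j in seq_len(ncol(X))) {
      d <- data.frame(v = Xtr[, j], age = tab$age[tr], sex = tab$sex[tr])
      fit <- lm(v ~ age + sex, data = d)
      resid_tr[, j] <- residuals(fit)
      x0[j] <- X[k, j] - predict(fit, data.frame(age = tab$age[k],
                                                 sex = tab$sex[k]))
    }
    mu <- colMeans(resid_tr)
    sg <- apply(resid_tr, 2, sd)
    Z <- sweep(sweep(resid_tr, 2, mu), 2, sg, "/")
    z0 <- (x0 - mu) / sg

    q <- oracle_inner(Z, ytr, cost, rerank, q_tie)$q

    fit <- oracle_svm(Z, ytr, cost)
    if (!rerank) {
      sel <- rev(oracle_rank(fit$w))[seq_len(q)]
    } else {
      active <- seq_len(ncol(X))
      while (length(active) > q) {
        wa <- fit$w
        pos <- which(abs(wa) == min(abs(wa)))
        pos <- pos[which.min(active[pos])]
        active <- active[-pos]
        fit <- oracle_svm(Z[, active, drop = FALSE], ytr, cost)
      }
      sel <- active
    }
    fit <- oracle_svm(Z[, sel, drop = FALSE], ytr, cost)
    out[[k]] <- list(q = q, selected = sort(tab$region_names[sel]),
                     pred = oracle_predict(fit, z0[sel]))
  }
  out
}

# dual SVM solved by brute force: enumerate every assignment of each alpha
# to {lower bound 0, upper bound C, free}; for each free set solve the
# equality-constrained stationarity system and keep the best feasible
# candidate. The optimum's active set is among the 3^n assignments, so the
# maximum over feasible candidates is the exact dual optimum (which equals
# the primal optimum by strong duality). Only viable for small n.
oracle_qp_dual_objective <- function(X, y, cost = 1) {
  n <- nrow(X)
  stopifnot(n <= 9)
  H <- (y %*% t(y)) * (X %*% t(X))
  dual_obj <- function(a) sum(a) - 0.5 * drop(t(a) %*% H %*% a)
  tol <- 1e-8
  best <- -Inf
  for (code in 0:(3^n - 1)) {
    st <- (code %/% 3^(0:(n - 1))) %% 3
    a <- ifelse(st == 1, cost, 0)
    F <- which(st == 2)
    if (length(F) == 0) {
      if (abs(sum(y * a)) < tol) best <- max(best, dual_obj(a))
      next
    }
    B <- setdiff(seq_len(n), F)
    rhs_top <- 1 - if (length(B)) H[F, B, drop = FALSE] %*% a[B] else 0
    M <- rbind(cbind(H[F, F, drop = FALSE], y[F]), c(y[F], 0))
    rhs <- c(rhs_top, -sum(y[B] * a[B]))
    sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    aF <- sol[seq_along(F)]
    if (any(aF < -tol) || any(aF > cost + tol)) next
    a[F] <- pmin(pmax(aF, 0), cost)
    best <- max(best, dual_obj(a))
  }
  best
}

# AUC by explicit concordant-pair counting (ties count 1/2)
oracle_auc_pairs <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == -1]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# exact binomial upper tail by direct combinatorial summation
oracle_binom_tail <- function(k, n, p) {
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

# a small random cohort for oracle-equivalence checks. At least 3 subjects
# per class, so every outer training fold keeps two per class and at least
# one residual degree of freedom after the age+sex regression (3
# regressors). Every feature carries a group shift of a distinct magnitude:
# with pure-noise features at this n, folds exist whose SVM optimum
# collapses to w = 0 exactly (a lone subject inside the other class's hull,
# all alphas at bound), and ranking zero weights compares floating-point
# dust that no two independent implementations resolve identically.
# Distinct real shifts keep every ranking decision well-posed while the
# instances stay random.
random_small_table <- function(seed) {
  set.seed(seed)
  n_pos <- sample(3:4, 1)
  n_neg <- sample(3:4, 1)
  n <- n_pos + n_neg
  P <- sample(2:4, 1)
  X <- matrix(abs(rnorm(n * P, mean = 10, sd = 3)), n, P)
  X[seq_len(n_pos), ] <- X[seq_len(n_pos), , drop = FALSE] +
    rep(2 + 2.5 * sample(P), each = n_pos)
  # alternating sex indicator: mixed within each group, so the group shift
  # cannot be exactly absorbed by the per-fold sex regression
  feature_table(X,
                subject_id = sprintf("s%02d", seq_len(n)),
                group = c(rep("meditator", n_pos), rep("control", n_neg)),
                age = runif(n, 25, 65),
                sex = seq_len(n) %% 2,
                region_names = sprintf("r%02d", seq_len(P)),
                positive_class = "meditator")
}
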