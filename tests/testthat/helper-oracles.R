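# Independent numeric oracles used to cross-check the iterative fits, plus
# small fixture generators. The oracles share no code path with the package:
# they optimise explicit objective functions written out term by term,
# through unconstrained reparameterisations (logistic memberships, softmax
# centers) and general-purpose optim().

# Random point on the probability simplex (Dirichlet(1,...,1)).
random_simplex <- function(s) {
  g <- stats::rgamma(s, 1)
  g / sum(g)
}

# Weighted-distortion objective of fuzzy 2-means on 1-d data, written
# directly: memberships from logistic parameters, centers as the closed-form
# weighted means, J = sum u^m (x - v)^2.
oracle_fcm_objective <- function(theta, x, m) {
  u1 <- stats::plogis(theta)
  U <- cbind(u1, 1 - u1)
  W <- U^m
  cs <- colSums(W)
  if (any(cs == 0)) return(1e10)
  v <- colSums(W * x) / cs
  J <- 0
  for (k in seq_along(x)) {
    for (i in 1:2) J <- J + W[k, i] * (x[k] - v[i])^2
  }
  J
}

oracle_fcm_min <- function(x, m = 2, restarts = 25) {
  n <- length(x)
  best <- Inf
  for (r in seq_len(restarts)) {
    th0 <- stats::rnorm(n, 0, 3)
    fit <- tryCatch(
      stats::optim(th0, oracle_fcm_objective, x = x, m = m, method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value < best) best <- fit$value
  }
  best
}

# KL consensus objective for c = 2, written out directly: memberships from
# logistic parameters, each center row a softmax over s values (last logit
# pinned to 0), divergences summed term by term.
oracle_fce_objective <- function(theta, Y, m, kl_floor = 1e-12) {
  n <- nrow(Y)
  s <- ncol(Y)
  u1 <- stats::plogis(theta[seq_len(n)])
  U <- cbind(u1, 1 - u1)
  O <- matrix(0, 2, s)
  for (i in 1:2) {
    logits <- c(theta[n + (i - 1) * (s - 1) + seq_len(s - 1)], 0)
    e <- exp(logits - max(logits))
    O[i, ] <- e / sum(e)
  }
  J <- 0
  for (k in seq_len(n)) {
    for (i in 1:2) {
      d <- 0
      for (j in seq_len(s)) {
        if (Y[k, j] > 0) d <- d + Y[k, j] * log(Y[k, j] / max(O[i, j], kl_floor))
      }
      J <- J + U[k, i]^m * max(d, 0)
    }
  }
  J
}

oracle_fce_min <- function(Y, m = 2, restarts = 25) {
  n <- nrow(Y)
  s <- ncol(Y)
  npar <- n + 2 * (s - 1)
  best <- Inf
  for (r in seq_len(restarts)) {
    th0 <- stats::rnorm(npar, 0, 2)
    fit <- tryCatch(
      stats::optim(th0, oracle_fce_objective, Y = Y, m = m, method = "BFGS",
                   control = list(maxit = 3000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value < best) best <- fit$value
  }
  best
}

# Exhaustive-permutation alignment oracle: tries every relabeling of the
# predicted classes onto the joint class set and returns the best accuracy.
oracle_align_accuracy <- function(pred, ref) {
  classes <- sort(union(unique(as.vector(ref)), unique(as.vector(pred))))
  k <- length(classes)
  perm_list <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perm_list(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- -Inf
  for (p in perm_list(classes)) {
    relabeled <- p[match(as.vector(pred), classes)]
    best <- max(best, mean(relabeled == as.vector(ref)))
  }
  best
}

# Best converged objective of a package fit over a few seeds (tight tol),
# used when comparing local iterative fits against global oracles.
best_fce_objective <- function(Y, c = 2, m = 2, seeds = 1:3) {
  min(vapply(seeds, function(s) {
    fit <- fce_kl_fit(Y, c, m = m, max_iter = 500, tol = 1e-12, seed = s)
    fit$objective[length(fit$objective)]
  }, numeric(1)))
}

best_fcm_objective <- function(x, c = 2, m = 2, seeds = 1:3) {
  min(vapply(seeds, function(s) {
    fit <- fcm_fit(x, c, m = m, max_iter = 500, tol = 1e-12, seed = s)
    fit$objective[length(fit$objective)]
  }, numeric(1)))
}

expect_row_stochastic <- function(U, tol = 1e-9) {
  expect_true(all(U >= -tol & U <= 1 + tol))
  expect_true(max(abs(rowSums(U) - 1)) <= tol)
}
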