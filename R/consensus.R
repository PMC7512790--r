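# KL-divergence consensus over concatenated soft partitions.

#' Concatenate and normalize basic partitions
#'
#' Stacks the r membership matrices column-wise and divides by r, so that
#' every pixel's row becomes a discrete probability vector of length
#' s = sum of the member cluster counts. This probability-profile matrix is
#' the input to the KL consensus.
#'
#' @param partitions List of membership matrices sharing the same number of
#'   rows; each must be row-stochastic.
#' @return n x s matrix whose rows sum to 1.
#' @examples
#' u1 <- matrix(c(0.7, 0.2, 0.1), 1)
#' u2 <- matrix(c(0.1, 0.7, 0.2), 1)
#' concatenate_normalize(list(u1, u2))
#' @export
concatenate_normalize <- function(partitions) {
  if (!is.list(partitions) || length(partitions) < 1) {
    stop("partitions must be a non-empty list", call. = FALSE)
  }
  ns <- vapply(partitions, nrow, integer(1))
  if (length(unique(ns)) != 1) {
    stop("all partitions must cover the same data (row counts differ)", call. = FALSE)
  }
  for (i in seq_along(partitions)) {
    assert_row_stochastic(partitions[[i]], what = sprintf("partition %d", i))
  }
  do.call(cbind, partitions) / length(partitions)
}

#' Kullback-Leibler divergence between discrete distributions
#'
#' \eqn{D_{KL}(p \| q) = \sum_j p_j \log(p_j / q_j)} with the conventions
#' 0 log 0 = 0 and q floored at `kl_floor` inside the ratio (membership
#' matrices routinely contain exact zeros). Natural logarithm.
#'
#' @param p,q Probability vectors of equal length.
#' @param kl_floor Small positive guard for zero entries of `q`.
#' @return Non-negative scalar (up to floating-point round-off).
#' @export
kl_divergence <- function(p, q, kl_floor = 1e-12) {
  if (length(p) != length(q)) stop("p and q must have equal length", call. = FALSE)
  if (any(p < 0) || any(q < 0)) stop("probability vectors must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("p and q must each sum to 1", call. = FALSE)
  }
  pos <- p > 0
  sum(p[pos] * log(p[pos] / pmax(q[pos], kl_floor)))
}

# n x c matrix of D_KL(y_k || o_i), vectorised; tiny negatives clipped to 0.
.kl_matrix <- function(Y, O, kl_floor = 1e-12) {
  plogp <- Y * log(Y)
  plogp[Y == 0] <- 0
  D <- rowSums(plogp) - tcrossprod(Y, log(pmax(O, kl_floor)))
  pmax(D, 0)
}

#' Consensus center update
#'
#' \eqn{o_{ij} = \sum_k u_{ik}^m y_{kj} / \sum_h \sum_k u_{ik}^m y_{kh}}:
#' each center is the membership-weighted convex combination of the
#' probability profiles, so center rows stay on the simplex.
#'
#' @param Y n x s probability-profile matrix (rows sum to 1).
#' @param U n x c membership matrix.
#' @param m Fuzzification coefficient.
#' @return c x s center matrix with non-negative entries and unit row sums.
#' @export
update_centers <- function(Y, U, m = 2) {
  if (nrow(Y) != nrow(U)) stop("Y and U must have the same number of rows", call. = FALSE)
  W <- U^m
  cs <- colSums(W)
  if (any(cs <= 0)) {
    stop("empty cluster: a consensus cluster has no supporting membership; re-seed the initialisation",
         call. = FALSE)
  }
  O <- crossprod(W, Y)
  O / rowSums(O)
}

#' Consensus membership update
#'
#' \eqn{u_{ik} = 1 / \sum_\ell (D_{KL}(y_k \| o_i) / D_{KL}(y_k \| o_\ell))^{1/(m-1)}}.
#' If a profile has zero divergence to one or more centers (within 1e-12),
#' its mass is split equally among those centers, the singular limit of the
#' update.
#'
#' @inheritParams update_centers
#' @param O c x s center matrix, rows on the simplex.
#' @param kl_floor Guard for zero center entries inside the log ratio.
#' @return n x c row-stochastic membership matrix.
#' @export
update_memberships <- function(Y, O, m = 2, kl_floor = 1e-12) {
  D <- .kl_matrix(Y, O, kl_floor)
  if (any(!is.finite(D))) stop("non-finite divergence encountered", call. = FALSE)
  zero <- D <= 1e-12
  U <- matrix(0, nrow(D), ncol(D))
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    z <- zero[hit, , drop = FALSE]
    U[hit, ] <- z / rowSums(z)
  }
  if (any(!hit)) {
    w <- D[!hit, , drop = FALSE]^(-1 / (m - 1))
    U[!hit, ] <- w / rowSums(w)
  }
  U
}

.init_consensus_centers <- function(Y, c, seed, init_centers) {
  if (!is.null(init_centers)) {
    O <- as.matrix(init_centers)
    if (nrow(O) != c || ncol(O) != ncol(Y)) {
      stop("init_centers must be a c x s matrix", call. = FALSE)
    }
    return(O)
  }
  uy <- unique(Y)
  pool <- if (nrow(uy) >= c) uy else Y
  if (nrow(pool) < c) stop("fewer data rows than clusters", call. = FALSE)
  idx <- with_seed_opt(seed, sample.int(nrow(pool), c))
  pool[idx, , drop = FALSE]
}

.consensus_result <- function(U, O, trace, t, converged) {
  structure(
    list(memberships = U, centers = O, objective = trace,
         iterations = t, converged = converged),
    class = c("klfce_consensus", "klfce_fit")
  )
}

#' KL-divergence fuzzy cluster ensemble (consensus fit)
#'
#' Alternating minimisation of
#' \eqn{J = \sum_k \sum_i u_{ik}^m D_{KL}(y_k \| o_i)} over row-stochastic
#' memberships and simplex-constrained centers, starting from `c` distinct
#' profile rows sampled under `seed`. Each iteration applies the membership
#' update then the center update; J is recorded after both and is
#' non-increasing. Iteration stops when |J(t) - J(t-1)| < `tol` or after
#' `max_iter` iterations.
#'
#' @param Y n x s probability-profile matrix from [concatenate_normalize()].
#' @param c Number of consensus clusters.
#' @param m Fuzzification coefficient (> 1).
#' @param max_iter Maximum number of iterations.
#' @param tol Convergence threshold on successive objective values.
#' @param seed Integer seed for center initialisation.
#' @param init_centers Optional explicit c x s initial centers.
#' @param kl_floor Guard constant for logs/ratios, in (0, 1e-6].
#' @return A `klfce_consensus` object: `memberships`, `centers`, `objective`
#'   trace, `iterations`, `converged`.
#' @export
fce_kl_fit <- function(Y, c, m = 2, max_iter = 100, tol = 1e-5,
                       seed = NULL, init_centers = NULL, kl_floor = 1e-12) {
  assert_row_stochastic(Y, what = "profile matrix Y")
  if (c < 1 || c > nrow(Y)) stop("need 1 <= c <= n", call. = FALSE)
  if (m <= 1) stop("m must exceed 1", call. = FALSE)
  if (kl_floor <= 0 || kl_floor > 1e-6) stop("kl_floor must lie in (0, 1e-6]", call. = FALSE)
  O <- .init_consensus_centers(Y, c, seed, init_centers)
  trace <- numeric(0)
  j_prev <- Inf
  converged <- FALSE
  U <- NULL
  t <- 0L
  while (t < max_iter) {
    t <- t + 1L
    U <- update_memberships(Y, O, m, kl_floor)
    O <- update_centers(Y, U, m)
    j <- sum(U^m * .kl_matrix(Y, O, kl_floor))
    trace <- c(trace, j)
    if (abs(j - j_prev) < tol) {
      converged <- TRUE
      break
    }
    j_prev <- j
  }
  .consensus_result(U, O, trace, t, converged)
}

#' Spatial KL fuzzy cluster ensemble for images
#'
#' As [fce_kl_fit()], but on every iteration the membership update is
#' followed by neighbourhood smoothing
#' (\link{spatial_smooth_memberships}, default 5x5 window); the smoothed
#' memberships drive the center update and the reported objective, and are
#' what the fit returns. Because the smoothing step sits outside the
#' stationarity conditions of the objective, monotone descent of J is not
#' guaranteed (and not asserted); termination is by the `tol`/`max_iter`
#' rule. `window = 1` reproduces [fce_kl_fit()] exactly.
#'
#' @inheritParams fce_kl_fit
#' @param dim Integer `c(height, width)` of the pixel grid (row-major order).
#' @param window Odd smoothing window side (default 5).
#' @return A `klfce_consensus` object; `memberships` are the smoothed ones.
#' @export
fce_skl_fit <- function(Y, dim, c, m = 2, window = 5, max_iter = 100, tol = 1e-5,
                        seed = NULL, init_centers = NULL, kl_floor = 1e-12) {
  assert_row_stochastic(Y, what = "profile matrix Y")
  dim <- as.integer(dim)
  if (nrow(Y) != prod(dim)) {
    stop(sprintf("profile rows (%d) do not match grid %d x %d", nrow(Y), dim[1], dim[2]),
         call. = FALSE)
  }
  window <- check_odd_window(window)
  if (m <= 1) stop("m must exceed 1", call. = FALSE)
  O <- .init_consensus_centers(Y, c, seed, init_centers)
  trace <- numeric(0)
  j_prev <- Inf
  converged <- FALSE
  U <- NULL
  t <- 0L
  while (t < max_iter) {
    t <- t + 1L
    U <- update_memberships(Y, O, m, kl_floor)
    U <- spatial_smooth_memberships(U, dim, window)
    O <- update_centers(Y, U, m)
    j <- sum(U^m * .kl_matrix(Y, O, kl_floor))
    trace <- c(trace, j)
    if (abs(j - j_prev) < tol) {
      converged <- TRUE
      break
    }
    j_prev <- j
  }
  .consensus_result(U, O, trace, t, converged)
}

#' One-call ensemble segmentation of an image
#'
#' Convenience pipeline: generate the basic partitions, concatenate and
#' normalize them, run the chosen consensus method, and defuzzify to a hard
#' label map.
#'
#' @param image Numeric matrix: the image grid.
#' @param c Number of segments.
#' @param method `"fce_skl"` (spatial, default) or `"fce_kl"`.
#' @param members Base clusterer specs, see [default_members()].
#' @param m Fuzzification coefficient for members and consensus.
#' @param window Consensus smoothing window (fce_skl only).
#' @param max_iter,tol Convergence settings.
#' @param seed Integer seed controlling member and consensus initialisation.
#' @return List with `labels` (height x width integer map, 0-based),
#'   `memberships`, `fit` (the consensus fit), and `partitions`.
#' @export
segment_ensemble <- function(image, c, method = c("fce_skl", "fce_kl"),
                             members = default_members(), m = 2, window = 5,
                             max_iter = 100, tol = 1e-5, seed = NULL) {
  method <- match.arg(method)
  parts <- generate_basic_partitions(image, c, members, m = m,
                                     max_iter = max_iter, tol = tol,
                                     seed = derive_seed(seed, 1))
  Y <- concatenate_normalize(parts)
  fit <- if (method == "fce_skl") {
    fce_skl_fit(Y, dim(image), c, m = m, window = window,
                max_iter = max_iter, tol = tol, seed = derive_seed(seed, 2))
  } else {
    fce_kl_fit(Y, c, m = m, max_iter = max_iter, tol = tol,
               seed = derive_seed(seed, 2))
  }
  list(labels = defuzzify(fit$memberships, dim(image)),
       memberships = fit$memberships, fit = fit, partitions = parts)
}
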