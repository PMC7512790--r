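# Base soft clusterers: fuzzy c-means and its locally spatial variant.

# Squared Euclidean distances between n x d data and c x d centers.
.sq_dist <- function(X, V) {
  D <- outer(rowSums(X^2), rowSums(V^2), "+") - 2 * tcrossprod(X, V)
  pmax(D, 0)
}

# Memberships from squared distances: u_ik = 1 / sum_j (d_ik/d_jk)^(2/(m-1)).
# A datum coinciding with one or more centers gets its mass split equally
# among the coincident centers (the zero-distance limit of the update).
.fcm_memberships <- function(d2, m) {
  hit <- d2 < 1e-24
  u <- matrix(0, nrow(d2), ncol(d2))
  any_hit <- rowSums(hit) > 0
  if (any(any_hit)) {
    h <- hit[any_hit, , drop = FALSE]
    u[any_hit, ] <- h / rowSums(h)
  }
  if (any(!any_hit)) {
    w <- d2[!any_hit, , drop = FALSE]^(-1 / (m - 1))
    u[!any_hit, ] <- w / rowSums(w)
  }
  u
}

.fcm_prepare_data <- function(x) {
  if (is.matrix(x)) matrix(flatten_image(x), ncol = 1) else matrix(as.numeric(x), ncol = 1)
}

.fcm_init_centers <- function(X, c, seed, init_centers) {
  if (!is.null(init_centers)) {
    V <- matrix(as.numeric(init_centers), ncol = ncol(X))
    if (nrow(V) != c) stop("init_centers must supply one center per cluster", call. = FALSE)
    return(V)
  }
  ux <- unique(X)
  if (nrow(ux) < c) {
    stop("degenerate input: fewer distinct data values than clusters", call. = FALSE)
  }
  idx <- with_seed_opt(seed, sample.int(nrow(ux), c))
  ux[idx, , drop = FALSE]
}

#' Fuzzy c-means clustering of grayscale data
#'
#' Minimises the weighted within-cluster distortion
#' \eqn{J = \sum_k \sum_i u_{ik}^m \|x_k - v_i\|^2} by alternating the
#' closed-form membership and center updates. A matrix input is treated as an
#' image grid and flattened row-major; a vector is used as-is.
#'
#' Centers are initialised by sampling `c` distinct data values under `seed`,
#' so runs are reproducible. The objective trace is recorded after each full
#' (membership, center) update and is non-increasing by construction of the
#' alternating minimisation.
#'
#' @param x Numeric matrix (image grid, flattened row-major) or numeric vector
#'   of intensities.
#' @param c Number of clusters (at least 1, at most the number of data).
#' @param m Fuzzification coefficient, greater than 1. Larger values give
#'   softer partitions; 2 is the conventional choice.
#' @param max_iter Maximum number of alternating iterations.
#' @param tol Convergence threshold on successive objective values |J(t) - J(t-1)|.
#' @param seed Optional integer seed for center initialisation.
#' @param init_centers Optional explicit initial centers (length-`c` vector for
#'   grayscale data), overriding seeded initialisation.
#' @return An object of class `klfce_fit`: a list with `memberships` (n x c,
#'   rows summing to 1), `centers`, `objective` (the J trace), `iterations`,
#'   and `converged`.
#' @examples
#' fit <- fcm_fit(c(0, 0, 10, 10), c = 2, seed = 1)
#' fit$centers
#' @export
fcm_fit <- function(x, c, m = 2, max_iter = 100, tol = 1e-5,
                    seed = NULL, init_centers = NULL) {
  X <- .fcm_prepare_data(x)
  n <- nrow(X)
  if (any(!is.finite(X))) stop("data must be finite", call. = FALSE)
  if (c < 1 || c != round(c)) stop("invalid configuration: c must be a positive integer", call. = FALSE)
  if (c > n) stop("invalid configuration: more clusters than data points", call. = FALSE)
  if (m <= 1) stop("invalid configuration: m must exceed 1", call. = FALSE)
  if (tol <= 0) stop("invalid configuration: tol must be positive", call. = FALSE)
  V <- .fcm_init_centers(X, c, seed, init_centers)
  .fcm_loop(X, V, m, max_iter, tol, smooth = NULL)
}

# Shared alternating loop; `smooth` is an optional function applied to the
# membership matrix each iteration (used by the spatial variant).
.fcm_loop <- function(X, V, m, max_iter, tol, smooth = NULL) {
  trace <- numeric(0)
  j_prev <- Inf
  converged <- FALSE
  U <- NULL
  t <- 0L
  while (t < max_iter) {
    t <- t + 1L
    U <- .fcm_memberships(.sq_dist(X, V), m)
    if (!is.null(smooth)) U <- smooth(U)
    W <- U^m
    cs <- colSums(W)
    if (any(cs <= 0)) stop("empty cluster at iteration ", t, call. = FALSE)
    V <- crossprod(W, X) / cs
    j <- sum(W * .sq_dist(X, V))
    trace <- c(trace, j)
    if (abs(j - j_prev) < tol) {
      converged <- TRUE
      break
    }
    j_prev <- j
  }
  structure(
    list(memberships = U, centers = V, objective = trace,
         iterations = t, converged = converged),
    class = "klfce_fit"
  )
}

#' @export
print.klfce_fit <- function(x, ...) {
  cat(sprintf(
    "soft clustering fit: n = %d, c = %d, %d iteration(s), %s (final J = %.6g)\n",
    nrow(x$memberships), ncol(x$memberships), x$iterations,
    if (isTRUE(x$converged)) "converged" else "not converged",
    x$objective[length(x$objective)]
  ))
  invisible(x)
}

#' Neighbourhood smoothing of a membership field
#'
#' Replaces each pixel's membership by the average of its own value and the
#' mean over a square window centred on it:
#' \eqn{\hat u_{ik} = (\mathrm{mean}_{\omega \in NB(x_k)} u_{i\omega} + u_{ik}) / 2}.
#' At the image border the window is truncated to its intersection with the
#' grid (the centre pixel is always a member), so the operator is an exact
#' average everywhere and preserves row sums exactly.
#'
#' @param U Membership matrix, n x c, rows summing to 1, with n = prod(dim).
#' @param dim Integer vector `c(height, width)` of the pixel grid; pixels are
#'   ordered row-major.
#' @param window Odd window side length; `1` is the identity.
#' @return Smoothed membership matrix of the same shape.
#' @export
spatial_smooth_memberships <- function(U, dim, window = 3) {
  window <- check_odd_window(window)
  dim <- as.integer(dim)
  if (length(dim) != 2 || any(dim < 1)) stop("dim must be c(height, width)", call. = FALSE)
  if (nrow(U) != prod(dim)) {
    stop(sprintf("membership rows (%d) do not match grid %d x %d", nrow(U), dim[1], dim[2]),
         call. = FALSE)
  }
  if (window == 1L) return(U)
  out <- U
  for (i in seq_len(ncol(U))) {
    field <- unflatten_image(U[, i], dim)
    out[, i] <- flatten_image((box_mean(field, window) + field) / 2)
  }
  out
}

#' Spatially regularised fuzzy c-means for images
#'
#' Fuzzy c-means in which, on every iteration, the membership update is
#' followed by [spatial_smooth_memberships()]; centers and the objective are
#' then computed from the smoothed memberships, which are also what the fit
#' returns. The smoothing pulls isolated noisy pixels toward the membership
#' of their neighbourhood, so piecewise-constant regions segment cleanly
#' under moderate noise. `window = 1` reduces exactly to [fcm_fit()].
#'
#' @inheritParams fcm_fit
#' @param image Numeric matrix: the image grid.
#' @param window Odd side length of the smoothing window (default 3).
#' @return A `klfce_fit` object, as for [fcm_fit()].
#' @export
sfcm_fit <- function(image, c, m = 2, window = 3, max_iter = 100, tol = 1e-5,
                     seed = NULL, init_centers = NULL) {
  if (!is.matrix(image)) stop("sfcm_fit requires an image grid (matrix)", call. = FALSE)
  window <- check_odd_window(window)
  dims <- dim(image)
  X <- .fcm_prepare_data(image)
  if (any(!is.finite(X))) stop("data must be finite", call. = FALSE)
  if (c < 1 || c > nrow(X)) stop("invalid configuration: need 1 <= c <= n", call. = FALSE)
  if (m <= 1) stop("invalid configuration: m must exceed 1", call. = FALSE)
  V <- .fcm_init_centers(X, c, seed, init_centers)
  smooth <- if (window == 1L) NULL else {
    function(U) spatial_smooth_memberships(U, dims, window)
  }
  .fcm_loop(X, V, m, max_iter, tol, smooth = smooth)
}

#' Default ensemble member specification
#'
#' Four diverse, fully specified base clusterers: two fuzzy c-means runs with
#' independently derived seeds, and spatial fuzzy c-means at two neighbourhood
#' scales (3x3 and 5x5). Diversity comes from initialisation and spatial
#' scale; every member is defined by the standard membership/center updates.
#'
#' @return Named list of member specs for [generate_basic_partitions()]; each
#'   spec has `method` ("fcm" or "sfcm") and, for "sfcm", a `window`.
#' @export
default_members <- function() {
  list(
    fcm_a   = list(method = "fcm"),
    fcm_b   = list(method = "fcm"),
    sfcm_w3 = list(method = "sfcm", window = 3),
    sfcm_w5 = list(method = "sfcm", window = 5)
  )
}

#' Generate the basic soft partitions of an image
#'
#' Runs each configured base clusterer on the same image and collects the
#' resulting membership matrices, the inputs to the consensus step. Each
#' member may use its own cluster count `c` and (for "sfcm") window; member
#' seeds are derived deterministically from `seed` and the member index, so
#' the whole ensemble is reproducible from one integer.
#'
#' @param image Numeric matrix: the (possibly noisy) image grid.
#' @param c Default cluster count for members that do not set their own.
#' @param members Named list of member specs; see [default_members()].
#' @param m Fuzzification coefficient shared by all members.
#' @param max_iter,tol Convergence settings shared by all members.
#' @param seed Integer seed from which each member's initialisation seed is
#'   derived.
#' @return Named list of membership matrices, one per member, each n x c_f
#'   with rows summing to 1.
#' @export
generate_basic_partitions <- function(image, c, members = default_members(),
                                      m = 2, max_iter = 100, tol = 1e-5,
                                      seed = NULL) {
  if (length(members) == 0) stop("members must be non-empty", call. = FALSE)
  if (is.null(names(members)) || any(names(members) == "")) {
    names(members) <- paste0("member_", seq_along(members))
  }
  out <- vector("list", length(members))
  names(out) <- names(members)
  for (f in seq_along(members)) {
    spec <- members[[f]]
    cf <- spec$c %||% c
    sf <- derive_seed(seed, f)
    fit <- switch(
      spec$method %||% "unknown",
      fcm = fcm_fit(image, cf, m = m, max_iter = max_iter, tol = tol, seed = sf),
      sfcm = sfcm_fit(image, cf, m = m, window = spec$window %||% 3,
                      max_iter = max_iter, tol = tol, seed = sf),
      stop(sprintf("unknown base clusterer '%s' in member '%s'",
                   spec$method %||% "<missing>", names(members)[f]), call. = FALSE)
    )
    out[[f]] <- fit$memberships
  }
  out
}
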