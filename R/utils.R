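# Internal helpers shared across modules.

# Row-major flattening: pixel k = (row - 1) * width + col, matching the
# 0-based row-major convention used for the data vector x_k.
flatten_image <- function(img) as.vector(t(img))

unflatten_image <- function(v, dim) matrix(v, nrow = dim[1], byrow = TRUE)

# Evaluate expr under a temporary seed; seed = NULL leaves the RNG alone.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Deterministic derived seeds, kept inside 32-bit integer range.
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) %% 2146319 * 1000 + 9973 * i + 1) %% 2147483647)
}

assert_row_stochastic <- function(U, tol = 1e-8, what = "membership matrix") {
  if (!is.matrix(U) || !is.numeric(U)) {
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  }
  if (any(!is.finite(U))) stop(sprintf("%s has non-finite entries", what), call. = FALSE)
  if (any(U < -tol) || any(U > 1 + tol)) {
    stop(sprintf("%s entries must lie in [0, 1]", what), call. = FALSE)
  }
  if (any(abs(rowSums(U) - 1) > tol)) {
    stop(sprintf("rows of %s must sum to 1", what), call. = FALSE)
  }
  invisible(U)
}

check_odd_window <- function(window) {
  if (length(window) != 1 || is.na(window) || window < 1 || window %% 2 != 1) {
    stop("window must be an odd integer >= 1", call. = FALSE)
  }
  as.integer(window)
}

# Truncated box mean: mean of the (window x window) neighbourhood centred on
# each pixel, intersected with the image; the centre pixel is included and
# the divisor is the actual neighbour count. Separable shift-accumulate.
box_mean <- function(mat, window) {
  window <- check_odd_window(window)
  if (window == 1L) return(mat)
  h <- (window - 1L) %/% 2L
  nr <- nrow(mat)
  nc <- ncol(mat)
  vsum <- matrix(0, nr, nc)
  for (d in -h:h) {
    src <- seq_len(nr) + d
    ok <- src >= 1L & src <= nr
    vsum[ok, ] <- vsum[ok, , drop = FALSE] + mat[src[ok], , drop = FALSE]
  }
  hsum <- matrix(0, nr, nc)
  for (d in -h:h) {
    src <- seq_len(nc) + d
    ok <- src >= 1L & src <= nc
    hsum[, ok] <- hsum[, ok, drop = FALSE] + vsum[, src[ok], drop = FALSE]
  }
  cnt_r <- pmin(seq_len(nr) + h, nr) - pmax(seq_len(nr) - h, 1L) + 1L
  cnt_c <- pmin(seq_len(nc) + h, nc) - pmax(seq_len(nc) - h, 1L) + 1L
  hsum / outer(cnt_r, cnt_c)
}

# All permutations of 1..k as a k! x k matrix, lexicographic order.
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    rest <- seq_len(k)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
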