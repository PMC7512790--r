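# Synthetic phantoms and noise models for benchmarking segmentation.

.new_phantom <- function(image, labels, levels) {
  structure(
    list(image = image, labels = labels,
         n_regions = length(levels), intensity_levels = levels),
    class = "klfce_phantom"
  )
}

#' @export
print.klfce_phantom <- function(x, ...) {
  cat(sprintf("phantom: %d x %d, %d region(s), levels {%s}\n",
              nrow(x$image), ncol(x$image), x$n_regions,
              paste(signif(x$intensity_levels, 4), collapse = ", ")))
  invisible(x)
}

#' Two-value phantom image
#'
#' A square binary image split into two vertical halves: the left columns at
#' intensity 0 (label 0), the right columns at intensity 1 (label 1). The
#' two-region layout with a single compact straight boundary is the classic
#' easiest-case benchmark for noise-robust segmentation.
#'
#' @param size Side length in pixels (default 50).
#' @return A `klfce_phantom`: list with `image`, integer `labels`,
#'   `n_regions`, `intensity_levels`.
#' @export
make_two_value_phantom <- function(size = 50) {
  if (size < 2) stop("size must be at least 2", call. = FALSE)
  img <- matrix(0, size, size)
  img[, (floor(size / 2) + 1):size] <- 1
  .new_phantom(img, labels = matrix(as.integer(img), size, size), levels = c(0, 1))
}

#' Four-region quadrant phantom
#'
#' A square image divided into four equal quadrants at equally spaced
#' intensity levels {0, 1/3, 2/3, 1} (labels 0-3, row-major quadrant order:
#' top-left, top-right, bottom-left, bottom-right). A synthetic stand-in for
#' four-tissue segmentation benchmarks; the equal level spacing makes the
#' clean image exactly separable with four clusters.
#'
#' @param size Even side length in pixels (default 64).
#' @return A `klfce_phantom`.
#' @export
make_trin_phantom <- function(size = 64) {
  if (size < 2 || size %% 2 != 0) stop("size must be an even integer >= 2", call. = FALSE)
  half <- size %/% 2
  lab <- matrix(0L, size, size)
  lab[seq_len(half), (half + 1):size] <- 1L
  lab[(half + 1):size, seq_len(half)] <- 2L
  lab[(half + 1):size, (half + 1):size] <- 3L
  levels <- c(0, 1, 2, 3) / 3
  img <- matrix(levels[lab + 1L], size, size)
  .new_phantom(img, lab, levels)
}

.clean_image <- function(x) {
  if (inherits(x, "klfce_phantom")) x$image
  else if (is.matrix(x)) x
  else stop("expected a phantom or an image matrix", call. = FALSE)
}

.noise_sigma <- function(img, level_percent) {
  if (level_percent < 0) stop("noise level must be non-negative", call. = FALSE)
  r <- diff(range(img))
  if (r == 0) stop("degenerate input: constant image has zero intensity range", call. = FALSE)
  level_percent / 100 * r
}

#' Additive Gaussian noise
#'
#' Adds i.i.d. zero-mean Gaussian noise to every pixel. The noise level is a
#' percentage of the clean image's intensity range: sigma =
#' (level_percent/100) * (max - min). No clipping is applied, so the output
#' may leave the clean intensity range; clusterers operate on raw real
#' intensities.
#'
#' @param x A `klfce_phantom` or an image matrix.
#' @param level_percent Noise level as a percentage of the intensity range.
#' @param seed Optional integer seed; the output is bit-identical for
#'   identical inputs and seed.
#' @return Noisy image matrix with the same shape (ground-truth labels of a
#'   phantom are untouched).
#' @export
add_gaussian_noise <- function(x, level_percent, seed = NULL) {
  img <- .clean_image(x)
  sigma <- .noise_sigma(img, level_percent)
  e <- with_seed_opt(seed, rnorm(length(img), 0, sigma))
  img + matrix(e, nrow(img), ncol(img))
}

#' Rician noise
#'
#' The magnitude-MRI noise model: each pixel becomes
#' sqrt((I + e1)^2 + e2^2) with e1, e2 i.i.d. Normal(0, sigma^2) and sigma =
#' (level_percent/100) * intensity range. Output is everywhere non-negative;
#' where the clean signal is zero the noisy values are Rayleigh(sigma)
#' distributed.
#'
#' @inheritParams add_gaussian_noise
#' @return Non-negative noisy image matrix with the same shape.
#' @export
add_rician_noise <- function(x, level_percent, seed = NULL) {
  img <- .clean_image(x)
  sigma <- .noise_sigma(img, level_percent)
  n <- length(img)
  e <- with_seed_opt(seed, rnorm(2 * n, 0, sigma))
  e1 <- matrix(e[seq_len(n)], nrow(img), ncol(img))
  e2 <- matrix(e[n + seq_len(n)], nrow(img), ncol(img))
  sqrt((img + e1)^2 + e2^2)
}
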