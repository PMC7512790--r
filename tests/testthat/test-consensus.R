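# Concatenation/normalization and the KL consensus fits.

two_partition_example <- function() {
  u1 <- rbind(c(0.7, 0.2, 0.1), c(0.9, 0.1, 0.0), c(0.2, 0.6, 0.2),
              c(0.1, 0.9, 0.0), c(0.1, 0.2, 0.7))
  u2 <- rbind(c(0.1, 0.7, 0.2), c(0.0, 0.8, 0.2), c(0.1, 0.1, 0.8),
              c(0.2, 0.1, 0.7), c(0.6, 0.2, 0.2))
  list(u1, u2)
}

test_that("concatenation halves and stacks rows; r = 1 is the identity", {
  Y <- concatenate_normalize(two_partition_example())
  expect_equal(dim(Y), c(5L, 6L))
  expect_equal(Y[1, ], c(0.35, 0.10, 0.05, 0.05, 0.35, 0.10))
  expect_row_stochastic(Y)
  U <- two_partition_example()[[1]]
  expect_equal(concatenate_normalize(list(U)), U)
})

test_that("concatenation validates its inputs", {
  expect_error(concatenate_normalize(list(matrix(0.5, 2, 2), matrix(0.5, 3, 2))),
               "row counts differ")
  bad <- matrix(c(0.5, 0.6, 0.5, 0.6), 2, 2)
  expect_error(concatenate_normalize(list(bad)), "sum to 1")
})

test_that("KL divergence: identity, one-hot case, validation", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2))
  y <- c(0.35, 0.10, 0.05, 0.05, 0.35, 0.10)
  expect_equal(kl_divergence(y, y), 0)
  expect_error(kl_divergence(c(1, 0), c(0.5, 0.3, 0.2)), "equal length")
  expect_error(kl_divergence(c(1.2, -0.2), c(0.5, 0.5)), "non-negative")
})

test_that("KL divergence is non-negative, zero only for equal distributions", {
  withr::with_seed(21, {
    for (case in 1:50) {
      s <- sample(2:6, 1)
      p <- random_simplex(s)
      q <- random_simplex(s)
      d <- kl_divergence(p, q)
      expect_gte(d, -1e-12)
      if (max(abs(p - q)) > 1e-3) expect_gt(d, 0)
    }
  })
})

test_that("center update is the membership-weighted profile average", {
  Y <- concatenate_normalize(two_partition_example())
  # c = 1, equal memberships: the column mean
  O <- update_centers(Y, matrix(1, 5, 1), m = 2)
  expect_equal(O[1, ], colMeans(Y))
  # single supporting datum reproduces that datum's row
  Y2 <- rbind(c(1, 0), c(0, 1))
  O2 <- update_centers(Y2, cbind(c(1, 0), c(0, 1)), m = 2)
  expect_equal(O2, diag(2))
  # hand-evaluated fractional case: (0.64, 0.04)/0.68
  O3 <- update_centers(Y2, cbind(c(0.8, 0.2), c(0.2, 0.8)), m = 2)
  expect_equal(O3[1, ], c(0.64, 0.04) / 0.68)
  # empty cluster is an error
  expect_error(update_centers(Y2, cbind(c(1, 1), c(0, 0)), m = 2), "empty cluster")
})

test_that("membership update handles singular, symmetric and generic cases", {
  O <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.1, 0.8))
  # profile equal to a center: all mass there
  U <- update_memberships(O[1, , drop = FALSE], O, m = 2)
  expect_equal(U[1, ], c(1, 0))
  # equidistant profile: symmetric split
  Osym <- rbind(c(0.7, 0.3), c(0.3, 0.7))
  U2 <- update_memberships(matrix(c(0.5, 0.5), 1), Osym, m = 2)
  expect_equal(U2[1, ], c(0.5, 0.5))
  # generic ratio D1 = 0.1, D2 = 0.3 at m = 2 gives 0.75 / 0.25; verify the
  # closed form against divergences computed by the exported kl_divergence
  y <- c(0.6, 0.3, 0.1)
  d <- c(kl_divergence(y, O[1, ]), kl_divergence(y, O[2, ]))
  U3 <- update_memberships(matrix(y, 1), O, m = 2)
  expect_equal(U3[1, 1], 1 / (1 + d[1] / d[2]), tolerance = 1e-12)
  dd <- c(-log(0.9), -log(0.8))
  expect_equal(update_memberships(matrix(c(1, 0), 1),
                                  rbind(c(0.9, 0.1), c(0.8, 0.2)), m = 2)[1, ],
               (1 / dd) / sum(1 / dd), tolerance = 1e-12)
})

test_that("two groups of identical profiles form a zero-divergence fixed point", {
  Y <- rbind(matrix(rep(c(1, 0, 0), 3), 3, byrow = TRUE),
             matrix(rep(c(0, 0, 1), 3), 3, byrow = TRUE))
  fit <- fce_kl_fit(Y, 2, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$objective[length(fit$objective)], 0, tolerance = 1e-10)
  expect_equal(sort(fit$centers[, 1]), c(0, 1), tolerance = 1e-9)
  expect_true(all(apply(fit$memberships, 1, max) > 1 - 1e-9))
})

test_that("duplicating every profile doubles the objective and fixes the centers", {
  Y <- withr::with_seed(8, t(replicate(4, random_simplex(3))))
  init <- Y[1:2, ]
  f1 <- fce_kl_fit(Y, 2, init_centers = init, tol = 1e-12, max_iter = 300)
  f2 <- fce_kl_fit(rbind(Y, Y), 2, init_centers = init, tol = 1e-12, max_iter = 300)
  expect_equal(f2$objective[length(f2$objective)],
               2 * f1$objective[length(f1$objective)], tolerance = 1e-8)
  expect_equal(f2$centers, f1$centers, tolerance = 1e-6)
})

test_that("objective descends and simplex constraints hold on random inputs", {
  for (case in 1:4) {
    Y <- withr::with_seed(30 + case, t(replicate(25, random_simplex(5))))
    fit <- fce_kl_fit(Y, 3, seed = case, tol = 1e-10, max_iter = 200)
    expect_true(all(diff(fit$objective) <= 1e-8))
    expect_row_stochastic(fit$memberships)
    expect_row_stochastic(fit$centers)
    expect_true(all(fit$centers >= 0))
  }
})

test_that("the converged fit is a stationary point of the update pair", {
  Y <- withr::with_seed(77, t(replicate(30, random_simplex(4))))
  fit <- fce_kl_fit(Y, 2, seed = 3, tol = 1e-13, max_iter = 500)
  O2 <- update_centers(Y, fit$memberships, m = 2)
  U2 <- update_memberships(Y, O2, m = 2)
  expect_lt(max(abs(O2 - fit$centers)), 1e-6)
  expect_lt(max(abs(U2 - fit$memberships)), 1e-6)
})

test_that("permuting initial centers permutes clusters and leaves J unchanged", {
  Y <- withr::with_seed(55, t(replicate(12, random_simplex(4))))
  init <- Y[c(2, 9, 5), ]
  f1 <- fce_kl_fit(Y, 3, init_centers = init, tol = 1e-11, max_iter = 300)
  f2 <- fce_kl_fit(Y, 3, init_centers = init[c(3, 1, 2), ], tol = 1e-11, max_iter = 300)
  expect_equal(f2$centers, f1$centers[c(3, 1, 2), ], tolerance = 1e-9)
  expect_equal(f2$memberships, f1$memberships[, c(3, 1, 2)], tolerance = 1e-9)
  expect_equal(f2$objective[length(f2$objective)],
               f1$objective[length(f1$objective)], tolerance = 1e-10)
})

test_that("converged objective matches the brute-force minimizer on tiny instances", {
  withr::with_seed(99, {
    for (case in 1:3) {
      n <- sample(4:5, 1)
      s <- sample(3:4, 1)
      Y <- t(replicate(n, random_simplex(s)))
      expect_equal(best_fce_objective(Y, seeds = 1:4),
                   oracle_fce_min(Y, restarts = 15),
                   tolerance = 1e-4)
    }
  })
})

test_that("spatial consensus: window 1 reproduces the plain fit exactly", {
  ph <- make_two_value_phantom(12)
  noisy <- add_gaussian_noise(ph, 30, seed = 5)
  parts <- generate_basic_partitions(noisy, 2, seed = 2)
  Y <- concatenate_normalize(parts)
  f1 <- fce_kl_fit(Y, 2, seed = 6)
  f2 <- fce_skl_fit(Y, dim(noisy), 2, window = 1, seed = 6)
  expect_identical(f1$memberships, f2$memberships)
  expect_identical(f1$objective, f2$objective)
})

test_that("spatial consensus corrects a flipped-profile pixel that the plain fit keeps", {
  # two clean vertical regions of one-hot profiles with a single flipped pixel
  dims <- c(10, 10)
  lab <- matrix(0L, dims[1], dims[2])
  lab[, 6:10] <- 1L
  truth <- lab
  # mildly soft profiles so divergences stay finite and informative
  Y <- matrix(0.1, prod(dims), 2)
  Y[cbind(seq_len(prod(dims)), as.vector(t(lab)) + 1L)] <- 0.9
  k <- (5 - 1) * dims[2] + 3  # lone flip deep inside region 0
  Y[k, ] <- c(0.4, 0.6)
  init <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  plain <- fce_kl_fit(Y, 2, init_centers = init)
  spatial <- fce_skl_fit(Y, dims, 2, window = 5, init_centers = init)
  lab_plain <- defuzzify(plain$memberships, dims)
  lab_spatial <- defuzzify(spatial$memberships, dims)
  expect_equal(lab_plain[5, 3], 1L)     # plain consensus keeps the flip
  expect_equal(lab_spatial[5, 3], 0L)   # smoothing restores the surroundings
  expect_equal(segmentation_accuracy(lab_spatial, truth), 1)
  expect_row_stochastic(spatial$memberships)
  expect_row_stochastic(spatial$centers)
})

test_that("spatial consensus terminates by tolerance or iteration cap", {
  ph <- make_two_value_phantom(12)
  noisy <- add_gaussian_noise(ph, 40, seed = 9)
  Y <- concatenate_normalize(generate_basic_partitions(noisy, 2, seed = 2))
  fit <- fce_skl_fit(Y, dim(noisy), 2, seed = 4, max_iter = 7, tol = 0)
  expect_false(fit$converged)
  expect_equal(fit$iterations, 7L)
  expect_error(fce_skl_fit(Y, c(12, 13), 2, seed = 1), "do not match grid")
})
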