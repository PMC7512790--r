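# Fuzzy c-means base clusterer.

test_that("well-separated pairs converge to their group means with crisp memberships", {
  fit <- fcm_fit(c(0, 0, 10, 10), c = 2, m = 2, seed = 1, tol = 1e-10, max_iter = 200)
  centers <- sort(fit$centers[, 1])
  expect_equal(centers, c(0, 10), tolerance = 1e-6)
  own <- apply(fit$memberships, 1, max)
  expect_true(all(own > 0.99))
  # converged objective agrees with the independent simplex minimizer
  withr::with_seed(11, {
    expect_equal(fit$objective[length(fit$objective)],
                 oracle_fcm_min(c(0, 0, 10, 10), restarts = 10),
                 tolerance = 1e-6)
  })
})

test_that("degenerate sizes behave: single datum, datum exactly at a center", {
  fit1 <- fcm_fit(5, c = 1, seed = 1)
  expect_equal(fit1$memberships, matrix(1, 1, 1))
  expect_equal(as.numeric(fit1$centers), 5)

  fit2 <- fcm_fit(c(0, 10), c = 2, init_centers = c(0, 10))
  expect_equal(fit2$memberships, diag(2))
  expect_equal(fit2$objective[length(fit2$objective)], 0)
})

test_that("invalid and degenerate configurations are rejected", {
  expect_error(fcm_fit(c(1, 2), c = 3), "invalid configuration")
  expect_error(fcm_fit(rep(3, 10), c = 2), "degenerate")
  expect_error(fcm_fit(c(1, 2, 3), c = 2, m = 1), "invalid configuration")
  expect_error(fcm_fit(c(1, NA, 3), c = 2), "finite")
})

test_that("objective is non-increasing and memberships row-stochastic on random data", {
  for (case in 1:5) {
    x <- withr::with_seed(100 + case, stats::runif(40))
    fit <- fcm_fit(x, c = 3, seed = case, tol = 1e-9, max_iter = 150)
    expect_row_stochastic(fit$memberships)
    expect_true(all(diff(fit$objective) <= 1e-9))
  }
})

test_that("converged objective matches the brute-force minimizer on tiny instances", {
  withr::with_seed(42, {
    for (case in 1:4) {
      n <- sample(3:5, 1)
      x <- stats::runif(n)
      expect_equal(best_fcm_objective(x, seeds = 1:4),
                   oracle_fcm_min(x, restarts = 20),
                   tolerance = 1e-6)
    }
  })
})

test_that("permuting the data permutes membership rows identically", {
  x <- withr::with_seed(5, stats::runif(20))
  perm <- withr::with_seed(6, sample(20))
  init <- c(0.2, 0.8)
  f1 <- fcm_fit(x, 2, init_centers = init, tol = 1e-10)
  f2 <- fcm_fit(x[perm], 2, init_centers = init, tol = 1e-10)
  expect_equal(f2$memberships, f1$memberships[perm, ], tolerance = 1e-12)
  expect_equal(f2$centers, f1$centers, tolerance = 1e-12)
})

test_that("basic partition generation is deterministic, diverse, and configurable", {
  ph <- make_two_value_phantom(20)
  noisy <- add_gaussian_noise(ph, 30, seed = 3)
  parts <- generate_basic_partitions(noisy, 2, seed = 9)
  expect_length(parts, 4)
  expect_named(parts, c("fcm_a", "fcm_b", "sfcm_w3", "sfcm_w5"))
  for (U in parts) expect_row_stochastic(U)
  # deterministic given the seed
  parts2 <- generate_basic_partitions(noisy, 2, seed = 9)
  expect_identical(parts, parts2)
  # the two seeded fcm members differ somewhere
  expect_true(any(parts$fcm_a != parts$fcm_b))
  # single member and unknown member
  one <- generate_basic_partitions(noisy, 2, members = list(f = list(method = "fcm")), seed = 1)
  expect_length(one, 1)
  expect_error(
    generate_basic_partitions(noisy, 2, members = list(x = list(method = "nlsfcm"))),
    "unknown base clusterer"
  )
})
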