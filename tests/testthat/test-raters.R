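test_that("logistic probability follows the psychometric curve", {
  flat <- psychometric_curve(0, 0)
  expect_equal(logistic_probability(flat, c(-3, 0, 0.5, 42)), rep(0.5, 4))
  crv <- psychometric_curve(-6, 12)
  expect_equal(logistic_probability(crv, -(-6) / 12), 0.5)
  expect_equal(logistic_probability(crv, 1), 0.997527, tolerance = 1e-6)
  i <- seq(0, 1, by = 0.01)
  expect_true(all(diff(logistic_probability(crv, i)) > 0)) # monotone
})

test_that("maximum-likelihood fit recovers known psychometric parameters", {
  b <- c(-6, 12)
  sim <- withr::with_seed(101, {
    i <- stats::runif(1e4)
    y <- stats::rbinom(1e4, 1, stats::plogis(b[1] + b[2] * i))
    data.frame(intensity = i, label = y)
  })
  fit <- fit_psychometric(sim)
  se <- attr(fit, "se")
  expect_false(attr(fit, "separation"))
  expect_lt(abs(fit$beta0 - b[1]), 3 * se[1])
  expect_lt(abs(fit$beta1 - b[2]), 3 * se[2])
  # consistency: standard errors shrink with n
  fit_small <- fit_psychometric(sim[1:1000, ])
  expect_true(all(attr(fit_small, "se") > se))
})

test_that("a threshold labeler is flagged as separated, slope capped", {
  i <- seq(0.01, 0.99, length.out = 400)
  fit <- fit_psychometric(i, as.integer(i > 0.5))
  expect_true(attr(fit, "separation"))
  expect_equal(abs(fit$beta1), 150)
  expect_equal(-fit$beta0 / fit$beta1, 0.5, tolerance = 0.02)
})

test_that("symmetric labeling data yield a midpoint near 0.5", {
  sim <- withr::with_seed(7, {
    i <- stats::runif(5e3)
    data.frame(intensity = i,
               label = stats::rbinom(5e3, 1, stats::plogis(10 * (i - 0.5))))
  })
  fit <- fit_psychometric(sim)
  expect_equal(-fit$beta0 / fit$beta1, 0.5, tolerance = 0.05)
})

test_that("degenerate labeling data are rejected", {
  expect_error(fit_psychometric(numeric(0), integer(0)), "non-empty")
  expect_error(fit_psychometric(c(0.2, 0.8), c(1, 1)), "both classes")
  expect_error(fit_psychometric(c(0.2, 0.8), c(2, 0)), "binary")
})

test_that("curve averaging is the arithmetic mean of coefficients", {
  a <- psychometric_curve(-4, 10)
  b <- psychometric_curve(-6, 14)
  avg <- average_curves(list(a, b))
  expect_equal(c(avg$beta0, avg$beta1), c(-5, 12))
  expect_equal(average_curves(list(a, a)), a)
  expect_equal(average_curves(list(b, a)), avg) # permutation invariance
  expect_error(average_curves(list()), "empty")
})

test_that("probabilistic labeling matches its Bernoulli model", {
  img <- image_volume(withr::with_seed(3, array(stats::runif(15^3), rep(15, 3))),
                      grid_spec(2.4, 1, rep(36, 3)))
  all_in <- probabilistic_label(img, psychometric_curve(50, 0), seed = 1)
  expect_true(all(all_in$data))
  none <- probabilistic_label(img, psychometric_curve(-50, 0), seed = 1)
  expect_false(any(none$data))
  crv <- default_curve("joint")
  p <- logistic_probability(crv, img$data)
  counts <- vapply(1:100, function(s) {
    sum(probabilistic_label(img, crv, seed = s)$data)
  }, 0)
  mu <- sum(p)
  se_mean <- sqrt(sum(p * (1 - p)) / 100)
  expect_lt(abs(mean(counts) - mu), 2.58 * se_mean) # 99% envelope
  # reproducible draws; expected mode is deterministic thresholding at 0.5
  expect_identical(probabilistic_label(img, crv, seed = 5)$data,
                   probabilistic_label(img, crv, seed = 5)$data)
  expect_identical(probabilistic_label(img, crv, mode = "expected")$data,
                   array(p >= 0.5, dim(p)))
})

test_that("conjunct masks behave as intersections", {
  g <- grid_spec(2.4, 1, rep(36, 3))
  a <- label_mask(withr::with_seed(1, array(stats::runif(15^3) < 0.4, rep(15, 3))), g)
  b <- label_mask(withr::with_seed(2, array(stats::runif(15^3) < 0.6, rep(15, 3))), g)
  empty <- label_mask(array(FALSE, rep(15, 3)), g)
  expect_identical(conjunct_mask(a, a)$data, a$data)
  expect_identical(conjunct_mask(a, empty)$data, empty$data)
  expect_lte(mask_volume(conjunct_mask(a, b)),
             min(mask_volume(a), mask_volume(b)))
  expect_error(conjunct_mask(a, label_mask(array(TRUE, c(18, 18, 18)),
                                           grid_spec(2.0))), "mismatch")
})

test_that("optimal threshold interpolates the survival function over ties", {
  v <- c(rep(1.0, 300), rep(0.5, 200), rep(0.0, 9500))
  img <- image_volume(array(v, c(100, 100, 1)),
                      grid_spec(0.36, 1, c(36, 36, 0.36)))
  t <- optimal_threshold(img, 0.04)
  expect_gt(as.numeric(t), 0.5)
  expect_lt(as.numeric(t), 1.0)
  expect_equal(as.numeric(t), oracle_survival_threshold(v, 0.04))
  expect_equal(attr(t, "achieved_proportion"), 0.04)
})

test_that("optimal threshold matches the brute-force oracle on random data", {
  for (s in 1:5) {
    v <- withr::with_seed(s, stats::runif(1000)^3)
    img <- image_volume(array(v, c(10, 10, 10)),
                        grid_spec(3.6, 1, rep(36, 3)))
    for (target in c(0.01, 0.1, 0.5, 0.9)) {
      expect_equal(as.numeric(optimal_threshold(img, target)),
                   oracle_survival_threshold(v, target), tolerance = 1e-12)
    }
  }
})

test_that("large-volume histogram path equals the exact small-volume path", {
  v <- withr::with_seed(77, stats::runif(2^21 + 2^19))
  n <- length(v)
  for (target in c(0.003535, 0.25, 1 / n * 1.5)) {
    fast <- voxphantom:::.survival_threshold(v, target)
    expect_equal(fast$threshold, oracle_survival_threshold(v, target),
                 tolerance = 1e-12)
  }
})

test_that("threshold edge cases follow the documented conventions", {
  v <- c(0.9, stats::runif(999, 0, 0.5))
  img <- image_volume(array(v, c(10, 10, 10)), grid_spec(3.6, 1, rep(36, 3)))
  t <- optimal_threshold(img, 1 / 1000) # just the single maximum voxel
  expect_equal(as.numeric(t), 0.9)
  expect_equal(sum(img$data >= as.numeric(t)), 1L)
  const <- image_volume(array(0.5, c(10, 10, 10)), grid_spec(3.6, 1, rep(36, 3)))
  expect_error(optimal_threshold(const, 0.1), "degenerate")
  expect_error(optimal_threshold(img, 0), "in \\(0, 1\\)")
  expect_error(optimal_threshold(img, 1), "in \\(0, 1\\)")
})

test_that("optimal labeling matches the ground-truth proportional volume", {
  e <- ellipsoid()
  pose <- list(base_orientation("diagonal"), sample_rigid_transform(seed = 4))
  img <- simulate_volume(e, grid_spec(0.5), pose)
  m <- optimal_label(img, e)
  expect_equal(attr(m, "continuous_volume"), ellipsoid_volume(e),
               tolerance = 1e-9)
  expect_equal(mask_volume(m), ellipsoid_volume(e), tolerance = 0.01)

  # coarse grid: the discrete volume is within one voxel of the best
  # achievable threshold count
  img2 <- simulate_volume(e, grid_spec(2.0), pose)
  m2 <- optimal_label(img2, e)
  vv <- voxel_volume(grid_spec(2.0))
  counts <- vapply(unique(as.vector(img2$data)),
                   function(t) sum(img2$data >= t), 0)
  best <- min(abs(counts * vv - ellipsoid_volume(e)))
  expect_lte(abs(mask_volume(m2) - ellipsoid_volume(e)), best + vv)
})

test_that("optimal labeling of the oracle image recovers the true shape", {
  e <- ellipsoid()
  pose <- list(base_orientation("orthogonal"), sample_rigid_transform(seed = 8))
  g <- grid_spec(0.2)
  orc <- rasterize_oracle(e, g, pose, subdivisions = 2)
  m <- optimal_label(orc, e)
  membership <- label_mask(rasterize_oracle(e, g, pose, 1)$data >= 0.5, g)
  expect_gt(dice(m, membership), 0.99)
})
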