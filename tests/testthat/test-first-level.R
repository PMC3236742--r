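# First-level GLM machinery: HRF, design, smoothing, OLS, contrasts,
# fixed effects.

test_that("the canonical HRF kernel is peak-normalized with a ~5 s peak and a dead tail", {
  h <- canonical_hrf(dt = 0.1, duration = 32)
  expect_length(h, 320L)
  expect_equal(max(h), 1)
  argmax_s <- (which.max(h) - 1L) * 0.1
  expect_gte(argmax_s, 4.5)
  expect_lte(argmax_s, 5.5)
  expect_lt(abs(h[length(h)]), 0.01)
  expect_error(canonical_hrf(dt = 0), "finite|in \\[")
  expect_error(canonical_hrf(dt = -1), "in \\[")
})

test_that("design matrices have task, confound and intercept columns in order", {
  empty <- data.frame(condition = character(), onset = numeric(),
                      duration = numeric())
  # with no events the three task columns are identically zero
  d0 <- build_design(empty, n_frames = 20L, tr = 2)
  expect_equal(ncol(d0$X), 4L)
  expect_true(all(d0$X[, 1:3] == 0))
  expect_true(all(d0$X[, 4] == 1))

  ev <- data.frame(condition = c("M", "F", "S"), onset = c(4, 20, 40),
                   duration = 2)
  conf <- matrix(rnorm(50 * 6), 50, 6)
  d <- build_design(ev, 50L, tr = 2, confounds = conf)
  expect_equal(ncol(d$X), 10L)   # 3 task + 6 confounds + intercept
  expect_equal(d$names[10], "intercept")
  expect_equal(unname(d$X[, 4:9]), conf)
  expect_error(build_design(ev, 40L, tr = 2, confounds = conf), "frames")
})

test_that("HRF convolution equals the direct discrete-sum oracle", {
  tr <- 2; n_frames <- 60L
  ev <- data.frame(condition = "M",
                   onset = c(4, 10, 30, 90), duration = tr)
  d <- build_design(ev, n_frames, tr)
  h <- canonical_hrf(tr)
  ind <- numeric(n_frames)
  ind[ev$onset / tr + 1L] <- 1
  oracle <- vapply(seq_len(n_frames), function(t) {
    sum(vapply(seq_len(t), function(k) {
      lag <- t - k
      if (lag + 1L <= length(h)) ind[k] * h[lag + 1L] else 0
    }, numeric(1)))
  }, numeric(1))
  expect_equal(unname(d$X[, "M"]), oracle, tolerance = 1e-10)
})

test_that("Gaussian smoothing preserves constants, commutes with shifts, and fwhm 0 is the identity", {
  withr::with_seed(8, dat <- array(rnorm(10 * 10 * 6), c(10, 10, 6)))
  vol <- new_volume(dat, voxel_dims = c(2, 2, 3))
  expect_identical(gaussian_smooth(vol, 0)$data, dat)

  const <- new_volume(array(3.7, c(10, 10, 6)), voxel_dims = c(2, 2, 3))
  expect_equal(gaussian_smooth(const, 9)$data, const$data, tolerance = 1e-10)

  s1 <- gaussian_smooth(vol, 9)$data
  shifted <- new_volume(dat + 5, voxel_dims = c(2, 2, 3))
  expect_equal(gaussian_smooth(shifted, 9)$data, s1 + 5, tolerance = 1e-10)
  expect_error(gaussian_smooth(vol, -1), "in \\[")
})

test_that("voxelwise OLS matches the normal-equations oracle and its residuals are orthogonal", {
  withr::with_seed(9, {
    n <- 40L; gd <- c(3L, 3L, 2L)
    ev <- data.frame(condition = rep(c("M", "F", "S"), each = 4),
                     onset = sort(sample(seq(0, 70, by = 2), 12)),
                     duration = 2)
    des <- build_design(ev, n, tr = 2)
    beta_true <- matrix(rnorm(4 * prod(gd)), 4)
    Y <- des$X %*% beta_true + matrix(rnorm(n * prod(gd), 0, 0.3), n)
  })
  run <- new_volume(array(t(Y), c(gd, n)))
  fit <- fit_glm(run, des)
  oracle <- solve(crossprod(des$X)) %*% crossprod(des$X, Y)
  expect_equal(unname(fit$betas), unname(oracle), tolerance = 1e-8)
  expect_lt(max(abs(crossprod(des$X, Y - des$X %*% fit$betas))), 1e-8)
  expect_equal(fit$dof, n - 4L)

  # noiseless data are recovered exactly
  run0 <- new_volume(array(t(des$X %*% beta_true), c(gd, n)))
  fit0 <- fit_glm(run0, des)
  expect_equal(unname(fit0$betas), unname(beta_true), tolerance = 1e-8)
  expect_true(all(fit0$sigma2 < 1e-16))

  bad <- des
  bad$X <- cbind(des$X, dup = des$X[, "M"])
  bad$names <- c(des$names, "dup")
  expect_error(fit_glm(run, bad), "rank deficient.*dup|dup.*rank deficient")
})

test_that("contrast maps implement c'beta with the OLS variance formula", {
  withr::with_seed(10, {
    n <- 50L
    ev <- data.frame(condition = rep(c("M", "F", "S"), each = 5),
                     onset = sort(sample(seq(0, 90, by = 2), 15)),
                     duration = 2)
    des <- build_design(ev, n, tr = 2)
  })
  gd <- c(2L, 2L, 1L)
  beta <- matrix(1.5, 4, prod(gd))  # equal M and F betas
  run <- new_volume(array(t(des$X %*% beta +
                              matrix(rnorm(n * prod(gd), 0, 0.1), n)),
                          c(gd, n)))
  fit <- fit_glm(run, des)
  cm <- contrast_map(fit, c(1, -1, 0))
  # symmetry: equal planted M and F responses cancel up to noise
  cm0 <- contrast_map(fit_glm(new_volume(array(t(des$X %*% beta), c(gd, n))),
                              des), c(1, -1, 0))
  expect_equal(as.numeric(cm0$effect$data), rep(0, prod(gd)),
               tolerance = 1e-10)
  # identity contrast reproduces the M beta map
  cmM <- contrast_map(fit, c(1, 0, 0))
  expect_equal(as.numeric(cmM$effect$data), unname(fit$betas["M", ]),
               tolerance = 1e-12)
  expect_error(contrast_map(fit, c(1, -1)), "length")
})

test_that("the contrast variance matches a Monte-Carlo replicate SD", {
  withr::with_seed(11, {
    n <- 60L
    ev <- data.frame(condition = rep(c("M", "F", "S"), each = 6),
                     onset = sort(sample(seq(0, 110, by = 2), 18)),
                     duration = 2)
    des <- build_design(ev, n, tr = 2)
    sigma <- 0.8
    reps <- 10000L
    Y <- matrix(rnorm(n * reps, 0, sigma), n)  # zero-signal replicates
  })
  cv <- c(1, 0, -1, 0)
  XtXinv <- solve(crossprod(des$X))
  est <- as.numeric(crossprod(cv, XtXinv %*% crossprod(des$X, Y)))
  analytic <- sigma^2 * as.numeric(crossprod(cv, XtXinv %*% cv))
  expect_equal(var(est), analytic, tolerance = 0.1)
  # and the per-fit variance estimate agrees in expectation
  run <- new_volume(array(t(Y[, 1:50]), c(5L, 5L, 2L, n)))
  fit <- fit_glm(run, des)
  cm <- contrast_map(fit, c(1, 0, -1))
  expect_equal(mean(as.numeric(cm$variance$data)), analytic,
               tolerance = 0.15)
})

test_that("fixed-effects combination weights runs by inverse variance", {
  gd <- c(2L, 2L, 1L)
  mk <- function(x) new_volume(array(x, gd))
  one <- fixed_effects_combine(list(mk(1.3)), list(mk(0.5)))
  expect_equal(as.numeric(one$effect$data), rep(1.3, 4))
  expect_equal(as.numeric(one$variance$data), rep(0.5, 4))

  eq <- fixed_effects_combine(list(mk(1), mk(3)), list(mk(2), mk(2)))
  expect_equal(as.numeric(eq$effect$data), rep(2, 4))

  # variances 1 and 3 -> weights 0.75 / 0.25
  two <- fixed_effects_combine(list(mk(4), mk(8)), list(mk(1), mk(3)))
  expect_equal(as.numeric(two$effect$data), rep(0.75 * 4 + 0.25 * 8, 4))
  expect_equal(as.numeric(two$variance$data), rep(1 / (1 + 1 / 3), 4))
  expect_true(all(two$variance$data <= 1))  # information never decreases

  expect_warning(
    zv <- fixed_effects_combine(list(mk(2), mk(4)), list(mk(0), mk(1))),
    "zero run variance")
  expect_equal(as.numeric(zv$effect$data), rep(3, 4))
  expect_error(fixed_effects_combine(list(), list()), "no runs")
  expect_error(
    fixed_effects_combine(list(mk(1), new_volume(array(1, c(3, 2, 1)))),
                          list(mk(1), new_volume(array(1, c(3, 2, 1))))),
    "grid mismatch")
})
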