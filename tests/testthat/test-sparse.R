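test_that("unregularized fit matches a second-order solver (glm)", {
  set.seed(41)
  X <- matrix(rnorm(50 * 4), 50, 4)
  y <- rbinom(50, 1, plogis(X[, 1] - 0.5 * X[, 2]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  fit <- fit_l1_logistic(X, y, lambda = 0, tol = 1e-12)
  ref <- glm(y ~ X, family = binomial)
  expect_equal(unname(c(fit$intercept, fit$coefficients)),
               unname(coef(ref)), tolerance = 1e-5)
})

test_that("solver beats a fine grid search on a 2-feature instance", {
  set.seed(42)
  X <- matrix(rnorm(30 * 2), 30, 2)
  y <- rbinom(30, 1, plogis(1.5 * X[, 1]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  lambda <- 0.3 * lambda_grid(X, y)[1]
  fit <- fit_l1_logistic(X, y, lambda, tol = 1e-12)
  grid_pts <- expand.grid(x1 = seq(-2, 2, 0.05), x2 = seq(-2, 2, 0.05),
                          c = seq(-1.5, 1.5, 0.1))
  objs <- apply(grid_pts, 1, function(v)
    evoinform:::l1_objective(X, y, v[1:2], v[3], lambda))
  expect_lte(fit$objective, min(objs) + 1e-6)
})

test_that("lambda_max obeys the KKT boundary", {
  set.seed(43)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rep(c(1, 0), each = 20)
  X[, 3] <- X[, 3] + ifelse(y == 1, 1.5, -1.5)  # dominant feature
  lmax <- lambda_grid(X, y)[1]
  at <- fit_l1_logistic(X, y, lmax * (1 + 1e-6), tol = 1e-12)
  expect_length(at$support, 0)
  expect_equal(at$intercept, log(sum(y == 1) / sum(y == 0)), tolerance = 1e-4)
  below <- fit_l1_logistic(X, y, 0.99 * lmax, tol = 1e-12)
  expect_gt(length(below$support), 0)
})

test_that("lambda_grid construction and homogeneity", {
  set.seed(44)
  X <- matrix(rnorm(60), 20, 3)
  y <- rep(c(1, 0), 10)
  g <- lambda_grid(X, y, n_values = 10, ratio = 0.01)
  expect_length(g, 10)
  expect_true(all(diff(g) < 0))
  expect_equal(g[10], 0.01 * g[1])
  expect_equal(lambda_grid(2 * X, y)[1], 2 * g[1])
  # per-feature penalties shift lambda_max
  gp <- lambda_grid(X, y, penalty = c(2, 1, 1))
  grad <- abs(drop(crossprod(X, y - mean(y))))
  expect_equal(gp[1], max(grad / c(2, 1, 1)))
  expect_error(lambda_grid(matrix(0, 20, 3), y), "degenerate")
})

test_that("weighted problem rescales to the adaptive-penalty optimum", {
  set.seed(45)
  for (rep in 1:5) {
    X <- matrix(rnorm(40 * 10), 40, 10)
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    W <- runif(10, 0.5, 3)
    Xw <- sweep(X, 2, W, "*")
    lambda <- 0.3 * lambda_grid(Xw, y)[1]
    f1 <- fit_l1_logistic(Xw, y, lambda, tol = 1e-12)
    z <- W * f1$coefficients
    f2 <- fit_l1_logistic(X, y, lambda, penalty = 1 / W, tol = 1e-12)
    obj_rescaled <- evoinform:::l1_objective(X, y, z, f1$intercept, lambda,
                                             penalty = 1 / W)
    gap <- (obj_rescaled - f2$objective) / max(1, abs(f2$objective))
    expect_lt(abs(gap), 1e-4)
  }
})

test_that("support size is non-increasing along the lambda path", {
  set.seed(46)
  X <- matrix(rnorm(60 * 12), 60, 12)
  y <- rep(c(1, 0), each = 30)
  X[, 1] <- X[, 1] + ifelse(y == 1, 1, -1)
  grid <- lambda_grid(X, y, 12, 0.01)
  sizes <- sapply(grid, function(l)
    length(fit_l1_logistic(X, y, l, tol = 1e-10)$support))
  expect_true(all(diff(sizes) >= -1))  # tolerance-level flicker allowed
  expect_gte(sizes[12], sizes[1])
})

test_that("stability selection ranks planted signal first and is reproducible", {
  set.seed(47)
  X <- matrix(rnorm(60 * 20), 60, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- rep(c(0, 1), each = 30)
  X[, 1] <- X[, 1] + ifelse(y == 1, 1.5, -1.5)
  sp <- stability_select(X, y, n_bootstraps = 40, seed = 9)
  expect_true(all(sp$frequency >= 0 & sp$frequency <= 1))
  expect_equal(names(which.max(sp$frequency)), "f1")
  expect_gt(sp$frequency["f1"], 0.9)
  expect_true("f1" %in% sp$selected)
  # bit-identical under the same seed; the global RNG stream is untouched
  rng_before <- .Random.seed
  sp2 <- stability_select(X, y, n_bootstraps = 40, seed = 9)
  expect_identical(sp, sp2)
  expect_identical(rng_before, .Random.seed)
})

test_that("chance selections on pure noise are few", {
  counts <- sapply(1:5, function(s) {
    set.seed(s + 400)
    X <- matrix(rnorm(60 * 20), 60, 20)
    y <- rep(c(0, 1), each = 30)
    length(stability_select(X, y, n_bootstraps = 30, seed = s)$selected)
  })
  expect_lt(mean(counts), 20 * 0.5)   # far below the feature count
})

test_that("the threshold is strict: frequency equal to it is not selected", {
  set.seed(48)
  X <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(c(0, 1), each = 20)
  sp <- stability_select(X, y, n_bootstraps = 20, seed = 2)
  at <- sp$frequency[1]
  resel <- stability_select(X, y, n_bootstraps = 20, seed = 2, threshold = at)
  expect_false("f1" %in% resel$selected)
  strictly_below <- stability_select(X, y, n_bootstraps = 20, seed = 2,
                                     threshold = at - 1e-9)
  expect_true("f1" %in% strictly_below$selected)
})

test_that("raising one feature's weight never lowers its selection frequency", {
  set.seed(49)
  X <- matrix(rnorm(60 * 10), 60, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rep(c(0, 1), each = 30)
  X[, 2] <- X[, 2] + ifelse(y == 1, 0.4, -0.4)  # weak signal
  freqs <- sapply(c(0.5, 1, 2, 4), function(k) {
    Xw <- X; Xw[, 2] <- k * X[, 2]
    mean(sapply(1:4, function(s)
      stability_select(Xw, y, n_bootstraps = 15, seed = s)$frequency["f2"]))
  })
  expect_true(all(diff(freqs) >= -0.02))  # non-decreasing up to MC noise
})

test_that("subsample mode draws half-size resamples and still works", {
  set.seed(50)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- rep(c(0, 1), each = 30)
  X[, 1] <- X[, 1] + ifelse(y == 1, 1.5, -1.5)
  sp <- stability_select(X, y, n_bootstraps = 20, seed = 3, subsample = TRUE)
  expect_equal(names(which.max(sp$frequency)), "f1")
})

test_that("solver rejects degenerate inputs", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_l1_logistic(X, rep(1, 10), 0.1), "both classes")
  expect_error(fit_l1_logistic(X, rep(c(1, 0), 5), -1), "lambda")
  Xb <- X; Xb[1, 1] <- NA
  expect_error(fit_l1_logistic(Xb, rep(c(1, 0), 5), 0.1), "non-finite")
  expect_error(fit_l1_logistic(X, c(rep(2, 5), rep(0, 5)), 0.1), "labels")
})
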