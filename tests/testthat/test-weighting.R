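test_that("labeled_matrix validates its inputs", {
  X <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("s", 1:4), paste0("f", 1:3)))
  lm <- labeled_matrix(X, c(1, 0, 1, 0))
  expect_false(lm$z_scored)
  expect_error(labeled_matrix(X, c(1, 0, 2, 0)), "binary")
  expect_error(labeled_matrix(X, c(1, 0)), "one entry per sample")
  X2 <- X; rownames(X2) <- c("a", "a", "b", "c")
  expect_error(labeled_matrix(X2, c(1, 0, 1, 0)), "duplicate sample")
})

test_that("statistical weights match the hand-computed pooled t test", {
  # classes {1,2,3} vs {4,5,6}: pooled sd 1, se = sqrt(2/3), t = -3/se
  X <- matrix(c(4, 5, 6, 1, 2, 3), ncol = 1, dimnames = list(NULL, "f"))
  lm <- labeled_matrix(X, c(1, 1, 1, 0, 0, 0))
  ws <- statistical_weights(lm)
  t_hand <- 3 / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(ws$t, t_hand, tolerance = 1e-12)
  expect_equal(ws$t, 3.674, tolerance = 1e-3)
  expect_equal(ws$df, 4)
  ref <- t.test(X[1:3, 1], X[4:6, 1], var.equal = TRUE)
  expect_equal(ws$p, ref$p.value, tolerance = 1e-12)
  expect_equal(ws$WS, -log10(ref$p.value))
})

test_that("statistical weights agree with t.test across random features", {
  set.seed(21)
  X <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(c(1, 0), c(12, 18))
  ws <- statistical_weights(labeled_matrix(X, y))
  for (j in 1:8) {
    ref <- t.test(X[y == 1, j], X[y == 0, j], var.equal = TRUE)$p.value
    expect_equal(ws$p[j], ref, tolerance = 1e-12)
  }
  welch <- statistical_weights(labeled_matrix(X, y), var_equal = FALSE)
  ref_w <- t.test(X[y == 1, 1], X[y == 0, 1])$p.value
  expect_equal(welch$p[1], ref_w, tolerance = 1e-12)
})

test_that("WS is label-swap invariant and handles degenerate features", {
  set.seed(22)
  X <- cbind(flat = rep(2, 20), noise = rnorm(20))
  y <- rep(c(1, 0), 10)
  expect_warning(ws <- statistical_weights(labeled_matrix(X, y)),
                 "zero-variance")
  expect_equal(ws$p[1], 1)      # identical in both classes -> no association
  expect_equal(ws$WS[1], 0)
  expect_warning(ws_swap <- statistical_weights(labeled_matrix(X, 1 - y)),
                 "zero-variance")
  expect_equal(ws$p, ws_swap$p)
  # separated constants hit the floor
  X2 <- cbind(sep = rep(c(1, 0), 10), noise = rnorm(20))
  expect_warning(ws2 <- statistical_weights(labeled_matrix(X2, rep(c(1, 0), 10))),
                 "zero-variance")
  expect_equal(ws2$p[1], 1e-300)
  expect_equal(ws2$WS[1], 300)
  expect_error(statistical_weights(labeled_matrix(X[1:3, ], c(1, 0, 0))),
               "at least 2")
})

test_that("z_normalize centers and scales with the sample-sd convention", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 10, 20))
  expect_warning(z <- z_normalize(labeled_matrix(X, c(1, 0, 1))),
                 "zero-variance")
  expect_equal(colnames(z$values), c("a", "c"))   # constant feature dropped
  expect_equal(unname(z$values[, "a"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(z$values)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z$values, 2, sd)), c(1, 1), tolerance = 1e-12)
  # stored transform sends a new sample at the training mean to zero
  new <- matrix(c(2, 5, 10), 1, dimnames = list("new", c("a", "b", "c")))
  expect_equal(unname(apply_z_transform(new, z$center, z$scale)[1, ]),
               c(0, 0))
  expect_error(apply_z_transform(new[, 1, drop = FALSE], z$center, z$scale),
               "missing feature")
  expect_error(z_normalize(z), "already z-scored")
  expect_error(z_normalize(labeled_matrix(cbind(k = rep(1, 4)), c(1, 0, 1, 0))),
               "zero variance")
})

test_that("assemble_weights applies the clinical max-WE and sum rules", {
  cons <- data.frame(gene_id = c("g1", "g2", "g3"), WE = c(0.1, 0.25, 0.2))
  meta <- data.frame(feature_id = c("m1", "m2", "m3", "c1"),
                     kind = c("molecular", "molecular", "molecular", "clinical"),
                     gene_id = c("g1", "g2", "g3", NA))
  ws <- data.frame(feature_id = meta$feature_id, WS = c(2, 0, 1, 3))
  w <- assemble_weights(cons, meta, ws)
  expect_equal(w$WE, c(0.1, 0.25, 0.2, 0.25))   # clinical gets the max
  expect_equal(w$W, w$WE + w$WS)
  expect_equal(w$W[1], 2.1)

  # order independence
  shuf <- c(3, 1, 4, 2)
  w2 <- assemble_weights(cons[c(2, 3, 1), ], meta[shuf, ], ws[c(4, 2, 3, 1), ])
  expect_equal(w2$W[match(w$feature_id, w2$feature_id)], w$W)

  # zeroed evolutionary scale propagates through the clinical rule
  w_s <- assemble_weights(cons, meta, ws, we_scale = 0)
  expect_equal(w_s$W, w_s$WS)

  expect_error(assemble_weights(cons, meta[meta$kind == "clinical", ], ws),
               "no molecular")
  meta_bad <- meta; meta_bad$gene_id[1] <- NA
  expect_error(assemble_weights(cons, meta_bad, ws), "without a gene link")
  meta_bad2 <- meta; meta_bad2$gene_id[1] <- "nope"
  expect_error(assemble_weights(cons, meta_bad2, ws), "finite WE")
})

test_that("apply_weights multiplies features and leaves the original intact", {
  set.seed(30)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  z <- z_normalize(labeled_matrix(X, rep(c(1, 0), 5)))
  w1 <- data.frame(feature_id = paste0("f", 1:4), W = rep(1, 4))
  expect_equal(apply_weights(z, w1)$values, z$values)
  w <- data.frame(feature_id = paste0("f", 1:4), W = c(2.25, 1, 0.5, 3))
  zw <- apply_weights(z, w)
  expect_equal(zw$values[, 1], 2.25 * z$values[, 1])
  # homogeneity: doubling W doubles the weighted matrix
  w2 <- w; w2$W <- 2 * w$W
  expect_equal(apply_weights(z, w2)$values, 2 * zw$values)
  expect_error(apply_weights(z, w[1:3, ]), "missing weight")
  expect_error(apply_weights(labeled_matrix(X, rep(c(1, 0), 5)), w),
               "z-scored")
})
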