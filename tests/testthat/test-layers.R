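test_that("identity-initialized first-iteration expansion reproduces its input", {
  x <- array(rnorm(3 * 1 * 4 * 4), c(3, 1, 4, 4))
  params <- list(w1 = 1, b1 = 0, w2 = matrix(1, 1, 1), b2 = 0)
  expect_equal(expand_heads_first(x, params)[, 1, , ], x[, 1, , ],
               tolerance = 1e-12)
  expect_error(expand_heads_first(array(0, c(2, 3, 4, 4)), params), "single head")
})

test_that("first-iteration expansion reaches the configured head count", {
  set.seed(20)
  m <- build_model(model_config(), seed = 1)
  x <- array(runif(4 * 1 * 48 * 48), c(4, 1, 48, 48))
  out <- expand_heads_first(x, m$params$iter1$q)
  expect_equal(dim(out), c(4L, 64L, 48L, 48L))
})

test_that("double-layer expansion parameter count matches weight enumeration", {
  p <- chanattn:::init_expand_params(64)
  n <- length(p$w1) + length(p$b1) + length(p$w2) + length(p$b2)
  expect_equal(n, (1 * 64 + 64) + (64 * 64 + 64))
  expect_equal(multihead_param_count(1, 64, 48, 48, "conv", first = TRUE), n)
})

test_that("uniform single-head mixing is the head mean; general case matches a loop", {
  set.seed(21)
  x <- array(rnorm(2 * 5 * 3 * 3), c(2, 5, 3, 3))
  pm <- list(w = matrix(1 / 5, 1, 5), b = 0)
  out <- mix_heads(x, pm)
  expect_equal(out[, 1, , ], apply(x, c(1, 3, 4), mean), tolerance = 1e-12)
  # explicit loop oracle for a 5 -> 3 mixing
  pm2 <- list(w = matrix(rnorm(15), 3, 5), b = rnorm(3))
  out2 <- mix_heads(x, pm2)
  for (o in 1:3) {
    ref <- array(pm2$b[o], c(2, 3, 3))
    for (m in 1:5) ref <- ref + pm2$w[o, m] * x[, m, , ]
    expect_equal(out2[, o, , ], ref, tolerance = 1e-12)
  }
})

test_that("adaptive pooling: squeeze is the global channel mean", {
  set.seed(22)
  x <- array(rnorm(3 * 4 * 6 * 6), c(3, 4, 6, 6))
  out <- adaptive_pool(x, squeeze_channels = TRUE)
  expect_equal(dim(out), c(4L, 1L, 1L, 1L))
  for (m in 1:4) expect_equal(out[m, 1, 1, 1], mean(x[, m, , ]))
})

test_that("divisible spatial pooling is exact block averaging", {
  set.seed(23)
  x <- array(rnorm(2 * 3 * 48 * 48), c(2, 3, 48, 48))
  out <- adaptive_pool(x, pool_target = c(3, 24, 24))
  expect_equal(dim(out), c(2L, 3L, 24L, 24L))
  blk <- x[2, 1, 5:6, 11:12]
  expect_equal(out[2, 1, 3, 6], mean(blk), tolerance = 1e-12)
  expect_error(adaptive_pool(x, pool_target = c(3, 50, 24)), "exceeds")
})

test_that("head-axis pooling uses adaptive regions", {
  x <- array(0, c(1, 4, 2, 2))
  x[1, , 1, 1] <- c(1, 3, 5, 7)
  out <- adaptive_pool(x, pool_target = c(2, 2, 2))
  expect_equal(out[1, , 1, 1], c(2, 6))   # means of head pairs
})

test_that("standard comparator: M = 1 with identity map returns the head", {
  set.seed(24)
  x <- array(rnorm(2 * 1 * 3 * 3), c(2, 1, 3, 3))
  p <- list(w = diag(9), b = numeric(9))
  expect_equal(standard_multihead(x, p), x, tolerance = 1e-12)
})

test_that("standard comparator is head-order sensitive unlike a symmetric map", {
  set.seed(25)
  x <- array(rnorm(1 * 2 * 2 * 2), c(1, 2, 2, 2))
  p <- chanattn:::init_std_params(2, 2, 2, 2)
  xs <- x[, 2:1, , , drop = FALSE]
  expect_gt(max(abs(standard_multihead(x, p) - standard_multihead(xs, p))), 1e-8)
})

test_that("conv head mixing needs strictly fewer parameters at every stage", {
  stages <- list(list(m = 1, o = 64, s = 48, first = TRUE),
                 list(m = 64, o = 128, s = 24, first = FALSE),
                 list(m = 128, o = 256, s = 12, first = FALSE))
  for (st in stages) {
    conv <- multihead_param_count(st$m, st$o, st$s, st$s, "conv", st$first)
    std <- multihead_param_count(st$m, st$o, st$s, st$s, "standard")
    expect_lt(conv, std)
  }
})
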