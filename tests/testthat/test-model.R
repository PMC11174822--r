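test_that("the default configuration matches its reference budget and shapes", {
  m <- build_model(model_config(), seed = 1)
  expect_equal(count_parameters(m), 830216)
  set.seed(1)
  fw <- predict_window(m, array(runif(4 * 48 * 48), c(4, 48, 48)))
  expect_length(fw$vmh, 256)
  expect_equal(sum(fw$probs), 1, tolerance = 1e-9)
})

test_that("Q/K/V projections share shape but not parameters", {
  m <- build_model(tiny_config(), seed = 2)
  x <- array(runif(2 * 1 * 8 * 8), c(2, 1, 8, 8))
  qkv <- project_qkv(x, m$params$iter1, first = TRUE)
  expect_equal(dim(qkv$Q), c(2L, 3L, 8L, 8L))
  expect_equal(dim(qkv$K), dim(qkv$Q))
  expect_gt(max(abs(qkv$Q - qkv$K)), 1e-6)
  # identical projection weights force Q = K = V
  m$params$iter1$k <- m$params$iter1$q
  m$params$iter1$v <- m$params$iter1$q
  qkv2 <- project_qkv(x, m$params$iter1, first = TRUE)
  expect_identical(qkv2$Q, qkv2$K)
  expect_identical(qkv2$Q, qkv2$V)
})

test_that("total projection parameters across the default schedule add up", {
  m <- build_model(model_config(), seed = 3)
  qkv_total <- sum(vapply(1:3, function(i)
    chanattn:::count_scalars(m$params[[paste0("iter", i)]]), numeric(1)))
  per_proj <- multihead_param_count(1, 64, 48, 48, "conv", first = TRUE) +
    multihead_param_count(64, 128, 24, 24, "conv") +
    multihead_param_count(128, 256, 12, 12, "conv")
  expect_equal(qkv_total, 3 * per_proj)
  expect_equal(qkv_total, 136896)
})

test_that("the iteration chain reproduces the reference shape schedule", {
  m <- build_model(model_config(), seed = 4)
  x <- array(runif(4 * 1 * 48 * 48), c(4, 1, 48, 48))
  h1 <- run_iteration(x, m, 1)
  expect_equal(dim(h1), c(4L, 64L, 24L, 24L))
  h2 <- run_iteration(h1, m, 2)
  expect_equal(dim(h2), c(4L, 128L, 12L, 12L))
  h3 <- run_iteration(h2, m, 3)
  expect_equal(dim(h3), c(256L, 1L, 1L, 1L))
})

test_that("one trunk instance runs any channel count without re-instantiation", {
  m <- build_model(tiny_config(), seed = 5)
  n_params <- count_parameters(m, trunk_only = TRUE)
  for (C in c(3, 4, 8)) {
    fw <- predict_window(m, array(runif(C * 8 * 8), c(C, 8, 8)))
    expect_length(fw$vmh, 5)
    expect_equal(count_parameters(m, trunk_only = TRUE), n_params)
  }
})

test_that("the feature vector is invariant to channel permutation", {
  m <- build_model(model_config(), seed = 6)
  set.seed(6)
  S <- array(runif(4 * 48 * 48), c(4, 48, 48))
  f1 <- predict_window(m, S)
  f2 <- predict_window(m, S[c(3, 1, 4, 2), , ])
  rel <- max(abs(f1$vmh - f2$vmh)) / max(abs(f1$vmh))
  expect_lt(rel, 1e-5)
  expect_lt(max(abs(f1$probs - f2$probs)), 1e-6)
})

test_that("a tiny iteration equals the composition of its oracle-checked parts", {
  cfg <- tiny_config(heads = c(3, 4), spec_size = 8)
  m <- build_model(cfg, seed = 7)
  set.seed(7)
  x <- array(runif(2 * 1 * 8 * 8), c(2, 1, 8, 8))
  got <- run_iteration(x, m, 1)
  # manual composition: project -> per-head patches -> attention -> fold -> pool
  qkv <- project_qkv(x, m$params$iter1, first = TRUE)
  M <- dim(qkv$Q)[2]
  vprime <- array(0, dim(qkv$V))
  for (h in seq_len(M)) {
    qp <- extract_patches(qkv$Q[, h, , ], kernel = 2, stride = 2)
    kp <- extract_patches(qkv$K[, h, , ], kernel = 2, stride = 2)
    vp <- extract_patches(qkv$V[, h, , ], kernel = 2, stride = 2)
    orc <- oracle_attention(qp$values, kp$values, vp$values)
    vp$values <- orc$out
    vprime[, h, , ] <- fold_patches(vp)
  }
  ref <- adaptive_pool(vprime, pool_target = c(3, 4, 4))
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("head-importance gate matches its scalar definition", {
  D <- 5
  params <- list(w = matrix(0, D, D), b = numeric(D))
  v <- rnorm(D)
  expect_equal(head_importance(v, params), 0.5 * v, tolerance = 1e-12)
  set.seed(8)
  params <- list(w = matrix(rnorm(D * D), D), b = rnorm(D))
  got <- head_importance(v, params)
  gates <- 1 / (1 + exp(-(params$w %*% v + params$b)))
  expect_equal(got, as.vector(gates) * v, tolerance = 1e-12)
  expect_true(all(gates > 0 & gates < 1))
  expect_error(head_importance(rnorm(3), params), "length")
})

test_that("gating is monotone in the gate pre-activation", {
  D <- 4
  v <- c(2, -1, 0.5, 3)
  base <- list(w = matrix(0, D, D), b = numeric(D))
  up <- base; up$b[1] <- 1
  expect_gt(abs(head_importance(v, up)[1]), abs(head_importance(v, base)[1]))
})

test_that("classifier produces normalized probabilities and exact log-loss", {
  params <- list(fc1 = list(w = matrix(0, 4, 5), b = numeric(4)),
                 fc2 = list(w = matrix(0, 3, 4), b = numeric(3)))
  p <- classify(rnorm(5), params)
  expect_equal(p, rep(1 / 3, 3), tolerance = 1e-12)   # zero weights -> uniform
  set.seed(9)
  params$fc1$w <- matrix(rnorm(20), 4); params$fc1$b <- rnorm(4)
  params$fc2$w <- matrix(rnorm(12), 3); params$fc2$b <- rnorm(3)
  v <- rnorm(5)
  p <- classify(v, params)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p > 0 & p < 1))
  # hand-computed cross-entropy for a labeled toy batch
  h <- pmax(params$fc1$w %*% v + params$fc1$b, 0)
  logits <- as.vector(params$fc2$w %*% h + params$fc2$b)
  ref <- exp(logits) / sum(exp(logits))
  expect_equal(p, ref, tolerance = 1e-9)
  expect_equal(-log(p[2]), -log(ref[2]), tolerance = 1e-9)
})

test_that("fully connected 256 -> 256 layer counts 65,792 parameters", {
  m <- build_model(model_config(), seed = 10)
  expect_equal(chanattn:::count_scalars(m$params$gate), 256 * 256 + 256)
})

test_that("ablation switches change the assembled model", {
  cfg_off <- tiny_config(head_importance = FALSE)
  m <- build_model(cfg_off, seed = 11)
  expect_null(m$params$gate)
  fw <- predict_window(m, array(runif(2 * 8 * 8), c(2, 8, 8)))
  expect_identical(fw$vmh, fw$feature)     # gate bypassed
  cfg_std <- tiny_config(multihead = "standard")
  ms <- build_model(cfg_std, seed = 11)
  expect_equal(dim(ms$params$iter2$q$w), c(4L * 16L, 3L * 16L))
  fw2 <- predict_window(ms, array(runif(2 * 8 * 8), c(2, 8, 8)))
  expect_equal(sum(fw2$probs), 1, tolerance = 1e-9)
  expect_gt(count_parameters(ms), count_parameters(build_model(tiny_config(), 11)))
})
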