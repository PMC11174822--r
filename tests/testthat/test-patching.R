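test_that("patch-group counts match explicit position enumeration", {
  expect_equal(count_patch_groups(c(48, 48), c(2, 2), 2), 576)
  expect_equal(count_patch_groups(c(7, 9), c(1, 1), 1), 63)
  expect_equal(count_patch_groups(c(5, 5), c(2, 2), 1), 16)
  set.seed(42)
  for (r in 1:50) {
    H <- sample(2:30, 1); W <- sample(2:30, 1)
    kh <- sample(1:min(4, H), 1); kw <- sample(1:min(4, W), 1)
    stride <- sample(1:4, 1)
    expect_equal(count_patch_groups(c(H, W), c(kh, kw), stride),
                 length(oracle_patch_positions(H, W, kh, kw, stride)),
                 info = sprintf("H=%d W=%d k=%dx%d s=%d", H, W, kh, kw, stride))
  }
  expect_error(count_patch_groups(c(4, 4), c(5, 2), 1), "larger than")
})

test_that("extract_patches unfolds row-major kernel windows", {
  m <- array(matrix(1:4, 2, 2, byrow = TRUE), c(1, 2, 2))
  p <- extract_patches(m, kernel = 2, stride = 2)
  expect_equal(dim(p$values), c(1L, 4L, 1L))
  expect_equal(as.vector(p$values), c(1, 2, 3, 4))  # row-major flattening

  m2 <- array(0, c(1, 4, 4))
  m2[1, , ] <- matrix(1:16, 4, 4, byrow = TRUE)
  p2 <- extract_patches(m2, kernel = 2, stride = 2)
  expect_equal(dim(p2$values), c(1L, 4L, 4L))
  # group order is row-major over positions; first group is the top-left window
  expect_equal(p2$values[1, , 1], c(1, 2, 5, 6))
  expect_equal(p2$values[1, , 2], c(3, 4, 7, 8))
  expect_equal(p2$values[1, , 3], c(9, 10, 13, 14))

  m3 <- array(rnorm(3 * 48 * 48), c(3, 48, 48))
  p3 <- extract_patches(m3, kernel = 2, stride = 2)
  expect_equal(dim(p3$values), c(3L, 4L, 576L))
  expect_equal(dim(p3$values)[3], count_patch_groups(c(48, 48), c(2, 2), 2))
})

test_that("fold is the exact inverse for non-overlapping strides", {
  set.seed(4)
  x <- array(rnorm(2 * 6 * 8), c(2, 6, 8))
  p <- extract_patches(x, kernel = 2, stride = 2)
  expect_identical(fold_patches(p), x)   # pure rearrangement, zero error
})

test_that("constant patches fold to a constant map under overlap", {
  p <- extract_patches(array(5, c(1, 5, 5)), kernel = 2, stride = 1)
  f <- fold_patches(p)
  expect_equal(as.vector(f), rep(5, 25))
})

test_that("overlapping fold equals the scatter-and-divide oracle", {
  set.seed(5)
  for (geom in list(c(3, 3, 2, 2, 1), c(5, 4, 2, 2, 1), c(6, 6, 3, 3, 2))) {
    H <- geom[1]; W <- geom[2]; kh <- geom[3]; kw <- geom[4]; s <- geom[5]
    x <- array(rnorm(2 * H * W), c(2, H, W))
    p <- extract_patches(x, kernel = c(kh, kw), stride = s)
    expect_equal(fold_patches(p), oracle_fold(p$values, H, W, kh, kw, s),
                 tolerance = 1e-12)
  }
})

test_that("patch extraction commutes with channel permutation", {
  set.seed(6)
  x <- array(rnorm(4 * 6 * 6), c(4, 6, 6))
  perm <- c(3, 1, 4, 2)
  p1 <- extract_patches(x[perm, , ], kernel = 2, stride = 2)
  p2 <- extract_patches(x, kernel = 2, stride = 2)
  expect_identical(p1$values, p2$values[perm, , ])
})

test_that("extract B always equals count_patch_groups", {
  set.seed(7)
  for (r in 1:10) {
    H <- sample(3:15, 1); W <- sample(3:15, 1)
    k <- c(sample(1:3, 1), sample(1:3, 1)); s <- sample(1:3, 1)
    if (any(k > c(H, W))) next
    p <- extract_patches(array(rnorm(H * W), c(1, H, W)), k, s)
    expect_equal(dim(p$values)[3], count_patch_groups(c(H, W), k, s))
  }
})
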