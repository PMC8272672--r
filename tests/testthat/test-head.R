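test_that("train-mode batch normalization standardizes a batch", {
  p <- bnParams(1)
  out <- batchNormalize(c(1, 2, 3), p, "train")$values
  expect_equal(mean(out), 0, tolerance = 1e-12)
  expect_equal(mean(out^2), 1, tolerance = 1e-3)   # biased variance vs eps guard
})

test_that("a constant batch collapses to the shift parameter", {
  p <- bnParams(1, scale = 2, shift = 3)
  out <- batchNormalize(c(5, 5, 5), p, "train")$values
  expect_equal(out, c(3, 3, 3), tolerance = 1e-9)
})

test_that("batch normalization matches the direct formula to 1e-10", {
  set.seed(2)
  x <- matrix(rnorm(40, 3, 2), 10, 4)
  p <- bnParams(4, scale = c(1, 2, 0.5, -1), shift = c(0, 1, -2, 0.3))
  got <- batchNormalize(x, p, "train")$values
  for (j in 1:4) {
    q <- mean(x[, j]); v <- mean((x[, j] - q)^2)  # biased variance
    ref <- p@scale[j] * (x[, j] - q) / sqrt(v + p@eps) + p@shift[j]
    expect_equal(got[, j], ref, tolerance = 1e-10)
  }
})

test_that("eval mode applies the running moments from training", {
  set.seed(3)
  xtr <- matrix(rnorm(30, 1, 2), 10, 3)
  xev <- matrix(rnorm(15), 5, 3)
  fit <- batchNormalize(xtr, bnParams(3), "train")
  got <- batchNormalize(xev, fit$params, "eval")$values
  q <- colMeans(xtr); v <- colMeans(sweep(xtr, 2, q)^2)
  ref <- sweep(sweep(xev, 2, q), 2, sqrt(v + 1e-5), "/")
  expect_equal(got, ref, tolerance = 1e-10)
  expect_error(batchNormalize(xev, bnParams(3), "eval"), "train-mode")
})

test_that("train-mode output is standardized for any batch with spread", {
  set.seed(4)
  for (rep in 1:5) {
    x <- matrix(runif(60, -5, 5), 20, 3)
    out <- batchNormalize(x, bnParams(3), "train")$values
    expect_equal(unname(colMeans(out)), rep(0, 3), tolerance = 1e-10)
    expect_equal(unname(colMeans(out^2)), rep(1, 3), tolerance = 1e-3)
  }
})

test_that("relu clamps below zero and passes positives", {
  expect_identical(relu(-1), 0)
  expect_identical(relu(3), 3)
  expect_identical(relu(c(-2, 0, 7)), c(0, 0, 7))
  m <- matrix(c(-1, 2, -3, 4), 2, 2)
  expect_identical(relu(m), matrix(c(0, 2, 0, 4), 2, 2))
})

test_that("adaptive max pooling follows the stride/kernel rule", {
  set.seed(5)
  m7 <- matrix(rnorm(49), 7, 7)
  expect_equal(adaptiveMaxPool(m7, 7), m7)              # stride 1, kernel 1
  m14 <- matrix(rnorm(196), 14, 14)
  expect_equal(adaptiveMaxPool(m14, 7), naiveMaxPool(m14, 2, 2))
  m10 <- matrix(rnorm(100), 10, 10)
  got <- adaptiveMaxPool(m10, 3)                        # stride 3, kernel 4
  expect_equal(got, naiveMaxPool(m10, 4, 3))
  for (i in 1:3) for (j in 1:3)
    expect_equal(got[i, j],
                 max(m10[(i - 1) * 3 + 1:4, (j - 1) * 3 + 1:4]))
  expect_error(adaptiveMaxPool(m10, 11), "exceeds")
})

test_that("adaptive max pooling equals the sliding-window oracle on all small sizes", {
  set.seed(6)
  for (In in 1:16) {
    m <- matrix(rnorm(In * In), In, In)
    for (Out in 1:In) {
      stride <- In %/% Out
      kernel <- In - (Out - 1) * stride
      expect_equal(adaptiveMaxPool(m, Out), naiveMaxPool(m, kernel, stride),
                   info = sprintf("In=%d Out=%d", In, Out))
    }
  }
})

test_that("the deep projection has the configured dimension and affine form", {
  pr <- randomProjection(8, outDim = 1026, seed = 1)
  expect_identical(length(projectDeepFeatures(numeric(8), pr)), 1026L)
  pr2 <- randomProjection(32, outDim = 1026, seed = 2)
  expect_identical(length(projectDeepFeatures(runif(32), pr2)), 1026L)
  # hand-set 2 -> 3 affine on (1, 2)
  toy <- list(w = matrix(c(1, 0, -1, 2, 0.5, 0.25), 2, 3), b = c(0.1, -10, 0))
  expect_equal(projectDeepFeatures(c(1, 2), toy),
               pmax(0, c(1 + 0 + 0.1, -1 + 4 - 10, 0.5 + 0.5)), tolerance = 1e-12)
  expect_error(projectDeepFeatures(numeric(5), pr), "does not match")
})

test_that("traditional features are fixed-length, deterministic and finite", {
  img <- generateDataset(phantomConfig(nImages = 1, seed = 13))[[1]]
  f1 <- traditionalFeatures(img); f2 <- traditionalFeatures(img)
  expect_identical(f1, f2)
  expect_identical(length(f1), 32L)
  expect_true(all(is.finite(f1)))
  expect_identical(anyDuplicated(names(f1)), 0L)
})

test_that("degenerate constant images take the zero conventions", {
  f <- traditionalFeatures(matrix(0.5, 40, 40))
  expect_identical(unname(f["int_sd"]), 0)
  expect_identical(unname(f["hist_entropy"]), 0)
  expect_identical(unname(f["glcm_contrast"]), 0)
  expect_identical(unname(f["glcm_correlation"]), 0)
  expect_identical(unname(f["grad_mag_mean"]), 0)
})

test_that("mean intensity of a half-black/half-white image is one half", {
  m <- cbind(matrix(0, 32, 16), matrix(1, 32, 16))
  expect_equal(unname(traditionalFeatures(m)["int_mean"]), 0.5, tolerance = 1e-12)
})

test_that("min-max scaling maps the training range onto [0, 1]", {
  set.seed(7)
  x <- matrix(rnorm(50), 10, 5); x[, 3] <- 2  # constant column
  sc <- fitScaling(x)
  z <- applyScaling(x, sc)
  expect_equal(unname(apply(z[, -3], 2, min)), rep(0, 4))
  expect_equal(unname(apply(z[, -3], 2, max)), rep(1, 4))
  expect_true(all(z[, 3] == 0))
  znew <- applyScaling(matrix(100, 1, 5), sc)  # out-of-range clipped
  expect_true(all(znew >= 0 & znew <= 1))
})
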