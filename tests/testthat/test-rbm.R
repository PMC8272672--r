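test_that("hidden forward pass is the sigmoid of the affine input", {
  m0 <- setParams(rbmModel(3, 2), t = numeric(3), beta = numeric(2),
                  W = matrix(0, 3, 2))
  expect_equal(hiddenForward(c(1, 0, 1), m0), c(0.5, 0.5), tolerance = 1e-12)

  # raising one hidden bias raises exactly that unit's probability
  m1 <- setParams(m0, beta = c(1, 0))
  p0 <- hiddenForward(c(1, 0, 1), m0); p1 <- hiddenForward(c(1, 0, 1), m1)
  expect_gt(p1[1], p0[1]); expect_equal(p1[2], p0[2])

  # 3-visible/2-hidden hand computation on m = (1, 0, 1)
  W <- matrix(c(0.5, -1, 2, 0.25, 0.75, -0.5), 3, 2)
  mh <- setParams(m0, beta = c(0.1, -0.2), W = W)
  expected <- 1 / (1 + exp(-c(0.5 + 2 + 0.1, 0.25 - 0.5 - 0.2)))
  expect_equal(hiddenForward(c(1, 0, 1), mh), expected, tolerance = 1e-12)
  expect_error(hiddenForward(c(1, 0), mh), "visible units")
})

test_that("the printed forward variant adds the visible bias to the input", {
  W <- matrix(c(1, -1, 0.5, 0.2, 0.3, -0.4), 3, 2)
  mh <- setParams(rbmModel(3, 2), t = c(0.5, -0.5, 1), beta = c(0, 0.1), W = W)
  m <- c(0.2, 0.8, 0.4)
  expected <- 1 / (1 + exp(-(drop((m + mh@visibleBias) %*% W) + mh@hiddenBias)))
  expect_equal(hiddenForward(m, mh, variant = "printed"), expected,
               tolerance = 1e-12)
})

test_that("the energy of the empty configuration is zero", {
  m <- setParams(rbmModel(4, 2), t = rnorm(4), beta = rnorm(2),
                 W = matrix(rnorm(8), 4, 2))
  expect_identical(rbmEnergy(rep(0, 4), rep(0, 2), m), 0)
})

test_that("a one-active-unit configuration gives the hand-computed energy", {
  # effectively a single visible/single hidden pair: the second visible
  # unit is held at 0 with zero bias, so it contributes nothing
  m <- setParams(rbmModel(2, 1), t = c(0.5, 0), beta = 0.25,
                 W = matrix(c(2, 0), 2, 1))
  expect_equal(rbmEnergy(c(1, 0), 1, m), -2.75, tolerance = 1e-12)
})

test_that("energy matches a triple-loop brute force on random instances", {
  set.seed(10)
  for (rep in 1:5) {
    t <- rnorm(5); beta <- rnorm(4); W <- matrix(rnorm(20), 5, 4)
    m <- setParams(rbmModel(5, 4), t = t, beta = beta, W = W)
    x <- rbinom(5, 1, 0.5); y <- rbinom(4, 1, 0.5)
    expect_equal(rbmEnergy(x, y, m), naiveEnergy(x, y, t, beta, W),
                 tolerance = 1e-12)
    printed <- -sum(t * x) - sum(beta * y) - drop(t %*% W %*% y)
    expect_equal(rbmEnergy(x, y, m, variant = "printed"), printed,
                 tolerance = 1e-12)
  }
})

test_that("zero parameters give uniform exact marginals", {
  m <- setParams(rbmModel(3, 2), t = numeric(3), beta = numeric(2),
                 W = matrix(0, 3, 2))
  mg <- exactMarginals(m)
  expect_equal(mg$pVisible, rep(1 / 8, 8), tolerance = 1e-12)
  expect_equal(mg$pHidden, rep(1 / 4, 4), tolerance = 1e-12)
})

test_that("exact marginals are normalized for arbitrary finite parameters", {
  set.seed(11)
  for (rep in 1:5) {
    m <- setParams(rbmModel(6, 3), t = rnorm(6, 0, 2), beta = rnorm(3, 0, 2),
                   W = matrix(rnorm(18, 0, 2), 6, 3))
    mg <- exactMarginals(m)
    expect_lt(abs(sum(mg$pVisible) - 1), 1e-10)
    expect_lt(abs(sum(mg$pHidden) - 1), 1e-10)
  }
  expect_error(exactMarginals(rbmModel(18, 4)), "20 total units")
})

test_that("a 2-visible/1-hidden model matches full hand enumeration", {
  t <- c(0.3, -0.2); beta <- 0.5; W <- matrix(c(1, -0.7), 2, 1)
  m <- setParams(rbmModel(2, 1), t = t, beta = beta, W = W)
  xs <- as.matrix(expand.grid(0:1, 0:1)); ys <- 0:1
  # all 8 joint terms written out longhand
  boltz <- matrix(0, 4, 2)
  for (a in 1:4) for (b in 1:2) {
    x <- xs[a, ]; y <- ys[b]
    boltz[a, b] <- exp(sum(t * x) + beta * y + y * sum(x * W))
  }
  Z <- sum(boltz)
  mg <- exactMarginals(m)
  expect_equal(mg$pVisible, rowSums(boltz) / Z, tolerance = 1e-12)
  expect_equal(mg$pHidden, colSums(boltz) / Z, tolerance = 1e-12)
  expect_equal(mg$logZ, log(Z), tolerance = 1e-12)
})

test_that("enumerated marginals equal the analytic hidden-summed product form", {
  set.seed(12)
  m <- setParams(rbmModel(5, 3), t = rnorm(5), beta = rnorm(3),
                 W = matrix(rnorm(15), 5, 3))
  mg <- exactMarginals(m)
  X <- mg$visibleStates
  unnorm <- exp(X %*% m@visibleBias) *
    apply(1 + exp(sweep(X %*% m@weights, 2, m@hiddenBias, "+")), 1, prod)
  expect_equal(mg$pVisible, as.numeric(unnorm / sum(unnorm)), tolerance = 1e-10)
  # exactLogLikelihood agrees with log of the enumerated marginal
  idx <- c(3, 17, 25)
  expect_equal(exactLogLikelihood(X[idx, ], m), sum(log(mg$pVisible[idx])),
               tolerance = 1e-10)
})

test_that("contrastive divergence raises the exact likelihood objective", {
  set.seed(13)
  x <- matrix(rbinom(48, 1, rep(c(0.8, 0.2), each = 24)), 8, 6)
  cfg <- trainConfig(epochs = 50, superviseEpochs = 0, seed = 3)
  fit <- trainFusionModel(x, labels = rep(0:1, 4), nHidden = 3, config = cfg)
  init <- rbmModel(6, 3, seed = cfg$seed)
  expect_gte(exactLogLikelihood(x, fit), exactLogLikelihood(x, init))
  expect_identical(nrow(fit@trainLog), 50L)
  expect_gte(fit@trainLog$logLik[50], fit@trainLog$logLik[1])
})

test_that("training is bit-reproducible under a fixed seed", {
  set.seed(14)
  x <- matrix(runif(120), 20, 6)
  y <- rep(0:1, 10)
  cfg <- trainConfig(epochs = 20, seed = 5)
  a <- trainFusionModel(x, y, nHidden = 3, config = cfg)
  b <- trainFusionModel(x, y, nHidden = 3, config = cfg)
  expect_identical(a@weights, b@weights)
  expect_identical(a@outWeights, b@outWeights)
})

test_that("a linearly separable toy set is memorized after fine-tuning", {
  set.seed(15)
  n <- 12
  x0 <- cbind(matrix(runif(3 * n, 0.75, 1), n, 3), matrix(runif(3 * n, 0, 0.25), n, 3))
  x1 <- cbind(matrix(runif(3 * n, 0, 0.25), n, 3), matrix(runif(3 * n, 0.75, 1), n, 3))
  x <- rbind(x0, x1); y <- rep(0:1, each = n)
  fit <- trainFusionModel(x, y, nHidden = 4, config = trainConfig(epochs = 30, seed = 2))
  expect_identical(predictFusion(x, fit)$call, y)
})

test_that("single-class labels are rejected by the supervised phase", {
  x <- matrix(runif(30), 10, 3)
  expect_error(trainFusionModel(x, rep(1, 10), nHidden = 2), "both classes")
})

test_that("prediction applies the 0.5-is-positive decision rule", {
  m <- rbmModel(4, 2, seed = 1)
  expect_error(predictFusion(runif(4), m), "trained")
  m@trained <- TRUE                     # zero output head
  pr <- predictFusion(runif(4), m)
  expect_equal(pr$prob, 0.5, tolerance = 1e-12)
  expect_identical(pr$call, 1L)         # boundary counts as positive
  m2 <- m; m2@outBias <- 1
  expect_gt(predictFusion(c(1, 0, 1, 0), m2)$prob,
            predictFusion(c(1, 0, 1, 0), m)$prob)
  # hand-set 2-hidden output layer on known hidden probabilities
  mh <- setParams(rbmModel(3, 2), t = numeric(3), beta = numeric(2),
                  W = matrix(0, 3, 2))      # hidden probs are exactly 0.5
  mh@outWeights <- c(2, -1); mh@outBias <- 0.3; mh@trained <- TRUE
  expect_equal(predictFusion(c(0, 1, 0), mh)$prob,
               1 / (1 + exp(-(0.5 * 2 - 0.5 * 1 + 0.3))), tolerance = 1e-12)
})

test_that("CD training recovers the likelihood of a known generator", {
  gen <- setParams(rbmModel(6, 3),
                   t = c(0.4, -0.3, 0.2, 0, -0.4, 0.3),
                   beta = c(0.2, -0.2, 0.1),
                   W = matrix(local({set.seed(42); rnorm(18, 0, 1.2)}), 6, 3))
  train <- sampleVisible(gen, 300, seed = 21)
  heldout <- sampleVisible(gen, 200, seed = 22)
  fit <- trainFusionModel(train, labels = rep(0:1, 150), nHidden = 3,
                          config = trainConfig(epochs = 300, superviseEpochs = 0,
                                               seed = 7))
  llGen <- exactLogLikelihood(heldout, gen)
  llFit <- exactLogLikelihood(heldout, fit)
  expect_lt(abs(llFit / llGen - 1), 0.10)
})

test_that("visible sampling from a small model is seeded and binary", {
  m <- setParams(rbmModel(4, 2), t = rnorm(4), beta = rnorm(2),
                 W = matrix(rnorm(8), 4, 2))
  a <- sampleVisible(m, 50, seed = 3); b <- sampleVisible(m, 50, seed = 3)
  expect_identical(a, b)
  expect_true(all(a %in% 0:1))
  expect_identical(dim(a), c(50L, 4L))
})
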