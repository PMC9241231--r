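test_that("identity filter (K=1, theta0=1) reproduces the signal", {
  Lt <- scaledLaplacian(buildSequenceGraph(5, 1))
  S <- matrix(rnorm(5))
  expect_equal(chebConv(S, Lt, array(1, c(1, 1, 1))), S)
})

test_that("pure T1 filter applies the scaled Laplacian", {
  Lt <- scaledLaplacian(buildSequenceGraph(2, 1), "approx2")
  theta <- array(0, c(2, 1, 1))
  theta[2, 1, 1] <- 1
  S <- matrix(c(3, -4))
  expect_equal(chebConv(S, Lt, theta), Lt@matrix %*% S)
})

test_that("cheb_conv matches the spectral eigendecomposition oracle", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    w <- sample(seq_len(n - 1), 1)
    Lt <- scaledLaplacian(buildSequenceGraph(n, w), "exact")
    K <- sample(1:4, 1)
    cin <- sample(1:3, 1)
    cout <- sample(1:3, 1)
    theta <- lapply(seq_len(K), function(k) matrix(rnorm(cin * cout), cin))
    S <- matrix(rnorm(n * cin), n, cin)
    expect_equal(
      chebConv(S, Lt, theta),
      spectralFilterOracle(Lt, S, theta),
      tolerance = 1e-6
    )
  }
})

test_that("cheb_conv is linear in signal and coefficients", {
  set.seed(5)
  Lt <- scaledLaplacian(buildSequenceGraph(7, 2))
  theta <- lapply(1:3, function(k) matrix(rnorm(6), 2, 3))
  X <- matrix(rnorm(14), 7, 2)
  Y <- matrix(rnorm(14), 7, 2)
  expect_equal(
    chebConv(2.5 * X - 1.2 * Y, Lt, theta),
    2.5 * chebConv(X, Lt, theta) - 1.2 * chebConv(Y, Lt, theta),
    tolerance = 1e-8
  )
  theta2 <- lapply(theta, function(m) 3 * m)
  expect_equal(chebConv(X, Lt, theta2), 3 * chebConv(X, Lt, theta),
    tolerance = 1e-8)
})

test_that("preprocessing layer is per-position and identity-extendable", {
  X <- oneHotEncode("ACGUN", 5)
  # identity extension: first 4 channels reproduce X
  W <- cbind(diag(4), matrix(0, 4, 2))
  out <- preprocessLayer(X, W)
  expect_equal(out[, 1:4], X, ignore_attr = TRUE)
  # zero rows stay zero under zero bias
  expect_equal(out[5, ], rep(0, 6))
  # locality: perturbing one input row changes only that output row
  set.seed(2)
  Wr <- matrix(rnorm(24), 4, 6)
  X2 <- X
  X2[3, ] <- X2[3, ] + rnorm(4)
  d <- preprocessLayer(X2, Wr) - preprocessLayer(X, Wr)
  expect_true(all(d[-3, ] == 0))
  expect_gt(max(abs(d[3, ])), 0)
})

test_that("chebnet forward pass honours shape, zeros and homogeneity", {
  L <- 8L
  Lt <- scaledLaplacian(buildSequenceGraph(L, 1))
  set.seed(31)
  pre <- list(weights = matrix(rnorm(4 * 3), 4, 3), bias = numeric(3))
  l1 <- list(theta = lapply(1:2, function(k) matrix(rnorm(3 * 4), 3, 4)),
    bias = numeric(4))
  l2 <- list(theta = lapply(1:2, function(k) matrix(rnorm(4 * 5), 4, 5)),
    bias = numeric(5))
  v <- chebnetForward(oneHotEncode(randomRNA(L), L), Lt, pre, l1, l2)
  expect_length(v, L * 5)

  # all-zero input with zero biases -> all-zero features
  z <- chebnetForward(matrix(0, L, 4), Lt, pre, l1, l2)
  expect_equal(z, rep(0, L * 5))

  # slope = 1 makes the stack linear: doubling layer-1 theta doubles
  # the layer-1 activations, hence (with slope 1) scales nothing else
  # nonlinearly
  X <- oneHotEncode(randomRNA(L), L)
  l1d <- list(theta = lapply(l1$theta, function(m) 2 * m), bias = l1$bias)
  h1 <- leakyRelu(chebConv(preprocessLayer(X, pre$weights), Lt,
    l1$theta, l1$bias), 1)
  h1d <- leakyRelu(chebConv(preprocessLayer(X, pre$weights), Lt,
    l1d$theta, l1d$bias), 1)
  expect_equal(h1d, 2 * h1, tolerance = 1e-10)
})

test_that("flatten order is row-major over (position, channel)", {
  L <- 4L
  Lt <- scaledLaplacian(buildSequenceGraph(L, 1))
  pre <- list(weights = diag(4), bias = numeric(4))
  idf <- list(theta = list(diag(4)), bias = numeric(4)) # K=1 identity
  X <- oneHotEncode("ACGU", L)
  v <- chebnetForward(X, Lt, pre, idf, idf)
  expect_equal(v, as.vector(t(X))) # channel varies fastest
})

test_that("order-K filters on a path have the expected receptive field", {
  # K = 2 (terms T0, T1) with radius-1 adjacency: output at position i
  # depends on inputs {i-1, i, i+1} only
  L <- 9L
  Lt <- scaledLaplacian(buildSequenceGraph(L, 1))
  set.seed(13)
  theta <- lapply(1:2, function(k) matrix(rnorm(4), 2, 2))
  X <- matrix(rnorm(L * 2), L, 2)
  X2 <- X
  X2[5, ] <- X2[5, ] + 1
  d <- rowSums(abs(chebConv(X2, Lt, theta) - chebConv(X, Lt, theta)))
  expect_true(all(d[c(4, 5, 6)] > 0))
  expect_equal(d[-c(4, 5, 6)], rep(0, L - 3))
})

test_that("gradients through the spectral branch match finite differences", {
  cfg <- toyConfig(windowLength = 6L, ablation = "chebnet_only")
  m <- deepPNModel(cfg)
  set.seed(41)
  B <- 3L
  Xb <- randomOneHotBatch(B, 6L)
  y <- c(1, 0, 1)
  lossFn <- function(p) {
    binaryCrossEntropy(
      deepPN:::nnForward(p, cfg, m@chebBasis, Xb, B)$p, y
    )$mean
  }
  g <- deepPN:::nnLossGrad(m@params, cfg, m@chebBasis, Xb, y, B)$grads
  nms <- c("preW", "preB", "cheb1W", "cheb1B", "cheb2W", "cheb2B")
  num <- numericalGrad(lossFn, m@params, nms)
  for (nm in nms) {
    expect_equal(g[[nm]], num[[nm]], tolerance = 1e-4, ignore_attr = TRUE)
  }
})
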