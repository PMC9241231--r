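test_that("fusion concatenates spectral-first and rejects empty branches", {
  a <- rnorm(8)
  b <- rnorm(12)
  f <- fuseFeatures(a, b)
  expect_length(f, 20)
  expect_equal(f[1:8], a)
  expect_equal(f[9:20], b)
  expect_equal(fuseFeatures(a, NULL), a) # ablation: surviving branch
  expect_error(fuseFeatures(numeric(0), b), "empty")
  expect_error(fuseFeatures(NULL, NULL), "non-empty")
})

test_that("zero-parameter head outputs probability one half", {
  head <- list(W1 = matrix(0, 6, 5), b1 = numeric(5),
    W2 = matrix(0, 5, 4), b2 = numeric(4),
    W3 = matrix(0, 4, 1), b3 = numeric(1))
  expect_equal(predictProba(rnorm(6), head = head), 0.5)
})

test_that("inference head is deterministic; probability is monotone in bias", {
  set.seed(3)
  head <- list(W1 = matrix(rnorm(30), 6, 5), b1 = rnorm(5),
    W2 = matrix(rnorm(20), 5, 4), b2 = rnorm(4),
    W3 = matrix(rnorm(4), 4, 1), b3 = 0)
  H <- rnorm(6)
  expect_identical(predictProba(H, head = head), predictProba(H, head = head))
  probs <- vapply(c(-5, 0, 5, 50), function(b) {
    h <- head
    h$b3 <- b
    predictProba(H, head = h)
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
  expect_gt(probs[4], 1 - 1e-10)
})

test_that("binary cross-entropy matches its closed forms", {
  # perfect prediction contributes ~0
  expect_lt(binaryCrossEntropy(1 - 1e-7, 1)$sum, 1e-6)
  # all-half predictions: sum = n log 2
  for (n in c(1, 7, 100)) {
    expect_equal(binaryCrossEntropy(rep(0.5, n), rep(c(0, 1),
      length.out = n))$sum, n * log(2), tolerance = 1e-12)
  }
  # direct evaluation
  expect_equal(binaryCrossEntropy(c(0.8, 0.3), c(1, 0))$sum,
    -(log(0.8) + log(0.7)), tolerance = 1e-12)
  expect_equal(binaryCrossEntropy(c(0.8, 0.3), c(1, 0))$mean,
    -(log(0.8) + log(0.7)) / 2, tolerance = 1e-12)
  expect_error(binaryCrossEntropy(c(0.5), c(1, 0)), "equal length")
})

test_that("8:2 split is exact, stratified, reproducible and a partition", {
  d <- RBPDataset(
    vapply(1:10, function(i) randomRNA(21), character(1)),
    rep(c(1L, 0L), each = 5)
  )
  sp <- splitDataset(d, 0.8, seed = 7)
  expect_length(sp$trainIdx, 8)
  expect_length(sp$testIdx, 2)
  expect_equal(sum(labels(sp$train)), 4) # stratification: 4 of 5 positives
  # partition: disjoint and exhaustive
  expect_length(intersect(sp$trainIdx, sp$testIdx), 0)
  expect_setequal(c(sp$trainIdx, sp$testIdx), 1:10)
  # seed reproducibility
  sp2 <- splitDataset(d, 0.8, seed = 7)
  expect_identical(sp$trainIdx, sp2$trainIdx)
  sp3 <- splitDataset(d, 0.8, seed = 8)
  expect_false(identical(sp$trainIdx, sp3$trainIdx))
  # single-class rejection
  dOne <- RBPDataset(vapply(1:6, function(i) randomRNA(9), character(1)),
    rep(1L, 6))
  expect_error(splitDataset(dOne, 0.8, 1), "both classes")
})

test_that("patience rule stops after two declining epochs, keeping the best", {
  tr <- earlyStopTrace(c(0.70, 0.80, 0.79, 0.78), patience = 2)
  expect_true(tr$stopped)
  expect_equal(tr$stopEpoch, 4)
  expect_equal(tr$bestEpoch, 2)
  # no stop when improvements keep coming
  tr2 <- earlyStopTrace(c(0.5, 0.6, 0.55, 0.65, 0.7), patience = 2)
  expect_false(tr2$stopped)
  expect_equal(tr2$bestEpoch, 5)
  # plateaus count as non-improvement
  tr3 <- earlyStopTrace(c(0.7, 0.7, 0.7), patience = 2)
  expect_true(tr3$stopped)
  expect_equal(tr3$stopEpoch, 3)
  expect_equal(tr3$bestEpoch, 1)
})

test_that("rank AUC matches the pair-counting oracle and pROC", {
  set.seed(19)
  for (i in 1:15) {
    n <- sample(6:25, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(rnorm(n), 1) # rounding forces ties
    expect_equal(aucRank(s, y), aucPairOracle(s, y), tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    y <- c(rep(1, 8), rep(0, 9))
    s <- c(rnorm(8, 1), rnorm(9))
    expect_equal(aucRank(s, y),
      as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
      tolerance = 1e-12)
  }
})

test_that("evaluation handles separation, ties and single-class sets", {
  expect_equal(aucRank(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(aucRank(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_true(is.na(aucRank(rnorm(4), rep(1, 4))))
})

test_that("the model memorizes a separable toy set and is seed-stable", {
  set.seed(53)
  pos <- vapply(1:6, function(i) {
    s <- randomRNA(15)
    substr(s, 5, 10) <- "UGCAUG"
    s
  }, character(1))
  neg <- vapply(1:6, function(i) randomRNA(15), character(1))
  d <- RBPDataset(c(pos, neg), rep(c(1L, 0L), each = 6))
  cfg <- deepPNConfig(
    encoding = list(windowLength = 15L),
    chebnet = list(K = 2L, embedChannels = 4L, channels = c(4L, 6L)),
    cnn = list(kernelSize = 6L, filters = c(4L, 6L)),
    head = list(hidden = c(16L, 8L), dropout = 0),
    training = list(maxEpochs = 60L, patience = 60L, monitor = "test"),
    seed = 5
  )
  fit <- trainDeepPN(deepPNModel(cfg), d, monitorData = d)
  rep <- evaluateModel(fit, d)
  expect_equal(accuracy(rep), 1)
  expect_equal(rocAUC(rep), 1)
  # determinism: bit-identical history under the same seed
  fit2 <- trainDeepPN(deepPNModel(cfg), d, monitorData = d)
  expect_identical(fit@history, fit2@history)
})

test_that("training respects the patience budget and restores the best", {
  set.seed(59)
  d <- RBPDataset(vapply(1:30, function(i) randomRNA(9), character(1)),
    rep(c(1L, 0L), 15))
  cfg <- deepPNConfig(
    encoding = list(windowLength = 9L),
    chebnet = list(K = 2L, embedChannels = 3L, channels = c(3L, 3L)),
    cnn = list(kernelSize = 3L, filters = c(3L, 3L)),
    head = list(hidden = c(8L, 4L)),
    training = list(maxEpochs = 25L, patience = 2L),
    seed = 11
  )
  fit <- trainDeepPN(deepPNModel(cfg), d)
  h <- fit@history$monitorMetric
  # never trains past best epoch + patience
  expect_lte(nrow(fit@history), fit@bestEpoch + cfg$training$patience)
  expect_equal(fit@bestEpoch, which.max(h))
})

test_that("ablations shrink the fused dimension and still train", {
  for (ab in c("chebnet_only", "cnn_only")) {
    cfg <- toyConfig(windowLength = 8L, ablation = ab)
    cfg$training$maxEpochs <- 2L
    m <- deepPNModel(cfg)
    dims <- deepPN:::branchDims(cfg)
    expect_equal(nrow(m@params$headW1),
      if (ab == "chebnet_only") dims$cheb else dims$cnn)
    set.seed(61)
    d <- RBPDataset(vapply(1:12, function(i) randomRNA(8), character(1)),
      rep(c(1L, 0L), 6))
    fit <- trainDeepPN(m, d)
    expect_s4_class(fit, "DeepPNFit")
    p <- predictProba(fit, d)
    expect_true(all(p > 0 & p < 1))
  }
  # full model fused dim is the sum of the branches
  cfgF <- toyConfig(windowLength = 8L)
  dimsF <- deepPN:::branchDims(cfgF)
  expect_equal(dimsF$fused, dimsF$cheb + dimsF$cnn)
})

test_that("best-so-far train loss trends down on learnable data", {
  set.seed(67)
  pos <- vapply(1:20, function(i) {
    s <- randomRNA(12)
    substr(s, 4, 7) <- "GGCC"
    s
  }, character(1))
  neg <- vapply(1:20, function(i) randomRNA(12), character(1))
  d <- RBPDataset(c(pos, neg), rep(c(1L, 0L), each = 20))
  cfg <- deepPNConfig(
    encoding = list(windowLength = 12L),
    chebnet = list(K = 2L, embedChannels = 4L, channels = c(4L, 4L)),
    cnn = list(kernelSize = 4L, filters = c(4L, 4L)),
    head = list(hidden = c(16L, 8L), dropout = 0),
    training = list(maxEpochs = 15L, patience = 15L),
    seed = 13
  )
  fit <- trainDeepPN(deepPNModel(cfg), d)
  l <- fit@history$trainLoss
  expect_lt(cummin(l)[length(l)], l[1] * 0.8)
})
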