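recursiveMerge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- recursiveMerge(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Experiment configuration with field-standard defaults
#'
#' Assembles the full nested configuration of the pipeline. Defaults
#' follow the published training regime where one is stated (window
#' length 101 nt, batch size 16, Adam with learning rate 0.001,
#' early-stopping patience 2 epochs, 8:2 train/test split, 16 and 32
#' convolution filters sharing one kernel size) and this package's
#' documented choices otherwise (path graph of radius 1, Chebyshev
#' order 3, kernel size 10, embedding width 16, dense head 128-64-1
#' with dropout 0.5, LeakyReLU slope 0.01).
#'
#' @param ... named overrides merged recursively into the defaults,
#'   e.g. \code{deepPNConfig(cnn = list(kernelSize = 6), seed = 7)}.
#' @return nested list with blocks \code{encoding}, \code{graph},
#'   \code{chebnet}, \code{cnn}, \code{head}, \code{training},
#'   \code{seed}, \code{outputDir}.
#' @export
deepPNConfig <- function(...) {
  cfg <- list(
    encoding = list(windowLength = 101L),
    graph = list(window = 1L, lambdaMaxMode = "exact"),
    chebnet = list(K = 3L, embedChannels = 16L, channels = c(16L, 32L),
      slope = 0.01),
    cnn = list(kernelSize = 10L, filters = c(16L, 32L),
      padding = "valid", slope = 0.01),
    head = list(hidden = c(128L, 64L), dropout = 0.5, slope = 0.01),
    training = list(
      batchSize = 16L, learningRate = 0.001, optimizer = "adam",
      maxEpochs = 15L, patience = 2L, splitRatio = 0.8,
      monitorFraction = 0.1, monitor = "heldout", restoreBest = TRUE,
      ablation = "deeppn"
    ),
    seed = 1L,
    outputDir = "."
  )
  override <- list(...)
  if (length(override)) {
    if (is.null(names(override)) || any(names(override) == "")) {
      stop("configuration overrides must be named")
    }
    cfg <- recursiveMerge(cfg, override)
  }
  stopifnot(
    cfg$training$batchSize >= 1,
    cfg$training$patience >= 1,
    cfg$training$splitRatio > 0, cfg$training$splitRatio < 1,
    cfg$head$dropout >= 0, cfg$head$dropout < 1,
    cfg$training$ablation %in% c("deeppn", "chebnet_only", "cnn_only"),
    cfg$cnn$padding %in% c("valid", "same"),
    cfg$training$monitor %in% c("heldout", "test")
  )
  cfg
}

# Feature-vector lengths of the two branches under a configuration.
branchDims <- function(cfg) {
  L <- cfg$encoding$windowLength
  chebLen <- L * cfg$chebnet$channels[2]
  Lc <- if (identical(cfg$cnn$padding, "same")) {
    L
  } else {
    L - 2L * (cfg$cnn$kernelSize - 1L)
  }
  if (Lc < 1L) stop("kernel size too large for the window length")
  cnnLen <- Lc * cfg$cnn$filters[2]
  list(
    cheb = chebLen, cnn = cnnLen,
    fused = switch(cfg$training$ablation,
      deeppn = chebLen + cnnLen,
      chebnet_only = chebLen,
      cnn_only = cnnLen
    )
  )
}

heInit <- function(nr, nc, fanIn) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fanIn)), nr, nc)
}

#' Initialize the two-branch classifier
#'
#' Builds the position graph and its scaled Laplacian for the
#' configured window length, precomputes the Chebyshev polynomial
#' basis, and draws He-initialized parameters for every layer using
#' the configuration seed. The ablation mode fixes the fused feature
#' dimension of the dense head at initialization.
#'
#' @param config a configuration from \code{\link{deepPNConfig}}.
#' @return a \linkS4class{DeepPNModel}.
#' @export
deepPNModel <- function(config = deepPNConfig()) {
  L <- config$encoding$windowLength
  graph <- buildSequenceGraph(L, config$graph$window)
  Lt <- scaledLaplacian(graph, config$graph$lambdaMaxMode)
  basis <- chebyshevBasis(Lt, config$chebnet$K)

  K <- config$chebnet$K
  C0 <- config$chebnet$embedChannels
  C1 <- config$chebnet$channels[1]
  C2 <- config$chebnet$channels[2]
  kern <- config$cnn$kernelSize
  F1 <- config$cnn$filters[1]
  F2 <- config$cnn$filters[2]
  dims <- branchDims(config)
  h1 <- config$head$hidden[1]
  h2 <- config$head$hidden[2]
  ab <- config$training$ablation

  params <- withSeed(config$seed, {
    p <- list()
    if (ab != "cnn_only") {
      p$preW <- heInit(4L, C0, 4L)
      p$preB <- numeric(C0)
      p$cheb1W <- heInit(K * C0, C1, K * C0)
      p$cheb1B <- numeric(C1)
      p$cheb2W <- heInit(K * C1, C2, K * C1)
      p$cheb2B <- numeric(C2)
    }
    if (ab != "chebnet_only") {
      p$conv1W <- heInit(kern * 4L, F1, kern * 4L)
      p$conv1B <- numeric(F1)
      p$conv2W <- heInit(kern * F1, F2, kern * F1)
      p$conv2B <- numeric(F2)
    }
    p$headW1 <- heInit(dims$fused, h1, dims$fused)
    p$headB1 <- numeric(h1)
    p$headW2 <- heInit(h1, h2, h1)
    p$headB2 <- numeric(h2)
    p$headW3 <- heInit(h2, 1L, h2)
    p$headB3 <- numeric(1L)
    p
  })

  new("DeepPNModel",
    params = params, config = config, laplacian = Lt, chebBasis = basis
  )
}

#' Fuse the two branch feature vectors
#'
#' Concatenates the spectral-branch vector followed by the
#' convolutional-branch vector, in that fixed order, forming the input
#' of the fully connected head. Under an ablation the fused vector is
#' simply the surviving branch.
#'
#' @param cheb numeric feature vector from the spectral branch, or
#'   \code{NULL} under \code{"cnn_only"}.
#' @param cnn numeric feature vector from the convolutional branch, or
#'   \code{NULL} under \code{"chebnet_only"}.
#' @return numeric fused feature vector.
#' @export
fuseFeatures <- function(cheb, cnn) {
  if ((is.null(cheb) || !length(cheb)) && (is.null(cnn) || !length(cnn))) {
    stop("at least one non-empty branch vector is required")
  }
  if (!is.null(cheb) && !length(cheb)) stop("empty spectral branch vector")
  if (!is.null(cnn) && !length(cnn)) stop("empty convolutional branch vector")
  c(cheb, cnn)
}

#' Dense classification head
#'
#' Three affine layers with LeakyReLU between them; dropout is applied
#' to the two hidden activations only in training mode (inverted
#' dropout, so inference needs no rescaling). The final score passes
#' through the logistic function, confining the output to (0, 1).
#'
#' @param H fused feature vector, or a matrix with one row per sample.
#' @param head list with \code{W1,b1,W2,b2,W3,b3}.
#' @param training logical; enables dropout.
#' @param dropout dropout probability for the hidden layers.
#' @param slope LeakyReLU negative slope.
#' @return probability vector in (0, 1).
#' @export
denseHead <- function(H, head, training = FALSE, dropout = 0.5,
                      slope = 0.01) {
  if (is.vector(H)) H <- matrix(H, nrow = 1)
  keep <- 1 - dropout
  G1 <- leakyRelu(sweep(H %*% head$W1, 2, head$b1, "+"), slope)
  if (training && keep < 1) {
    G1 <- G1 * matrix(
      (stats::runif(length(G1)) < keep) / keep, nrow(G1), ncol(G1)
    )
  }
  G2 <- leakyRelu(sweep(G1 %*% head$W2, 2, head$b2, "+"), slope)
  if (training && keep < 1) {
    G2 <- G2 * matrix(
      (stats::runif(length(G2)) < keep) / keep, nrow(G2), ncol(G2)
    )
  }
  sigmoid(as.vector(sweep(G2 %*% head$W3, 2, head$b3, "+")))
}

#' Binary cross-entropy of predicted probabilities
#'
#' The conditional log-likelihood loss
#' \deqn{\zeta = -\sum_i y_i \log p_i + (1 - y_i) \log(1 - p_i)}
#' with probabilities clipped to \eqn{[\epsilon, 1-\epsilon]}
#' (\eqn{\epsilon = 10^{-7}}) to keep the value finite. Returned both
#' as the sum over samples and as the per-sample mean the optimizer
#' minimizes.
#'
#' @param probs predicted probabilities.
#' @param labels 0/1 truth labels, same length.
#' @param eps clipping bound.
#' @return list with elements \code{sum} and \code{mean}.
#' @examples
#' binaryCrossEntropy(rep(0.5, 4), c(1, 0, 1, 0))$sum # 4 * log(2)
#' @export
binaryCrossEntropy <- function(probs, labels, eps = 1e-7) {
  if (length(probs) != length(labels)) {
    stop("probs and labels must have equal length")
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  p <- pmin(pmax(probs, eps), 1 - eps)
  ll <- labels * log(p) + (1 - labels) * log(1 - p)
  list(sum = -sum(ll), mean = -mean(ll))
}

#' Stratified train/test split
#'
#' Seed-reproducible random partition assigning
#' \code{ceiling(ratio * n)} records to the training set, stratified
#' so each class keeps (as closely as possible) its overall
#' proportion. Train and test are disjoint and exhaustive.
#'
#' @param data an \linkS4class{RBPDataset} with both classes present.
#' @param ratio training fraction (default 0.8, the 8:2 convention).
#' @param seed integer seed controlling the partition.
#' @return list with elements \code{train} and \code{test}, plus the
#'   index vectors \code{trainIdx}, \code{testIdx}.
#' @export
splitDataset <- function(data, ratio = 0.8, seed = 1) {
  n <- length(data)
  if (n < 5L) stop("need at least 5 records to split")
  y <- labels(data)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present to form a training split")
  }
  nTrain <- as.integer(ceiling(ratio * n))
  idx <- withSeed(seed, {
    pos <- sample(which(y == 1L))
    neg <- sample(which(y == 0L))
    nPosTr <- round(nTrain * length(pos) / n)
    nPosTr <- min(max(nPosTr, 1L), length(pos) - 1L)
    nNegTr <- nTrain - nPosTr
    nNegTr <- min(max(nNegTr, 1L), length(neg) - 1L)
    nPosTr <- nTrain - nNegTr
    list(
      train = sort(c(pos[seq_len(nPosTr)], neg[seq_len(nNegTr)])),
      test = sort(c(
        pos[-seq_len(nPosTr)], neg[-seq_len(nNegTr)]
      ))
    )
  })
  list(
    train = data[idx$train], test = data[idx$test],
    trainIdx = idx$train, testIdx = idx$test
  )
}

#' Early-stopping trace over a monitored metric sequence
#'
#' Replays the patience rule on a per-epoch metric sequence (larger is
#' better): training stops once the metric has sat below its running
#' best for \code{patience} consecutive epochs, and the parameters of
#' the best epoch are the ones retained. The same rule drives
#' \code{\link{trainDeepPN}}.
#'
#' @param metrics numeric vector of the monitored metric per epoch.
#' @param patience consecutive non-improving epochs tolerated.
#' @return list with \code{stopEpoch} (the epoch after which training
#'   halts, \code{length(metrics)} if the rule never fires),
#'   \code{bestEpoch}, and \code{stopped} (whether the rule fired).
#' @examples
#' earlyStopTrace(c(0.70, 0.80, 0.79, 0.78), patience = 2)
#' @export
earlyStopTrace <- function(metrics, patience = 2) {
  patience <- stopifnotScalarCount(patience, "patience")
  best <- -Inf
  bestEpoch <- 0L
  sinceBest <- 0L
  for (e in seq_along(metrics)) {
    if (metrics[e] > best) {
      best <- metrics[e]
      bestEpoch <- e
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest >= patience) {
        return(list(stopEpoch = e, bestEpoch = bestEpoch, stopped = TRUE))
      }
    }
  }
  list(
    stopEpoch = length(metrics), bestEpoch = bestEpoch, stopped = FALSE
  )
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic:
#' the probability that a random positive scores above a random
#' negative, with ties contributing 1/2 (midranks).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in [0, 1], or \code{NA} if only one class is present.
#' @export
aucRank <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' @describeIn predictProba probabilities for every record of a
#'   dataset under a (trained or freshly initialized) model. Dropout
#'   is disabled, so the output is deterministic.
#' @param newdata an \linkS4class{RBPDataset}.
#' @param batchSize records per forward chunk.
#' @export
setMethod("predictProba", "DeepPNModel",
  function(object, newdata, batchSize = 256L, ...) {
    stopifnot(is(newdata, "RBPDataset"))
    cfg <- object@config
    L <- cfg$encoding$windowLength
    X <- encodeDataset(newdata, L)
    n <- length(newdata)
    p <- numeric(n)
    for (start in seq.int(1L, n, by = batchSize)) {
      end <- min(start + batchSize - 1L, n)
      rows <- ((start - 1L) * L + 1L):(end * L)
      p[start:end] <- nnForward(
        object@params, cfg, object@chebBasis,
        X[rows, , drop = FALSE], end - start + 1L
      )$p
    }
    p
  }
)

#' @describeIn predictProba probabilities from a fitted model (the
#'   best-epoch parameters).
#' @export
setMethod("predictProba", "DeepPNFit", function(object, newdata, ...) {
  predictProba(object@model, newdata, ...)
})

#' @describeIn predictProba a fused feature vector pushed through a
#'   dense head given explicitly (see \code{\link{denseHead}}).
#' @param head dense-head parameter list.
#' @param training logical; enables dropout.
#' @param ... passed on to \code{\link{denseHead}}.
#' @export
setMethod("predictProba", "numeric",
  function(object, head, training = FALSE, ...) {
    denseHead(object, head, training = training, ...)
  }
)

#' Evaluate a model on a labeled dataset
#'
#' Accuracy at probability threshold 0.5, AUC by the rank statistic
#' (absent for a single-class set), and the cross-entropy loss as both
#' sum and per-sample mean.
#'
#' @param object a \linkS4class{DeepPNModel} or \linkS4class{DeepPNFit}.
#' @param data an \linkS4class{RBPDataset}.
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateModel <- function(object, data) {
  if (is(object, "DeepPNFit")) object <- object@model
  y <- labels(data)
  p <- predictProba(object, data)
  loss <- binaryCrossEntropy(p, y)
  new("EvalReport",
    accuracy = mean((p >= 0.5) == (y == 1L)),
    auc = aucRank(p, y),
    lossSum = loss$sum, lossMean = loss$mean,
    n = length(y)
  )
}
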