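#' Train the two-branch classifier
#'
#' Mini-batch optimization of the mean binary cross-entropy with Adam
#' (moment parameters 0.9/0.999, epsilon 1e-8) at the configured
#' learning rate and batch size. After every epoch the monitored
#' accuracy is recorded; training halts once that metric has sat below
#' its running best for \code{patience} consecutive epochs (or at
#' \code{maxEpochs}), and by default the parameters of the best epoch
#' are restored into the returned fit.
#'
#' By default a stratified monitoring split (\code{monitorFraction} of
#' the provided training data) is carved out and the remainder is used
#' for gradient steps, keeping the stopping decision free of test-set
#' leakage. Setting \code{training$monitor = "test"} in the
#' configuration instead monitors \code{monitorData} supplied by the
#' caller (the historical regime of monitoring test accuracy), which
#' is provided for reproduction purposes only.
#'
#' The run is fully deterministic under the configuration seed on a
#' single thread: parameter initialization, batch shuffling and
#' dropout all draw from one seeded stream.
#'
#' @param model a freshly initialized \linkS4class{DeepPNModel}.
#' @param data training \linkS4class{RBPDataset} with both classes
#'   present.
#' @param monitorData dataset monitored for early stopping when the
#'   configuration says \code{monitor = "test"}; ignored otherwise.
#' @param verbose print per-epoch progress.
#' @return a \linkS4class{DeepPNFit}.
#' @export
trainDeepPN <- function(model, data, monitorData = NULL, verbose = FALSE) {
  stopifnot(is(model, "DeepPNModel"), is(data, "RBPDataset"))
  cfg <- model@config
  tc <- cfg$training
  y <- labels(data)
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes")
  }

  if (identical(tc$monitor, "test")) {
    if (is.null(monitorData)) {
      stop("monitor = \"test\" requires monitorData")
    }
    fitData <- data
    monData <- monitorData
  } else {
    sp <- splitDataset(data, ratio = 1 - tc$monitorFraction,
      seed = cfg$seed + 1L)
    fitData <- sp$train
    monData <- sp$test
  }

  L <- cfg$encoding$windowLength
  X <- encodeDataset(fitData, L)
  yFit <- labels(fitData)
  n <- length(fitData)
  basis <- model@chebBasis
  params <- model@params
  state <- adamInit(params)

  history <- data.frame(
    epoch = integer(), trainLoss = numeric(), monitorMetric = numeric()
  )
  bestParams <- params
  bestEpoch <- 0L
  stoppedEarly <- FALSE

  withSeed(cfg$seed, {
    for (epoch in seq_len(tc$maxEpochs)) {
      ord <- sample.int(n)
      epochLoss <- 0
      nBatches <- 0L
      for (start in seq.int(1L, n, by = tc$batchSize)) {
        idx <- ord[start:min(start + tc$batchSize - 1L, n)]
        B <- length(idx)
        rows <- as.vector(outer(seq_len(L), (idx - 1L) * L, "+"))
        step <- nnLossGrad(
          params, cfg, basis, X[rows, , drop = FALSE], yFit[idx], B,
          training = TRUE
        )
        upd <- adamStep(params, step$grads, state, lr = tc$learningRate)
        params <- upd$params
        state <- upd$state
        epochLoss <- epochLoss + step$loss
        nBatches <- nBatches + 1L
      }

      probe <- model
      probe@params <- params
      pMon <- predictProba(probe, monData)
      metric <- mean((pMon >= 0.5) == (labels(monData) == 1L))
      history[epoch, ] <- list(epoch, epochLoss / nBatches, metric)
      if (verbose) {
        message(sprintf(
          "epoch %d  train loss %.4f  monitor acc %.4f",
          epoch, epochLoss / nBatches, metric
        ))
      }

      dec <- earlyStopTrace(history$monitorMetric, tc$patience)
      if (dec$bestEpoch == epoch) bestParams <- params
      bestEpoch <- dec$bestEpoch
      if (dec$stopped) {
        stoppedEarly <- TRUE
        break
      }
    }
  })

  model@params <- if (isTRUE(tc$restoreBest)) bestParams else params
  new("DeepPNFit",
    model = model, history = history,
    bestEpoch = as.integer(bestEpoch), stoppedEarly = stoppedEarly
  )
}
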