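# Independent oracles and fixture builders shared across the suite.
# These deliberately use the slowest, most literal formulation of each
# quantity so they stay independent of the package's optimized paths.

randomRNA <- function(len, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Literal nested-loop cross-correlation, "valid" mode.
bruteConv <- function(signal, weights, bias = NULL) {
  # weights: (filters, kernel, channels)
  d <- dim(weights)
  Lout <- nrow(signal) - d[2] + 1L
  out <- matrix(0, Lout, d[1])
  for (f in seq_len(d[1])) {
    for (i in seq_len(Lout)) {
      acc <- 0
      for (j in seq_len(d[2])) {
        for (c in seq_len(d[3])) {
          acc <- acc + weights[f, j, c] * signal[i + j - 1L, c]
        }
      }
      out[i, f] <- acc + if (is.null(bias)) 0 else bias[f]
    }
  }
  out
}

# Spectral-domain Chebyshev filter via dense eigendecomposition:
# Ltilde = U diag(lam) U',  y = U (sum_k theta_k T_k(diag(lam))) U' x
# with T_k evaluated by the scalar recursion on each eigenvalue.
spectralFilterOracle <- function(Ltilde, signal, thetaList) {
  eg <- eigen(Ltilde@matrix, symmetric = TRUE)
  lam <- eg$values
  K <- length(thetaList)
  Tk <- matrix(0, length(lam), K)
  Tk[, 1] <- 1
  if (K >= 2) Tk[, 2] <- lam
  if (K >= 3) {
    for (k in 3:K) Tk[, k] <- 2 * lam * Tk[, k - 1] - Tk[, k - 2]
  }
  cout <- ncol(thetaList[[1]])
  out <- matrix(0, nrow(signal), cout)
  xs <- crossprod(eg$vectors, signal) # U' x, per input channel
  for (co in seq_len(cout)) {
    acc <- matrix(0, length(lam), 1)
    for (k in seq_len(K)) {
      acc <- acc + (Tk[, k] * xs) %*% thetaList[[k]][, co, drop = FALSE]
    }
    out[, co] <- eg$vectors %*% acc
  }
  out
}

# O(n^2) pair-counting AUC with half-credit ties.
aucPairOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# Tiny model configuration for gradient checks and end-to-end toys.
toyConfig <- function(windowLength = 6L, kernel = 3L, seed = 2,
                      ablation = "deeppn") {
  deepPNConfig(
    encoding = list(windowLength = windowLength),
    chebnet = list(K = 2L, embedChannels = 3L, channels = c(3L, 4L)),
    cnn = list(kernelSize = kernel, filters = c(3L, 4L)),
    head = list(hidden = c(5L, 4L), dropout = 0),
    training = list(ablation = ablation),
    seed = seed
  )
}

randomOneHotBatch <- function(B, L) {
  X <- matrix(0, B * L, 4)
  X[cbind(seq_len(B * L), sample(4, B * L, replace = TRUE))] <- 1
  X
}

# Central finite differences of a scalar function of the parameter
# list, one parameter tensor at a time.
numericalGrad <- function(lossFn, params, names, h = 1e-5) {
  out <- list()
  for (nm in names) {
    g <- params[[nm]] * 0
    for (i in seq_along(g)) {
      p2 <- params
      p2[[nm]][i] <- p2[[nm]][i] + h
      up <- lossFn(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * h
      dn <- lossFn(p2)
      g[i] <- (up - dn) / (2 * h)
    }
    out[[nm]] <- g
  }
  out
}

dinucCounts <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(chars) < 2) return(table(character(0)))
  table(paste0(chars[-length(chars)], chars[-1]))
}
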