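# Normalize a Chebyshev coefficient container to a list of K
# (Cin x Cout) matrices. Accepts a 3-d array (K, Cin, Cout) or a list.
thetaAsList <- function(theta) {
  if (is.array(theta) && length(dim(theta)) == 3L) {
    lapply(seq_len(dim(theta)[1]), function(k) {
      matrix(theta[k, , ], nrow = dim(theta)[2], ncol = dim(theta)[3])
    })
  } else if (is.list(theta)) {
    theta
  } else if (is.matrix(theta)) {
    list(theta)
  } else {
    stop("theta must be a (K, Cin, Cout) array or a list of matrices")
  }
}

#' Chebyshev spectral graph convolution
#'
#' Filters a node signal with a K-term Chebyshev polynomial of the
#' rescaled Laplacian:
#' \deqn{Y_{:,c} = \sum_{k=0}^{K-1} T_k(\tilde L)\, S\, \theta_{k,:,c}}
#' which is the recursion form of the spectral filter
#' \eqn{g_\theta = \sum_k \theta_k T_k(\tilde\Lambda)}. Linear in both
#' the signal and the coefficients.
#'
#' @param signal L x Cin node-feature matrix (vector = one column).
#' @param Ltilde a \linkS4class{ScaledLaplacian} over the same L nodes.
#' @param theta coefficients: a \code{(K, Cin, Cout)} array or list of
#'   K \code{Cin x Cout} matrices.
#' @param bias optional length-Cout bias added to every row.
#' @return L x Cout filtered signal.
#' @examples
#' Lt <- scaledLaplacian(buildSequenceGraph(4, 1))
#' # K = 1 with theta0 = 1 is the identity filter
#' chebConv(matrix(rnorm(4)), Lt, array(1, c(1, 1, 1)))
#' @export
chebConv <- function(signal, Ltilde, theta, bias = NULL) {
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1)
  th <- thetaAsList(theta)
  K <- length(th)
  cin <- nrow(th[[1]])
  if (ncol(signal) != cin) {
    stop(sprintf(
      "signal has %d channels but theta expects %d", ncol(signal), cin
    ))
  }
  terms <- chebyshevApply(Ltilde, signal, K)
  Y <- terms[[1]] %*% th[[1]]
  if (K >= 2L) {
    for (k in 2:K) Y <- Y + terms[[k]] %*% th[[k]]
  }
  if (!is.null(bias)) Y <- sweep(Y, 2, bias, "+")
  Y
}

#' Per-position embedding of the one-hot input
#'
#' The learnable linear projection applied to the raw one-hot matrix
#' before the spectral layers: each position's 4-channel indicator is
#' mapped independently to C embedding channels. With the weights fixed
#' to the identity extension the first 4 output channels reproduce the
#' input, which makes the layer testable in isolation.
#'
#' @param X L x 4 one-hot matrix.
#' @param weights 4 x C projection matrix.
#' @param bias optional length-C bias.
#' @return L x C embedded signal.
#' @export
preprocessLayer <- function(X, weights, bias = NULL) {
  if (ncol(X) != nrow(weights)) {
    stop("weights must have one row per input channel")
  }
  Y <- X %*% weights
  if (!is.null(bias)) Y <- sweep(Y, 2, bias, "+")
  Y
}

#' Forward pass of the spectral (ChebNet) branch
#'
#' Embedding, two Chebyshev graph-convolution layers each followed by
#' LeakyReLU, then flattening in fixed row-major (position, channel)
#' order:
#' \code{v = Flatten(LeakyReLU(ChebConv(LeakyReLU(ChebConv(l(X))))))}.
#'
#' @param X L x 4 one-hot matrix.
#' @param Ltilde \linkS4class{ScaledLaplacian} over the L positions.
#' @param preprocess list with \code{weights} (4 x C0) and optional
#'   \code{bias}.
#' @param layer1,layer2 lists with \code{theta} and optional
#'   \code{bias} as in \code{\link{chebConv}}.
#' @param slope LeakyReLU negative slope (default 0.01).
#' @return numeric feature vector of length \code{L * Cout2}, channel
#'   index varying fastest within each position.
#' @export
chebnetForward <- function(X, Ltilde, preprocess, layer1, layer2,
                           slope = 0.01) {
  H <- preprocessLayer(X, preprocess$weights, preprocess$bias)
  H <- leakyRelu(chebConv(H, Ltilde, layer1$theta, layer1$bias), slope)
  H <- leakyRelu(chebConv(H, Ltilde, layer2$theta, layer2$bias), slope)
  as.vector(t(H))
}
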