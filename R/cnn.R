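# Normalize convolution weights to a (kernel * Cin) x F matrix whose
# row blocks are offset-major: row (j-1)*Cin + c holds offset j,
# channel c. Accepts a 3-d array (F, kernel, Cin) or the flat matrix.
convWeightsAsMatrix <- function(weights) {
  if (is.array(weights) && length(dim(weights)) == 3L) {
    d <- dim(weights) # (filters, kernel, channels)
    W <- matrix(0, nrow = d[2] * d[3], ncol = d[1])
    for (f in seq_len(d[1])) {
      W[, f] <- as.vector(t(matrix(weights[f, , ], d[2], d[3])))
    }
    W
  } else if (is.matrix(weights)) {
    weights
  } else {
    stop("weights must be a (filters, kernel, channels) array or matrix")
  }
}

# Sliding-window expansion (im2col): stack, for every valid offset, the
# kernel-width slice of the signal so convolution becomes one matrix
# product. Rows of the result are output positions; column block j
# holds the channels at window offset j.
im2col <- function(signal, kernel) {
  L <- nrow(signal)
  Lout <- L - kernel + 1L
  rows <- seq_len(Lout)
  do.call(cbind, lapply(0:(kernel - 1L), function(j) {
    signal[rows + j, , drop = FALSE]
  }))
}

#' 1-D sliding-window convolution over a sequence signal
#'
#' Cross-correlation semantics (no kernel flip): output position
#' \code{i}, filter \code{f} is the dot product of the kernel with the
#' signal window starting at \code{i}, plus the filter bias.
#' \code{"valid"} yields \code{L - kernel + 1} positions;
#' \code{"same"} zero-pads symmetrically to keep \code{L} positions.
#'
#' @param signal L x Cin matrix (one-hot input or previous layer
#'   output).
#' @param weights \code{(filters, kernel, Cin)} array, or the
#'   equivalent \code{(kernel*Cin) x filters} matrix with offset-major
#'   row blocks.
#' @param bias optional length-filters bias.
#' @param padding \code{"valid"} (default) or \code{"same"}.
#' @return Lout x filters response matrix.
#' @examples
#' X <- oneHotEncode("ACGUA", 5)
#' motif <- array(0, c(1, 3, 4))
#' motif[1, , ] <- oneHotEncode("CGU", 3)
#' conv1d(X, motif) # response peaks (3) at offset 2 where CGU sits
#' @export
conv1d <- function(signal, weights, bias = NULL,
                   padding = c("valid", "same")) {
  padding <- match.arg(padding)
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1)
  W <- convWeightsAsMatrix(weights)
  cin <- ncol(signal)
  if (nrow(W) %% cin != 0) {
    stop("weight rows are not a multiple of the input channel count")
  }
  kernel <- nrow(W) %/% cin
  if (padding == "same") {
    padLeft <- (kernel - 1L) %/% 2L
    padRight <- kernel - 1L - padLeft
    signal <- rbind(
      matrix(0, padLeft, cin), signal, matrix(0, padRight, cin)
    )
  } else if (kernel > nrow(signal)) {
    stop(sprintf(
      "kernel size %d exceeds signal length %d in 'valid' mode",
      kernel, nrow(signal)
    ))
  }
  Y <- im2col(signal, kernel) %*% W
  if (!is.null(bias)) Y <- sweep(Y, 2, bias, "+")
  Y
}

#' Forward pass of the motif-scanning convolutional branch
#'
#' Two convolution layers sharing one kernel size (16 then 32 filters
#' under the default configuration), each followed by LeakyReLU, then
#' flattening in fixed row-major (position, channel) order:
#' \code{v = Flatten(LeakyReLU(Conv(LeakyReLU(Conv(X)))))}. No pooling
#' layers sit between the convolutions.
#'
#' @param X L x 4 one-hot matrix.
#' @param layer1,layer2 lists with \code{weights} and optional
#'   \code{bias} as in \code{\link{conv1d}}.
#' @param slope LeakyReLU negative slope (default 0.01).
#' @param padding passed to both layers.
#' @return numeric feature vector, channel index varying fastest
#'   within each retained position.
#' @export
cnnForward <- function(X, layer1, layer2, slope = 0.01,
                       padding = c("valid", "same")) {
  padding <- match.arg(padding)
  H <- leakyRelu(conv1d(X, layer1$weights, layer1$bias, padding), slope)
  H <- leakyRelu(conv1d(H, layer2$weights, layer2$bias, padding), slope)
  as.vector(t(H))
}
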