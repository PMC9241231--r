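#' Build the position graph of a sequence window
#'
#' Connects positions \code{i} and \code{j} whenever
#' \code{0 < |i - j| <= window}: a path graph for \code{window = 1},
#' reflecting the covalent backbone, with wider radii as a smoothing
#' knob. One graph per window length serves every sequence; only the
#' node features differ.
#'
#' @param length number of positions (>= 2).
#' @param window neighbour radius, \code{1 <= window < length}.
#' @return a \linkS4class{SequenceGraph}.
#' @examples
#' buildSequenceGraph(3, 1) # the 3-node path
#' @export
buildSequenceGraph <- function(length, window = 1) {
  length <- stopifnotScalarCount(length, "length")
  window <- stopifnotScalarCount(window, "window")
  if (length < 2L) stop("length must be at least 2")
  if (window >= length) stop("window must be smaller than length")
  d <- abs(outer(seq_len(length), seq_len(length), "-"))
  A <- (d > 0 & d <= window) * 1
  new("SequenceGraph", adjacency = A, window = window)
}

#' Rescaled normalized Laplacian of a position graph
#'
#' Computes the symmetric normalized Laplacian
#' \eqn{L = I - D^{-1/2} A D^{-1/2}} and rescales it to
#' \eqn{\tilde L = 2 L / \lambda_{max} - I}, mapping the spectrum into
#' \eqn{[-1, 1]} so Chebyshev filters are well defined. Mode
#' \code{"exact"} uses the computed top eigenvalue (cheap, done once per
#' window length); \code{"approx2"} uses the common shortcut
#' \eqn{\lambda_{max} = 2}, the upper bound of the normalized-Laplacian
#' spectrum.
#'
#' @param graph a \linkS4class{SequenceGraph}.
#' @param lambdaMaxMode \code{"exact"} or \code{"approx2"}.
#' @return a \linkS4class{ScaledLaplacian}.
#' @export
scaledLaplacian <- function(graph, lambdaMaxMode = c("exact", "approx2")) {
  stopifnot(is(graph, "SequenceGraph"))
  lambdaMaxMode <- match.arg(lambdaMaxMode)
  A <- graph@adjacency
  deg <- rowSums(A)
  if (any(deg == 0)) {
    stop("graph has an isolated node (zero degree); Laplacian undefined")
  }
  dinv <- 1 / sqrt(deg)
  L <- diag(nrow(A)) - (dinv * A) %*% diag(dinv)
  L <- (L + t(L)) / 2 # symmetrize away rounding noise
  lmax <- if (lambdaMaxMode == "exact") {
    max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  } else {
    2
  }
  Lt <- 2 * L / lmax - diag(nrow(A))
  new("ScaledLaplacian", matrix = Lt, lambdaMax = lmax, mode = lambdaMaxMode)
}

#' Apply the Chebyshev polynomial basis to a signal
#'
#' Evaluates the three-term recursion
#' \eqn{T_k(x) = 2 x T_{k-1}(x) - T_{k-2}(x)} with \eqn{T_0 = I},
#' \eqn{T_1 = \tilde L} on the node signal, returning the list
#' \eqn{[T_0(\tilde L) S, \ldots, T_{K-1}(\tilde L) S]}. The recursion
#' avoids any eigendecomposition at filter time.
#'
#' @param Ltilde a \linkS4class{ScaledLaplacian}.
#' @param signal numeric matrix with one row per node (a vector is
#'   treated as a one-column matrix).
#' @param K number of polynomial terms (>= 1).
#' @return list of \code{K} matrices, each the shape of \code{signal}.
#' @export
chebyshevApply <- function(Ltilde, signal, K) {
  stopifnot(is(Ltilde, "ScaledLaplacian"))
  K <- stopifnotScalarCount(K, "K")
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1)
  M <- Ltilde@matrix
  if (nrow(signal) != nrow(M)) {
    stop(sprintf(
      "signal has %d rows but the graph has %d nodes",
      nrow(signal), nrow(M)
    ))
  }
  terms <- vector("list", K)
  terms[[1]] <- signal
  if (K >= 2L) terms[[2]] <- M %*% signal
  if (K >= 3L) {
    for (k in 3:K) {
      terms[[k]] <- 2 * (M %*% terms[[k - 1]]) - terms[[k - 2]]
    }
  }
  terms
}

#' Dense Chebyshev polynomial matrices of a scaled Laplacian
#'
#' Materializes \eqn{T_k(\tilde L)} for \code{k = 0..K-1} by the same
#' three-term recursion. For a fixed window length these are computed
#' once and reused for every sequence, turning each graph-convolution
#' layer into plain matrix products.
#'
#' @inheritParams chebyshevApply
#' @return list of \code{K} dense matrices.
#' @export
chebyshevBasis <- function(Ltilde, K) {
  stopifnot(is(Ltilde, "ScaledLaplacian"))
  K <- stopifnotScalarCount(K, "K")
  n <- nrow(Ltilde@matrix)
  chebyshevApply(Ltilde, diag(n), K)
}
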