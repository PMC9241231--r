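#' @import methods
NULL

#' Labeled RNA sequence dataset
#'
#' Container pairing RNA sequences with binary bound/unbound labels, the
#' unit of input for training and evaluation. Sequences are stored as an
#' \linkS4class{RNAStringSet}; any \code{T} in the input is converted to
#' \code{U} on construction and characters outside \code{A,C,G,U,N} are
#' rejected. An optional truth table carries simulation ground truth
#' (planted motif positions) for audits.
#'
#' @slot sequences \linkS4class{RNAStringSet} of RNA windows.
#' @slot labels integer vector of 0/1 labels, one per sequence.
#' @slot truth \code{data.frame} with columns \code{id}, \code{label},
#'   \code{plantedPos} (\code{-1} where no motif was planted), or a
#'   zero-row frame when ground truth is unknown.
#'
#' @export
setClass("RBPDataset",
  representation(
    sequences = "RNAStringSet",
    labels = "integer",
    truth = "data.frame"
  )
)

setValidity("RBPDataset", function(object) {
  msg <- character()
  if (length(object@sequences) != length(object@labels))
    msg <- c(msg, "sequences and labels must have equal length")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 or 1")
  if (nrow(object@truth) && nrow(object@truth) != length(object@labels))
    msg <- c(msg, "truth table must have one row per record")
  if (length(msg)) msg else TRUE
})

#' Position graph over a fixed-length sequence window
#'
#' Undirected graph whose nodes are sequence positions, with an edge
#' between positions \code{i} and \code{j} whenever
#' \code{0 < |i - j| <= window}. This is the backbone-adjacency the
#' spectral branch filters over; the topology is shared by all sequences
#' of the same length.
#'
#' @slot adjacency symmetric 0/1 matrix with zero diagonal.
#' @slot window integer neighbour radius.
#'
#' @export
setClass("SequenceGraph",
  representation(adjacency = "matrix", window = "integer")
)

setValidity("SequenceGraph", function(object) {
  A <- object@adjacency
  msg <- character()
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  if (nrow(A) >= 1 && any(diag(A) != 0)) msg <- c(msg, "diagonal must be zero")
  if (!isSymmetric(unname(A))) msg <- c(msg, "adjacency must be symmetric")
  if (!all(A %in% c(0, 1))) msg <- c(msg, "adjacency entries must be 0/1")
  if (length(object@window) != 1L || object@window < 1L)
    msg <- c(msg, "window must be a single positive integer")
  if (length(msg)) msg else TRUE
})

#' Rescaled normalized graph Laplacian
#'
#' Holds \eqn{\tilde L = 2L/\lambda_{max} - I} where
#' \eqn{L = I - D^{-1/2} A D^{-1/2}} is the symmetric normalized
#' Laplacian. When \code{lambdaMax} is the exact top eigenvalue the
#' spectrum of \eqn{\tilde L} lies in \eqn{[-1, 1]}, the domain on which
#' Chebyshev polynomials are well behaved.
#'
#' @slot matrix the rescaled Laplacian \eqn{\tilde L}.
#' @slot lambdaMax largest eigenvalue of \eqn{L} used for rescaling.
#' @slot mode \code{"exact"} or \code{"approx2"}.
#'
#' @export
setClass("ScaledLaplacian",
  representation(matrix = "matrix", lambdaMax = "numeric", mode = "character")
)

setValidity("ScaledLaplacian", function(object) {
  M <- object@matrix
  msg <- character()
  if (nrow(M) != ncol(M)) msg <- c(msg, "matrix must be square")
  if (max(abs(M - t(M))) > 1e-10) msg <- c(msg, "matrix must be symmetric to 1e-10")
  if (object@lambdaMax <= 0) msg <- c(msg, "lambdaMax must be positive")
  if (length(msg)) msg else TRUE
})

#' Position probability matrix motif model
#'
#' Columnwise base-probability model of a binding motif over the RNA
#' alphabet; rows are ordered \code{A,C,G,U} and every column sums to 1.
#' Used by the synthetic generator to plant ground-truth binding signal.
#'
#' @slot pwm 4 x m probability matrix, rownames \code{A,C,G,U}.
#' @slot name motif label.
#'
#' @export
setClass("MotifModel", representation(pwm = "matrix", name = "character"))

setValidity("MotifModel", function(object) {
  p <- object@pwm
  msg <- character()
  if (nrow(p) != 4L || !identical(rownames(p), c("A", "C", "G", "U")))
    msg <- c(msg, "pwm must have 4 rows named A,C,G,U")
  if (any(p < 0)) msg <- c(msg, "pwm entries must be >= 0")
  if (ncol(p) < 1L) msg <- c(msg, "pwm must have at least one column")
  if (ncol(p) >= 1L && max(abs(colSums(p) - 1)) > 1e-9)
    msg <- c(msg, "pwm columns must sum to 1 (tol 1e-9)")
  if (length(msg)) msg else TRUE
})

#' Two-branch RBP binding-site classifier
#'
#' Holds the full parameter set and resolved configuration of the
#' parallel classifier: the per-position embedding and two Chebyshev
#' graph-convolution layers (spectral branch), two sliding-window
#' convolution layers (motif-scanning branch), and the three-layer fully
#' connected head. The position-graph Laplacian and its Chebyshev
#' polynomial basis are precomputed once per window length and stored
#' with the model.
#'
#' @slot params named list of weight matrices and bias vectors.
#' @slot config resolved experiment configuration (see
#'   \code{\link{deepPNConfig}}).
#' @slot laplacian \linkS4class{ScaledLaplacian} of the position graph.
#' @slot chebBasis list of dense \eqn{T_k(\tilde L)} matrices,
#'   \code{k = 0..K-1}.
#'
#' @export
setClass("DeepPNModel",
  representation(
    params = "list", config = "list",
    laplacian = "ScaledLaplacian", chebBasis = "list"
  )
)

#' Fitted classifier with training history
#'
#' @slot model the \linkS4class{DeepPNModel} holding the parameters from
#'   the best monitored epoch (or the final epoch when best-restoration
#'   is disabled).
#' @slot history \code{data.frame} with columns \code{epoch},
#'   \code{trainLoss}, \code{monitorMetric}.
#' @slot bestEpoch epoch whose parameters are stored.
#' @slot stoppedEarly whether the patience rule fired before
#'   \code{maxEpochs}.
#'
#' @export
setClass("DeepPNFit",
  representation(
    model = "DeepPNModel", history = "data.frame",
    bestEpoch = "integer", stoppedEarly = "logical"
  )
)

#' Evaluation report
#'
#' Classification metrics on a labeled dataset: accuracy at threshold
#' 0.5, AUC by the rank statistic (ties count 1/2; \code{NA} when only
#' one class is present), and the binary cross-entropy both as the
#' summed negative log-likelihood and as the per-sample mean.
#'
#' @slot accuracy fraction correct.
#' @slot auc area under the ROC curve, or \code{NA}.
#' @slot lossSum summed binary cross-entropy.
#' @slot lossMean per-sample mean binary cross-entropy.
#' @slot n number of records evaluated.
#'
#' @export
setClass("EvalReport",
  representation(
    accuracy = "numeric", auc = "numeric",
    lossSum = "numeric", lossMean = "numeric", n = "integer"
  )
)

setValidity("EvalReport", function(object) {
  msg <- character()
  if (object@accuracy < 0 || object@accuracy > 1)
    msg <- c(msg, "accuracy must be in [0, 1]")
  if (!is.na(object@auc) && (object@auc < 0 || object@auc > 1))
    msg <- c(msg, "auc must be in [0, 1]")
  if (object@lossSum < 0) msg <- c(msg, "loss must be >= 0")
  if (length(msg)) msg else TRUE
})
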