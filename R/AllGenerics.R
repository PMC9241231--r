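#' Extract the sequences of a dataset
#' @param x an \linkS4class{RBPDataset}.
#' @return an \linkS4class{RNAStringSet}.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname sequences
#' @export
setMethod("sequences", "RBPDataset", function(x) x@sequences)

#' Extract the 0/1 labels of a dataset
#' @param object an \linkS4class{RBPDataset}.
#' @param ... ignored.
#' @return integer vector of labels.
#' @export
setMethod("labels", "RBPDataset", function(object, ...) object@labels)

#' Ground-truth table of a simulated dataset
#' @param x an \linkS4class{RBPDataset}.
#' @return \code{data.frame} with \code{id}, \code{label},
#'   \code{plantedPos}; zero rows when no ground truth is attached.
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname truthTable
#' @export
setMethod("truthTable", "RBPDataset", function(x) x@truth)

#' @describeIn RBPDataset-class number of records.
#' @param x an \linkS4class{RBPDataset}.
#' @export
setMethod("length", "RBPDataset", function(x) length(x@labels))

#' @describeIn RBPDataset-class subset records.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "RBPDataset", function(x, i, j, ..., drop = TRUE) {
  tr <- if (nrow(x@truth)) x@truth[i, , drop = FALSE] else x@truth
  new("RBPDataset",
    sequences = x@sequences[i], labels = x@labels[i], truth = tr
  )
})

#' Accuracy of an evaluation report
#' @param x an \linkS4class{EvalReport}.
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname accuracy
#' @export
setMethod("accuracy", "EvalReport", function(x) x@accuracy)

#' AUC of an evaluation report
#' @param x an \linkS4class{EvalReport}.
#' @return the rank-statistic AUC, or \code{NA} for a single-class set.
#' @export
setGeneric("rocAUC", function(x) standardGeneric("rocAUC"))

#' @rdname rocAUC
#' @export
setMethod("rocAUC", "EvalReport", function(x) x@auc)

#' Cross-entropy loss of an evaluation report
#' @param x an \linkS4class{EvalReport}.
#' @param type \code{"sum"} (the summed negative log-likelihood) or
#'   \code{"mean"} (per-sample mean, the quantity the optimizer
#'   minimizes).
#' @export
setGeneric("evalLoss", function(x, type = c("sum", "mean")) {
  standardGeneric("evalLoss")
})

#' @rdname evalLoss
#' @export
setMethod("evalLoss", "EvalReport", function(x, type = c("sum", "mean")) {
  switch(match.arg(type), sum = x@lossSum, mean = x@lossMean)
})

#' Predict binding probabilities
#'
#' @param object a \linkS4class{DeepPNModel}, \linkS4class{DeepPNFit},
#'   or a numeric fused feature vector (in which case \code{head} must
#'   supply the dense-head parameters).
#' @param ... passed to methods.
#' @return numeric vector of probabilities in (0, 1).
#' @export
setGeneric("predictProba", function(object, ...) {
  standardGeneric("predictProba")
})

setMethod("show", "RBPDataset", function(object) {
  n1 <- sum(object@labels == 1L)
  cat("RBPDataset with", length(object@labels), "records (",
    n1, "positive /", length(object@labels) - n1, "negative )\n")
  if (length(object@sequences))
    cat("  window widths:", paste(unique(range(
      Biostrings::width(object@sequences))), collapse = "-"), "nt\n")
  if (nrow(object@truth)) cat("  ground-truth table attached\n")
})

setMethod("show", "SequenceGraph", function(object) {
  cat("SequenceGraph:", nrow(object@adjacency), "positions, neighbour radius",
    object@window, "\n")
})

setMethod("show", "ScaledLaplacian", function(object) {
  cat("ScaledLaplacian on", nrow(object@matrix), "nodes; lambda_max =",
    format(object@lambdaMax, digits = 6), paste0("(", object@mode, ")"), "\n")
})

setMethod("show", "MotifModel", function(object) {
  cat("MotifModel", object@name, "- width", ncol(object@pwm), "nt, consensus",
    paste(rownames(object@pwm)[apply(object@pwm, 2, which.max)],
      collapse = ""), "\n")
})

setMethod("show", "DeepPNModel", function(object) {
  cfg <- object@config
  npar <- sum(vapply(object@params, length, integer(1)))
  cat("DeepPNModel (", cfg$training$ablation, ")\n", sep = "")
  cat("  window:", cfg$encoding$windowLength, "nt | graph radius:",
    cfg$graph$window, "| Chebyshev order:", cfg$chebnet$K, "\n")
  cat("  conv kernel:", cfg$cnn$kernelSize, "| filters:",
    paste(cfg$cnn$filters, collapse = "/"), "| parameters:", npar, "\n")
})

setMethod("show", "DeepPNFit", function(object) {
  h <- object@history
  cat("DeepPNFit:", nrow(h), "epochs trained; best epoch", object@bestEpoch,
    if (object@stoppedEarly) "(early stop)" else "(max epochs)", "\n")
  if (nrow(h))
    cat("  final train loss", format(h$trainLoss[nrow(h)], digits = 4),
      "| best monitor metric",
      format(max(h$monitorMetric), digits = 4), "\n")
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport on", object@n, "records\n")
  cat("  accuracy:", format(object@accuracy, digits = 4),
    "| AUC:", ifelse(is.na(object@auc), "NA",
      format(object@auc, digits = 4)),
    "| mean loss:", format(object@lossMean, digits = 4), "\n")
})
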