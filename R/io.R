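#' Build a labeled dataset from sequences and labels
#'
#' @param seqs character vector, \code{RNAStringSet}, or any
#'   \code{XStringSet}; \code{T} is accepted and converted to \code{U}.
#' @param labels 0/1 vector, one per sequence.
#' @param truth optional ground-truth \code{data.frame}.
#' @return an \linkS4class{RBPDataset}.
#' @examples
#' RBPDataset(c(a = "ACGU", b = "GGUU"), c(1, 0))
#' @export
RBPDataset <- function(seqs, labels, truth = NULL) {
  if (is(seqs, "XStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  cleaned <- vapply(unname(seqs), cleanResidues, character(1))
  names(cleaned) <- names(seqs)
  rna <- Biostrings::RNAStringSet(cleaned)
  if (is.null(truth)) {
    truth <- data.frame(
      id = character(), label = integer(), plantedPos = integer(),
      stringsAsFactors = FALSE
    )
  }
  new("RBPDataset",
    sequences = rna, labels = as.integer(labels), truth = truth
  )
}

readFastaChecked <- function(path, tag) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in ", path, ": ", conditionMessage(e))
    }
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  w <- Biostrings::width(set)
  if (any(w == 0L)) {
    stop(sprintf(
      "record '%s' in %s has no sequence line",
      names(set)[which(w == 0L)[1]], path
    ))
  }
  chars <- as.character(set)
  for (i in seq_along(chars)) {
    chars[i] <- tryCatch(
      cleanResidues(chars[i]),
      error = function(e) {
        stop(sprintf(
          "record '%s' (%s, %s): %s",
          names(set)[i], tag, path, conditionMessage(e)
        ))
      }
    )
  }
  names(chars) <- names(set)
  chars
}

#' Read a paired positive/negative FASTA dataset
#'
#' The paired-FASTA convention of CLIP benchmark distributions: one
#' file of bound windows, one of unbound controls. Positives get label
#' 1, negatives 0; \code{T} is converted to \code{U}; ids duplicated
#' across the two files are disambiguated with \code{pos|}/\code{neg|}
#' prefixes.
#'
#' @param posPath,negPath paths to the FASTA files.
#' @return an \linkS4class{RBPDataset}, positives first.
#' @export
readFastaPair <- function(posPath, negPath) {
  pos <- readFastaChecked(posPath, "positives")
  neg <- readFastaChecked(negPath, "negatives")
  if (length(intersect(names(pos), names(neg)))) {
    names(pos) <- paste0("pos|", names(pos))
    names(neg) <- paste0("neg|", names(neg))
  }
  RBPDataset(
    c(pos, neg),
    c(rep(1L, length(pos)), rep(0L, length(neg)))
  )
}

#' Write a dataset as paired FASTA plus a truth table
#'
#' Produces \code{<prefix>.positives.fa}, \code{<prefix>.negatives.fa}
#' and, when ground truth is attached, \code{<prefix>.truth.tsv}.
#'
#' @param data an \linkS4class{RBPDataset}.
#' @param prefix output path prefix.
#' @return invisibly, the written file paths.
#' @export
writeDatasetFasta <- function(data, prefix) {
  y <- labels(data)
  posFile <- paste0(prefix, ".positives.fa")
  negFile <- paste0(prefix, ".negatives.fa")
  Biostrings::writeXStringSet(sequences(data)[y == 1L], posFile)
  Biostrings::writeXStringSet(sequences(data)[y == 0L], negFile)
  files <- c(posFile, negFile)
  if (nrow(truthTable(data))) {
    truthFile <- paste0(prefix, ".truth.tsv")
    utils::write.table(truthTable(data), truthFile, sep = "\t",
      quote = FALSE, row.names = FALSE)
    files <- c(files, truthFile)
  }
  invisible(files)
}

#' Read / write an experiment configuration as YAML
#'
#' Reads a YAML file and merges it over the package defaults, so a
#' config echoed by a run reproduces that run when fed back in.
#'
#' @param path YAML file path.
#' @return resolved configuration list.
#' @export
readExperimentConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  do.call(deepPNConfig, user)
}

#' @rdname readExperimentConfig
#' @param config configuration list to serialize.
#' @export
writeExperimentConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' A versioned archive holding every parameter tensor together with
#' the resolved configuration; the Laplacian and Chebyshev basis are
#' rebuilt from the configuration on load, so the archive stays small.
#'
#' @param object a \linkS4class{DeepPNModel} or \linkS4class{DeepPNFit}.
#' @param path checkpoint file path.
#' @export
saveCheckpoint <- function(object, path) {
  fit <- NULL
  if (is(object, "DeepPNFit")) {
    fit <- list(
      history = object@history, bestEpoch = object@bestEpoch,
      stoppedEarly = object@stoppedEarly
    )
    object <- object@model
  }
  saveRDS(
    list(
      schema = "deepPN-checkpoint-1",
      config = object@config, params = object@params, fit = fit
    ),
    path
  )
  invisible(path)
}

#' @rdname saveCheckpoint
#' @return \code{loadCheckpoint}: the restored
#'   \linkS4class{DeepPNModel} or \linkS4class{DeepPNFit}.
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$schema, "deepPN-checkpoint-1")) {
    stop("unrecognized checkpoint schema")
  }
  model <- deepPNModel(ck$config)
  model@params <- ck$params
  if (is.null(ck$fit)) return(model)
  new("DeepPNFit",
    model = model, history = ck$fit$history,
    bestEpoch = ck$fit$bestEpoch, stoppedEarly = ck$fit$stoppedEarly
  )
}

#' Export training history as TSV
#'
#' @param fit a \linkS4class{DeepPNFit}.
#' @param path output file.
#' @export
exportHistory <- function(fit, path) {
  utils::write.table(fit@history, path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

#' Export per-sequence predictions as TSV
#'
#' Columns: sequence id, probability, predicted label at threshold
#' 0.5.
#'
#' @param object model or fit.
#' @param data an \linkS4class{RBPDataset}.
#' @param path output file.
#' @export
exportPredictions <- function(object, data, path) {
  p <- predictProba(object, data)
  ids <- names(sequences(data))
  if (is.null(ids)) ids <- sprintf("seq_%04d", seq_along(p))
  utils::write.table(
    data.frame(id = ids, probability = p,
      predictedLabel = as.integer(p >= 0.5)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Export an evaluation report as JSON or TSV
#'
#' @param report an \linkS4class{EvalReport}.
#' @param path output file; extension \code{.json} selects JSON,
#'   anything else TSV.
#' @export
exportEvalReport <- function(report, path) {
  vals <- list(
    accuracy = report@accuracy, auc = report@auc,
    lossSum = report@lossSum, lossMean = report@lossMean, n = report@n
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("jsonlite is required for JSON export")
    }
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(
      data.frame(metric = names(vals), value = unlist(vals)),
      path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}

#' Export the one-hot encoding of sequences as TSV
#'
#' One row per position, columns \code{A,C,G,U}, records separated by
#' their id in a leading column; a debugging aid.
#'
#' @param data an \linkS4class{RBPDataset}.
#' @param path output file.
#' @param windowLength encoding window.
#' @export
exportOneHot <- function(data, path, windowLength = 101) {
  ids <- names(sequences(data))
  if (is.null(ids)) ids <- sprintf("seq_%04d", seq_len(length(data)))
  blocks <- lapply(seq_len(length(data)), function(i) {
    X <- oneHotEncode(as.character(sequences(data)[[i]]), windowLength)
    data.frame(id = ids[i], position = seq_len(nrow(X)), X)
  })
  utils::write.table(do.call(rbind, blocks), path, sep = "\t",
    quote = FALSE, row.names = FALSE)
  invisible(path)
}
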