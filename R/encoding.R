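#' One-hot encode an RNA sequence into a fixed window
#'
#' Each position becomes a 4-dimensional indicator over the alphabet
#' \code{A,C,G,U} (columns in that order). \code{N} positions map to an
#' all-zero row, as do padding rows, so every row sums to exactly 1 or
#' 0 and padding is inert under convolution. Sequences shorter than the
#' window are right-padded with zero rows; longer sequences are
#' centre-truncated, since binding evidence in CLIP-style windows is
#' centred on the crosslink site.
#'
#' @param seq residue string over \code{A,C,G,U,N} (\code{T} accepted
#'   as \code{U}), or an \code{RNAString}.
#' @param windowLength number of rows of the output (default 101, the
#'   standard intercepted CLIP window length).
#' @return \code{windowLength} x 4 numeric matrix with columns
#'   \code{A,C,G,U}.
#' @examples
#' oneHotEncode("ACGU", 4) # the 4x4 identity
#' @export
oneHotEncode <- function(seq, windowLength = 101) {
  seq <- cleanResidues(as.character(seq))
  windowLength <- stopifnotScalarCount(windowLength, "windowLength")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L > windowLength) {
    start <- (L - windowLength) %/% 2 + 1L
    chars <- chars[start:(start + windowLength - 1L)]
    L <- windowLength
  }
  X <- matrix(0, nrow = windowLength, ncol = 4,
    dimnames = list(NULL, RNA_BASES))
  hit <- match(chars, RNA_BASES) # N -> NA -> stays all-zero
  ok <- which(!is.na(hit))
  X[cbind(ok, hit[ok])] <- 1
  X
}

#' k-gram frequency features
#'
#' Counts every base permutation of each order \code{1..k} over the
#' sliding windows of the sequence and normalizes counts to
#' frequencies within each order, yielding a vector of dimension
#' \eqn{\sum_{i=1}^{k} 4^i} (84 for \code{k = 3}). Windows containing
#' \code{N} are skipped rather than imputed. Within each order the
#' permutations are enumerated alphabetically (\code{A < C < G < U}).
#'
#' @param seq residue string (\code{T} accepted as \code{U}).
#' @param k maximum order (default 3).
#' @return named numeric vector of per-order frequencies, with
#'   attribute \code{k}.
#' @examples
#' f <- kgramFeatures("ACGU", k = 1) # each base 0.25
#' length(kgramFeatures("ACGUACGU", k = 3)) # 84
#' @export
kgramFeatures <- function(seq, k = 3) {
  seq <- cleanResidues(as.character(seq))
  k <- stopifnotScalarCount(k, "k")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  informative <- sum(chars %in% RNA_BASES)
  if (k > informative) {
    stop(sprintf(
      "k = %d exceeds the informative sequence length (%d)", k, informative
    ))
  }
  out <- numeric(0)
  for (ord in seq_len(k)) {
    vocab <- sort(apply(
      expand.grid(replicate(ord, RNA_BASES, simplify = FALSE),
        stringsAsFactors = FALSE),
      1, paste, collapse = ""
    ))
    counts <- stats::setNames(numeric(length(vocab)), vocab)
    n <- length(chars) - ord + 1L
    if (n >= 1L) {
      starts <- seq_len(n)
      wins <- substring(seq, starts, starts + ord - 1L)
      wins <- wins[!grepl("N", wins, fixed = TRUE)]
      if (length(wins)) {
        tab <- table(wins)
        counts[names(tab)] <- as.numeric(tab)
        counts <- counts / sum(counts)
      }
    }
    out <- c(out, counts)
  }
  attr(out, "k") <- k
  out
}

#' Overlapping k-mer tokens
#'
#' Returns the length-\code{k} substrings of the sequence in order,
#' advancing by \code{stride}. Tokens containing \code{N} are dropped,
#' consistent with the k-gram window rule.
#'
#' @param seq residue string (\code{T} accepted as \code{U}).
#' @param k token length.
#' @param stride step between successive windows (default 1,
#'   overlapping).
#' @return character vector of tokens.
#' @examples
#' kmerTokens("ACGUA", 4) # "ACGU" "CGUA"
#' @export
kmerTokens <- function(seq, k = 4, stride = 1) {
  seq <- cleanResidues(as.character(seq))
  k <- stopifnotScalarCount(k, "k")
  stride <- stopifnotScalarCount(stride, "stride")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  informative <- sum(chars %in% RNA_BASES)
  if (k > informative) {
    stop(sprintf(
      "k = %d exceeds the informative sequence length (%d)", k, informative
    ))
  }
  starts <- seq.int(1L, nchar(seq) - k + 1L, by = stride)
  toks <- substring(seq, starts, starts + k - 1L)
  toks[!grepl("N", toks, fixed = TRUE)]
}

# Encode every record of a dataset into one stacked matrix of
# dimension (n * windowLength) x 4, rows blocked per record with the
# position index varying fastest. This is the layout the batched
# network kernels consume.
encodeDataset <- function(data, windowLength = 101) {
  seqs <- as.character(sequences(data))
  n <- length(seqs)
  X <- matrix(0, nrow = n * windowLength, ncol = 4)
  for (i in seq_len(n)) {
    X[((i - 1L) * windowLength + 1L):(i * windowLength), ] <-
      oneHotEncode(seqs[i], windowLength)
  }
  X
}
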