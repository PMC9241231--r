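RNA_BASES <- c("A", "C", "G", "U")

leakyRelu <- function(x, slope = 0.01) {
  pos <- x > 0
  x * pos + (slope * x) * !pos
}

leakyReluGrad <- function(x, slope = 0.01) {
  pos <- x > 0
  pos + slope * !pos
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Clean and validate an RNA residue string
#'
#' Uppercases, maps \code{T} to \code{U} (DNA-alphabet input is
#' accepted), and rejects any character outside \code{A,C,G,U,N},
#' reporting the first offending position.
#'
#' @param x character scalar of residues.
#' @return cleaned residue string over \code{A,C,G,U,N}.
#' @examples
#' cleanResidues("acgtn") # "ACGUN"
#' @export
cleanResidues <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("residues must be a single character string")
  if (nchar(x) == 0L) stop("residues must be non-empty")
  x <- chartr("acgutn", "ACGUUN", x)
  x <- chartr("T", "U", x)
  bad <- regexpr("[^ACGUN]", x)
  if (bad > 0L) {
    stop(sprintf(
      "invalid residue '%s' at position %d", substr(x, bad, bad), bad
    ))
  }
  x
}

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

stopifnotScalarCount <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != floor(x))
    stop(what, " must be a single positive integer")
  as.integer(x)
}
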