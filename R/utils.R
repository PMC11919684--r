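# shared internal helpers

# the 20-letter standard amino-acid alphabet, in the conventional order
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Run code with a temporary, restored RNG state
#'
#' All randomised operations in the package route their seed through this
#' helper so that a fixed seed gives identical results without disturbing the
#' caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code code to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# sample() without the length-1 surprise: always treats x as a vector
sampleVec <- function(x, size) {
  if (length(x) == 0L || size == 0L) return(x[0])
  x[sample.int(length(x), size)]
}

# coerce a character scalar / AAString / length-1 AAStringSet to a plain
# uppercase character scalar
asSequence <- function(x) {
  if (methods::is(x, "XStringSet")) {
    stopifnot(length(x) == 1L)
    x <- as.character(x[[1L]])
  } else if (methods::is(x, "XString")) {
    x <- as.character(x)
  }
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

# split a sequence string into single characters
seqChars <- function(x) strsplit(asSequence(x), "", fixed = TRUE)[[1L]]

stopIfEmptySequence <- function(x) {
  if (nchar(x) == 0L) stop("sequence must be non-empty")
  invisible(x)
}
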