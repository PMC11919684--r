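#' @rdname structureSequence
#' @export
setGeneric("structureSequence", function(x, ...) standardGeneric("structureSequence"))

#' @rdname residueConfidences
#' @export
setGeneric("residueConfidences", function(x, ...) standardGeneric("residueConfidences"))

#' Log-probabilities of the observed residues at requested positions
#'
#' The core of the scorer contract: given a sequence, return the scorer's
#' log-probability of the residue actually present at each requested
#' position. `masked` names the positions hidden from the scorer on this
#' pass; a context-free scorer ignores it, a contextual adapter must honour
#' it. All values must be <= 0 and deterministic for fixed inputs.
#'
#' @param scorer a [LikelihoodScorer-class].
#' @param sequence character scalar or `AAString`.
#' @param positions integer positions to report (default: all).
#' @param masked integer positions masked on this pass (default: `positions`).
#' @return numeric vector of log-probabilities, one per requested position.
#' @export
setGeneric("scoreLogProbs", function(scorer, sequence, positions = NULL,
                                     masked = positions)
  standardGeneric("scoreLogProbs"))

#' Residue distribution at one MSA position, for sampling
#'
#' @param scorer a [LikelihoodScorer-class] supporting generation.
#' @param msa aligned `AAStringSet` (equal widths).
#' @param row index of the row being resampled (excluded from the context).
#' @param position column being sampled.
#' @return numeric probability vector over the 20 standard residues.
#' @export
setGeneric("sampleDistribution", function(scorer, msa, row, position)
  standardGeneric("sampleDistribution"))

#' @rdname selectedSequences
#' @export
setGeneric("selectedSequences", function(x) standardGeneric("selectedSequences"))

#' @rdname controlPairs
#' @export
setGeneric("controlPairs", function(x) standardGeneric("controlPairs"))

#' @rdname stageCounts
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))
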