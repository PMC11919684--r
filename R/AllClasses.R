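#' StructureModel: a parsed single-model protein structure
#'
#' Holds the ATOM records of a predicted (or experimental) structure as a
#' plain atom table. The B-factor column is interpreted as a per-residue
#' prediction confidence in \[0, 100\] (the pLDDT convention of structure
#' predictors, which write the confidence into the B-factor field).
#'
#' @slot atoms data.frame with columns `chain`, `resno`, `resname`, `atom`
#'   (atom name), `element`, `x`, `y`, `z` (Angstrom), `b` (B-factor /
#'   confidence).
#'
#' @seealso [readStructure()], [makeStructure()], [structureSequence()],
#'   [residueConfidences()], [shrakeRupley()]
#' @export
setClass("StructureModel", representation(atoms = "data.frame"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z", "b")
  if (!all(need %in% names(a)))
    return(paste("atoms table must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("structure must contain at least one atom")
  for (ch in unique(a$chain)) {
    r <- a$resno[a$chain == ch]
    runs <- rle(r)$values            # consecutive residue blocks, file order
    if (is.unsorted(runs, strictly = TRUE))
      return(sprintf("residue numbering not strictly increasing in chain %s", ch))
  }
  TRUE
})

#' MaskSchedule: which positions are masked on each scoring pass
#'
#' A schedule with interval `m` masks every `m`-th position per pass and
#' therefore needs exactly `m` passes to cover every position once.
#' `interval = 1` is the degenerate single-pass schedule that masks (or, for
#' context-free scorers, simply visits) every position.
#'
#' @slot interval positive integer masking interval.
#' @export
setClass("MaskSchedule", representation(interval = "integer"))

setValidity("MaskSchedule", function(object) {
  if (length(object@interval) != 1L || is.na(object@interval) ||
      object@interval < 1L)
    return("interval must be a single positive integer")
  TRUE
})

#' LikelihoodScorer: the scorer contract
#'
#' Virtual parent for anything that can report the log-probability of the
#' observed residue at requested positions of a sequence (optionally in the
#' context of an MSA) and, for generation, expose the full per-position
#' residue distribution. Real language models attach here via adapters; the
#' package ships [pssmScorer()] as a deterministic, dependency-free
#' implementation so the whole pipeline is testable offline.
#'
#' @export
setClass("LikelihoodScorer", representation("VIRTUAL"))

#' PssmScorer: position-specific scoring matrix scorer
#'
#' A context-free scorer backed by a position probability matrix with
#' pseudocount `alpha`. When constructed without an MSA it operates in
#' "context mode": the matrix is derived on the fly from whatever MSA it is
#' asked to score against (see [msaContextScore()]).
#'
#' @slot probs numeric matrix, positions x 20 residues, rows summing to 1;
#'   zero-row matrix in context mode.
#' @slot alpha pseudocount used when (re)deriving the matrix from an MSA.
#' @export
setClass("PssmScorer", contains = "LikelihoodScorer",
         representation(probs = "matrix", alpha = "numeric"))

setValidity("PssmScorer", function(object) {
  p <- object@probs
  if (nrow(p) > 0L) {
    if (ncol(p) != 20L) return("probs must have 20 columns")
    if (any(p < 0)) return("probabilities must be non-negative")
    if (any(abs(rowSums(p) - 1) > 1e-8)) return("rows of probs must sum to 1")
  }
  if (length(object@alpha) != 1L || object@alpha < 0)
    return("alpha must be a single non-negative number")
  TRUE
})

#' FilterPolicy: tunable parameters of the selection filter
#'
#' Defaults reproduce the validation-round procedure: candidates must sit in
#' a 50--80\% identity band to the closest training sequence (both endpoints
#' inclusive), clear the top-10th-percentile language-model cutoff calibrated
#' on natural sequences, and pass sequence quality checks; 200 passing
#' sequences are sampled, the top 40 by structure score retained, 18 drawn
#' for the bench, and each selection is paired with a filter-failing control
#' within 1\% identity.
#'
#' @slot identityBand numeric length-2, inclusive identity band.
#' @slot lmPercentile top percentile (of natural scores) for the cutoff.
#' @slot nPrefilterSample number of passing sequences sampled for structure
#'   prediction.
#' @slot topNStructure number retained after ranking by structure score.
#' @slot nFinal number drawn from the structure-ranked set.
#' @slot controlTolerance maximum |identity difference| for a control pair.
#' @slot maxHomopolymerRun longest allowed single-residue run.
#' @slot maxDimerSpan longest allowed residue span of a 2-mer tandem run.
#' @slot extraRepeatLimits named integer vector (names "3","4") of optional
#'   additional k-mer unit limits; empty by default.
#' @seealso [filterPolicy()]
#' @export
setClass("FilterPolicy", representation(
  identityBand = "numeric", lmPercentile = "numeric",
  nPrefilterSample = "integer", topNStructure = "integer", nFinal = "integer",
  controlTolerance = "numeric", maxHomopolymerRun = "integer",
  maxDimerSpan = "integer", extraRepeatLimits = "integer"))

setValidity("FilterPolicy", function(object) {
  if (length(object@identityBand) != 2L ||
      object@identityBand[1] > object@identityBand[2])
    return("identityBand must be c(lower, upper) with lower <= upper")
  if (object@lmPercentile <= 0 || object@lmPercentile > 100)
    return("lmPercentile must be in (0, 100]")
  if (!(object@nFinal <= object@topNStructure &&
        object@topNStructure <= object@nPrefilterSample))
    return("need nFinal <= topNStructure <= nPrefilterSample")
  if (object@controlTolerance < 0) return("controlTolerance must be >= 0")
  TRUE
})

#' FilterReport: full record of one filter run
#'
#' @slot candidates per-candidate data.frame: identity, language-model score,
#'   each criterion's pass/fail, stage reached, failure reasons.
#' @slot cutoff calibrated language-model cutoff.
#' @slot selected character ids of the final selection.
#' @slot controls data.frame of control pairings (selected, control,
#'   identity difference; NA control = unmatched).
#' @slot stageCounts named integer vector of survivors per stage.
#' @slot policy the [FilterPolicy-class] used.
#' @slot seed integer seed of the run's random draws.
#' @export
setClass("FilterReport", representation(
  candidates = "data.frame", cutoff = "numeric", selected = "character",
  controls = "data.frame", stageCounts = "integer", policy = "FilterPolicy",
  seed = "integer"))
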