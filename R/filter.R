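#' Construct a filter policy
#'
#' @param identityBand inclusive identity band to the closest training
#'   sequence, default `c(0.5, 0.8)`.
#' @param lmPercentile top percentile of natural language-model scores used
#'   as the cutoff, default 10.
#' @param nPrefilterSample passing sequences sampled for structure scoring,
#'   default 200.
#' @param topNStructure retained after ranking by structure score, default 40.
#' @param nFinal final seeded draw, default 18.
#' @param controlTolerance max |identity difference| for a matched control,
#'   default 0.01.
#' @param maxHomopolymerRun longest allowed single-residue run, default 3.
#' @param maxDimerSpan longest allowed residue span of a 2-mer tandem,
#'   default 4 (so three or more tandem copies fail).
#' @param extraRepeatLimits optional named integer vector of additional
#'   k-mer unit limits, e.g. `c("3" = 3)`.
#' @return a [FilterPolicy-class].
#' @export
filterPolicy <- function(identityBand = c(0.5, 0.8), lmPercentile = 10,
                         nPrefilterSample = 200, topNStructure = 40,
                         nFinal = 18, controlTolerance = 0.01,
                         maxHomopolymerRun = 3, maxDimerSpan = 4,
                         extraRepeatLimits = integer(0)) {
  methods::new("FilterPolicy",
    identityBand = as.numeric(identityBand),
    lmPercentile = as.numeric(lmPercentile),
    nPrefilterSample = as.integer(nPrefilterSample),
    topNStructure = as.integer(topNStructure),
    nFinal = as.integer(nFinal),
    controlTolerance = as.numeric(controlTolerance),
    maxHomopolymerRun = as.integer(maxHomopolymerRun),
    maxDimerSpan = as.integer(maxDimerSpan),
    extraRepeatLimits = {
      x <- as.integer(extraRepeatLimits)
      names(x) <- names(extraRepeatLimits)
      x
    })
}

#' Calibrate the language-model cutoff on natural sequences
#'
#' The cutoff is the top `lmPercentile`-th percentile of the natural
#' calibration scores (see [percentileThreshold()]): a candidate passes if
#' its score is at least the cutoff.
#'
#' @param naturalScores language-model scores of natural (untested held-out)
#'   sequences; at least 5, with a warning below 20.
#' @param policy a [FilterPolicy-class].
#' @return numeric cutoff.
#' @export
calibrateCutoff <- function(naturalScores, policy = filterPolicy()) {
  if (length(naturalScores) == 0L) stop("empty calibration set")
  if (length(naturalScores) < 5L)
    stop("need at least 5 natural calibration scores, got ",
         length(naturalScores))
  if (length(naturalScores) < 20L)
    warning("fewer than 20 calibration scores; cutoff will be coarse")
  percentileThreshold(naturalScores, policy@lmPercentile, "top")
}

#' Sequence stage of the filter
#'
#' Applies the fast per-sequence criteria: identity to the closest training
#' sequence inside the band (inclusive), language-model score at or above
#' the calibrated cutoff, and the [qualityCheck()] criteria. Every failing
#' candidate lists all violated criteria, not just the first.
#'
#' @param candidates named `AAStringSet`.
#' @param scores data.frame with columns `id`, `identity`, `lm_score`
#'   covering every candidate (an unscored candidate is an error naming the
#'   missing metric).
#' @param cutoff calibrated cutoff from [calibrateCutoff()].
#' @param policy a [FilterPolicy-class].
#' @param tmPredictor optional transmembrane adapter (see [qualityCheck()]).
#' @return data.frame, one row per candidate: scores, per-criterion logicals,
#'   `pass`, and comma-separated `reasons`.
#' @export
sequenceStage <- function(candidates, scores, cutoff, policy = filterPolicy(),
                          tmPredictor = NULL) {
  ids <- names(candidates)
  stopifnot(!is.null(ids))
  for (col in c("identity", "lm_score")) {
    if (!col %in% names(scores))
      stop("candidates not scored for metric: ", col)
    miss <- setdiff(ids, scores$id[!is.na(scores[[col]])])
    if (length(miss))
      stop("candidate(s) missing metric '", col, "': ",
           paste(head(miss, 5), collapse = ", "))
  }
  if (is.null(tmPredictor))
    message("no transmembrane predictor attached; tm check not evaluated")
  sc <- scores[match(ids, scores$id), ]
  rows <- lapply(seq_along(ids), function(i) {
    qc <- qualityCheck(candidates[[i]], policy = policy,
                       tmPredictor = tmPredictor,
                       identity = sc$identity[i], quiet = TRUE)
    lm_pass <- sc$lm_score[i] >= cutoff
    reasons <- qc$reasons
    if (!lm_pass) reasons <- c(reasons, "lm_below_cutoff")
    data.frame(id = ids[i], identity = sc$identity[i],
               lm_score = sc$lm_score[i],
               starts_with_m = qc$starts_with_m, repeat_ok = qc$repeat_ok,
               tm_free = qc$tm_free, identity_in_band = qc$identity_in_band,
               lm_pass = lm_pass, pass = qc$passed && lm_pass,
               reasons = paste(reasons, collapse = ","))
  })
  do.call(rbind, rows)
}

#' Structure stage of the filter
#'
#' From the sequence-stage survivors: a seeded random sample of
#' `nPrefilterSample` (all of them, with a message, if fewer), ranking of the
#' sampled set by structure score (descending), retention of the top
#' `topNStructure`, and a seeded draw of `nFinal`. Sampled candidates with a
#' missing structure score are set aside and reported; ranks back-fill from
#' below the top-N window.
#'
#' @param passingIds ids surviving [sequenceStage()]; must number at least
#'   `nFinal`.
#' @param structureScores data.frame with `id` and `structure_score`.
#' @param policy a [FilterPolicy-class].
#' @param seed integer seed for both draws.
#' @return list with `sampled`, `ranked` (scored, descending), `top`,
#'   `selected` and `missing_scores` character vectors.
#' @export
structureStage <- function(passingIds, structureScores,
                           policy = filterPolicy(), seed = 1) {
  stopifnot(length(passingIds) >= policy@nFinal)
  withSeed(seed, {
    sampled <- if (length(passingIds) > policy@nPrefilterSample) {
      sampleVec(passingIds, policy@nPrefilterSample)
    } else {
      message("only ", length(passingIds),
              " passing sequences; sampling all of them")
      passingIds
    }
    sc <- structureScores$structure_score[match(sampled, structureScores$id)]
    missing <- sampled[is.na(sc)]
    scored <- sampled[!is.na(sc)]
    ranked <- scored[order(-sc[!is.na(sc)], scored)]
    top <- head(ranked, policy@topNStructure)
    if (length(top) < policy@nFinal)
      stop("fewer structure-scored sequences (", length(top),
           ") than nFinal (", policy@nFinal, ")")
    selected <- sampleVec(top, policy@nFinal)
    list(sampled = sampled, ranked = ranked, top = top, selected = selected,
         missing_scores = missing)
  })
}

#' Identity-matched negative controls
#'
#' For each selected sequence, a seeded random draw (without replacement)
#' from the filter-failing pool restricted to members whose identity to the
#' closest training sequence is within `controlTolerance` of the selection's.
#' Selections with an empty in-tolerance pool are reported as unmatched, not
#' dropped.
#'
#' @param selected data.frame with `id` and `identity` of the selections.
#' @param failingPool data.frame with `id` and `identity` of filter-failing
#'   candidates.
#' @param policy a [FilterPolicy-class].
#' @param seed integer seed.
#' @return data.frame with `selected`, `control` (`NA` if unmatched),
#'   `identity_selected`, `identity_control`, `delta_identity`.
#' @export
matchControls <- function(selected, failingPool, policy = filterPolicy(),
                          seed = 1) {
  stopifnot(all(c("id", "identity") %in% names(selected)),
            all(c("id", "identity") %in% names(failingPool)))
  withSeed(seed, {
    pool <- failingPool
    rows <- lapply(seq_len(nrow(selected)), function(i) {
      ok <- which(abs(pool$identity - selected$identity[i]) <=
                  policy@controlTolerance)
      if (length(ok) == 0L)
        return(data.frame(selected = selected$id[i], control = NA_character_,
                          identity_selected = selected$identity[i],
                          identity_control = NA_real_,
                          delta_identity = NA_real_))
      pick <- if (length(ok) == 1L) ok else sample(ok, 1L)
      out <- data.frame(selected = selected$id[i], control = pool$id[pick],
                        identity_selected = selected$identity[i],
                        identity_control = pool$identity[pick],
                        delta_identity = abs(pool$identity[pick] -
                                             selected$identity[i]))
      pool <<- pool[-pick, , drop = FALSE]
      out
    })
    do.call(rbind, rows)
  })
}

#' Run the full selection filter
#'
#' End-to-end: calibrate the language-model cutoff on natural scores, apply
#' the sequence stage, the structure stage, and pair each selection with an
#' identity-matched control from the failing pool.
#'
#' @param candidates named `AAStringSet` of generated candidates.
#' @param scores data.frame with `id`, `identity`, `lm_score` and
#'   `structure_score` (the latter may be `NA` outside the sampled set).
#' @param naturalScores language-model scores of natural calibration
#'   sequences.
#' @param policy a [FilterPolicy-class].
#' @param seed integer seed for all draws.
#' @param tmPredictor optional transmembrane adapter.
#' @return a [FilterReport-class].
#' @export
runCompss <- function(candidates, scores, naturalScores,
                      policy = filterPolicy(), seed = 1, tmPredictor = NULL) {
  seed <- as.integer(seed)
  cutoff <- calibrateCutoff(naturalScores, policy)
  seqtab <- sequenceStage(candidates, scores, cutoff, policy, tmPredictor)
  passing <- seqtab$id[seqtab$pass]
  st <- structureStage(passing, scores, policy, seed = seed)
  seqtab$stage <- ifelse(!seqtab$pass, "sequence_fail",
                  ifelse(seqtab$id %in% st$selected, "selected",
                  ifelse(seqtab$id %in% st$top, "top_structure",
                  ifelse(seqtab$id %in% st$sampled, "structure_sampled",
                         "sequence_pass"))))
  seltab <- seqtab[seqtab$id %in% st$selected, c("id", "identity")]
  failtab <- seqtab[!seqtab$pass, c("id", "identity")]
  controls <- matchControls(seltab, failtab, policy, seed = seed)
  counts <- c(input = nrow(seqtab), sequence_pass = length(passing),
              structure_sampled = length(st$sampled),
              top_structure = length(st$top), selected = length(st$selected),
              controls_matched = sum(!is.na(controls$control)))
  methods::new("FilterReport", candidates = seqtab, cutoff = cutoff,
               selected = st$selected, controls = controls,
               stageCounts = as.integer(counts) |> setNames(names(counts)),
               policy = policy, seed = seed)
}

#' Ids selected by a filter run
#' @param x a [FilterReport-class].
#' @rdname selectedSequences
#' @export
setMethod("selectedSequences", "FilterReport", function(x) x@selected)

#' Control pairings of a filter run
#' @param x a [FilterReport-class].
#' @rdname controlPairs
#' @export
setMethod("controlPairs", "FilterReport", function(x) x@controls)

#' Per-stage survivor counts of a filter run
#' @param x a [FilterReport-class].
#' @rdname stageCounts
#' @export
setMethod("stageCounts", "FilterReport", function(x) x@stageCounts)

#' Per-candidate table of a filter run
#' @param x a [FilterReport-class].
#' @export
candidateTable <- function(x) {
  stopifnot(methods::is(x, "FilterReport"))
  x@candidates
}

#' Calibrated cutoff of a filter run
#' @param x a [FilterReport-class].
#' @export
filterCutoff <- function(x) {
  stopifnot(methods::is(x, "FilterReport"))
  x@cutoff
}

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport (seed ", object@seed, ")\n", sep = "")
  cat("  lm cutoff: ", format(object@cutoff, digits = 4), "\n", sep = "")
  sc <- object@stageCounts
  cat("  stages: ", paste(names(sc), sc, sep = "=", collapse = " -> "), "\n",
      sep = "")
  cat("  unmatched controls: ", sum(is.na(object@controls$control)), "\n",
      sep = "")
})

#' Write a filter report to disk
#'
#' Writes the per-candidate table and control pairings as TSV plus a JSON
#' run manifest (cutoff, seed, policy, per-stage counts).
#'
#' @param report a [FilterReport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFilterReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(candidateTable(report), file.path(dir, "candidates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(controlPairs(report), file.path(dir, "controls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  p <- report@policy
  manifest <- list(
    tool = as.character(utils::packageVersion("compss")),
    seed = report@seed, cutoff = report@cutoff,
    stage_counts = as.list(stageCounts(report)),
    selected = selectedSequences(report),
    policy = list(identityBand = p@identityBand, lmPercentile = p@lmPercentile,
                  nPrefilterSample = p@nPrefilterSample,
                  topNStructure = p@topNStructure, nFinal = p@nFinal,
                  controlTolerance = p@controlTolerance))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
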