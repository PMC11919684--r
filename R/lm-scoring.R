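#' Construct a masking schedule
#'
#' @param interval positive integer masking interval m; pass j (of m) masks
#'   positions congruent to j modulo m, so the m passes cover every position
#'   exactly once.
#' @return a [MaskSchedule-class].
#' @export
maskSchedule <- function(interval) {
  methods::new("MaskSchedule", interval = as.integer(interval))
}

#' Mask sets of a schedule over a sequence of length L
#'
#' @param schedule a [MaskSchedule-class].
#' @param L sequence length.
#' @return list of integer vectors, one per pass; their union is `1:L`, each
#'   position appearing exactly once, and positions within one pass are at
#'   least `interval` apart.
#' @export
maskSets <- function(schedule, L) {
  m <- schedule@interval
  lapply(seq_len(m), function(j) seq.int(j, L, by = m))
}

#' Build a PSSM mock scorer
#'
#' A position probability matrix with pseudocount `alpha` built from an
#' aligned MSA: column j's probability of residue a is
#' `(count(a, j) + alpha) / (n_obs(j) + 20 * alpha)`, gaps excluded from the
#' counts. Context-free (masking cannot change it) and fully deterministic,
#' it stands behind the [LikelihoodScorer-class] contract wherever a real
#' language model would. Called without an MSA it returns a context-mode
#' scorer whose matrix is derived from whatever MSA it is later applied to.
#'
#' @param msa aligned `AAStringSet` (equal widths, gaps as `-`), or `NULL`
#'   for context mode.
#' @param alpha pseudocount, default 1.
#' @return a [PssmScorer-class].
#' @export
pssmScorer <- function(msa = NULL, alpha = 1) {
  probs <- if (is.null(msa)) {
    matrix(numeric(0), nrow = 0, ncol = 20, dimnames = list(NULL, AA20))
  } else {
    pssmFromMsa(msa, alpha)
  }
  methods::new("PssmScorer", probs = probs, alpha = alpha)
}

pssmFromMsa <- function(msa, alpha, exclude_row = 0L) {
  rows <- lapply(as.character(msa), function(s) strsplit(s, "")[[1]])
  if (length(unique(lengths(rows))) != 1L) stop("MSA rows have unequal widths")
  if (exclude_row > 0L) rows <- rows[-exclude_row]
  if (length(rows) == 0L) stop("MSA has no context rows")
  L <- length(rows[[1]])
  m <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, AA20))
  for (r in rows) {
    use <- which(r %in% AA20)
    if (length(use))
      m[cbind(use, match(r[use], AA20))] <- m[cbind(use, match(r[use], AA20))] + 1
  }
  nobs <- rowSums(m)
  (m + alpha) / (nobs + 20 * alpha)
}

resolveScorer <- function(scorer, msa) {
  if (methods::is(scorer, "PssmScorer") && nrow(scorer@probs) == 0L)
    return(pssmScorer(msa, scorer@alpha))
  scorer
}

#' @rdname scoreLogProbs
#' @export
setMethod("scoreLogProbs", "PssmScorer",
          function(scorer, sequence, positions = NULL, masked = positions) {
  s <- asSequence(sequence)
  if (nrow(scorer@probs) == 0L)
    stop("context-mode PssmScorer has no matrix; score via msaContextScore()")
  L <- nchar(s)
  if (L != nrow(scorer@probs))
    stop("sequence length ", L, " does not match scorer length ",
         nrow(scorer@probs))
  if (is.null(positions)) positions <- seq_len(L)
  ch <- seqChars(s)[positions]
  idx <- match(ch, AA20)
  if (anyNA(idx)) stop("non-standard residue at scored position")
  log(scorer@probs[cbind(positions, idx)])
})

#' @rdname sampleDistribution
#' @export
setMethod("sampleDistribution", "PssmScorer", function(scorer, msa, row, position) {
  # single-column counts over the context rows (target row excluded)
  col <- substr(as.character(msa)[-row], position, position)
  col <- col[col %in% AA20]
  counts <- tabulate(match(col, AA20), nbins = 20L)
  names(counts) <- AA20
  (counts + scorer@alpha) / (length(col) + 20 * scorer@alpha)
})

#' Average log-probability of a sequence under a scorer
#'
#' The alignment-free language-model metric: the mean over positions of the
#' log-probability of the observed residue. Without a schedule this is a
#' single unmasked pass. With a [maskSchedule()] of interval m, the sequence
#' is scored in m passes, pass j masking every m-th position starting at j;
#' per-position values are pooled over all passes (each position scored
#' exactly once) and averaged.
#'
#' @param scorer a [LikelihoodScorer-class].
#' @param sequence character scalar or `AAString`.
#' @param schedule `NULL` (unmasked single pass) or a [MaskSchedule-class].
#' @return numeric mean log-probability (<= 0).
#' @examples
#' msa <- Biostrings::AAStringSet(c("MKV", "MKV"))
#' averageLogProb(pssmScorer(msa, alpha = 0.01), "MKV")
#' @export
averageLogProb <- function(scorer, sequence, schedule = NULL) {
  s <- asSequence(sequence)
  stopIfEmptySequence(s)
  L <- nchar(s)
  if (is.null(schedule)) {
    vals <- scoreLogProbs(scorer, s, positions = seq_len(L), masked = integer(0))
  } else {
    sets <- maskSets(schedule, L)
    vals <- numeric(L)
    for (j in seq_along(sets)) {
      v <- tryCatch(scoreLogProbs(scorer, s, positions = sets[[j]],
                                  masked = sets[[j]]),
                    error = function(e) stop("scorer failed on pass ", j, ": ",
                                             conditionMessage(e)))
      vals[sets[[j]]] <- v
    }
    stopifnot(sum(lengths(sets)) == L)
  }
  mean(vals)
}

# star alignment of neighbours onto query coordinates: for each neighbour,
# the residue aligned to each query position (or "-"); row 1 is the query
starMsa <- function(query, neighbours, matrix, gapOpening = 10, gapExtension = 2) {
  q <- asSequence(query)
  rows <- vapply(as.character(neighbours), function(ref) {
    aln <- globalAlign(q, ref, matrix = matrix, gapOpening = gapOpening,
                       gapExtension = gapExtension)
    qc <- strsplit(aln$gapped_query, "")[[1]]
    rc <- strsplit(aln$gapped_reference, "")[[1]]
    paste(rc[qc != "-"], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  out <- Biostrings::AAStringSet(c(q, rows))
  names(out) <- c("query", names(neighbours))
  out
}

#' MSA-context language-model score
#'
#' Builds an MSA of the query plus its `nContext` nearest training sequences
#' (nearest by global-alignment score; the MSA is a star alignment onto
#' query coordinates, or any pre-aligned rows via a custom `aligner`), then
#' scores the query row with [averageLogProb()] under a masking schedule of
#' the given interval. Defaults mirror the standard construction: 31
#' context sequences, six passes at interval six.
#'
#' @param scorer a [LikelihoodScorer-class]; a context-mode [pssmScorer()]
#'   derives its matrix from the constructed MSA.
#' @param query character scalar or `AAString`.
#' @param trainingSet non-empty named `AAStringSet`.
#' @param nContext number of context sequences (clamped to the training-set
#'   size).
#' @param interval masking interval.
#' @param matrix substitution matrix for neighbour search and star alignment.
#' @param aligner optional `function(query, neighbours)` returning an aligned
#'   `AAStringSet` whose first row is the query in query coordinates.
#' @return numeric mean log-probability of the query row.
#' @export
msaContextScore <- function(scorer, query, trainingSet, nContext = 31,
                            interval = 6, matrix = getSubstitutionMatrix(),
                            aligner = NULL) {
  if (length(trainingSet) == 0L) stop("training set is empty")
  q <- checkAlphabet(query)
  refs <- Biostrings::AAStringSet(as.character(trainingSet))
  if (is.null(names(refs))) names(refs) <- as.character(seq_along(refs))
  scores <- Biostrings::pairwiseAlignment(
    refs, Biostrings::AAString(q), type = "global",
    substitutionMatrix = matrix, scoreOnly = TRUE,
    gapOpening = 10, gapExtension = 2)
  n <- min(nContext, length(refs))
  ord <- order(-scores, names(refs))
  neighbours <- refs[ord[seq_len(n)]]
  msa <- if (is.null(aligner)) starMsa(q, neighbours, matrix)
         else aligner(q, neighbours)
  averageLogProb(resolveScorer(scorer, msa), q, maskSchedule(interval))
}

#' Generate sequences by iterative masking and sampling
#'
#' Masked positions of the target row(s) of a seed MSA are replaced by draws
#' from the scorer's residue distribution until every position has been
#' resampled once (one full iteration; `nIter` repeats the sweep). Two modes
#' mirror the two schedules in common use: `"whole_msa"` resamples every row of
#' the seed MSA in turn; `"single_sequence_neighbors"` resamples one row at
#' a time against a context of its `nContext` most similar rows. Positions
#' are visited in seeded random order; with a fixed `seed` the output is
#' identical across runs.
#'
#' @param scorer a [LikelihoodScorer-class] supporting [sampleDistribution()].
#' @param seedMsa aligned `AAStringSet`.
#' @param mode `"whole_msa"` or `"single_sequence_neighbors"`.
#' @param temperature sampling temperature; probabilities are raised to
#'   `1/temperature` and renormalised, and values below `1e-8` give the
#'   argmax (greedy) limit.
#' @param seed integer seed.
#' @param nIter full resampling sweeps per row, default 1.
#' @param nContext context size for `"single_sequence_neighbors"`.
#' @return `AAStringSet` of resampled (ungapped) sequences with metadata
#'   columns `mode` and `seed`.
#' @export
iterativeMaskSample <- function(scorer, seedMsa,
                                mode = c("whole_msa", "single_sequence_neighbors"),
                                temperature = 1, seed = 1, nIter = 1,
                                nContext = 31) {
  mode <- match.arg(mode)
  if (!methods::hasMethod("sampleDistribution", class(scorer)))
    stop("scorer does not support sampling")
  rows <- as.character(seedMsa)
  ids <- names(seedMsa)
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  L <- unique(nchar(rows))
  if (length(L) != 1L) stop("seed MSA rows have unequal widths")
  if (length(rows) < 2L) stop("seed MSA needs at least 2 rows")

  # identity between aligned rows, for neighbour contexts
  rowIdentity <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    mean(ca == cb)
  }

  resampleRow <- function(work, target) {
    # nIter full sweeps over the non-gap positions of one row,
    # in seeded random order, updating the working MSA after each draw
    cur <- strsplit(as.character(work[[target]]), "")[[1]]
    resample <- which(cur != "-")
    for (iter in seq_len(nIter)) {
      for (pos in sampleVec(resample, length(resample))) {
        p <- sampleDistribution(scorer, work, target, pos)
        cur[pos] <- if (temperature < 1e-8) {
          AA20[which.max(p)]
        } else {
          w <- p ^ (1 / temperature)
          sample(AA20, 1L, prob = w / sum(w))
        }
        work[target] <- Biostrings::AAStringSet(paste(cur, collapse = ""))
      }
    }
    work
  }

  withSeed(seed, {
    out <- character(length(rows))
    if (mode == "whole_msa") {
      # every row of one shared MSA is resampled in turn; draws made for
      # earlier rows are part of the context for later ones
      work <- Biostrings::AAStringSet(rows)
      for (r in seq_along(rows))
        work <- resampleRow(work, r)
      out <- gsub("-", "", as.character(work), fixed = TRUE)
    } else {
      # each row resampled independently against its most similar rows
      for (r in seq_along(rows)) {
        sims <- vapply(rows, rowIdentity, numeric(1), b = rows[r],
                       USE.NAMES = FALSE)
        sims[r] <- Inf             # keep the target row first
        ord <- order(-sims)
        ctx <- ord[seq_len(min(nContext + 1L, length(rows)))]
        work <- resampleRow(Biostrings::AAStringSet(rows[ctx]), 1L)
        out[r] <- gsub("-", "", as.character(work[[1L]]), fixed = TRUE)
      }
    }
    res <- Biostrings::AAStringSet(out)
    names(res) <- paste0(ids, "_resampled")
    S4Vectors::mcols(res) <- S4Vectors::DataFrame(
      mode = rep(mode, length(res)), seed = rep(as.integer(seed), length(res)))
    res
  })
}
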