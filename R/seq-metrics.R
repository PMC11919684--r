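#' Tandem k-mer repeat score
#'
#' Finds the longest run of contiguous, exact tandem copies of any k-mer
#' (any start offset, homopolymer k-mers included; only complete copies
#' count) and scores it as -1 x the number of repeat units. Long repeats are
#' a characteristic failure mode of generated sequences, so a more negative
#' score is worse. For example `AAAAAA` scores -6, -3, -2, -1 for k = 1..4,
#' and `LALALALA` scores -1, -4, -1, -2.
#'
#' @param sequence character scalar or `AAString`.
#' @param k repeat unit length in residues, 1 to 4.
#' @return list with `k`, `units` (maximal tandem copy count, >= 1) and
#'   `score` (= `-units`).
#' @examples
#' kmerRepeatScore("LALALALA", 2)$score  # -4
#' @export
kmerRepeatScore <- function(sequence, k) {
  s <- asSequence(sequence)
  k <- as.integer(k)
  stopifnot(length(k) == 1L, k >= 1L, k <= 4L)
  n <- nchar(s)
  if (n < k) stop("sequence shorter than k")
  ch <- seqChars(s)
  best <- 1L
  for (start in seq_len(n - k + 1L)) {
    unit <- ch[start:(start + k - 1L)]
    units <- 1L
    pos <- start + k
    while (pos + k - 1L <= n && all(ch[pos:(pos + k - 1L)] == unit)) {
      units <- units + 1L
      pos <- pos + k
    }
    if (units > best) best <- units
  }
  list(k = k, units = best, score = -best)
}

#' All four repeat scores for a set of sequences
#'
#' @param seqs `AAStringSet` or character vector.
#' @return data.frame with columns `id`, `repeat_1mer` .. `repeat_4mer`.
#' @export
repeatScores <- function(seqs) {
  ids <- if (is.null(names(seqs))) as.character(seq_along(seqs)) else names(seqs)
  ss <- as.character(seqs)
  out <- data.frame(id = ids)
  for (k in 1:4)
    out[[paste0("repeat_", k, "mer")]] <-
      vapply(ss, function(s) kmerRepeatScore(s, k)$score, numeric(1),
             USE.NAMES = FALSE)
  out
}

#' Net charge, absolute net charge and charged fraction
#'
#' Positive charges are counted over lysine and arginine, negative over
#' aspartate and glutamate; histidine is excluded. `charged_fraction` is the
#' fraction of residues that are K, R, D or E.
#'
#' @param sequence character scalar or `AAString`.
#' @return list with `net_charge`, `abs_net_charge`, `charged_fraction`.
#' @examples
#' chargeProfile("MKVDEH")  # net -1, |net| 1, fraction 0.5
#' @export
chargeProfile <- function(sequence) {
  s <- asSequence(sequence)
  stopIfEmptySequence(s)
  ch <- seqChars(s)
  pos <- sum(ch %in% c("K", "R"))
  neg <- sum(ch %in% c("D", "E"))
  list(net_charge = pos - neg,
       abs_net_charge = abs(pos - neg),
       charged_fraction = (pos + neg) / length(ch))
}

# longest run of a single identical residue
maxHomopolymerRun <- function(sequence) {
  r <- rle(seqChars(sequence))
  max(r$lengths)
}

# longest residue span covered by a tandem run of any 2-mer
maxDimerSpan <- function(sequence) {
  if (nchar(asSequence(sequence)) < 2L) return(0L)
  2L * kmerRepeatScore(sequence, 2L)$units
}

#' Sequence quality checks of the selection filter
#'
#' The fast checks applied before any expensive scoring: the sequence must
#' start with methionine (a marker of full-length sequences when the training
#' set does), must not contain a single-residue run longer than
#' `maxHomopolymerRun` residues nor a residue-pair tandem spanning more than
#' `maxDimerSpan` residues, and must lack a predicted transmembrane domain.
#' Without an attached transmembrane predictor that check is `NA` and not
#' counted against the sequence. An identity value, when supplied, is checked
#' against `band` (inclusive at both ends).
#'
#' @param sequence character scalar or `AAString`.
#' @param policy a [FilterPolicy-class] providing the repeat limits and band;
#'   default [filterPolicy()].
#' @param tmPredictor optional adapter: `function(sequence)` returning `TRUE`
#'   if a transmembrane domain is predicted.
#' @param identity optional identity to the closest training sequence.
#' @param quiet suppress the missing-predictor message.
#' @return list with logical fields `starts_with_m`, `repeat_ok`, `tm_free`
#'   (`NA` if unknown), `identity_in_band` (`NA` if unknown), `passed`, and
#'   `reasons`, a character vector of failed-criterion labels.
#' @export
qualityCheck <- function(sequence, policy = filterPolicy(), tmPredictor = NULL,
                         identity = NULL, quiet = FALSE) {
  s <- asSequence(sequence)
  stopIfEmptySequence(s)
  reasons <- character(0)

  starts_with_m <- substr(s, 1, 1) == "M"
  if (!starts_with_m) reasons <- c(reasons, "no_start_M")

  repeat_ok <- TRUE
  if (maxHomopolymerRun(s) > policy@maxHomopolymerRun) {
    repeat_ok <- FALSE
    reasons <- c(reasons, "homopolymer_run")
  }
  if (maxDimerSpan(s) > policy@maxDimerSpan) {
    repeat_ok <- FALSE
    reasons <- c(reasons, "dimer_run")
  }
  if (length(policy@extraRepeatLimits)) {
    for (kk in names(policy@extraRepeatLimits)) {
      if (kmerRepeatScore(s, as.integer(kk))$units >
          policy@extraRepeatLimits[[kk]]) {
        repeat_ok <- FALSE
        reasons <- c(reasons, paste0("repeat_", kk, "mer"))
      }
    }
  }

  if (is.null(tmPredictor)) {
    if (!quiet)
      message("no transmembrane predictor attached; tm check not evaluated")
    tm_free <- NA
  } else {
    tm_free <- !isTRUE(tmPredictor(s))
    if (!tm_free) reasons <- c(reasons, "transmembrane")
  }

  if (is.null(identity) || is.na(identity)) {
    identity_in_band <- NA
  } else {
    lo <- policy@identityBand[1]; hi <- policy@identityBand[2]
    identity_in_band <- identity >= lo && identity <= hi
    if (!identity_in_band)
      reasons <- c(reasons,
                   if (identity < lo) "identity_below_band" else "identity_above_band")
  }

  evaluable <- c(starts_with_m, repeat_ok, tm_free, identity_in_band)
  list(starts_with_m = starts_with_m, repeat_ok = repeat_ok,
       tm_free = tm_free, identity_in_band = identity_in_band,
       passed = all(evaluable[!is.na(evaluable)]), reasons = reasons)
}
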