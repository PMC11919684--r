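#' Specification of a synthetic protein family
#'
#' Controls the seeded generation of a toy family: a consensus, training and
#' natural-test sets, and candidate sequences with injected defects and a
#' planted activity rule. Defaults emulate the study conditions of a
#' filter-calibration campaign: candidates at 70-80\% identity to the closest
#' training sequence, training sequences about 90\% identical to the
#' consensus, mock language-model scores separating defect-free from
#' defective candidates, and activity planted at a high rate for defect-free
#' in-band high-scoring candidates and a low rate otherwise.
#'
#' @param consensusLength consensus length in residues, default 120.
#' @param nTrain,nTest,nCandidates set sizes, defaults 12, 50, 400. The
#'   natural test set doubles as the calibration set for the score cutoff;
#'   it is sized so the top-decile order statistic is stable, emulating the
#'   held-out natural test split (hundreds of sequences) such a campaign
#'   calibrates on.
#' @param identityBand target candidate-to-closest-training identity band,
#'   default `c(0.7, 0.8)`.
#' @param defectRates named rates of injected defects over candidates
#'   (`no_start_M`, `homopolymer_run`, `dimer_run`, `charge_shift`,
#'   `identity_out_of_band`).
#' @param pActiveHigh,pActiveLow planted activity probabilities for
#'   eligible (defect-free, in band, high mock score) vs other candidates,
#'   defaults 0.8 and 0.3.
#' @param seed integer seed.
#' @return classed list (`FamilySpec`).
#' @export
familySpec <- function(consensusLength = 120, nTrain = 12, nTest = 50,
                       nCandidates = 400, identityBand = c(0.7, 0.8),
                       defectRates = c(no_start_M = 0.06,
                                       homopolymer_run = 0.06,
                                       dimer_run = 0.06,
                                       charge_shift = 0.06,
                                       identity_out_of_band = 0.08),
                       pActiveHigh = 0.8, pActiveLow = 0.3, seed = 1) {
  stopifnot(consensusLength >= 30, nTrain >= 2, nTest >= 5, nCandidates >= 1,
            length(identityBand) == 2, identityBand[1] <= identityBand[2],
            identityBand[2] <= 1, pActiveHigh >= pActiveLow)
  if (identityBand[1] <= 0 || identityBand[2] > 1)
    stop("infeasible identity band")
  structure(list(consensusLength = consensusLength, nTrain = nTrain,
                 nTest = nTest, nCandidates = nCandidates,
                 identityBand = identityBand, defectRates = defectRates,
                 pActiveHigh = pActiveHigh, pActiveLow = pActiveLow,
                 seed = as.integer(seed)),
            class = "FamilySpec")
}

randomSeq <- function(L) paste(sample(AA20, L, replace = TRUE), collapse = "")

# substitute a fraction (1 - identity) of positions 2..L with different
# residues; keeps length, so alignment identity ~= fraction unchanged
mutateSeq <- function(sequence, identity) {
  ch <- seqChars(sequence)
  L <- length(ch)
  nmut <- round((1 - identity) * L)
  if (nmut > 0) {
    pos <- sampleVec(2:L, min(nmut, L - 1L))
    ch[pos] <- vapply(ch[pos], function(a) sampleVec(setdiff(AA20, a), 1L),
                      character(1))
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic protein family with defect-labelled candidates
#'
#' Deterministic for a fixed seed. Training and natural-test sequences
#' derive from a methionine-initiated consensus by substitution; candidates
#' derive from randomly chosen training sequences at target identities drawn
#' from the family spec's band. Injected defects are recorded in a per-candidate
#' manifest and are each detectable by the corresponding sequence metric
#' (start-M check, homopolymer run, 2-mer tandem, charge profile, identity
#' band). Mock language-model and structure scores separate defect-free from
#' defective candidates; planted activity follows a stated rule
#' (eligible candidates active with probability `pActiveHigh`, others
#' `pActiveLow`, where eligible = defect-free, identity in band and mock
#' score at or above the top-decile threshold of the natural scores -- the
#' same stringency the selection filter calibrates).
#'
#' @param spec a [familySpec()].
#' @return list with `train`, `test`, `candidates` (named `AAStringSet`s),
#'   `naturalScores` (mock scores of the test set), and `manifest`
#'   (per-candidate data.frame: defects, identity target, mock scores,
#'   planted activity).
#' @export
makeFamily <- function(spec) {
  stopifnot(inherits(spec, "FamilySpec"))
  withSeed(spec$seed, {
    L <- spec$consensusLength
    # random mutation can create tandem repeats by accident; defect labels
    # must be exact, so sequences meant to be clean are redrawn until the
    # repeat checks pass
    repeatClean <- function(s) qualityCheck(s, quiet = TRUE)$repeat_ok
    drawClean <- function(make) {
      for (try in 1:50) {
        s <- make()
        if (repeatClean(s)) return(s)
      }
      stop("could not draw a repeat-free sequence in 50 attempts")
    }
    consensus <- drawClean(function() paste0("M", randomSeq(L - 1L)))
    train <- vapply(seq_len(spec$nTrain), function(i)
      drawClean(function() mutateSeq(consensus, 0.90)), character(1))
    names(train) <- sprintf("train_%03d", seq_len(spec$nTrain))
    test <- vapply(seq_len(spec$nTest), function(i)
      mutateSeq(train[sample.int(spec$nTrain, 1L)],
                runif(1, spec$identityBand[1], spec$identityBand[2])),
      character(1))
    names(test) <- sprintf("test_%03d", seq_len(spec$nTest))

    n <- spec$nCandidates
    defects <- vector("list", n)
    seqs <- character(n)
    idtarget <- numeric(n)
    for (i in seq_len(n)) {
      d <- names(spec$defectRates)[runif(length(spec$defectRates)) <
                                   spec$defectRates]
      # an out-of-band candidate must stay out of band: the substitution-
      # heavy defects (charge shift, repeat windows) would drag its identity
      # back down, so they are not co-injected
      if ("identity_out_of_band" %in% d)
        d <- intersect(d, c("identity_out_of_band", "no_start_M"))
      idtarget[i] <- if ("identity_out_of_band" %in% d) 0.92
                     else runif(1, spec$identityBand[1], spec$identityBand[2])
      src <- train[sample.int(spec$nTrain, 1L)]
      # the mutated base (plus any charge shift) must be repeat-free, so
      # injected repeat defects are the only ones present
      base <- drawClean(function() {
        ch <- seqChars(mutateSeq(src, idtarget[i]))
        if ("charge_shift" %in% d) {
          at <- sampleVec(2:L, 12L)
          ch[at] <- "K"
        }
        paste(ch, collapse = "")
      })
      ch <- seqChars(base)
      # repeat defects get disjoint windows so they cannot mask one another
      if (any(c("homopolymer_run", "dimer_run") %in% d)) {
        win <- sample(2:(L - 12L), 1L)
        if ("dimer_run" %in% d) {
          ab <- sampleVec(AA20, 2L)
          ch[(win + 6L):(win + 11L)] <- rep(ab, 3L)
        }
        if ("homopolymer_run" %in% d)
          ch[win:(win + 4L)] <- sampleVec(AA20, 1L)
      }
      if ("no_start_M" %in% d) ch[1] <- sampleVec(setdiff(AA20, "M"), 1L)
      seqs[i] <- paste(ch, collapse = "")
      defects[[i]] <- d
    }
    ids <- sprintf("cand_%04d", seq_len(n))
    names(seqs) <- ids
    defect_free <- lengths(defects) == 0L

    # mock scores: defect-free candidates sit clearly above defective ones,
    # natural sequences in between (so the top-decile cutoff is selective)
    lm_score <- rnorm(n, mean = ifelse(defect_free, 0.7, -0.7), sd = 0.5)
    structure_score <- rnorm(n, mean = ifelse(defect_free, 0.5, -0.5), sd = 0.5)
    naturalScores <- rnorm(spec$nTest, mean = 0.3, sd = 0.5)
    names(naturalScores) <- names(test)

    in_band <- idtarget >= spec$identityBand[1] &
               idtarget <= spec$identityBand[2]
    # "high mock score" uses the same stringency the filter later calibrates
    # (top decile of the natural scores), so the planted activity contrast
    # mirrors the selected-versus-control contrast the filter measures
    lm_high <- lm_score >= percentileThreshold(naturalScores, 10)
    eligible <- defect_free & in_band & lm_high
    active <- as.integer(runif(n) < ifelse(eligible, spec$pActiveHigh,
                                           spec$pActiveLow))

    toSet <- function(x, src) {
      s <- Biostrings::AAStringSet(x)
      S4Vectors::mcols(s) <- S4Vectors::DataFrame(
        description = rep("", length(s)), source = rep(src, length(s)),
        has_x = rep(FALSE, length(s)), violations = rep("", length(s)))
      s
    }
    list(train = toSet(train, "natural_train"),
         test = toSet(test, "natural_test"),
         candidates = toSet(seqs, "generated"),
         naturalScores = naturalScores,
         manifest = data.frame(
           id = ids,
           defects = vapply(defects, paste, character(1), collapse = ","),
           defect_free = defect_free, identity_target = idtarget,
           lm_score = lm_score, structure_score = structure_score,
           eligible = eligible, active = active))
  })
}

#' Build a toy structure on ideal helical geometry
#'
#' Places backbone atoms (N, CA, C, O) and CB (except glycine) of every
#' residue on an ideal alpha-helical spiral (100 degrees twist, 1.5 A rise
#' per residue) and writes the supplied confidence profile into the B-factor
#' field. Geometrically plausible, not physically realistic -- intended to
#' exercise parsers, SASA and confidence metrics.
#'
#' @param sequence character scalar or `AAString`.
#' @param confidence per-residue confidence profile in \[0, 100\]; scalar
#'   values are recycled. Default 90.
#' @return a [StructureModel-class] (write it with [writeStructure()]).
#' @export
makeStructure <- function(sequence, confidence = 90) {
  s <- asSequence(sequence)
  stopIfEmptySequence(s)
  ch <- seqChars(s)
  nres <- length(ch)
  confidence <- rep_len(confidence, nres)
  stopifnot(all(confidence >= 0 & confidence <= 100))
  res3 <- vapply(ch, function(a) {
    r <- suppressWarnings(bio3d::aa123(a))
    if (is.na(r) || a == "X") "UNK" else r
  }, character(1))
  rows <- lapply(seq_len(nres), function(i) {
    th <- (i - 1L) * 100 * pi / 180
    z <- (i - 1L) * 1.5
    at <- rbind(
      N  = c(1.80 * cos(th - 0.45), 1.80 * sin(th - 0.45), z - 0.60),
      CA = c(2.30 * cos(th),        2.30 * sin(th),        z),
      C  = c(2.00 * cos(th + 0.45), 2.00 * sin(th + 0.45), z + 0.55),
      O  = c(3.20 * cos(th + 0.55), 3.20 * sin(th + 0.55), z + 0.85),
      CB = c(3.60 * cos(th - 0.10), 3.60 * sin(th - 0.10), z - 0.30))
    elem <- c("N", "C", "C", "O", "C")
    keep <- if (ch[i] == "G") 1:4 else 1:5
    data.frame(chain = "A", resno = i, resname = res3[i],
               atom = rownames(at)[keep], element = elem[keep],
               x = unname(at[keep, 1]), y = unname(at[keep, 2]),
               z = unname(at[keep, 3]), b = confidence[i],
               row.names = NULL)
  })
  methods::new("StructureModel", atoms = do.call(rbind, rows))
}

#' Generate a synthetic assay plate
#'
#' Produces long-format plate series from a truth table of per-enzyme
#' activity levels. MDH wells follow exponential NADH depletion
#' (`A(t) = A0 * exp(-k t)` with `k` proportional to activity, plus a slow
#' background drift shared with the negative control and a flat no-substrate
#' control); SOD wells follow linear formazan formation scaled down by
#' `0.9 * activity` inhibition, with no-SOD, no-XO and blank controls.
#' Gaussian noise of sd `noiseSd` is added to every reading; seeded.
#'
#' @param truthTable data.frame with `id`, `family` (`"mdh"` or `"sod"`) and
#'   `activity` in \[0, 1\] (wild type = 1).
#' @param noiseSd absorbance noise sd, default 0.01.
#' @param seed integer seed.
#' @param nReplicates technical replicates per series, default 3.
#' @return long data.frame as read by [readPlate()]; wild-type and control
#'   wells are appended per family automatically.
#' @export
makePlate <- function(truthTable, noiseSd = 0.01, seed = 1, nReplicates = 3) {
  stopifnot(all(c("id", "family", "activity") %in% names(truthTable)))
  withSeed(seed, {
    out <- list()
    well <- 0L
    addSeries <- function(id, family, role, absorbance, times) {
      wells <- sprintf("W%03d", well + seq_len(nReplicates))
      well <<- well + nReplicates
      data.frame(well = rep(wells, each = length(times)), id = id, role = role,
                 replicate = rep(seq_len(nReplicates), each = length(times)),
                 time_s = rep(times, nReplicates),
                 absorbance = pmax(0, absorbance + rnorm(length(absorbance),
                                                         0, noiseSd)))
    }
    mdhCurve <- function(activity, times)
      2.706 * exp(-(0.02 * activity + 2e-4) * times)
    sodCurve <- function(activity, times)
      0.10 + 4e-4 * (1 - 0.9 * activity) * times
    for (fam in unique(truthTable$family)) {
      tt <- truthTable[truthTable$family == fam, , drop = FALSE]
      if (fam == "mdh") {
        times <- seq(0, 300, by = 30)
        for (i in seq_len(nrow(tt)))
          out[[length(out) + 1L]] <- addSeries(
            tt$id[i], fam, "sample",
            rep(mdhCurve(tt$activity[i], times), nReplicates), times)
        out[[length(out) + 1L]] <- addSeries(
          "neg_mdh", fam, "negative_control",
          rep(mdhCurve(0, times), nReplicates), times)
        out[[length(out) + 1L]] <- addSeries(
          "nosub_mdh", fam, "no_substrate",
          rep(rep(0.05, length(times)), nReplicates), times)
        out[[length(out) + 1L]] <- addSeries(
          "wt_mdh", fam, "wildtype",
          rep(mdhCurve(1, times), nReplicates), times)
      } else if (fam == "sod") {
        times <- seq(0, 1800, by = 300)
        for (i in seq_len(nrow(tt)))
          out[[length(out) + 1L]] <- addSeries(
            tt$id[i], fam, "sample",
            rep(sodCurve(tt$activity[i], times), nReplicates), times)
        out[[length(out) + 1L]] <- addSeries(
          "nosod", fam, "no_sod", rep(sodCurve(0, times), nReplicates), times)
        out[[length(out) + 1L]] <- addSeries(
          "blank", fam, "blank",
          rep(rep(0.10, length(times)), nReplicates), times)
        out[[length(out) + 1L]] <- addSeries(
          "noxo", fam, "no_xo",
          rep(rep(0.10, length(times)), nReplicates), times)
        out[[length(out) + 1L]] <- addSeries(
          "wt_sod", fam, "wildtype",
          rep(sodCurve(1, times), nReplicates), times)
      } else stop("unknown family: ", fam)
    }
    do.call(rbind, out)
  })
}
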