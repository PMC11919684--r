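#' Load or read a substitution matrix
#'
#' `getSubstitutionMatrix("BLOSUM62")` returns the canonical published table
#' shipped with Biostrings. `readSubstitutionMatrix()` parses any matrix in
#' NCBI text format (e.g. a user-supplied PFASUM15 file) -- a `#`-commented
#' header, a row of residue letters, then one labelled score row per
#' residue.
#'
#' @param name matrix name known to Biostrings (e.g. `"BLOSUM62"`,
#'   `"BLOSUM45"`, `"PAM250"`).
#' @return integer matrix with residue row/column names.
#' @export
getSubstitutionMatrix <- function(name = "BLOSUM62") {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' @rdname getSubstitutionMatrix
#' @param path NCBI-format matrix file.
#' @export
readSubstitutionMatrix <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not an NCBI-format matrix file: ", path)
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  rn <- vapply(rows, `[`, character(1), 1)
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  dimnames(m) <- list(rn, cols)
  if (!all(AA20 %in% rownames(m)) || !all(AA20 %in% colnames(m)))
    stop("matrix does not cover the 20 standard residues")
  if (!isTRUE(all.equal(m[AA20, AA20], t(m[AA20, AA20]))))
    stop("matrix is not symmetric over the standard residues")
  m
}

checkAlphabet <- function(sequence) {
  s <- asSequence(sequence)
  stopIfEmptySequence(s)
  bad <- setdiff(unique(seqChars(s)), AA20)
  if (length(bad))
    stop("sequence contains non-standard letters: ", paste(bad, collapse = ","))
  s
}

#' Optimal global alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment under an affine gap model where a
#' gap of length L costs `gapOpening + L * gapExtension` (so a length-1 gap
#' costs 12 under the defaults), the convention of the FASTA-suite global
#' aligners. Identity is derived from the gapped alignment with gap columns
#' counted as non-matching and divided by the full alignment length
#' (configurable to drop terminal gap columns).
#'
#' @param query,reference character scalars or `AAString`s over the standard
#'   alphabet.
#' @param matrix substitution matrix (default BLOSUM62).
#' @param gapOpening,gapExtension affine gap parameters, defaults 10 and 2.
#' @param includeTerminalGaps count terminal gap columns in identity
#'   (default TRUE).
#' @return list with `gapped_query`, `gapped_reference`, `score`, `columns`
#'   (character vector: `"match"`, `"mismatch"`, `"gap"`), `identity`.
#' @examples
#' globalAlign("MKV", "MRV")$identity  # 2/3
#' @export
globalAlign <- function(query, reference, matrix = getSubstitutionMatrix(),
                        gapOpening = 10, gapExtension = 2,
                        includeTerminalGaps = TRUE) {
  q <- checkAlphabet(query)
  r <- checkAlphabet(reference)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(r), type = "global",
    substitutionMatrix = matrix, gapOpening = gapOpening,
    gapExtension = gapExtension)
  gq <- as.character(Biostrings::alignedPattern(aln))
  gr <- as.character(Biostrings::alignedSubject(aln))
  qc <- strsplit(gq, "")[[1]]
  rc <- strsplit(gr, "")[[1]]
  cols <- ifelse(qc == "-" | rc == "-", "gap",
                 ifelse(qc == rc, "match", "mismatch"))
  keep <- rep(TRUE, length(cols))
  if (!includeTerminalGaps) {
    nongap <- which(cols != "gap")
    keep <- seq_along(cols) >= min(nongap) & seq_along(cols) <= max(nongap)
  }
  list(gapped_query = gq, gapped_reference = gr,
       score = Biostrings::score(aln), columns = cols,
       identity = sum(cols[keep] == "match") / sum(keep))
}

#' Closest training sequence by global alignment score
#'
#' Aligns the query to every member of the training set and returns the hit
#' maximising the raw alignment score; ties break to the lexicographically
#' smaller reference id. Identity comes from the winning gapped alignment
#' (gap columns non-matching, full length).
#'
#' @inheritParams globalAlign
#' @param trainingSet non-empty named `AAStringSet` (or character vector).
#' @return list with `ref_id`, `score`, `identity`, `alignment` (as from
#'   [globalAlign()]).
#' @export
closestTraining <- function(query, trainingSet, matrix = getSubstitutionMatrix(),
                            gapOpening = 10, gapExtension = 2) {
  stopifnot(length(trainingSet) > 0L)
  q <- checkAlphabet(query)
  refs <- Biostrings::AAStringSet(as.character(trainingSet))
  if (is.null(names(refs))) names(refs) <- as.character(seq_along(refs))
  scores <- Biostrings::pairwiseAlignment(
    refs, Biostrings::AAString(q), type = "global",
    substitutionMatrix = matrix, gapOpening = gapOpening,
    gapExtension = gapExtension, scoreOnly = TRUE)
  top <- which(scores == max(scores))
  win <- top[order(names(refs)[top])][1]
  aln <- globalAlign(q, as.character(refs[[win]]), matrix = matrix,
                     gapOpening = gapOpening, gapExtension = gapExtension)
  list(ref_id = names(refs)[win], score = aln$score,
       identity = aln$identity, alignment = aln)
}

#' Closest-training identity and score for many queries at once
#'
#' @param queries named `AAStringSet`.
#' @inheritParams closestTraining
#' @return data.frame with `id`, `ref_id`, `score`, `identity`.
#' @export
closestTrainingBatch <- function(queries, trainingSet,
                                 matrix = getSubstitutionMatrix(),
                                 gapOpening = 10, gapExtension = 2) {
  stopifnot(length(trainingSet) > 0L, length(queries) > 0L)
  qs <- Biostrings::AAStringSet(as.character(queries))
  if (is.null(names(qs))) names(qs) <- as.character(seq_along(qs))
  refs <- Biostrings::AAStringSet(as.character(trainingSet))
  if (is.null(names(refs))) names(refs) <- as.character(seq_along(refs))
  smat <- vapply(seq_along(refs), function(j)
    Biostrings::pairwiseAlignment(qs, refs[[j]], type = "global",
                                  substitutionMatrix = matrix,
                                  gapOpening = gapOpening,
                                  gapExtension = gapExtension,
                                  scoreOnly = TRUE),
    numeric(length(qs)))
  smat <- matrix(smat, nrow = length(qs))
  out <- lapply(seq_along(qs), function(i) {
    top <- which(smat[i, ] == max(smat[i, ]))
    win <- top[order(names(refs)[top])][1]
    aln <- globalAlign(as.character(qs[[i]]), as.character(refs[[win]]),
                       matrix = matrix, gapOpening = gapOpening,
                       gapExtension = gapExtension)
    data.frame(id = names(qs)[i], ref_id = names(refs)[win],
               score = aln$score, identity = aln$identity)
  })
  do.call(rbind, out)
}

#' Mean substitution score over mismatched alignment positions
#'
#' Averages `matrix[q, r]` over alignment columns where the query and
#' reference residues differ, ignoring columns where either side is a gap.
#' With no mismatched columns the value is missing (`NA`) with an explicit
#' flag.
#'
#' @param alignment result of [globalAlign()].
#' @param matrix substitution matrix to average (need not be the alignment's).
#' @return list with `value` (`NA` when undefined), `n_mismatch`, and
#'   `no_mismatches` flag.
#' @export
mutantPositionMean <- function(alignment, matrix = getSubstitutionMatrix()) {
  qc <- strsplit(alignment$gapped_query, "")[[1]]
  rc <- strsplit(alignment$gapped_reference, "")[[1]]
  use <- qc != "-" & rc != "-" & qc != rc
  if (!any(use))
    return(list(value = NA_real_, n_mismatch = 0L, no_mismatches = TRUE))
  vals <- matrix[cbind(qc[use], rc[use])]
  list(value = mean(vals), n_mismatch = sum(use), no_mismatches = FALSE)
}

#' Mean score of the top-k training hits
#'
#' Scores the query against every training sequence and averages the k best
#' scores, emulating a "top 30 hits" homology summary. The internal backend
#' uses global-alignment raw scores; the `"phmmer"` backend shells out to the
#' phmmer executable and averages bit scores. The two backends are on
#' different scales and must not be mixed within one score table.
#'
#' @inheritParams closestTraining
#' @param k number of hits to average (default 30); with fewer than k
#'   training sequences the mean of all is returned with a warning.
#' @param backend `"internal"` or `"phmmer"`.
#' @return numeric mean score.
#' @export
topkMeanHomology <- function(query, trainingSet, k = 30,
                             backend = c("internal", "phmmer"),
                             matrix = getSubstitutionMatrix(),
                             gapOpening = 10, gapExtension = 2) {
  backend <- match.arg(backend)
  stopifnot(length(trainingSet) > 0L)
  q <- checkAlphabet(query)
  if (backend == "phmmer") {
    scores <- phmmerScores(q, trainingSet)
  } else {
    refs <- Biostrings::AAStringSet(as.character(trainingSet))
    scores <- Biostrings::pairwiseAlignment(
      refs, Biostrings::AAString(q), type = "global",
      substitutionMatrix = matrix, gapOpening = gapOpening,
      gapExtension = gapExtension, scoreOnly = TRUE)
  }
  if (length(scores) < k) {
    warning("fewer than k = ", k, " training sequences; averaging all ",
            length(scores))
    k <- length(scores)
  }
  mean(sort(scores, decreasing = TRUE)[seq_len(k)])
}

# adapter: per-reference phmmer bit scores of one query against a training set
phmmerScores <- function(query, trainingSet) {
  exe <- Sys.which("phmmer")
  if (exe == "")
    stop("phmmer executable not found; use backend = \"internal\" instead")
  qf <- tempfile(fileext = ".fasta"); tf <- tempfile(fileext = ".fasta")
  out <- tempfile(fileext = ".tbl")
  on.exit(unlink(c(qf, tf, out)))
  writeLines(c(">query", query), qf)
  refs <- Biostrings::AAStringSet(as.character(trainingSet))
  if (is.null(names(refs))) names(refs) <- as.character(seq_along(refs))
  Biostrings::writeXStringSet(refs, tf)
  status <- system2(exe, c("--tblout", out, "--noali", qf, tf),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("phmmer failed with status ", status)
  lines <- readLines(out)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) == 0L) return(numeric(0))
  vapply(strsplit(lines, "\\s+"), function(f) as.numeric(f[6]), numeric(1))
}
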