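#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased, whitespace-stripped, and `*` stop terminators
#' removed (with a message). Characters outside the 20-letter alphabet plus X
#' are replaced by X and recorded -- records are flagged, never dropped. The
#' id is the header up to the first whitespace; the remainder is kept as the
#' description.
#'
#' @param path FASTA file.
#' @param source provenance label stored on every record, one of
#'   `"natural_train"`, `"natural_test"`, `"generated"` or `NA`.
#' @return `AAStringSet` with metadata columns `description`, `source`,
#'   `has_x` (record contains X, either literal or substituted) and
#'   `violations` (offending characters, comma-separated, `""` if clean).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a toy record", "MKV"), f)
#' readFasta(f)
#' @export
readFasta <- function(path, source = NA_character_) {
  stopifnot(file.exists(path))
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ",
                                           conditionMessage(e)))
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(gsub("[[:space:]]", "", as.character(raw)))
  nstop <- sum(grepl("\\*", seqs))
  if (nstop > 0L) {
    message(nstop, " record(s) contained '*' terminators; removed")
    seqs <- gsub("\\*", "", seqs)
  }
  if (any(nchar(seqs) == 0L)) stop("record with empty sequence: ",
                                   paste(ids[nchar(seqs) == 0L], collapse = ", "))
  ok <- paste0(c(AA20, "X"), collapse = "")
  badpat <- paste0("[^", ok, "]")
  violations <- vapply(seqs, function(s) {
    bad <- unique(seqChars(gsub(paste0("[", ok, "]"), "", s)))
    paste(bad, collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  if (any(violations != "")) {
    warning(sum(violations != ""),
            " record(s) with non-amino-acid characters; replaced by X and flagged")
    seqs <- gsub(badpat, "X", seqs)
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    description = desc,
    source = rep(as.character(source), length(out)),
    has_x = grepl("X", seqs, fixed = TRUE),
    violations = violations)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs `AAStringSet` (descriptions in `mcols(seqs)$description`, if
#'   present, are appended to the headers).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  x <- if (methods::is(seqs, "AAStringSet")) seqs
       else Biostrings::AAStringSet(seqs)
  mc <- S4Vectors::mcols(seqs)
  if (!is.null(mc) && "description" %in% names(mc)) {
    d <- as.character(mc$description)
    names(x) <- ifelse(nzchar(d), paste(names(seqs), d), names(seqs))
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a multiple sequence alignment (aligned FASTA or A3M)
#'
#' In the A3M convention lowercase letters are insertions relative to the
#' alignment columns: they are removed for column-wise work and uppercased
#' when extracting ungapped sequences. `.` gap characters are normalised
#' to `-`.
#'
#' @param path alignment file.
#' @return list with `aligned` (`AAStringSet`, equal widths, gaps as `-`) and
#'   `sequences` (`AAStringSet`, ungapped, insertions restored and
#'   uppercased).
#' @export
readMsa <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty alignment file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  chars <- as.character(raw)
  chars <- gsub("[[:space:]]", "", chars)
  chars <- gsub(".", "-", chars, fixed = TRUE)
  aligned <- gsub("[a-z]", "", chars)               # drop A3M insertions
  if (length(unique(nchar(aligned))) != 1L)
    stop("alignment rows have unequal widths after removing insertions")
  ungapped <- toupper(gsub("-", "", chars, fixed = TRUE))
  al <- Biostrings::AAStringSet(aligned); names(al) <- ids
  un <- Biostrings::AAStringSet(ungapped); names(un) <- ids
  list(aligned = al, sequences = un)
}

#' Read / write a score table
#'
#' A score table is a tab-separated file with an `id` column and one column
#' per metric. Each metric carries an orientation flag (TRUE = higher is
#' better), stored in a `#orientation:` comment line and exposed as the
#' `"orientation"` attribute of the returned data.frame. Missing values are
#' explicit `NA`.
#'
#' @param path TSV file.
#' @return data.frame with attribute `orientation` (named logical).
#' @export
readScoreTable <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  orientation <- NULL
  if (startsWith(first, "#orientation:")) {
    spec <- strsplit(sub("^#orientation:\\s*", "", first), ",")[[1]]
    kv <- strsplit(trimws(spec), "=")
    orientation <- setNames(vapply(kv, function(p) p[2] == "+", logical(1)),
                            vapply(kv, `[`, character(1), 1))
  }
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(df)) stop("score table must have an 'id' column")
  if (anyDuplicated(df$id)) stop("duplicate ids in score table")
  attr(df, "orientation") <- orientation
  df
}

#' @rdname readScoreTable
#' @param df data.frame with an `id` column.
#' @param orientation named logical, TRUE where higher is better.
#' @export
writeScoreTable <- function(df, path, orientation = NULL) {
  stopifnot("id" %in% names(df))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(orientation)) {
    writeLines(paste0("#orientation: ", paste0(
      names(orientation), "=", ifelse(orientation, "+", "-"), collapse = ",")),
      con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run-configuration / policy YAML file
#'
#' Recognised keys mirror the arguments of [filterPolicy()].
#'
#' @param path YAML file.
#' @return a [FilterPolicy-class].
#' @export
readPolicy <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(filterPolicy, cfg)
}
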