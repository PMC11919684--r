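#' Read a PDB coordinate file into a StructureModel
#'
#' ATOM records are parsed with the fixed-column PDB convention (via bio3d);
#' HETATM records are ignored. Multi-model files use the first model with a
#' warning. The B-factor column is carried as per-residue prediction
#' confidence (structure predictors write pLDDT there).
#'
#' @param path PDB file.
#' @return a [StructureModel-class].
#' @export
readStructure <- function(path) {
  stopifnot(file.exists(path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  if (!is.null(pdb$xyz) && is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1L)
    warning("multi-model file; using first model")
  a <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("no ATOM records in ", path)
  elem <- a$elesy
  missing_elem <- is.na(elem) | elem == ""
  if (any(missing_elem))  # fall back on the first letter of the atom name
    elem[missing_elem] <- substr(gsub("[0-9]", "", a$elety[missing_elem]), 1, 1)
  methods::new("StructureModel", atoms = data.frame(
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    resno = a$resno, resname = a$resid, atom = a$elety,
    element = toupper(elem), x = a$x, y = a$y, z = a$z,
    b = a$b, stringsAsFactors = FALSE))
}

#' Write a StructureModel to a PDB file
#'
#' Emits standard fixed-column ATOM records (single chain ids and occupancy
#' 1.00); output round-trips through [readStructure()].
#'
#' @param x a [StructureModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(x, path) {
  a <- x@atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)),
    ifelse(nchar(a$atom) < 4L, paste0(" ", a$atom), a$atom),
    a$resname, a$chain, a$resno, a$x, a$y, a$z, 1.0, a$b, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

aa3to1 <- function(resnames) {
  out <- suppressWarnings(bio3d::aa321(resnames))
  out[is.na(out) | !(out %in% c(AA20, "X"))] <- "X"
  out
}

# per-residue view of the atom table: list of row-index vectors in file order
residueGroups <- function(x) {
  a <- x@atoms
  key <- paste(a$chain, a$resno, sep = "|")
  split(seq_len(nrow(a)), factor(key, levels = unique(key)))
}

#' One-letter sequence of a structure
#'
#' @param x a [StructureModel-class].
#' @param ... unused.
#' @return character scalar; unknown residue names become `X`.
#' @rdname structureSequence
#' @export
setMethod("structureSequence", "StructureModel", function(x, ...) {
  groups <- residueGroups(x)
  res <- vapply(groups, function(i) x@atoms$resname[i[1]], character(1))
  paste(aa3to1(res), collapse = "")
})

#' Per-residue prediction confidence
#'
#' Structure predictors write identical per-atom confidences within a
#' residue; the residue-level value is taken as the mean over its atoms
#' (robust to dialects that vary slightly). `level = "atom"` returns the raw
#' per-atom values instead.
#'
#' @param x a [StructureModel-class].
#' @param level `"residue"` (default) or `"atom"`.
#' @param ... unused.
#' @return numeric vector of confidences in \[0, 100\].
#' @rdname residueConfidences
#' @export
setMethod("residueConfidences", "StructureModel",
          function(x, level = c("residue", "atom"), ...) {
  level <- match.arg(level)
  b <- x@atoms$b
  if (all(is.na(b))) stop("structure has no B-factor values; confidence unavailable")
  if (level == "atom") return(b)
  vapply(residueGroups(x), function(i) mean(b[i]), numeric(1), USE.NAMES = FALSE)
})

setMethod("show", "StructureModel", function(object) {
  g <- residueGroups(object)
  cat(sprintf("StructureModel: %d atoms, %d residues, %d chain(s)\n",
              nrow(object@atoms), length(g), length(unique(object@atoms$chain))))
  cat("  sequence: ", substr(structureSequence(object), 1, 60),
      if (length(g) > 60L) "..." else "", "\n", sep = "")
})

#' Number of residues in a structure
#' @param x a [StructureModel-class].
#' @export
setMethod("length", "StructureModel", function(x) length(residueGroups(x)))

#' Atom table accessor
#'
#' @param x a [StructureModel-class].
#' @return the atom data.frame.
#' @export
atomTable <- function(x) {
  stopifnot(methods::is(x, "StructureModel"))
  x@atoms
}
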