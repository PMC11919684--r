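#' Van der Waals radii and probe settings for SASA
#'
#' Heavy-atom van der Waals radii (Angstrom) from the standard Bondi (1964)
#' compilation; hydrogens, normally absent from predicted structures, are
#' ignored by the SASA routine rather than folded into united-atom radii.
#'
#' @param probe probe radius in Angstrom, default 1.4 (water).
#' @param nPoints number of test points per atom sphere, default 960.
#' @param radii named numeric vector of element radii, overriding or
#'   extending the defaults.
#' @param unknownElement `"error"` (default) or `"skip"` (drop the atom with
#'   a warning).
#' @return list used by [shrakeRupley()].
#' @export
radiiSet <- function(probe = 1.4, nPoints = 960, radii = NULL,
                     unknownElement = c("error", "skip")) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
         H = 1.20)
  if (!is.null(radii)) r[names(radii)] <- radii
  stopifnot(all(r > 0), probe >= 0, nPoints >= 10)
  list(radii = r, probe = probe, nPoints = as.integer(nPoints),
       unknownElement = match.arg(unknownElement))
}

# near-uniform points on the unit sphere (Fibonacci lattice)
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic test-point SASA: each atom's sphere is expanded by the probe
#' radius and covered with `nPoints` near-uniform points; a point is
#' accessible if it lies outside every neighbouring atom's expanded sphere,
#' and the atom's area is the accessible fraction of its expanded-sphere
#' area. Atoms with element N, O or S are classed polar, everything else
#' (essentially carbon) apolar, and
#' `percent_polar = 100 * polar / total`. Hydrogens are ignored.
#'
#' @param structure a [StructureModel-class] with >= 1 atom.
#' @param radii a [radiiSet()].
#' @return list with `total`, `polar`, `apolar` (Angstrom^2),
#'   `percent_polar`, and `per_atom`, a data.frame of per-atom areas and
#'   polar class.
#' @export
shrakeRupley <- function(structure, radii = radiiSet()) {
  a <- atomTable(structure)
  a <- a[a$element != "H", , drop = FALSE]
  known <- a$element %in% names(radii$radii)
  if (any(!known)) {
    bad <- unique(a$element[!known])
    if (radii$unknownElement == "error")
      stop("unknown element(s): ", paste(bad, collapse = ","),
           "; extend radiiSet(radii=) or set unknownElement=\"skip\"")
    warning("skipping atoms with unknown element(s): ",
            paste(bad, collapse = ","))
    a <- a[known, , drop = FALSE]
  }
  if (nrow(a) == 0L) stop("no atoms with known elements")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rexp <- radii$radii[a$element] + radii$probe
  pts <- fibonacciSphere(radii$nPoints)
  n <- nrow(a)
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (rexp + rexp[i])^2 & seq_len(n) != i)
    # exactly coincident equal-radius duplicates: only the earlier atom
    # keeps its surface, so the pair exposes the area of one
    nb <- nb[!(d2[nb] == 0 & rexp[nb] == rexp[i] & nb > i)]
    p <- pts * rexp[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(p))
    for (j in nb) {
      if (!any(acc)) break
      dd <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
            (p[, 3] - xyz[j, 3])^2
      acc <- acc & dd > rexp[j]^2 * (1 + 1e-9)
    }
    area[i] <- 4 * pi * rexp[i]^2 * mean(acc)
  }
  polar_class <- a$element %in% c("N", "O", "S")
  total <- sum(area)
  polar <- sum(area[polar_class])
  list(total = total, polar = polar, apolar = total - polar,
       percent_polar = if (total > 0) 100 * polar / total else 0,
       per_atom = data.frame(a[, c("chain", "resno", "resname", "atom",
                                   "element")],
                             area = area, polar = polar_class))
}

#' Mean per-residue prediction confidence
#'
#' The structure-confidence metric: the unweighted mean of the per-residue
#' confidences carried in the B-factor field (pLDDT convention, 0-100).
#'
#' @param structure a [StructureModel-class].
#' @param level `"residue"` (default: residue values are atom means) or
#'   `"atom"`.
#' @return numeric mean confidence.
#' @export
meanConfidence <- function(structure, level = c("residue", "atom")) {
  mean(residueConfidences(structure, level = match.arg(level)))
}

.ifCache <- new.env(parent = emptyenv())

#' Inverse-folding score via an adapter
#'
#' The inverse-folding metric is the mean log-likelihood of the query
#' residues conditioned on a fixed backbone, as produced by a
#' structure-conditioned sequence model. The model itself attaches as an
#' adapter: `function(structure, sequence)` returning per-residue
#' log-likelihoods (or a single mean). Results are cached on
#' (structure, sequence) so repeated queries do not re-invoke the adapter.
#'
#' @param adapter the scorer adapter function.
#' @param structure a [StructureModel-class].
#' @param sequence character scalar; its length must equal the structure's
#'   residue count.
#' @param cache use the in-memory cache (default TRUE).
#' @return numeric mean per-residue log-likelihood.
#' @export
inverseFoldingScore <- function(adapter, structure, sequence, cache = TRUE) {
  stopifnot(is.function(adapter), methods::is(structure, "StructureModel"))
  s <- asSequence(sequence)
  if (nchar(s) != length(structure))
    stop("sequence length ", nchar(s), " does not match structure residue count ",
         length(structure))
  key <- rlang::hash(list(atomTable(structure), s))
  if (cache && !is.null(.ifCache[[key]])) return(.ifCache[[key]])
  val <- mean(adapter(structure, s))
  if (cache) .ifCache[[key]] <- val
  val
}

#' Parse a Rosetta-style score file
#'
#' Reads the whitespace-separated `SCORE:` table written by relax-style
#' protocols (adapter plumbing for energy-function metrics; no energy
#' function is implemented here).
#'
#' @param path score file.
#' @return data.frame, one row per decoy.
#' @export
parseRosettaScoreFile <- function(path) {
  stopifnot(file.exists(path))
  lines <- grep("^SCORE:", readLines(path), value = TRUE)
  if (length(lines) < 2L) stop("no SCORE: table in ", path)
  fields <- lapply(lines, function(l) strsplit(trimws(sub("^SCORE:", "", l)),
                                               "\\s+")[[1]])
  header <- fields[[1]]
  rows <- fields[-1]
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- header
  for (cn in setdiff(header, "description"))
    df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
  df
}
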