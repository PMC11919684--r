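# Independent oracles used across the suite. These deliberately re-derive
# results by brute force / enumeration, sharing no code with the package.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

randomAASeq <- function(L) paste(sample(AA, L, replace = TRUE), collapse = "")

# brute-force tandem repeat units: try every (offset, k-mer) and count copies
oracleRepeatUnits <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  best <- 1L
  for (start in seq_len(n - k + 1L)) {
    for (units in seq_len(n %/% k)) {
      end <- start + units * k - 1L
      if (end > n) break
      block <- ch[start:(start + k - 1L)]
      if (all(ch[start:end] == rep(block, units))) {
        best <- max(best, units)
      } else break
    }
  }
  best
}

# reference Gotoh dynamic programme: global alignment, affine gaps where a
# gap of length L costs open + L * extend; returns the optimal score only
oracleGotohScore <- function(q, r, mat, open = 10, extend = 2) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in a gap in the reference (q aligned)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in a gap in the query
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + extend * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + extend * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[qc[i], rc[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# all-pairs AUC: fraction of (active, inactive) pairs correctly ordered,
# ties counting one half
oracleAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# two-tailed Fisher p by direct enumeration of the hypergeometric support
oracleFisherTwoTailed <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) dhyper(x, r1, r2, c1), numeric(1))
  pobs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Spearman via explicit mid-ranks and the Pearson formula
oracleSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# convenience: write a FASTA file from a named character vector
writeFastaLines <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# uniform PssmScorer of a given length, built directly
uniformScorer <- function(L) {
  methods::new("PssmScorer",
               probs = matrix(1 / 20, nrow = L, ncol = 20,
                              dimnames = list(NULL, AA)),
               alpha = 1)
}

blosum62 <- getSubstitutionMatrix("BLOSUM62")
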