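test_that("mask schedules partition positions with the right spacing", {
  for (m in 1:6) {
    sets <- maskSets(maskSchedule(m), 17L)
    expect_length(sets, m)
    expect_equal(sort(unlist(sets)), 1:17)
    for (s in sets) if (length(s) > 1L) expect_true(all(diff(s) == m))
  }
  expect_error(maskSchedule(0), "positive")
})

test_that("average log-probability of a uniform scorer is log(1/20)", {
  sc <- uniformScorer(10L)
  set.seed(3)
  s <- randomAASeq(10)
  expect_equal(averageLogProb(sc, s), log(1 / 20))
  expect_equal(averageLogProb(sc, s, maskSchedule(6)), log(1 / 20))
})

test_that("a vanishing pseudocount makes the single-sequence PSSM certain", {
  msa <- Biostrings::AAStringSet("MKVLD")
  sc <- pssmScorer(msa, alpha = 1e-12)
  expect_equal(averageLogProb(sc, "MKVLD"), 0, tolerance = 1e-8)
})

test_that("masked pooling matches direct PSSM arithmetic on a small MSA", {
  msa <- Biostrings::AAStringSet(c("MKV", "MKV", "MAV"))
  sc <- pssmScorer(msa, alpha = 1)
  # independent arithmetic: column counts + pseudocount 1 over 3 + 20 rows
  p <- function(count) (count + 1) / (3 + 20)
  expected <- mean(log(c(p(3), p(2), p(3))))   # scoring MKV
  expect_equal(averageLogProb(sc, "MKV"), expected)
  expect_equal(averageLogProb(sc, "MKV", maskSchedule(2)), expected)
  expect_equal(averageLogProb(sc, "MAV"),
               mean(log(c(p(3), p(1), p(3)))))
})

test_that("masking cannot change a context-free scorer's score", {
  set.seed(17)
  for (i in 1:10) {
    L <- sample(8:40, 1)
    msa <- Biostrings::AAStringSet(vapply(1:4, function(j) randomAASeq(L),
                                          character(1)))
    sc <- pssmScorer(msa, alpha = 0.5)
    s <- randomAASeq(L)
    base <- averageLogProb(sc, s)
    for (m in c(2, 3, 6))
      expect_equal(averageLogProb(sc, s, maskSchedule(m)), base)
  }
})

test_that("scorer errors are informative", {
  sc <- uniformScorer(5L)
  expect_error(averageLogProb(sc, "MKV"), "length")
  expect_error(averageLogProb(pssmScorer(alpha = 1), "MKV"), "context-mode")
  expect_true(all(scoreLogProbs(sc, "MKVLD") <= 0))
})

test_that("MSA-context score equals the PSSM self-score for a verbatim query", {
  set.seed(71)
  base <- randomAASeq(30)
  train <- vapply(1:6, function(i) {
    ch <- strsplit(base, "")[[1]]
    pos <- sample(30, 4)
    ch[pos] <- vapply(ch[pos], function(a) sample(setdiff(AA, a), 1),
                      character(1))
    paste(ch, collapse = "")
  }, character(1))
  names(train) <- paste0("t", 1:6)
  trainSet <- Biostrings::AAStringSet(train)
  q <- train[["t3"]]

  got <- msaContextScore(pssmScorer(alpha = 1), q, trainSet,
                         nContext = 3, interval = 2)
  # independent: the context MSA is the query plus its 3 nearest neighbours
  # (all same length, substitution-only, so the star MSA is just the rows)
  scores <- vapply(train, function(r) globalAlign(q, r)$score, numeric(1))
  nb <- names(scores)[order(-scores, names(scores))][1:3]
  rows <- c(q, train[nb])
  counts <- function(j) {
    col <- substr(rows, j, j)
    (sum(col == substr(q, j, j)) + 1) / (length(rows) + 20)
  }
  expected <- mean(log(vapply(1:30, counts, numeric(1))))
  expect_equal(got, expected)
})

test_that("MSA-context score clamps to small training sets and is order-stable", {
  train <- Biostrings::AAStringSet(c(only = "MKVLDEGAWY"))
  v <- msaContextScore(pssmScorer(alpha = 1), "MKVLDEGAWY", train,
                       nContext = 31, interval = 6)
  expect_true(is.finite(v) && v <= 0)
  expect_error(msaContextScore(pssmScorer(alpha = 1), "MKV",
                               Biostrings::AAStringSet()), "empty")

  set.seed(72)
  base <- randomAASeq(25)
  fam <- vapply(1:5, function(i) {
    ch <- strsplit(base, "")[[1]]
    pos <- sample(25, i)  # distinct distances: no ties
    ch[pos] <- vapply(ch[pos], function(a) sample(setdiff(AA, a), 1),
                      character(1))
    paste(ch, collapse = "")
  }, character(1))
  names(fam) <- paste0("t", 1:5)
  s1 <- msaContextScore(pssmScorer(alpha = 1), base,
                        Biostrings::AAStringSet(fam), nContext = 3)
  perm <- sample(5)
  s2 <- msaContextScore(pssmScorer(alpha = 1), base,
                        Biostrings::AAStringSet(fam[perm]), nContext = 3)
  expect_equal(s1, s2)
})

test_that("iterative masking sampling is reproducible and degenerates correctly", {
  msa <- Biostrings::AAStringSet(c(a = "MKVLD", b = "MKVLD", c = "MKVLD"))
  # one-hot columns (tiny pseudocount): consensus comes back whatever the seed
  sc <- pssmScorer(alpha = 1e-9)
  for (seed in c(1, 99)) {
    out <- iterativeMaskSample(sc, msa, mode = "whole_msa", seed = seed)
    expect_equal(unname(as.character(out)), rep("MKVLD", 3))
  }

  set.seed(80)
  L <- 12
  msa2 <- Biostrings::AAStringSet(setNames(
    vapply(1:4, function(i) randomAASeq(L), character(1)), paste0("r", 1:4)))
  sc2 <- pssmScorer(alpha = 1)
  a <- iterativeMaskSample(sc2, msa2, mode = "single_sequence_neighbors",
                           seed = 7)
  b <- iterativeMaskSample(sc2, msa2, mode = "single_sequence_neighbors",
                           seed = 7)
  expect_identical(as.character(a), as.character(b))
  expect_equal(unique(S4Vectors::mcols(a)$mode), "single_sequence_neighbors")
  expect_equal(unique(S4Vectors::mcols(a)$seed), 7L)

  # temperature -> 0 gives the argmax (consensus) of the context columns
  msa3 <- Biostrings::AAStringSet(c("MKVLD", "MKVLD", "MAVLD", "MKVID"))
  out <- iterativeMaskSample(pssmScorer(alpha = 1e-9), msa3,
                             mode = "single_sequence_neighbors",
                             temperature = 0, seed = 5)
  expect_equal(as.character(out)[[1]], "MKVLD")
})

test_that("sampling from a uniform scorer is uniform within 3 sigma", {
  # 10 rows x 1000 columns, huge pseudocount => effectively uniform columns;
  # each output residue is a single draw: 10,000 draws in all
  set.seed(90)
  L <- 1000L
  msa <- Biostrings::AAStringSet(vapply(1:10, function(i) randomAASeq(L),
                                        character(1)))
  out <- iterativeMaskSample(pssmScorer(alpha = 1e9), msa,
                             mode = "whole_msa", seed = 42)
  draws <- unlist(strsplit(as.character(out), ""))
  expect_length(draws, 10000L)
  counts <- table(factor(draws, levels = AA))
  expected <- 10000 / 20
  sigma <- sqrt(10000 * (1 / 20) * (19 / 20))
  expect_true(all(abs(counts - expected) <= 3 * sigma))
})
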