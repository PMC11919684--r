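# one small fixture family shared across blocks in this file
famSmall <- makeFamily(familySpec(nCandidates = 120, seed = 5))
famScores <- data.frame(id = famSmall$manifest$id,
                        identity = famSmall$manifest$identity_target,
                        lm_score = famSmall$manifest$lm_score,
                        structure_score = famSmall$manifest$structure_score)

test_that("cutoff calibration follows the top-percentile rule", {
  expect_warning(cut10 <- calibrateCutoff(1:10), "fewer than 20")
  expect_equal(cut10, 10)
  expect_equal(sum(1:10 >= cut10), 1L)
  pol <- filterPolicy(lmPercentile = 100)
  expect_equal(suppressWarnings(calibrateCutoff(1:10, pol)), 1)
  expect_equal(suppressWarnings(calibrateCutoff(rep(2.5, 8))), 2.5)
  expect_error(calibrateCutoff(numeric(0)), "empty")
  expect_error(calibrateCutoff(1:3), "at least 5")
})

test_that("sequence stage partitions candidates with full reason lists", {
  cands <- Biostrings::AAStringSet(c(hi = "MKVLDEGAWY", band = "MKVLDEGAWY",
                                     rep = "MAAAAAEGWY"))
  sc <- data.frame(id = c("hi", "band", "rep"),
                   identity = c(0.7, 0.85, 0.7),
                   lm_score = c(5, 5, -5))
  tab <- suppressMessages(sequenceStage(cands, sc, cutoff = 0))
  expect_equal(tab$pass, c(TRUE, FALSE, FALSE))
  expect_match(tab$reasons[tab$id == "band"], "identity_above_band")
  expect_match(tab$reasons[tab$id == "rep"], "homopolymer_run")
  expect_match(tab$reasons[tab$id == "rep"], "lm_below_cutoff")

  sc$lm_score[2] <- NA
  expect_error(suppressMessages(sequenceStage(cands, sc, 0)), "lm_score")
  expect_error(suppressMessages(
    sequenceStage(cands, sc[, c("id", "lm_score")], 0)), "identity")
})

test_that("sequence stage matches the fixture defect manifest", {
  cutoff <- suppressWarnings(calibrateCutoff(famSmall$naturalScores))
  tab <- suppressMessages(
    sequenceStage(famSmall$candidates, famScores, cutoff))
  man <- famSmall$manifest[match(tab$id, famSmall$manifest$id), ]
  quality_defects <- c("no_start_M", "homopolymer_run", "dimer_run")
  has_quality_defect <- vapply(strsplit(man$defects, ","), function(d)
    any(d %in% quality_defects), logical(1))
  in_band <- man$identity_target >= 0.5 & man$identity_target <= 0.8
  expected_pass <- !has_quality_defect & in_band & man$lm_score >= cutoff
  expect_equal(tab$pass, expected_pass)
  # every injected quality defect surfaces as its own reason label
  for (d in quality_defects) {
    hit <- grepl(d, man$defects)
    expect_true(all(grepl(d, tab$reasons[hit])), info = d)
  }
})

test_that("structure stage is deterministic, ranked and back-filled", {
  ids <- sprintf("c%03d", 1:60)
  sc <- data.frame(id = ids, structure_score = seq_along(ids))  # increasing
  pol <- filterPolicy(nPrefilterSample = 40, topNStructure = 20, nFinal = 8)
  s1 <- structureStage(ids, sc, pol, seed = 7)
  s2 <- structureStage(ids, sc, pol, seed = 7)
  expect_identical(s1$selected, s2$selected)
  expect_length(s1$selected, 8L)
  # top-N are the largest scores among the sampled set
  sampled_scores <- sc$structure_score[match(s1$sampled, sc$id)]
  expect_setequal(s1$top,
                  s1$sampled[order(-sampled_scores)][1:20])
  expect_true(all(s1$selected %in% s1$top))

  # fewer passing than the sample size: all are taken, with a message
  expect_message(s3 <- structureStage(ids[1:10], sc, filterPolicy(nFinal = 5,
                 topNStructure = 8, nPrefilterSample = 20), seed = 1),
                 "sampling all")
  expect_setequal(s3$sampled, ids[1:10])

  # missing structure scores are set aside and the window back-fills
  sc$structure_score[match(s1$top[1:3], sc$id)] <- NA
  s4 <- structureStage(ids, sc, pol, seed = 7)
  expect_true(all(s1$top[1:3] %in% s4$missing_scores))
  expect_length(s4$top, 20L)
  expect_error(structureStage(ids[1:5], sc, pol), "nFinal")
})

test_that("control matching respects the identity tolerance", {
  sel <- data.frame(id = c("s1", "s2"), identity = c(0.70, 0.60))
  pool <- data.frame(id = c("f1", "f2", "f3"),
                     identity = c(0.705, 0.601, 0.9))
  m <- matchControls(sel, pool, seed = 3)
  expect_equal(m$control, c("f1", "f2"))
  expect_true(all(m$delta_identity <= 0.01))

  # empty in-tolerance pool: unmatched, not dropped
  m2 <- matchControls(data.frame(id = "s", identity = 0.3), pool, seed = 3)
  expect_true(is.na(m2$control))

  set.seed(1)
  sel18 <- data.frame(id = sprintf("s%02d", 1:18),
                      identity = runif(18, 0.55, 0.75))
  pool50 <- data.frame(id = sprintf("f%02d", 1:50),
                       identity = runif(50, 0.55, 0.75))
  a <- matchControls(sel18, pool50, seed = 11)
  b <- matchControls(sel18, pool50, seed = 11)
  expect_identical(a, b)
  ok <- !is.na(a$control)
  expect_true(all(a$delta_identity[ok] <= 0.01))
  expect_false(anyDuplicated(a$control[ok]) > 0)   # without replacement
})

test_that("a full filter run is internally consistent", {
  pol <- filterPolicy(nPrefilterSample = 40, topNStructure = 20, nFinal = 8)
  rep <- suppressMessages(suppressWarnings(
    runCompss(famSmall$candidates, famScores, famSmall$naturalScores,
              pol, seed = 2)))
  expect_s4_class(rep, "FilterReport")
  tab <- candidateTable(rep)
  expect_setequal(tab$id, names(famSmall$candidates))   # everyone appears once
  counts <- stageCounts(rep)
  expect_true(all(diff(counts[c("input", "sequence_pass", "structure_sampled",
                                "top_structure", "selected")]) <= 0))
  # selected sequences re-validate against every policy criterion
  sel <- tab[tab$id %in% selectedSequences(rep), ]
  expect_true(all(sel$pass))
  expect_true(all(sel$identity >= 0.5 & sel$identity <= 0.8))
  expect_true(all(sel$lm_score >= filterCutoff(rep)))
  for (id in sel$id)
    expect_true(qualityCheck(famSmall$candidates[[id]], pol,
                             quiet = TRUE)$passed)
  # controls never overlap selections
  ctrl <- controlPairs(rep)
  expect_length(intersect(selectedSequences(rep),
                          ctrl$control[!is.na(ctrl$control)]), 0L)

  # reproducibility of the whole run
  rep2 <- suppressMessages(suppressWarnings(
    runCompss(famSmall$candidates, famScores, famSmall$naturalScores,
              pol, seed = 2)))
  expect_identical(selectedSequences(rep), selectedSequences(rep2))
  expect_identical(controlPairs(rep), controlPairs(rep2))
})

test_that("filter reports serialise to TSV plus a JSON manifest", {
  pol <- filterPolicy(nPrefilterSample = 40, topNStructure = 20, nFinal = 8)
  rep <- suppressMessages(suppressWarnings(
    runCompss(famSmall$candidates, famScores, famSmall$naturalScores,
              pol, seed = 2)))
  dir <- withr::local_tempdir()
  writeFilterReport(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("candidates.tsv",
                                               "controls.tsv",
                                               "manifest.json")))))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 2L)
  expect_equal(unlist(man$selected), selectedSequences(rep))
})

test_that("policy YAML round-trips through readPolicy", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("identityBand: [0.6, 0.9]", "lmPercentile: 20",
               "nPrefilterSample: 50", "topNStructure: 25", "nFinal: 10"), f)
  pol <- readPolicy(f)
  expect_s4_class(pol, "FilterPolicy")
  expect_equal(pol@identityBand, c(0.6, 0.9))
  expect_equal(pol@nFinal, 10L)
  expect_error(filterPolicy(nFinal = 50, topNStructure = 40), "nFinal")
})
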