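test_that("Beer-Lambert conversion is exact and linear", {
  expect_equal(nadhConcentration(0), 0)
  expect_equal(nadhConcentration(1.80), 1.80 / (0.29 * 6.22))
  expect_equal(nadhConcentration(0.29 * 6.22 * 0.5), 0.5)
  a <- c(0.2, 0.9, 1.4)
  expect_equal(nadhConcentration(3 * a), 3 * nadhConcentration(a))
  expect_error(nadhConcentration(-0.1), "non-negative")
})

test_that("MDH calls are one-sided: only significantly lower endpoints are active", {
  neg <- c(1.50, 1.52, 1.49)
  expect_false(mdhActivityCall(neg, neg)$active)
  fast <- c(0.20, 0.21, 0.19)
  call <- mdhActivityCall(fast, neg)
  expect_true(call$active)
  expect_lt(call$p, 1e-4)
  # above the control: inactive regardless of separation
  expect_false(mdhActivityCall(neg + 2, neg)$active)
  expect_error(mdhActivityCall(1.5, neg), "replicates")
})

test_that("SOD inhibition follows the four-absorbance formula", {
  expect_equal(sodInhibition(1.0, 0.2, 0.9, 0.1)$percent, 0)   # C-D = A-B
  expect_equal(sodInhibition(1.0, 0.2, 0.3, 0.3)$percent, 100) # C = D
  r <- sodInhibition(1.0, 0.1, 0.4, 0.1)
  expect_equal(r$percent, 100 * 0.6 / 0.9)
  expect_false(r$out_of_range)
  expect_true(sodInhibition(1.0, 0.1, 0.05, 0.2)$out_of_range)
  expect_error(sodInhibition(0.1, 0.2, 0.05, 0.0), "degenerate")
})

test_that("SOD inhibition is invariant only to fully symmetric offsets", {
  base <- sodInhibition(1.0, 0.1, 0.4, 0.1)$percent
  # the same constant on the (A, C) pair and on the (B, D) pair leaves both
  # differences, hence the rate, unchanged
  o <- 0.3
  expect_equal(sodInhibition(1.0 + o, 0.1 + o, 0.4 + o, 0.1 + o)$percent,
               base)
  # an offset on only one absorbance does change it
  expect_false(isTRUE(all.equal(
    sodInhibition(1.3, 0.1, 0.4, 0.1)$percent, base)))
})

mdhSeries <- function(a0, a90, reps = 3) {
  do.call(rbind, lapply(seq_len(reps), function(r)
    data.frame(replicate = r, time_s = c(0, 90),
               absorbance = c(a0[r], a90[r]))))
}

test_that("specific activity normalises to wild type", {
  wt <- mdhSeries(rep(2.7, 3), rep(1.0, 3))
  expect_equal(specificActivity(wt, wt, "mdh")$activity, 1)
  flat <- mdhSeries(rep(2.7, 3), rep(2.7, 3))
  expect_equal(specificActivity(flat, wt, "mdh")$activity, 0)
  half <- mdhSeries(rep(2.7, 3), rep(1.85, 3))
  expect_equal(specificActivity(half, wt, "mdh")$activity, 0.5)
  expect_error(specificActivity(
    data.frame(replicate = 1, time_s = c(0, 60), absorbance = c(2, 1)),
    wt, "mdh"), "90")
})

test_that("the t0 floor substitutes the negative-control mean", {
  # 250 uM at t0 (below the 275 uM floor) -> replaced by the negative mean
  a250 <- 250 / 1000 * 0.29 * 6.22
  a300 <- 300 / 1000 * 0.29 * 6.22
  a100 <- 100 / 1000 * 0.29 * 6.22
  s <- mdhSeries(rep(a250, 3), rep(a100, 3))
  neg <- mdhSeries(rep(a300, 3), rep(a300, 3))
  wt <- mdhSeries(rep(a300, 3), rep(a100, 3))
  r <- specificActivity(s, wt, "mdh", negativeSeries = neg)
  expect_equal(r$per_replicate, rep(200, 3), tolerance = 1e-9)
  expect_equal(r$activity, 1)
  # without a negative control the rule cannot fire
  expect_error(specificActivity(s, wt, "mdh"), "negative-control")
})

test_that("no-substrate drift is subtracted before endpoint extraction", {
  drift <- 0.3
  s <- mdhSeries(rep(2.7 + drift, 3), rep(1.0 + drift, 3))
  wt <- mdhSeries(rep(2.7 + drift, 3), rep(1.0 + drift, 3))
  ns <- mdhSeries(rep(drift, 3), rep(drift, 3))
  r <- specificActivity(s, wt, "mdh", noSubstrateSeries = ns)
  clean <- specificActivity(mdhSeries(rep(2.7, 3), rep(1.0, 3)),
                            mdhSeries(rep(2.7, 3), rep(1.0, 3)), "mdh")
  expect_equal(r$raw, clean$raw, tolerance = 1e-9)
})

test_that("wild type against itself stays at 1 under zero-mean noise", {
  plate <- makePlate(data.frame(id = "e1", family = "mdh", activity = 0.8),
                     noiseSd = 0.005, seed = 21)
  wt <- plate[plate$role == "wildtype", ]
  r <- specificActivity(wt, wt, "mdh")
  expect_equal(r$activity, 1, tolerance = 1e-12)  # ratio of identical means
  # and against an independently noised copy of itself, close to 1
  plate2 <- makePlate(data.frame(id = "e1", family = "mdh", activity = 0.8),
                      noiseSd = 0.005, seed = 22)
  wt2 <- plate2[plate2$role == "wildtype", ]
  expect_equal(specificActivity(wt2, wt, "mdh")$activity, 1, tolerance = 0.05)
})

test_that("whole plates analyse end to end for both assay chemistries", {
  truth <- data.frame(id = c("hot", "dead"), family = "mdh",
                      activity = c(0.9, 0))
  plate <- makePlate(truth, noiseSd = 0.01, seed = 31)
  res <- analyzePlate(plate, "mdh")
  expect_true(res$active[res$id == "hot"])
  expect_lt(res$p[res$id == "hot"], 1e-6)
  # the dead sample tracks the negative control: near-zero normalised
  # activity and a p-value orders of magnitude weaker than the hot one
  # (an occasional p <= alpha is the test's nominal false-positive rate)
  expect_lt(res$specific_activity[res$id == "dead"], 0.1)
  expect_gt(res$p[res$id == "dead"], 1e3 * res$p[res$id == "hot"])
  expect_gt(res$specific_activity[res$id == "hot"],
            res$specific_activity[res$id == "dead"])

  truthS <- data.frame(id = c("sod_hot", "sod_dead"), family = "sod",
                       activity = c(1, 0))
  plateS <- makePlate(truthS, noiseSd = 0.005, seed = 32)
  resS <- analyzePlate(plateS, "sod")
  expect_true(resS$active[resS$id == "sod_hot"])
  expect_false(resS$active[resS$id == "sod_dead"])
})

test_that("plate tables validate roles and timepoints on read", {
  plate <- makePlate(data.frame(id = "x", family = "mdh", activity = 1),
                     seed = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(plate, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readPlate(f)
  expect_equal(nrow(back), nrow(plate))
  bad <- plate; bad$role[1] <- "mystery"
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readPlate(f), "unknown role")
})
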