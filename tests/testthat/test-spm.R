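# tight optimizer settings for tiny exactly-solvable toys
toyConfig <- function(...) {
  args <- list(maxEpochs = 5000, valFraction = 0, dropout = 0,
               patience = 300, tol = 1e-9, seed = 3)
  over <- list(...)
  args[names(over)] <- over
  do.call(spmConfig, args)
}

twoSeqSE <- function(c0 = c(500L, 500L), c1 = c(900L, 100L)) {
  SelectionExperiment(cbind(R0 = c0, R1 = c1),
                      chainA = c("A", "B"), chainB = c("A", "B"),
                      scheme = schemeAB())
}

test_that("the two-sequence toy recovers the binomial MLE ln 9", {
  m <- fitSPM(twoSeqSE(), toyConfig())
  d <- diff(rev(scoreSequences(m, c("AA", "BB"), round = "R1")))
  expect_lt(abs(d - log(9)), 0.05)
  # global score difference has the same sign as the round-1 difference
  g <- diff(rev(scoreSequences(m, c("AA", "BB"))))
  expect_identical(sign(g), sign(d))
})

test_that("proportional counts across rounds yield near-flat fitness", {
  set.seed(2)
  sch <- scheme2x2abc()
  uni <- sample(enumerateSequences(sch), 80)
  base <- rpois(80, 60) + 1L
  cts <- cbind(R0 = base, R1 = base, R2 = base)
  se <- SelectionExperiment(cts, chainA = substr(uni, 1, 2),
                            chainB = substr(uni, 3, 4), scheme = sch)
  m <- fitSPM(se, toyConfig(maxEpochs = 1500, patience = 50))
  fr <- scoreSequences(m, uni, round = "R2")
  expect_lte(max(fr) - min(fr), 0.1)
})

test_that("fitting is deterministic given the seed", {
  sch <- scheme2x2abc()
  land <- sampleLandscape(sch, seed = 1)
  se <- simulateSelection(land, nRounds = 3, depth = 5000, seed = 2)
  cfg <- spmConfig(maxEpochs = 60, seed = 5)
  m1 <- fitSPM(se, cfg)
  m2 <- fitSPM(se, cfg)
  uni <- rownames(se)
  expect_identical(scoreSequences(m1, uni), scoreSequences(m2, uni))
  expect_identical(scoreSequences(m1, uni), scoreSequences(m1, uni))
})

test_that("adding a constant to the trunk leaves round probabilities unchanged", {
  m <- fitSPM(twoSeqSE(), toyConfig(maxEpochs = 300, patience = 50))
  se <- twoSeqSE()
  p1 <- predictCounts(m, se, "R1")
  shifted <- m
  L <- length(shifted@weights$b)
  shifted@weights$b[[L]] <- shifted@weights$b[[L]] + 25
  p2 <- predictCounts(shifted, se, "R1")
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("training loss decreases on a full-batch toy", {
  sch <- scheme2x2abc()
  land <- sampleLandscape(sch, seed = 4)
  se <- simulateSelection(land, nRounds = 3, depth = 2e4, seed = 5)
  m <- fitSPM(se, spmConfig(maxEpochs = 120, dropout = 0,
                            valFraction = 0, patience = 120, seed = 6))
  tr <- m@history$loss
  expect_lt(tr[length(tr)], tr[1])
  upticks <- sum(pmax(0, diff(tr)))
  expect_lt(upticks, 0.05 * (tr[1] - min(tr)))
})

test_that("single-round data and empty rounds are rejected", {
  se1 <- SelectionExperiment(cbind(R0 = c(5L, 5L)),
                             chainA = c("A", "B"), chainB = c("A", "B"),
                             scheme = schemeAB())
  expect_error(fitSPM(se1), "single round|unidentifiable")
  expect_error(scoreSequences(fitSPM(twoSeqSE(),
                                     toyConfig(maxEpochs = 5)),
                              "AX"), "outside")
})

test_that("expected counts renormalize to the round total", {
  sch <- scheme2x2abc()
  land <- sampleLandscape(sch, seed = 7)
  se <- simulateSelection(land, nRounds = 3, depth = 1e4, seed = 8)
  m <- fitSPM(se, spmConfig(maxEpochs = 80, seed = 9))
  for (r in c("R1", "R3")) {
    pred <- predictCounts(m, se, r)
    expect_equal(sum(pred), sum(selectionCounts(se)[, r]),
                 tolerance = 1e-6)
  }
})

test_that("cross-validation scores folds and returns the best config", {
  sch <- scheme2x2abc()
  land <- sampleLandscape(sch, seed = 10)
  se <- simulateSelection(land, nRounds = 3, depth = 1e4, seed = 11)
  grid <- list(spmConfig(maxEpochs = 60, seed = 12))
  cv <- crossvalidateSPM(se, grid, nFolds = 5, seed = 13)
  expect_identical(cv$bestIndex, 1L)
  expect_identical(dim(cv$mse), c(1L, 5L))
  expect_true(all(is.finite(cv$mse)))
  expect_error(crossvalidateSPM(se, list()), "empty")
})

test_that("model capacity is rewarded on an epistatic landscape", {
  sch <- scheme2x2abc()
  wins <- 0L
  for (s in 1:3) {
    land <- sampleLandscape(sch, additiveScale = 0.2, pairwiseScale = 1.5,
                            pairFraction = 0.8, seed = s)
    se <- simulateSelection(land, nRounds = 4, depth = 5e4, seed = s + 50)
    cts <- selectionCounts(se)
    finalSeqs <- which(cts[, ncol(cts)] > 0L)
    hold <- withr::with_seed(s, sample(finalSeqs,
                                       floor(0.2 * length(finalSeqs))))
    mseOf <- function(nLayers) {
      cfg <- spmConfig(nLayers = nLayers, maxEpochs = 150,
                       valFraction = 0, seed = s + 100)
      fit <- fitSPM(se, cfg, holdoutFinal = hold)
      pred <- predictCounts(fit, se)
      mean((pred[hold] - cts[hold, ncol(cts)])^2)
    }
    if (mseOf(4L) <= mseOf(0L)) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("bootstrap replicates preserve totals and are unbiased", {
  sch <- scheme2x2abc()
  land <- sampleLandscape(sch, seed = 20)
  se <- simulateSelection(land, nRounds = 2, depth = 3000, seed = 21)
  B <- 300
  boots <- bootstrapDatasets(se, B = B, seed = 22)
  tot <- roundTotals(se)
  for (b in boots[c(1, 100, B)])
    expect_identical(roundTotals(b), tot)
  # default replicate count follows the reference protocol
  expect_identical(eval(formals(bootstrapDatasets)$B), 1000L)
  # multinomial mean: the average resampled count approaches the original
  target <- rownames(se)[which.max(selectionCounts(se)[, "R2"])]
  draws <- vapply(boots, function(b)
    selectionCounts(b)[target, "R2"], 0L)
  k0 <- selectionCounts(se)[target, "R2"]
  se3 <- stats::sd(draws) / sqrt(B)
  expect_lt(abs(mean(draws) - k0), 3 * se3 + 1e-9)
})

test_that("models survive a serialization round-trip", {
  m <- fitSPM(twoSeqSE(), toyConfig(maxEpochs = 200, patience = 50))
  path <- withr::local_tempfile(fileext = ".json")
  saveFitnessModel(m, path)
  m2 <- readFitnessModel(path)
  seqs <- c("AA", "AB", "BA", "BB")
  expect_equal(scoreSequences(m2, seqs), scoreSequences(m, seqs),
               tolerance = 1e-12)
  expect_equal(scoreSequences(m2, seqs, "R1"),
               scoreSequences(m, seqs, "R1"), tolerance = 1e-12)
})
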