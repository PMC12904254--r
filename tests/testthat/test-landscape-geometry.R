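fourStateFitness <- function()
  lutFitness(c(AA = 3, AB = 0, BA = 1, BB = 2))

test_that("the 4-state toy yields depths 1 and 2", {
  fn <- fourStateFitness()
  ens <- simulateTrajectories(fn, schemeAB(), 2000, seed = 1)
  geo <- suppressWarnings(findWells(ens, fn, k = 20))
  geo <- wellDepth(geo, fn, schemeAB())
  w <- geo@wells
  expect_setequal(w$representative, c("AA", "BB"))
  expect_equal(w$depth[w$representative == "BB"], 1)  # BB->BA->AA
  expect_equal(w$depth[w$representative == "AA"], 2)  # AA->BA->BB
})

test_that("Dijkstra matches exhaustive path enumeration on 4 states", {
  fn <- fourStateFitness()
  E <- -fn(c("AA", "AB", "BA", "BB"))
  names(E) <- c("AA", "AB", "BA", "BB")
  nbr <- list(AA = c("AB", "BA"), AB = c("AA", "BB"),
              BA = c("AA", "BB"), BB = c("AB", "BA"))
  cost <- function(path) {
    sum(pmax(0, diff(E[path])))
  }
  # enumerate every simple path between AA and BB by DFS
  allPaths <- function(from, to) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == to) { out[[length(out) + 1L]] <<- path; return() }
      for (v in setdiff(nbr[[last]], path)) walk(c(path, v))
    }
    walk(from)
    out
  }
  bruteAAtoBB <- min(vapply(allPaths("AA", "BB"), cost, 0))
  bruteBBtoAA <- min(vapply(allPaths("BB", "AA"), cost, 0))
  ens <- simulateTrajectories(fn, schemeAB(), 500, seed = 2)
  geo <- wellDepth(suppressWarnings(findWells(ens, fn, 20)), fn,
                   schemeAB())
  expect_equal(geo@barriers["AA", "BB"], bruteAAtoBB)
  expect_equal(geo@barriers["BB", "AA"], bruteBBtoAA)
})

test_that("Dijkstra equals the relaxation oracle on larger spaces", {
  sch <- LibraryScheme(1, 2:3, alphabet = c("F", "L", "V", "M", "I"))
  land <- sampleLandscape(sch, seed = 3)   # 5^3 = 125 states
  fn <- function(s) scoreSequences(land, s)
  ens <- simulateTrajectories(land, sch, 4000, seed = 4)
  geo <- suppressWarnings(findWells(ens, fn, k = 4))
  geo <- wellDepth(geo, fn, sch)
  reps <- geo@wells$representative
  for (i in seq_along(reps)) {
    ora <- barrierOracle(fn, sch, reps[i], reps)
    expect_equal(unname(geo@barriers[i, ]), ora, tolerance = 1e-9)
  }
})

test_that("geometry is invariant to constant fitness shifts", {
  sch <- scheme2x2abc()
  land <- sampleLandscape(sch, seed = 5)
  fn <- function(s) scoreSequences(land, s)
  fnShift <- function(s) fn(s) + 42
  e1 <- simulateTrajectories(fn, sch, 3000, seed = 6)
  e2 <- simulateTrajectories(fnShift, sch, 3000, seed = 6)
  g1 <- wellDepth(suppressWarnings(findWells(e1, fn, 5)), fn, sch)
  g2 <- wellDepth(suppressWarnings(findWells(e2, fnShift, 5)), fnShift,
                  sch)
  expect_identical(g1@wells$representative, g2@wells$representative)
  expect_equal(g1@wells$relative_energy, g2@wells$relative_energy,
               tolerance = 1e-9)
  expect_equal(g1@wells$depth, g2@wells$depth, tolerance = 1e-9)
  expect_equal(g1@wells$accessibility, g2@wells$accessibility)
})

test_that("wells are ranked by accessibility with sane invariants", {
  sch <- scheme2x2abc()
  land <- sampleLandscape(sch, seed = 7)
  ens <- simulateTrajectories(land, sch, 5000, seed = 8)
  geo <- suppressWarnings(findWells(ens, land, k = 20))
  w <- geo@wells
  expect_true(all(diff(w$accessibility) <= 0))
  expect_equal(min(w$relative_energy), 0)
  expect_true(all(w$relative_energy >= 0))
  geo <- wellDepth(geo, land, sch)
  expect_true(all(geo@wells$depth >= 0))
  expect_true(all(diag(geo@barriers) == 0))
  # defaults follow the reference protocol
  expect_identical(eval(formals(findWells)$k), 20L)
})

test_that("a single-well landscape gets the +Inf depth sentinel", {
  sch <- schemeAB()
  land <- manualAdditiveLandscape(
    sch, matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE,
                dimnames = list(NULL, c("A", "B"))))
  ens <- simulateTrajectories(land, sch, 500, seed = 9)
  geo <- suppressWarnings(findWells(ens, land, k = 20))
  geo <- wellDepth(geo, land, sch)
  expect_identical(nrow(geo@wells), 1L)
  expect_identical(geo@wells$depth, Inf)
})

test_that("geometry comparison tests behave at the extremes", {
  set.seed(10)
  x <- data.frame(depth = rgamma(100, 5), accessibility = runif(100))
  pSame <- compareGeometries(x, x, factorDepth = 1, factorAccess = 1)
  expect_gt(pSame[["p_depth"]], 0.3)
  expect_lt(pSame[["p_depth"]], 0.7)
  y <- data.frame(depth = x$depth / 30, accessibility =
                    x$accessibility / 50)
  pSep <- compareGeometries(x, y)    # natural 10x above factor x synthetic
  expect_lt(pSep[["p_depth"]], 1e-6)
  expect_lt(pSep[["p_accessibility"]], 1e-6)
  expect_identical(eval(formals(compareGeometries)$factorDepth), 3)
  expect_identical(eval(formals(compareGeometries)$factorAccess), 5)
})

test_that("KD ratios convert to the printed energy gaps", {
  g1 <- energyGapFromKd(0.4e-6, 8.8e-6)
  g2 <- energyGapFromKd(2.4e-9, 6.7e-6)
  expect_equal(round(g1, 1), 1.8)
  expect_equal(round(g2, 1), 4.7)
  expect_equal(round(g2 / g1, 1), 2.6)
  expect_equal(energyGapFromKd(5e-6, 5e-6), 0)
  expect_error(energyGapFromKd(0, 1e-6), "positive")
})

test_that("the bootstrap geometry pipeline yields one row per replicate", {
  sch <- schemeABC()
  land <- sampleLandscape(sch, seed = 11)
  se <- simulateSelection(land, nRounds = 2, depth = 2000, seed = 12)
  stats <- bootstrapGeometry(se, B = 2, nTrajectories = 500, k = 3,
                             config = spmConfig(maxEpochs = 30,
                                                seed = 13),
                             seed = 14)
  expect_identical(nrow(stats), 2L)
  expect_true(all(stats$accessibility > 0 & stats$accessibility <= 1))
})
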