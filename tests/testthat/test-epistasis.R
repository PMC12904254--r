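xorFitness <- function(s)
  as.numeric(substr(s, 1, 1) == substr(s, 2, 2))

test_that("the 2x2 XOR toy decomposes exactly", {
  r <- decomposeFitness(xorFitness, schemeAB(), maxOrder = 2)
  eff <- epistasisEffects(r)
  expect_true(all(abs(eff$effect[eff$order == 1]) < 1e-12))
  pw <- eff[eff$order == 2, ]
  expect_equal(sort(pw$effect), c(-0.5, -0.5, 0.5, 0.5))
  terms <- epistasisTerms(r)
  expect_equal(terms$importance[terms$order == 2], 1.0)
  expect_identical(terms$chain_class[terms$order == 2], "inter")
})

test_that("a single-site indicator concentrates at its position", {
  sch <- scheme6mflv()
  ind <- function(s) as.numeric(substr(s, 3, 3) == "M")
  r <- decomposeFitness(ind, sch, maxOrder = 2)
  eff <- epistasisEffects(r)
  e3 <- eff[eff$term == "3", ]
  expect_equal(e3$effect[e3$config == "M"], 0.8, tolerance = 1e-12)
  expect_equal(unique(e3$effect[e3$config != "M"]), -0.2,
               tolerance = 1e-12)
  terms <- epistasisTerms(r)
  expect_equal(terms$importance[terms$term == "3"], 1.0)
  expect_true(all(terms$importance[terms$term != "3"] < 1e-12))
})

test_that("additive landscapes carry zero pairwise importance", {
  sch <- scheme2x2abc()
  land <- sampleLandscape(sch, pairwiseScale = 0, seed = 5)
  r <- decomposeFitness(land, sch, maxOrder = 2)
  terms <- epistasisTerms(r)
  expect_true(all(terms$importance[terms$order == 2] < 1e-9))
})

test_that("the decomposition matches an independent enumeration oracle", {
  sch <- scheme2x2abc()
  land <- sampleLandscape(sch, seed = 9)
  fn <- function(s) scoreSequences(land, s)
  r <- decomposeFitness(fn, sch, maxOrder = 2)
  ora <- anovaOracle(fn, sch, maxOrder = 2)
  expect_equal(r@intercept, ora$intercept, tolerance = 1e-9)
  eff <- epistasisEffects(r)
  ab <- schemeAlphabet(sch)
  for (i in 1:4) {
    mine <- eff[eff$term == as.character(i), ]
    expect_equal(mine$effect[match(ab, mine$config)],
                 unname(ora$main[[i]]), tolerance = 1e-9)
  }
  for (key in names(ora$pairs)) {
    mine <- eff[eff$term == key, ]
    got <- mine$effect[match(
      apply(expand.grid(ab, ab), 1, paste, collapse = ","),
      mine$config)]
    want <- as.vector(t(ora$pairs[[key]]))  # oracle is [a, b]
    # mine config order is (a,b) from expand.grid(a = ab, b = ab)
    want2 <- ora$pairs[[key]][cbind(
      match(sub(",.*", "", mine$config), ab),
      match(sub(".*,", "", mine$config), ab))]
    expect_equal(mine$effect, unname(want2), tolerance = 1e-9)
  }
})

test_that("effect sizes are zero-mean contrasts over each coordinate", {
  sch <- scheme2x2abc()
  land <- sampleLandscape(sch, seed = 13)
  r <- decomposeFitness(land, sch, maxOrder = 2)
  eff <- epistasisEffects(r)
  for (tm in unique(eff$term[eff$order == 1]))
    expect_equal(sum(eff$effect[eff$term == tm]), 0, tolerance = 1e-9)
  for (tm in unique(eff$term[eff$order == 2])) {
    sub <- eff[eff$term == tm, ]
    a <- sub("\\,.*", "", sub$config)
    for (letter in unique(a))
      expect_equal(sum(sub$effect[a == letter]), 0, tolerance = 1e-9)
  }
})

test_that("the full-order decomposition reconstructs fitness exactly", {
  sch <- LibraryScheme(1:2, 3, alphabet = c("A", "B", "C"))
  set.seed(31)
  uni <- enumerateSequences(sch)
  vals <- stats::setNames(rnorm(length(uni)), uni)
  r <- decomposeFitness(lutFitness(vals), sch, maxOrder = 3)
  probe <- sample(uni, 8)
  expect_equal(reconstructFitness(r, probe), unname(vals[probe]),
               tolerance = 1e-9)
})

test_that("importances are shift-invariant and scale-equivariant", {
  sch <- scheme2x2abc()
  land <- sampleLandscape(sch, seed = 17)
  fn <- function(s) scoreSequences(land, s)
  base <- epistasisTerms(decomposeFitness(fn, sch, maxOrder = 2))
  lin <- epistasisTerms(decomposeFitness(
    function(s) -2.5 * fn(s) + 7, sch, maxOrder = 2))
  expect_equal(lin$importance, 2.5 * base$importance, tolerance = 1e-9)
})

test_that("effectSizeAt looks up the variant configuration", {
  r <- decomposeFitness(xorFitness, schemeAB(), maxOrder = 2)
  expect_equal(effectSizeAt(r, c(1, 2), "AA"), 0.5)
  expect_equal(effectSizeAt(r, c(1, 2), "AB"), -0.5)
  expect_error(effectSizeAt(r, c(1, 3), "AA"), "not in the report")
  sch <- scheme2x2abc()
  add <- sampleLandscape(sch, pairwiseScale = 0, seed = 2)
  ra <- decomposeFitness(add, sch, maxOrder = 2)
  expect_equal(effectSizeAt(ra, c(1, 3), "ABCA"), 0, tolerance = 1e-9)
})

test_that("Monte-Carlo estimates converge to the exhaustive values", {
  sch <- scheme2x2abc()
  land <- sampleLandscape(sch, seed = 23)
  fn <- function(s) scoreSequences(land, s)
  exact <- epistasisTerms(decomposeFitness(fn, sch, maxOrder = 2))
  err <- function(n) {
    mc <- epistasisTerms(decomposeFitness(fn, sch, maxOrder = 2,
                                          exhaustiveLimit = 1,
                                          mcSamples = n, seed = 77))
    mean(abs(mc$importance - exact$importance))
  }
  eSmall <- err(2000); eBig <- err(50000)
  expect_lt(eBig, eSmall)
  expect_lt(eBig, 0.05)
})

test_that("REI is the mean-per-term inter/intra importance ratio", {
  # direct ratio on a report holding one inter and one intra pair term
  toy <- new("EpistasisReport", scheme = scheme2x2abc(), intercept = 0,
             effects = data.frame(),
             terms = data.frame(term = c("1,4", "1,2"), order = 2L,
                                chain_class = c("inter", "intra_A"),
                                importance = c(2, 1)),
             maxOrder = 2L, estimator = list(mode = "manual"))
  expect_equal(rei(toy, 2L), 2)

  # full decomposition: means run over every term of the order
  sch <- scheme2x2abc()
  fn <- function(s) {
    2 * (substr(s, 1, 1) == substr(s, 4, 4)) +
      1 * (substr(s, 1, 1) == substr(s, 2, 2))
  }
  r <- decomposeFitness(fn, sch, maxOrder = 2)
  terms <- epistasisTerms(r)
  expect_equal(terms$importance[terms$term == "1,4"], 2, tolerance = 1e-9)
  expect_equal(terms$importance[terms$term == "1,2"], 1, tolerance = 1e-9)
  # 4 inter pairs (one of importance 2), 2 intra pairs (one of 1)
  expect_equal(rei(r, 2L), (2 / 4) / (1 / 2), tolerance = 1e-9)

  # identical inter and intra structure on every pair: REI = 1
  eq <- function(i, j) function(s)
    as.numeric(substr(s, i, i) == substr(s, j, j))
  sym <- function(s) eq(1, 3)(s) + eq(1, 4)(s) + eq(2, 3)(s) +
    eq(2, 4)(s) + eq(1, 2)(s) + eq(3, 4)(s) / 2 + eq(3, 4)(s) / 2
  expect_equal(rei(decomposeFitness(sym, sch, maxOrder = 2), 2L), 1,
               tolerance = 1e-9)

  add <- sampleLandscape(sch, pairwiseScale = 0, seed = 3)
  expect_warning(v <- rei(decomposeFitness(add, sch, maxOrder = 2), 2L),
                 "undefined")
  expect_true(is.na(v))
})

test_that("external score tables decompose identically", {
  sch <- schemeABC()
  uni <- enumerateSequences(sch)
  set.seed(41)
  vals <- stats::setNames(rnorm(length(uni)), uni)
  direct <- decomposeFitness(lutFitness(vals), sch, maxOrder = 2)
  ext <- epistasisFromScores(
    data.frame(sequence = uni, score = unname(vals)), sch, maxOrder = 2)
  expect_equal(epistasisTerms(ext)$importance,
               epistasisTerms(direct)$importance, tolerance = 1e-12)
  shifted <- epistasisFromScores(
    data.frame(sequence = uni, score = unname(vals) + 11), sch, 2)
  expect_equal(epistasisTerms(shifted)$importance,
               epistasisTerms(direct)$importance, tolerance = 1e-9)
  expect_error(
    epistasisFromScores(data.frame(sequence = uni[-1],
                                   score = unname(vals)[-1]), sch, 2),
    "misses")
})
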