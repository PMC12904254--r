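makePairSE <- function(rows, scheme = schemeABC()) {
  cts <- matrix(rows$count, ncol = 1, dimnames = list(NULL, "R1"))
  SelectionExperiment(cts, chainA = rows$a, chainB = rows$b,
                      scheme = scheme)
}

test_that("hypergeometric p-values are exact", {
  # constructed marginals M=20, n=5, N=4, k=4 -> C(5,4)C(15,0)/C(20,4)
  rows <- data.frame(a = c("A", "A", "B"), b = c("A", "B", "C"),
                     count = c(4L, 1L, 15L))
  rec <- pairEnrichment(makePairSE(rows))
  r <- rec[rec$chain_a == "A" & rec$chain_b == "A", ]
  expect_identical(c(r$k, r$n, r$N, r$M), c(4L, 5L, 4L, 20L))
  expect_equal(r$p_value, 5 / 4845, tolerance = 1e-12)
  expect_equal(r$p_value, hyperSurvivalOracle(4, 5, 4, 20),
               tolerance = 1e-12)
})

test_that("p-values match the enumeration oracle over random tables", {
  set.seed(42)
  sch <- scheme2x2abc()
  uni <- enumerateSequences(sch)
  for (rep in 1:5) {
    cts <- matrix(rpois(40, 4), ncol = 1, dimnames = list(NULL, "R1"))
    seqs <- sample(uni, 40)
    se <- SelectionExperiment(cts, chainA = substr(seqs, 1, 2),
                              chainB = substr(seqs, 3, 4), scheme = sch)
    rec <- pairEnrichment(se)
    expect_gt(nrow(rec), 0)
    ora <- mapply(hyperSurvivalOracle, rec$k, rec$n, rec$N, rec$M)
    expect_equal(rec$p_value, unname(ora), tolerance = 1e-12)
  }
})

test_that("degenerate support gives p = 1", {
  rows <- data.frame(a = "A", b = "B", count = 7L)
  rec <- pairEnrichment(makePairSE(rows))   # n = N = M = k... p must be 1
  expect_equal(rec$p_value, 1)
})

test_that("the enrichment filter applies strict p and inclusive count", {
  rec <- data.frame(chain_a = "x", chain_b = "y", k = c(20L, 25L, 19L),
                    n = 1, N = 1, M = 1,
                    p_value = c(0.049, 0.05, 0.001))
  kept <- filterEnriched(rec)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$p_value, 0.049)   # p = 0.05 dropped, k = 19 dropped
})

test_that("loosening the filter never removes a retained record", {
  set.seed(1)
  rec <- data.frame(chain_a = "x", chain_b = "y",
                    k = sample(1:60, 50, TRUE), n = 1, N = 1, M = 1,
                    p_value = runif(50))
  tight <- filterEnriched(rec, pMax = 0.03, minCount = 30)
  loose <- filterEnriched(rec, pMax = 0.10, minCount = 10)
  expect_true(all(rownames(tight) %in% rownames(loose)))
})

test_that("enrichment reports both pair and sequence tallies", {
  rows <- data.frame(a = c("A", "A", "B"), b = c("A", "B", "A"),
                     count = c(3L, 2L, 4L))
  s <- attr(pairEnrichment(makePairSE(rows)), "summary")
  expect_identical(unname(s["n_pairs"]), 3L)
  expect_identical(unname(s["n_unique_sequences"]), 3L)
})

test_that("SSN edges follow the strict distance threshold", {
  seqs <- c("AAAA", "AABA", "ABBA", "BBBB")
  # d(1,2)=1, d(1,3)=2, d(1,4)=4, d(2,3)=1, d(2,4)=3, d(3,4)=2
  g <- buildSSN(seqs, threshold = 3)
  el <- apply(igraph::as_edgelist(g), 1, paste, collapse = "-")
  expect_setequal(el, c("AAAA-AABA", "AAAA-ABBA", "AABA-ABBA",
                        "ABBA-BBBB"))
  # threshold 3 means distance <= 2; distance-3 pair AABA-BBBB absent
  g2 <- buildSSN(seqs, threshold = 4)
  expect_identical(igraph::ecount(g2), 5)
  expect_error(buildSSN(c("AA", "AAA")), "equal length")
})

test_that("SSN is invariant under sequence reordering", {
  set.seed(8)
  sch <- scheme2x2abc()
  seqs <- sample(enumerateSequences(sch), 30)
  g1 <- buildSSN(seqs, 3)
  g2 <- buildSSN(rev(seqs), 3)
  key <- function(g) sort(apply(igraph::as_edgelist(g), 1, function(e)
    paste(sort(e), collapse = "-")))
  expect_identical(key(g1), key(g2))
})

test_that("hamming distance is symmetric and satisfies the triangle", {
  set.seed(3)
  sch <- scheme2x2abc()
  uni <- enumerateSequences(sch)
  for (i in 1:30) {
    tri <- sample(uni, 3)
    ab <- hammingDistance(tri[1], tri[2])
    ba <- hammingDistance(tri[2], tri[1])
    expect_identical(ab, ba)
    expect_lte(ab, hammingDistance(tri[1], tri[3]) +
                   hammingDistance(tri[3], tri[2]))
  }
})

test_that("communities: cliques, singletons, and the barbell", {
  # two disconnected triangles (cliques at distance >= threshold apart)
  seqs <- c("AAAA", "AAAB", "AABA", "CCCC", "CCCB", "CCBC")
  g <- buildSSN(seqs, threshold = 3)
  comm <- detectCommunities(g)
  expect_identical(length(unique(comm$membership)), 2L)
  expect_identical(sort(comm$sizes), c(3L, 3L))

  # a single clique: one community, a 1-node 0-edge community map
  g1 <- buildSSN(c("AAAA", "AAAB", "AABA"), threshold = 3)
  c1 <- detectCommunities(g1)
  expect_identical(length(unique(c1$membership)), 1L)
  expect_identical(igraph::vcount(c1$communityMap), 1)
  expect_identical(igraph::ecount(c1$communityMap), 0)

  # edgeless graph: all singleton communities
  g0 <- buildSSN(c("AAAA", "ABBB", "BABB", "BBAB"), threshold = 2)
  c0 <- detectCommunities(g0)
  expect_identical(length(unique(c0$membership)), 4L)

  # barbell: two 10-cliques joined by one edge -> the two cliques
  full <- igraph::make_full_graph(10)
  gb <- igraph::disjoint_union(full, full)
  gb <- igraph::add_edges(gb, c(1, 11))
  igraph::V(gb)$name <- paste0("n", 1:20)
  cb <- detectCommunities(gb)
  expect_identical(unname(length(unique(cb$membership))), 2L)
  expect_identical(length(unique(cb$membership[1:10])), 1L)
  expect_identical(length(unique(cb$membership[11:20])), 1L)
})

test_that("modularity partition matches the exhaustive 2-way oracle", {
  # barbell of two 5-cliques: enumerate all 2-partitions exhaustively
  full <- igraph::make_full_graph(5)
  g <- igraph::disjoint_union(full, full)
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- paste0("n", 1:10)
  best <- -Inf; bestPart <- NULL
  for (mask in 0:(2^9 - 1)) {   # fix node 1 in group 1 (symmetry)
    part <- c(1L, as.integer(intToBits(mask))[1:9] + 1L)
    m <- igraph::modularity(g, part)
    if (m > best) { best <- m; bestPart <- part }
  }
  comm <- detectCommunities(g)
  expect_identical(length(unique(comm$membership)), 2L)
  expect_equal(igraph::modularity(g, comm$membership), best,
               tolerance = 1e-12)
})

test_that("community map weights count inter-community edges", {
  full <- igraph::make_full_graph(4)
  g <- igraph::disjoint_union(full, full)
  g <- igraph::add_edges(g, c(1, 5, 2, 6))
  igraph::V(g)$name <- paste0("n", 1:8)
  comm <- detectCommunities(g)
  expect_identical(igraph::ecount(comm$communityMap), 1)
  expect_identical(igraph::E(comm$communityMap)$weight, 2L)
})

test_that("the pairing matrix cross-tabulates enriched pairs", {
  pairs <- data.frame(chain_a = c("a1", "a2", "a3", "a1", "a2"),
                      chain_b = c("b1", "b2", "b3", "b3", "b1"))
  clA <- c(a1 = "c1", a2 = "c2", a3 = "c3")
  clB <- c(b1 = "c1", b2 = "c2", b3 = "c3")
  m <- pairingMatrix(pairs, clA, clB)
  expect_identical(sum(m), 5L)
  expect_identical(sum(m[upper.tri(m) | lower.tri(m)]), 2L)
  expect_identical(unname(diag(m)), c(1L, 1L, 1L))

  within <- data.frame(chain_a = c("a1", "a1"), chain_b = c("b1", "b1"))
  mw <- pairingMatrix(within, clA, clB)
  expect_identical(unname(mw["c1", "c1"]), 2L)
  expect_true(all(mw[upper.tri(mw) | lower.tri(mw)] == 0L))

  empty <- pairingMatrix(pairs[0, ], clA, clB)
  expect_true(all(empty == 0L))
  expect_error(pairingMatrix(data.frame(chain_a = "zz", chain_b = "b1"),
                             clA, clB), "unlabeled")
})
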