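# Shared fixtures, built in code. Schemes use positions 1..p for brevity;
# "structures" are synthetic minimal PDBs written at test time.

schemeAB <- function() LibraryScheme(1, 2, alphabet = c("A", "B"))

schemeABC <- function() LibraryScheme(1, 2, alphabet = c("A", "B", "C"))

scheme2x2abc <- function()
  LibraryScheme(1:2, 3:4, alphabet = c("A", "B", "C"))

scheme6mflv <- function()
  LibraryScheme(1:3, 4:6, alphabet = c("F", "I", "L", "M", "V"))

zScheme <- function()
  LibraryScheme(c(8, 11, 14, 15, 45), c(29, 30, 33, 43, 44, 47),
                degenerateCodon = "DTS")

# lookup-table fitness over an explicitly named space
lutFitness <- function(values) function(s) unname(values[s])

# a TrueLandscape with hand-set additive effects (no pairwise terms)
manualAdditiveLandscape <- function(scheme, additive, intercept = 0) {
  new("TrueLandscape", scheme = scheme, intercept = intercept,
      additive = additive,
      pairwise = data.frame(pos_i = integer(), pos_j = integer(),
                            letter_i = character(),
                            letter_j = character(), value = numeric()),
      seed = 0L)
}

# hand-built trajectory ensemble for exclusivity/contribution hand counts
manualEnsemble <- function(scheme, pathList, fitness) {
  idxPaths <- lapply(pathList, function(p)
    coevoscape:::.seqToIndex(scheme, p))
  maxLen <- max(lengths(idxPaths))
  pm <- t(vapply(idxPaths, function(p)
    c(p, rep(NA_integer_, maxLen - length(p))), integer(maxLen)))
  term <- vapply(idxPaths, function(p) p[length(p)], 0L)
  n <- length(fitness)
  tc <- tabulate(term, n)
  vc <- integer(n)
  for (p in idxPaths) vc[unique(p)] <- vc[unique(p)] + 1L
  nz <- which(tc > 0L); vz <- which(vc > 0L)
  new("TrajectoryEnsemble", scheme = scheme,
      nTrajectories = length(pathList),
      terminalCounts = stats::setNames(tc[nz],
        coevoscape:::.indexToSeq(scheme, nz)),
      visitCounts = stats::setNames(vc[vz],
        coevoscape:::.indexToSeq(scheme, vz)),
      paths = pm, terminals = term, fitness = fitness, seed = 0L)
}

# synthetic toy complex: two chains of CA/CB pseudo-atoms on a grid, with
# planted cross-chain contacts. Returns the atom table.
toyComplexAtoms <- function() {
  # chain A residues 1-4 (library positions 2,3), chain B residues 1-4
  # (library positions 1,4). Atoms far apart by default (z = 0 vs 50).
  mk <- function(chain, resno, x, y, z)
    data.frame(chain = chain, resno = resno, resid = "ALA",
               elety = "CA", elesy = "C", x = x, y = y, z = z)
  rows <- list()
  for (r in 1:4) rows[[length(rows) + 1L]] <- mk("A", r, 10 * r, 0, 0)
  for (r in 1:4) rows[[length(rows) + 1L]] <- mk("B", r, 10 * r, 0, 50)
  do.call(rbind, rows)
}

# plant one cross-chain contact: append an extra atom of chain-B residue
# `resB` exactly `d` angstrom (in z) from the chain-A CA of `resA`. Each
# planted pair contributes exactly one atomic contact below 4 A because
# all other atoms sit >= 10 A apart.
plantContact <- function(atoms, resA, resB, d) {
  i <- which(atoms$chain == "A" & atoms$resno == resA)[1]
  extra <- data.frame(chain = "B", resno = resB, resid = "ALA",
                      elety = "CB", elesy = "C",
                      x = atoms$x[i], y = atoms$y[i], z = atoms$z[i] + d)
  rbind(atoms, extra)
}

# independent functional-ANOVA oracle: plain-loop conditional means over
# the fully enumerated space (no shared code with decomposeFitness)
anovaOracle <- function(fn, scheme, maxOrder = 2L) {
  ab <- schemeAlphabet(scheme)
  p <- totalPositions(scheme)
  grid <- do.call(expand.grid, c(rep(list(ab), p),
                                 stringsAsFactors = FALSE))
  seqs <- apply(grid, 1L, paste, collapse = "")
  F <- fn(seqs)
  b0 <- mean(F)
  main <- list()
  for (i in seq_len(p)) {
    m <- vapply(ab, function(a) mean(F[grid[[i]] == a]), 0)
    main[[i]] <- m - b0
  }
  pairs <- list()
  if (maxOrder >= 2L && p >= 2L) {
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
      M <- matrix(0, length(ab), length(ab), dimnames = list(ab, ab))
      for (a in ab) for (b in ab)
        M[a, b] <- mean(F[grid[[i]] == a & grid[[j]] == b]) -
          main[[i]][a] - main[[j]][b] - b0
      pairs[[paste(i, j, sep = ",")]] <- M
    }
  }
  list(intercept = b0, main = main, pairs = pairs)
}

# exact hypergeometric survival oracle by pmf enumeration
hyperSurvivalOracle <- function(k, n, N, M) {
  xs <- max(0, n + N - M):min(n, N)
  pmf <- choose(n, xs) * choose(M - n, N - xs) / choose(M, N)
  sum(pmf[xs >= k])
}

# independent minimal-cumulative-barrier oracle: Bellman-Ford style
# relaxation over the explicit move graph (edge list built by loops)
barrierOracle <- function(fn, scheme, from, to) {
  seqs <- enumerateSequences(scheme)
  E <- -fn(seqs)
  names(E) <- seqs
  chars <- strsplit(seqs, "")
  ab <- schemeAlphabet(scheme)
  nbrs <- lapply(chars, function(cs) {
    out <- character(0)
    for (i in seq_along(cs)) for (a in setdiff(ab, cs[i])) {
      v <- cs; v[i] <- a
      out <- c(out, paste(v, collapse = ""))
    }
    out
  })
  names(nbrs) <- seqs
  d <- stats::setNames(rep(Inf, length(seqs)), seqs)
  d[from] <- 0
  repeat {
    changed <- FALSE
    for (u in seqs) {
      if (!is.finite(d[u])) next
      for (v in nbrs[[u]]) {
        w <- d[u] + max(0, E[v] - E[u])
        if (w < d[v]) { d[v] <- w; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  unname(d[to])
}
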