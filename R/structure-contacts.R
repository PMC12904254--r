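#' Inter-chain heavy-atom contacts in a complex structure
#'
#' All pairs of heavy atoms across two chains with Euclidean distance
#' strictly below the cutoff. Hydrogens, waters, hetero atoms, models
#' beyond the first and alternate locations other than blank/"A" are
#' excluded.
#'
#' @param structure path to a PDB (\code{.pdb}) or mmCIF (\code{.cif})
#'   file, or a \code{bio3d} \code{pdb} object.
#' @param chainA,chainB chain identifiers.
#' @param cutoff distance bound in angstrom (default 4.0; the
#'   residue-level convention 3.8 is available by argument).
#' @return data.frame: \code{atom_a}, \code{atom_b}, \code{resno_a},
#'   \code{resno_b}, \code{resid_a}, \code{resid_b}, \code{distance}.
#' @export
interChainContacts <- function(structure, chainA, chainB, cutoff = 4.0) {
  pdb <- if (is.character(structure)) {
    if (grepl("\\.cif$", structure, ignore.case = TRUE))
      bio3d::read.cif(structure) else bio3d::read.pdb(structure)
  } else structure
  at <- pdb$atom
  keep <- at$type == "ATOM" &
    !(toupper(at$elesy %||% substr(trimws(at$elety), 1L, 1L)) %in% "H") &
    (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  for (ch in c(chainA, chainB))
    if (!ch %in% at$chain)
      stop(sprintf("chain '%s' not found; available: %s", ch,
                   paste(sort(unique(at$chain)), collapse = ", ")))
  a <- at[at$chain == chainA, , drop = FALSE]
  b <- at[at$chain == chainB, , drop = FALSE]
  ax <- as.matrix(a[, c("x", "y", "z")])
  bx <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * ax %*% t(bx)
  d2[d2 < 0] <- 0
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  data.frame(atom_a = a$elety[hit[, 1L]], atom_b = b$elety[hit[, 2L]],
             resno_a = a$resno[hit[, 1L]], resno_b = b$resno[hit[, 2L]],
             resid_a = a$resid[hit[, 1L]], resid_b = b$resid[hit[, 2L]],
             distance = sqrt(d2[hit]), row.names = NULL)
}

#' Classify inter-chain contacts by library/framework membership
#'
#' Labels each contact LL (both residues at randomized library
#' positions), LF_A (chain-A library against chain-B framework), LF_B
#' (chain-A framework against chain-B library) or FF, and computes the
#' contact ratio LL / (LF_A + LF_B) at atomic and residue level (a
#' residue pair is contacting when it has at least one atomic contact).
#'
#' @param contacts output of \code{\link{interChainContacts}} (chain A
#'   rows in \code{*_a} columns).
#' @param scheme the \linkS4class{LibraryScheme}; its per-chain positions
#'   must use the structure's residue numbering.
#' @return list with \code{contacts} (the input plus a \code{class}
#'   column), \code{counts} (LL, LF_A, LF_B, FF), \code{contactRatio},
#'   \code{residueCounts}, \code{residueContactRatio}; ratios are NA when
#'   the LF denominator is 0.
#' @export
classifyContacts <- function(contacts, scheme) {
  libA <- chainAPositions(scheme)
  libB <- chainBPositions(scheme)
  aLib <- contacts$resno_a %in% libA
  bLib <- contacts$resno_b %in% libB
  cls <- ifelse(aLib & bLib, "LL",
         ifelse(aLib & !bLib, "LF_A",
         ifelse(!aLib & bLib, "LF_B", "FF")))
  contacts$class <- cls
  lev <- c("LL", "LF_A", "LF_B", "FF")
  counts <- table(factor(cls, levels = lev))
  ratio <- function(ct) {
    den <- ct[["LF_A"]] + ct[["LF_B"]]
    if (den == 0L) NA_real_ else unname(ct[["LL"]] / den)
  }
  rpair <- !duplicated(contacts[, c("resno_a", "resno_b")])
  rcounts <- table(factor(cls[rpair], levels = lev))
  list(contacts = contacts,
       counts = stats::setNames(as.integer(counts), lev),
       contactRatio = ratio(counts),
       residueCounts = stats::setNames(as.integer(rcounts), lev),
       residueContactRatio = ratio(rcounts))
}

#' Write a minimal PDB file from an atom table
#'
#' Utility for exporting or constructing small (e.g. synthetic test)
#' structures: takes a data.frame with \code{chain}, \code{resno},
#' \code{resid}, \code{elety}, \code{elesy}, \code{x}, \code{y},
#' \code{z} and writes standard ATOM records.
#'
#' @param atoms atom table.
#' @param path output path.
#' @export
writeMinimalPDB <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, atoms$elety[i], atoms$resid[i], atoms$chain[i],
            atoms$resno[i], atoms$x[i], atoms$y[i], atoms$z[i],
            atoms$elesy[i])
  }, "")
  writeLines(c(lines, "END"), path)
  invisible(path)
}
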