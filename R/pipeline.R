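#' Pipeline configuration
#'
#' Bundles every stage parameter with the reference defaults (SSN
#' threshold 3; enrichment p < 0.05 and count >= 20; 20 wells; seed
#' thresholds 0.9 / 0.01 / 3 substitutions; contact cutoff 4.0 A) plus a
#' master seed from which every stochastic stage derives its own seed
#' deterministically.
#'
#' @param countsPath TSV count table (NULL to simulate instead).
#' @param schemePath scheme config file (required with countsPath).
#' @param scheme a \linkS4class{LibraryScheme} (alternative to
#'   schemePath; required when simulating).
#' @param simulate list of arguments for \code{\link{simulateSelection}}
#'   /\code{\link{sampleLandscape}} when no counts file is given.
#' @param ssnThreshold,pMax,minCount enrichment/SSN parameters.
#' @param spm an \code{\link{spmConfig}}.
#' @param maxOrder epistasis order.
#' @param nTrajectories,k trajectory/geometry parameters.
#' @param minExclusivity,minContribution,minDistance seed thresholds.
#' @param contactCutoff angstrom cutoff for structures.
#' @param structures optional named list: \code{path}, \code{chainA},
#'   \code{chainB} per structure.
#' @param masterSeed integer master seed.
#' @return a named list of class \code{"coevoPipelineConfig"}.
#' @export
pipelineConfig <- function(countsPath = NULL, schemePath = NULL,
                           scheme = NULL, simulate = list(),
                           ssnThreshold = 3L, pMax = 0.05,
                           minCount = 20L, spm = spmConfig(),
                           maxOrder = 2L, nTrajectories = 1e5, k = 20L,
                           minExclusivity = 0.9, minContribution = 0.01,
                           minDistance = 3L, contactCutoff = 4.0,
                           structures = NULL, masterSeed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- c("coevoPipelineConfig", "list")
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: load or simulate the selection dataset;
#' hypergeometric pair enrichment and SSN communities; SPM fit; epistasis
#' decomposition with REI; adaptive-walk simulation; well geometry and
#' depths; seed identification; optional structure-contact
#' classification. Every stage writes flat TSV/JSON into \code{outDir}
#' and a manifest records seeds and output hashes, so a rerun with the
#' same config is bit-identical.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory (created).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "coevoPipelineConfig"))
  if (!is.null(config$countsPath) && !file.exists(config$countsPath))
    stop("counts file not found: ", config$countsPath)
  if (!is.null(config$schemePath) && !file.exists(config$schemePath))
    stop("scheme file not found: ", config$schemePath)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ms <- config$masterSeed
  out <- list()

  ## stage: data
  scheme <- if (!is.null(config$schemePath)) readScheme(config$schemePath)
            else config$scheme
  if (is.null(scheme)) stop("a scheme (or schemePath) is required")
  if (!is.null(config$countsPath)) {
    se <- readCountsTSV(config$countsPath, scheme)
  } else {
    simArgs <- config$simulate
    land <- do.call(sampleLandscape, c(
      list(scheme = scheme),
      simArgs[intersect(names(simArgs),
                        names(formals(sampleLandscape))[-1])],
      list(seed = deriveSeed(ms, "landscape"))))
    se <- do.call(simulateSelection, c(
      list(landscape = land),
      simArgs[intersect(names(simArgs),
                        names(formals(simulateSelection))[-1])],
      list(seed = deriveSeed(ms, "selection"))))
    writeLandscapeTSV(land, file.path(outDir, "true_landscape.tsv"))
    out$landscape <- land
  }
  writeCountsTSV(se, file.path(outDir, "counts.tsv"))
  out$dataset <- se

  ## stage: enrichment + SSN
  enr <- pairEnrichment(se)
  enriched <- filterEnriched(enr, config$pMax, config$minCount)
  utils::write.table(
    cbind(enr, retained = enr$p_value < config$pMax &
            enr$k >= config$minCount),
    file.path(outDir, "enrichment.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  ssnSeqs <- if (nrow(enriched) > 0L)
    paste0(enriched$chain_a, enriched$chain_b) else character()
  if (length(ssnSeqs) > 1L) {
    ssn <- buildSSN(ssnSeqs, config$ssnThreshold)
    comm <- detectCommunities(ssn, seed = deriveSeed(ms, "communities"))
    writeSSN(ssn, comm, file.path(outDir, "ssn_edges.tsv"),
             file.path(outDir, "ssn_communities.tsv"))
    out$ssn <- ssn; out$communities <- comm
  }
  out$enrichment <- enr; out$enriched <- enriched

  ## stage: SPM
  cfg <- config$spm
  cfg$seed <- deriveSeed(ms, "spm")
  model <- fitSPM(se, cfg)
  saveFitnessModel(model, file.path(outDir, "spm_model.json"))
  scores <- data.frame(sequence = rownames(se),
                       fitness = scoreSequences(model, rownames(se)))
  utils::write.table(scores, file.path(outDir, "spm_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out$model <- model

  ## stage: epistasis
  rep2 <- decomposeFitness(model, scheme, maxOrder = config$maxOrder,
                           seed = deriveSeed(ms, "epistasis"))
  writeEpistasisTSV(rep2, file.path(outDir, "epistasis_terms.tsv"),
                    file.path(outDir, "epistasis_effects.tsv"))
  out$epistasis <- rep2
  out$rei <- tryCatch(rei(rep2, 2L), warning = function(w) NA_real_)

  ## stage: trajectories + geometry
  ens <- simulateTrajectories(model, scheme, config$nTrajectories,
                              seed = deriveSeed(ms, "walks"),
                              storePaths = TRUE)
  writeEnsembleTSV(ens, file.path(outDir, "trajectories.tsv"))
  geo <- suppressWarnings(findWells(ens, model, config$k))
  geo <- wellDepth(geo, model, scheme)
  writeGeometryTSV(geo, file.path(outDir, "wells.tsv"),
                   file.path(outDir, "barriers.tsv"))
  out$ensemble <- ens; out$geometry <- geo

  ## stage: seeds
  band <- fitnessBand(se, model)
  seeds <- findSeeds(ens, band, geo@wells$representative,
                     config$minExclusivity, config$minContribution,
                     config$minDistance)
  writeSeedsTSV(seeds, file.path(outDir, "seeds.tsv"))
  out$band <- band; out$seeds <- seeds

  ## stage: structures (optional)
  if (!is.null(config$structures)) {
    contactSummaries <- lapply(config$structures, function(s) {
      ct <- interChainContacts(s$path, s$chainA, s$chainB,
                               config$contactCutoff)
      classifyContacts(ct, scheme)
    })
    jsonlite::write_json(
      lapply(contactSummaries, function(cs)
        cs[c("counts", "contactRatio", "residueCounts",
             "residueContactRatio")]),
      file.path(outDir, "contacts.json"), auto_unbox = TRUE, digits = NA)
    out$contacts <- contactSummaries
  }

  ## manifest
  files <- list.files(outDir, full.names = TRUE)
  manifest <- list(
    package = as.character(utils::packageVersion("coevoscape")),
    masterSeed = ms,
    stageSeeds = list(landscape = deriveSeed(ms, "landscape"),
                      selection = deriveSeed(ms, "selection"),
                      communities = deriveSeed(ms, "communities"),
                      spm = deriveSeed(ms, "spm"),
                      epistasis = deriveSeed(ms, "epistasis"),
                      walks = deriveSeed(ms, "walks")),
    outputs = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}
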