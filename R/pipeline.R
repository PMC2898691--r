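# Pipeline orchestration: validated run configurations, the three
# commands (stats, simulate, abc) plus a scenario-recovery self-test,
# and provenance (config echo + package version + seeds) written into
# every output directory.  All randomness flows from config$seed.

#' Read and validate a run configuration
#'
#' Configurations are YAML mappings.  Common keys: \code{seed} (integer),
#' \code{out} (output directory), \code{force} (overwrite outputs).
#' Command-specific keys are validated by \code{\link{validateRunConfig}}.
#'
#' @param path YAML file path.
#' @return a named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .stopConfig("config file not found: ", path)
  yaml::read_yaml(path)
}

#' @rdname readRunConfig
#' @param config configuration list.
#' @param command one of \code{"stats"}, \code{"simulate"}, \code{"abc"},
#'   \code{"recover-test"}.
#' @export
validateRunConfig <- function(config, command) {
  if (!is.list(config)) .stopConfig("config must be a mapping")
  need <- switch(command,
    stats = c("fasta", "popmap", "out"),
    simulate = c("out"),
    abc = c("out"),
    "recover-test" = c("out"),
    .stopConfig("unknown command: ", command))
  missing <- setdiff(need, names(config))
  if (length(missing))
    .stopConfig("config for '", command, "' is missing keys: ",
                paste(missing, collapse = ", "))
  config$seed <- as.integer(config$seed %||% 1L)
  config$force <- isTRUE(config$force)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.prepareOutDir <- function(config, command) {
  out <- config$out
  marker <- file.path(out, "config-echo.yaml")
  if (dir.exists(out) && file.exists(marker) && !config$force)
    .stopConfig("output directory ", out,
                " already holds results; use force to overwrite")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  echo <- config
  echo$command <- command
  echo$packageVersion <- as.character(utils::packageVersion("stsDemog"))
  yaml::write_yaml(echo, marker)
  out
}

.loadPanelData <- function(config) {
  files <- config$fasta
  if (length(files) == 1L && dir.exists(files))
    files <- list.files(files, pattern = "\\.(fa|fasta|fas)$",
                        full.names = TRUE)
  if (length(files) == 0L) .stopData("no FASTA inputs found")
  alns <- lapply(sort(files), readSTSFasta)
  if (!is.null(config$siteClasses)) {
    cls <- readSiteClasses(config$siteClasses)
    alns <- lapply(alns, applySiteClasses, classes = cls)
  }
  panel <- readPopulationPanel(config$popmap)
  list(alignments = alns, panel = panel)
}

.checkLabels <- function(labels, panel) {
  known <- unique(unname(panel@labels))
  bad <- setdiff(labels, known)
  if (length(bad))
    .stopConfig("unknown population label: ", paste(bad, collapse = ", "),
                " (panel has: ", paste(known, collapse = ", "), ")")
}

#' Diversity / differentiation report command
#'
#' Reads a panel (per-locus FASTA + population map, optional site
#' classes), builds the SNP matrix and writes per-locus + mean diversity
#' tables (TSV), the weed/progenitor F_st summary, site partition and
#' ABC summary vector (JSON).
#'
#' @param config list with keys \code{fasta} (dir or file vector),
#'   \code{popmap}, \code{out}; optional \code{siteClasses},
#'   \code{weed}, \code{progenitor}, \code{populations},
#'   \code{siteClassSet} ("all" or "silent"), \code{targetedGroups},
#'   \code{force}, \code{seed}.
#' @return invisibly, a list with the computed tables.
#' @export
cmdStats <- function(config) {
  config <- validateRunConfig(config, "stats")
  dat <- .loadPanelData(config)
  panel <- dat$panel
  pops <- config$populations %||% unique(unname(panel@labels))
  .checkLabels(pops, panel)
  targeted <- config$targetedGroups %||% pops
  .checkLabels(targeted, panel)
  snp <- buildSNPMatrix(dat$alignments, panel, targeted)
  classes <- if (identical(config$siteClassSet, "silent"))
    c("silent", "synonymous", "noncoding") else
    c("all", "silent", "synonymous", "nonsynonymous")
  out <- .prepareOutDir(config, "stats")
  div <- diversitySummary(snp, pops, classes)
  utils::write.table(div, file.path(out, "diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  result <- list(diversity = div)
  if (!is.null(config$weed) && !is.null(config$progenitor)) {
    .checkLabels(c(config$weed, config$progenitor), panel)
    fst <- weirCockerhamFst(snp, config$weed, config$progenitor)
    part <- sitePartition(snp, config$weed, config$progenitor)
    sv <- abcSummaryVector(snp, config$weed, config$progenitor)
    utils::write.table(
      data.frame(locus = names(fst$perLocus), fst = fst$perLocus),
      file.path(out, "fst-per-locus.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(
      list(fstGrandMean = fst$grandMean, fstMedian = fst$median,
           sitePartition = part[c("shared", "private1", "private2",
                                  "fixed", "total")],
           summaryVector = as.list(sv)),
      file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    result$fst <- fst
    result$partition <- part
    result$summaryVector <- sv
  }
  invisible(result)
}

.modelFromConfig <- function(config, scaling) {
  if (!is.null(config$preset)) {
    presets <- datasetPresets()
    if (!config$preset %in% names(presets))
      .stopConfig("unknown preset '", config$preset, "'; available: ",
                  paste(names(presets), collapse = ", "))
    presets[[config$preset]](scaling)
  } else if (!is.null(config$model)) {
    m <- config$model
    DemographicModel(etaC = m$etaC, etaB = m$etaB, etaR = m$etaR,
                     tauS = m$tauS, tauF = m$tauF, tauG = m$tauG,
                     weedSelfing = m$weedSelfing %||% TRUE)
  } else {
    .stopConfig("simulate needs either a preset or an explicit model")
  }
}

.scalingFromConfig <- function(config) {
  s <- config$scaling %||% list()
  ScalingConfig(mu = s$mu %||% 1e-8,
                generationTime = s$generationTime %||% 1,
                nRef = s$nRef,
                rhoOverTheta = s$rhoOverTheta %||% 1,
                referenceThetaPerKb = s$referenceThetaPerKb %||% 7.787)
}

.coalConfigFromConfig <- function(config) {
  cc <- config$sampling %||% list()
  CoalescentConfig(nWeed = cc$nWeed %||% 24,
                   nProgenitor = cc$nProgenitor %||% 22,
                   nLoci = cc$nLoci %||% 48,
                   lengthBp = cc$lengthBp %||% 500,
                   weedLabel = cc$weedLabel %||% "weed",
                   progenitorLabel = cc$progenitorLabel %||% "progenitor")
}

#' Dataset simulation command
#'
#' Simulates a dataset under a preset or explicit model and writes it to
#' the output directory (FASTA per locus, population map, truth JSON and
#' a manifest with all seeds).
#'
#' @param config list with keys \code{out} and either \code{preset} or
#'   \code{model}; optional \code{scaling}, \code{sampling},
#'   \code{seed}, \code{force}.
#' @return invisibly, the \code{\link{makePseudoObserved}} result.
#' @export
cmdSimulate <- function(config) {
  config <- validateRunConfig(config, "simulate")
  scaling <- .scalingFromConfig(config)
  model <- .modelFromConfig(config, scaling)
  coal <- .coalConfigFromConfig(config)
  out <- .prepareOutDir(config, "simulate")
  res <- makePseudoObserved(model = model, scaling = scaling,
                            config = coal, seed = config$seed,
                            preset = config$preset %||% NA_character_,
                            dir = out)
  invisible(res)
}

#' Rejection-ABC command
#'
#' Computes the observed summary vector (from an on-disk dataset
#' directory with FASTA + popmap, or a pseudo-observed preset simulated
#' on the fly), runs rejection ABC over the configured scenarios, and
#' writes the per-scenario approximate-likelihood table (TSV row shaped
#' like the usual divergence-scenario reports), accepted draws (TSV),
#' the result summary (JSON) and optional marginal/contour plots (PDF).
#'
#' @param config list with keys \code{out} and either \code{data} (a
#'   directory with FASTA + popmap.tsv and weed/progenitor labels) or
#'   \code{preset}; optional \code{scenarios}, \code{sims},
#'   \code{tolerance}, \code{plots}, \code{scaling}, \code{sampling},
#'   \code{seed}, \code{force}.
#' @return invisibly, the \code{\link{ABCResult}}.
#' @export
cmdAbc <- function(config) {
  config <- validateRunConfig(config, "abc")
  scaling <- .scalingFromConfig(config)
  coal <- .coalConfigFromConfig(config)
  if (!is.null(config$data)) {
    dat <- .loadPanelData(list(
      fasta = config$data,
      popmap = config$popmap %||% file.path(config$data, "popmap.tsv"),
      siteClasses = config$siteClasses))
    weed <- config$weed %||% coal@weedLabel
    prog <- config$progenitor %||% coal@progenitorLabel
    .checkLabels(c(weed, prog), dat$panel)
    snp <- buildSNPMatrix(dat$alignments, dat$panel, c(weed, prog))
    observed <- abcSummaryVector(snp, weed, prog)
    coal <- CoalescentConfig(
      nWeed = sum(unname(dat$panel@labels) == weed),
      nProgenitor = sum(unname(dat$panel@labels) == prog),
      loci = data.frame(
        locusId = vapply(dat$alignments, locusId, ""),
        lengthBp = vapply(dat$alignments, lengthBp, integer(1))),
      weedLabel = weed, progenitorLabel = prog)
  } else if (!is.null(config$preset)) {
    po <- makePseudoObserved(scaling = scaling, config = coal,
                             seed = deriveSeed(config$seed, 1L),
                             preset = config$preset)
    observed <- abcSummaryVector(asSNPMatrix(po$dataset),
                                 coal@weedLabel, coal@progenitorLabel)
  } else {
    .stopConfig("abc needs either a data directory or a preset")
  }
  scenarios <- config$scenarios %||% .SCENARIOS
  result <- runABC(observed, scenarios,
                   simsPerScenario = config$sims %||% 1000,
                   tolerance = config$tolerance %||% 1,
                   scaling = scaling, config = coal,
                   seed = config$seed)
  out <- .prepareOutDir(config, "abc")
  ll <- approximateLikelihood(result)
  utils::write.table(as.data.frame(as.list(ll)),
                     file.path(out, "likelihoods.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  draws <- acceptedDraws(result)
  if (!is.null(draws) && nrow(draws))
    utils::write.table(draws, file.path(out, "accepted-draws.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(observed = as.list(result@observed), tolerance = result@tolerance,
         scales = as.list(result@scales), likelihoods = as.list(ll)),
    file.path(out, "abc-result.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  if (isTRUE(config$plots) && sum(vapply(result@scenarios,
                                         `[[`, 0, "nAccepted")) > 0) {
    grDevices::pdf(file.path(out, "abc-plots.pdf"), width = 7, height = 5)
    for (p in c("tauG", "tauF", "etaRRatio"))
      plotPosterior(posteriorDensity(result, p), main = p, xlab = p)
    plotSurface(likelihoodSurface(result))
    grDevices::dev.off()
  }
  if (all(ll == 0))
    warning("zero acceptances in every scenario; ",
            "likelihood table is all zeros")
  invisible(result)
}

#' Scenario-recovery self-test command
#'
#' Simulates pseudo-observed datasets under a named preset and checks
#' how often rejection ABC assigns the generating scenario the highest
#' approximate likelihood.  Writes a small JSON report.
#'
#' @param config list with keys \code{out}; optional \code{preset},
#'   \code{replicates}, \code{sims}, \code{tolerance}, \code{scenarios},
#'   \code{seed}, \code{force}.
#' @return invisibly, list with the per-replicate winners and the
#'   recovery rate.
#' @export
cmdRecoverTest <- function(config) {
  config <- validateRunConfig(config, "recover-test")
  preset <- config$preset %||% "SH-shaped"
  truthScenario <- switch(preset, "SH-shaped" = "founding_us",
                          "BHA1-shaped" = "post_domestication",
                          .stopConfig("unknown preset: ", preset))
  scenarios <- config$scenarios %||% .SCENARIOS
  scaling <- .scalingFromConfig(config)
  coal <- .coalConfigFromConfig(config)
  nrep <- config$replicates %||% 5
  sims <- config$sims %||% 1000
  refTables <- lapply(scenarios, function(s)
    scenarioReferenceTable(s, sims, scaling, coal, config$seed))
  winners <- character(nrep)
  for (r in seq_len(nrep)) {
    po <- makePseudoObserved(scaling = scaling, config = coal,
                             seed = deriveSeed(config$seed, 100L + r),
                             preset = preset)
    obs <- abcSummaryVector(asSNPMatrix(po$dataset), coal@weedLabel,
                            coal@progenitorLabel)
    res <- runABC(obs, scenarios, tolerance = config$tolerance %||% 1,
                  scaling = scaling, config = coal, seed = config$seed,
                  refTables = refTables)
    ll <- approximateLikelihood(res)
    winners[r] <- names(ll)[which.max(ll)]
  }
  out <- .prepareOutDir(config, "recover-test")
  report <- list(preset = preset, truthScenario = truthScenario,
                 winners = winners,
                 recoveryRate = mean(winners == truthScenario))
  jsonlite::write_json(report, file.path(out, "recover-test.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
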