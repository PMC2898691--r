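# Rejection-ABC over divergence-timing scenarios.  A scenario fixes the
# rule for the split time tauS; the remaining parameters share common
# priors.  Timing parameters and the progenitor size ratio are drawn from
# a discrete grid (cycled evenly), the two weed size ratios from
# continuous uniforms.  Acceptance uses Euclidean distance on summary
# statistics standardised by a robust scale (MAD) computed from a pilot
# pool spanning all scenarios, so acceptance proportions are comparable
# across scenarios and their ratios carry the model comparison.

.SCENARIOS <- c("founding_us", "post_domestication", "domestication",
                "pre_domestication")

#' ScenarioSpec: a divergence-timing hypothesis
#'
#' The four scenarios differ only in the rule for the split time
#' \code{tauS}: \describe{
#'   \item{founding_us}{divergence at introduction: \code{tauS = tauF}.}
#'   \item{post_domestication}{divergence after domestication but before
#'     introduction: \code{tauF < tauS <= domesticationTime}.}
#'   \item{domestication}{divergence at domestication:
#'     \code{tauS = domesticationTime}.}
#'   \item{pre_domestication}{divergence before domestication:
#'     \code{domesticationTime <= tauS <= tauSMax}.}
#' }
#' Shared priors: \code{tauG} in (0, tauGMax], \code{tauF} in
#' (tauG, tauFMax], progenitor relative size \code{etaC/N_ref} in
#' \code{etaCRange}, and the size ratios \code{etaR/etaC} and
#' \code{etaB/etaR} uniform on (0, 1].
#'
#' @slot name scenario name.
#' @slot tauGMax upper limit (years) for the expansion time; default 140,
#'   matching the onset of rapid expansion of cultivation around 1870
#'   relative to a circa-2010 sampling date.
#' @slot tauFMax upper limit for the founding time (default 400 years,
#'   the introduction of cultivation to the new range).
#' @slot etaCRange range of the progenitor size as a fraction of the
#'   reference size (default 0.1-0.7, bracketing observed crop-to-wild
#'   diversity ratios).
#' @slot domesticationTime years before present (default 12,000).
#' @slot tauSMax oldest split considered (default 50,000).
#' @export
setClass("ScenarioSpec",
  representation(name = "character", tauGMax = "numeric",
                 tauFMax = "numeric", etaCRange = "numeric",
                 domesticationTime = "numeric", tauSMax = "numeric"))

setValidity("ScenarioSpec", function(object) {
  if (!object@name %in% .SCENARIOS)
    return(paste("unknown scenario; must be one of:",
                 paste(.SCENARIOS, collapse = ", ")))
  if (object@tauGMax <= 0 || object@tauFMax <= object@tauGMax)
    return("need 0 < tauGMax < tauFMax")
  if (length(object@etaCRange) != 2L || diff(object@etaCRange) <= 0 ||
      object@etaCRange[1] <= 0)
    return("etaCRange must be an increasing positive pair")
  if (object@tauSMax <= object@domesticationTime)
    return("tauSMax must exceed domesticationTime")
  TRUE
})

#' Construct a ScenarioSpec
#'
#' @param name one of \code{"founding_us"}, \code{"post_domestication"},
#'   \code{"domestication"}, \code{"pre_domestication"}.
#' @param tauGMax,tauFMax,etaCRange,domesticationTime,tauSMax prior
#'   settings; see \linkS4class{ScenarioSpec}.
#' @return a \code{ScenarioSpec}.
#' @examples
#' scenarioSpec("founding_us")
#' @export
scenarioSpec <- function(name, tauGMax = 140, tauFMax = 400,
                         etaCRange = c(0.1, 0.7),
                         domesticationTime = 12000, tauSMax = 50000) {
  new("ScenarioSpec", name = name, tauGMax = tauGMax, tauFMax = tauFMax,
      etaCRange = etaCRange, domesticationTime = domesticationTime,
      tauSMax = tauSMax)
}

setMethod("show", "ScenarioSpec", function(object) {
  cat("ScenarioSpec:", object@name, "\n")
  cat(sprintf("  tauG in (0, %g], tauF in (tauG, %g], etaC/Nref in [%g, %g]\n",
              object@tauGMax, object@tauFMax, object@etaCRange[1],
              object@etaCRange[2]))
  cat("  tauS rule:",
      switch(object@name,
             founding_us = "tauS = tauF",
             post_domestication = sprintf("tauF < tauS <= %g",
                                          object@domesticationTime),
             domestication = sprintf("tauS = %g", object@domesticationTime),
             pre_domestication = sprintf("%g <= tauS <= %g",
                                         object@domesticationTime,
                                         object@tauSMax)), "\n")
})

# -- prior grid ---------------------------------------------------------------

#' PriorGrid: discretised priors for one scenario
#'
#' Grid points cover the closed upper endpoints of the half-open timing
#' priors and both endpoints of closed ranges; tuples violating the time
#' ordering (\code{tauF <= tauG}, \code{tauS < tauF}) are excluded and
#' counted.
#'
#' @slot scenario the \code{\link{scenarioSpec}} used.
#' @slot cells data.frame of valid grid cells (tauG, tauF, tauS, etaC).
#' @slot nExcluded number of invalid tuples removed.
#' @slot resolution per-parameter grid sizes.
#' @export
setClass("PriorGrid",
  representation(scenario = "ScenarioSpec", cells = "data.frame",
                 nExcluded = "integer", resolution = "integer"))

setMethod("show", "PriorGrid", function(object) {
  cat("PriorGrid:", object@scenario@name, "-", nrow(object@cells),
      "valid cells (", object@nExcluded, "invalid tuples excluded)\n")
})

#' Build the prior grid for a scenario
#'
#' @param spec a \code{\link{scenarioSpec}}.
#' @param resolution named integer vector: grid sizes for \code{tauG},
#'   \code{tauF}, \code{tauS} and \code{etaC} (each >= 2 where the
#'   parameter is gridded; fixed-rule parameters ignore it).
#' @return a \code{PriorGrid}.
#' @export
buildPriorGrid <- function(spec, resolution = c(tauG = 7, tauF = 7,
                                                tauS = 7, etaC = 7)) {
  stopifnot(is(spec, "ScenarioSpec"))
  res <- resolution
  gridded <- c("tauG", "tauF", "etaC",
               if (spec@name %in% c("post_domestication",
                                    "pre_domestication")) "tauS")
  if (any(res[gridded] < 2))
    .stopConfig("grid resolution must be >= 2 for gridded parameters")
  tauG <- seq(spec@tauGMax / res["tauG"], spec@tauGMax,
              length.out = res["tauG"])
  tauF <- seq(spec@tauFMax / res["tauF"], spec@tauFMax,
              length.out = res["tauF"])
  etaC <- seq(spec@etaCRange[1], spec@etaCRange[2],
              length.out = res["etaC"])
  tauS <- switch(spec@name,
    founding_us = NA_real_,
    post_domestication = seq(spec@domesticationTime / res["tauS"],
                             spec@domesticationTime,
                             length.out = res["tauS"]),
    domestication = spec@domesticationTime,
    pre_domestication = seq(spec@domesticationTime, spec@tauSMax,
                            length.out = res["tauS"]))
  cells <- expand.grid(tauG = tauG, tauF = tauF, tauS = tauS, etaC = etaC,
                       KEEP.OUT.ATTRS = FALSE)
  if (spec@name == "founding_us") cells$tauS <- cells$tauF
  nAll <- nrow(cells)
  ok <- cells$tauF > cells$tauG & cells$tauS >= cells$tauF
  cells <- cells[ok, , drop = FALSE]
  rownames(cells) <- NULL
  if (nrow(cells) == 0L) .stopConfig("scenario prior ranges admit no cells")
  new("PriorGrid", scenario = spec, cells = cells,
      nExcluded = as.integer(nAll - nrow(cells)),
      resolution = as.integer(res[c("tauG", "tauF", "tauS", "etaC")]))
}

#' Draw parameter sets from a prior grid
#'
#' Grid cells are cycled evenly (draws-per-cell as equal as possible);
#' the size ratios \code{etaR/etaC} and \code{etaB/etaR} are drawn
#' uniform on (0, 1].
#'
#' @param grid a \code{\link{buildPriorGrid}} result.
#' @param n number of draws.
#' @param seed integer seed.
#' @return data.frame with columns tauG, tauF, tauS, etaC, etaRRatio,
#'   etaBRatio.
#' @export
drawParameters <- function(grid, n, seed = 1L) {
  stopifnot(is(grid, "PriorGrid"), n >= 1)
  idx <- rep(seq_len(nrow(grid@cells)), length.out = n)
  out <- grid@cells[idx, , drop = FALSE]
  rownames(out) <- NULL
  withSeed(seed, {
    out$etaRRatio <- 1 - runif(n)   # uniform on (0, 1]
    out$etaBRatio <- 1 - runif(n)
  })
  out
}

# one parameter-set row -> DemographicModel (sizes floored at 1 individual)
.paramsToModel <- function(p, nRef, weedSelfing = TRUE) {
  etaC <- max(1, p$etaC * nRef)
  etaR <- max(1, p$etaRRatio * etaC)
  etaB <- max(1, p$etaBRatio * etaR)
  DemographicModel(etaC = etaC, etaB = etaB, etaR = etaR, tauS = p$tauS,
                   tauF = p$tauF, tauG = p$tauG,
                   weedSelfing = weedSelfing)
}

# -- reference tables ---------------------------------------------------------

#' Simulate a reference table for one scenario
#'
#' Draws \code{nSims} parameter sets from the scenario's priors and
#' simulates the eight-statistic summary vector for each, using the fast
#' compiled path.  Reference tables can be reused across observed
#' datasets (standard practice for rejection ABC with a common prior).
#'
#' @param spec a \code{\link{scenarioSpec}} (or scenario name).
#' @param nSims number of simulations.
#' @param scaling a \code{\link{ScalingConfig}}.
#' @param config a \code{\link{CoalescentConfig}}.
#' @param seed integer seed; the table is reproducible from
#'   (spec, nSims, seed) regardless of other scenarios run.
#' @param resolution grid resolution passed to
#'   \code{\link{buildPriorGrid}}.
#' @param weedSelfing halve weed-lineage sizes?
#' @return list with \code{scenario}, \code{params} (data.frame) and
#'   \code{stats} (nSims x 8 matrix).
#' @export
scenarioReferenceTable <- function(spec, nSims, scaling = ScalingConfig(),
                                   config = CoalescentConfig(), seed = 1L,
                                   resolution = c(tauG = 7, tauF = 7,
                                                  tauS = 7, etaC = 7),
                                   weedSelfing = TRUE) {
  if (is.character(spec)) spec <- scenarioSpec(spec)
  grid <- buildPriorGrid(spec, resolution)
  scSeed <- deriveSeed(seed, match(spec@name, .SCENARIOS))
  params <- drawParameters(grid, nSims, seed = scSeed)
  lengths <- as.numeric(config@loci$lengthBp)
  stats <- matrix(NA_real_, nSims, 8L)
  simSeeds <- withSeed(deriveSeed(scSeed, 2L),
                       sample.int(2147483646L, nSims, replace = TRUE))
  # inlined, vectorised equivalent of .paramsToModel + toCoalescentUnits
  # (kept in exact agreement by a regression test); sizes floored at one
  # individual, weed-lineage sizes halved under selfing
  nRef <- scaling@nRef
  half <- if (weedSelfing) 0.5 else 1
  thetaPerSite <- 4 * nRef * scaling@mu
  fourN <- 4 * nRef * scaling@generationTime
  etaC <- pmax(1, params$etaC * nRef)
  etaR <- pmax(1, params$etaRRatio * etaC)
  etaB <- pmax(1, params$etaBRatio * etaR)
  xC <- etaC / nRef
  xR <- etaR / nRef * half
  xB <- etaB / nRef * half
  xP <- etaC / nRef * half
  nW <- config@nWeed
  nP <- config@nProgenitor
  for (i in seq_len(nSims)) {
    collapse <- params$tauS[i] <= params$tauF[i]
    evTime <- c(params$tauG[i], if (!collapse) params$tauF[i],
                params$tauS[i]) / fourN
    evType <- c(0L, if (!collapse) 0L, 1L)
    evPop <- c(0L, if (!collapse) 0L, 0L)
    evParam <- c(xB[i], if (!collapse) xP[i], 1)
    stats[i, ] <- .simSummaryCpp(nW, nP, lengths, thetaPerSite,
                                 scaling@rhoOverTheta,
                                 c(xR[i], xC[i]), evTime, evType, evPop,
                                 evParam, as.numeric(simSeeds[i]))
  }
  colnames(stats) <- c("pooledPi", "sWeed", "sProgenitor", "fixed",
                       "privateWeed", "privateProgenitor", "shared",
                       "sUnion")
  list(scenario = spec@name, params = params, stats = stats)
}

#' Rejection step on a precomputed statistic table
#'
#' @param observed numeric vector of observed statistics.
#' @param stats matrix of simulated statistics (rows = simulations).
#' @param tolerance absolute acceptance radius in standardised units.
#' @param scales per-statistic scales used for standardisation.
#' @return list with \code{distance} and logical \code{accepted}.
#' @export
abcReject <- function(observed, stats, tolerance, scales) {
  stopifnot(length(observed) == ncol(stats),
            length(scales) == ncol(stats))
  z <- sweep(stats, 2L, observed, "-")
  z <- sweep(z, 2L, scales, "/")
  d <- sqrt(rowSums(z^2))
  list(distance = d, accepted = d <= tolerance)
}

# robust per-statistic scales from a pooled pilot of simulated statistics;
# the MAD collapses to zero for count statistics that are mostly zero, in
# which case the standard deviation (then 1) is the fallback
.pilotScales <- function(pooled) {
  sc <- apply(pooled, 2L, stats::mad)
  fb <- apply(pooled, 2L, stats::sd)
  use <- !is.finite(sc) | sc == 0
  sc[use] <- fb[use]
  zero <- !is.finite(sc) | sc == 0
  if (any(zero)) {
    warning("zero pilot variance for: ",
            paste(colnames(pooled)[zero], collapse = ", "),
            "; standardised by 1")
    sc[zero] <- 1
  }
  sc
}

# -- ABCResult ----------------------------------------------------------------

#' ABCResult: outcome of a rejection-ABC run
#'
#' @slot observed the observed summary vector.
#' @slot scales per-statistic standardisation constants (pilot MAD).
#' @slot tolerance absolute standardised acceptance radius.
#' @slot scenarios named list; per scenario: \code{params} (draws with
#'   \code{distance} and \code{accepted} columns), \code{nSims},
#'   \code{nAccepted}.
#' @slot seed master seed.
#' @param result an \code{ABCResult}.
#' @param scenario scenario name, or NULL for all.
#' @aliases approximateLikelihood acceptedDraws
#' @export
setClass("ABCResult",
  representation(observed = "numeric", scales = "numeric",
                 tolerance = "numeric", scenarios = "list",
                 seed = "numeric"))

setMethod("show", "ABCResult", function(object) {
  cat("ABCResult: tolerance", object@tolerance, "(standardised units)\n")
  ll <- approximateLikelihood(object)
  for (nm in names(ll)) {
    sc <- object@scenarios[[nm]]
    cat(sprintf("  %-20s %d / %d accepted  ~L = %.4g\n", nm,
                sc$nAccepted, sc$nSims, ll[[nm]]))
  }
})

#' Run rejection ABC over divergence scenarios
#'
#' For each scenario, parameters are drawn from its prior grid, datasets
#' simulated and summarised by the eight pooled statistics, and draws
#' accepted when the standardised Euclidean distance to the observed
#' vector is at most \code{tolerance}.  Standardisation constants are
#' robust scales (MAD) computed once from the pooled simulations of all
#' scenarios, so acceptance proportions are directly comparable across
#' scenarios; the per-scenario acceptance proportion is the approximate
#' likelihood.
#'
#' @param observed observed summary vector
#'   (\code{\link{abcSummaryVector}} order).
#' @param scenarios list of \code{\link{scenarioSpec}} objects or
#'   scenario names.
#' @param simsPerScenario simulations per scenario.
#' @param tolerance absolute standardised acceptance radius; \code{Inf}
#'   accepts everything.
#' @param scaling,config,resolution,weedSelfing simulation settings, as in
#'   \code{\link{scenarioReferenceTable}}.
#' @param seed master seed; results are bit-identical given the same
#'   seed and configuration, and per-scenario tables do not depend on
#'   the order in which scenarios are listed.
#' @param refTables optional precomputed list of
#'   \code{\link{scenarioReferenceTable}} results (reused across
#'   observed datasets).
#' @return an \code{\link{ABCResult}}.
#' @export
runABC <- function(observed, scenarios = .SCENARIOS,
                   simsPerScenario = 1000, tolerance = 1,
                   scaling = ScalingConfig(), config = CoalescentConfig(),
                   seed = 1L, resolution = c(tauG = 7, tauF = 7, tauS = 7,
                                             etaC = 7),
                   weedSelfing = TRUE, refTables = NULL) {
  if (!all(is.finite(observed)))
    .stopData("observed summary vector must be finite")
  if (is.null(refTables)) {
    refTables <- lapply(scenarios, function(s)
      scenarioReferenceTable(s, simsPerScenario, scaling, config, seed,
                             resolution, weedSelfing))
  }
  names(refTables) <- vapply(refTables, `[[`, "", "scenario")
  pooled <- do.call(rbind, lapply(refTables[order(names(refTables))],
                                  `[[`, "stats"))
  scales <- .pilotScales(pooled)
  out <- list()
  for (nm in names(refTables)) {
    tab <- refTables[[nm]]
    rej <- abcReject(observed, tab$stats, tolerance, scales)
    params <- tab$params
    params$distance <- rej$distance
    params$accepted <- rej$accepted
    out[[nm]] <- list(params = params, nSims = nrow(tab$stats),
                      nAccepted = sum(rej$accepted))
  }
  new("ABCResult", observed = as.numeric(observed), scales = scales,
      tolerance = tolerance, scenarios = out, seed = as.numeric(seed))
}

#' @describeIn ABCResult-class approximate likelihood (accepted /
#'   simulated) for one scenario or all.
#' @export
setMethod("approximateLikelihood", "ABCResult",
          function(result, scenario = NULL) {
  if (is.null(scenario)) {
    return(vapply(result@scenarios, function(sc)
      sc$nAccepted / sc$nSims, numeric(1)))
  }
  if (!scenario %in% names(result@scenarios))
    .stopConfig("scenario not simulated: ", scenario)
  sc <- result@scenarios[[scenario]]
  sc$nAccepted / sc$nSims
})

#' @describeIn ABCResult-class accepted parameter draws, pooled over
#'   scenarios unless one is named.
#' @export
setMethod("acceptedDraws", "ABCResult", function(result, scenario = NULL) {
  nms <- if (is.null(scenario)) names(result@scenarios) else scenario
  draws <- lapply(nms, function(nm) {
    if (!nm %in% names(result@scenarios))
      .stopConfig("scenario not simulated: ", nm)
    p <- result@scenarios[[nm]]$params
    p <- p[p$accepted, , drop = FALSE]
    if (nrow(p)) p$scenario <- nm
    p
  })
  do.call(rbind, c(draws, list(make.row.names = FALSE)))
})

# -- posterior summaries ------------------------------------------------------

#' Marginal posterior density of one parameter
#'
#' Histogram density of the accepted draws on a fixed binning of the
#' parameter's prior range, with the prior marginal (density of all
#' draws) overlaid for comparison.  Densities integrate to 1.
#'
#' @param result an \code{\link{ABCResult}}.
#' @param parameter one of \code{"tauG"}, \code{"tauF"}, \code{"tauS"},
#'   \code{"etaC"}, \code{"etaRRatio"}, \code{"etaBRatio"},
#'   \code{"intensity"} (percent decline \eqn{100(1 - \eta_b/\eta_r)}).
#' @param bins number of bins.
#' @param scenario restrict to one scenario (default: pool all).
#' @return data.frame with columns mid, density, prior; attribute
#'   \code{empty} flags zero acceptances.
#' @export
posteriorDensity <- function(result, parameter, bins = 20,
                             scenario = NULL) {
  all <- .pooledParams(result, scenario)
  vals <- .paramColumn(all, parameter)
  acc <- vals[all$accepted]
  rng <- range(vals, finite = TRUE)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  dens <- function(v) {
    if (length(v) == 0L) return(rep(0, bins))
    h <- hist(pmin(pmax(v, rng[1]), rng[2]), breaks = breaks,
              plot = FALSE)
    h$density
  }
  out <- data.frame(mid = mid, density = dens(acc), prior = dens(vals))
  attr(out, "empty") <- length(acc) == 0L
  if (length(acc) == 0L)
    warning("no accepted draws; posterior density is empty")
  out
}

.pooledParams <- function(result, scenario = NULL) {
  nms <- if (is.null(scenario)) names(result@scenarios) else scenario
  bad <- setdiff(nms, names(result@scenarios))
  if (length(bad)) .stopConfig("scenario not simulated: ", bad[1])
  do.call(rbind, c(lapply(nms, function(nm)
    result@scenarios[[nm]]$params), list(make.row.names = FALSE)))
}

.paramColumn <- function(params, parameter) {
  if (parameter == "intensity")
    return(100 * (1 - params$etaBRatio))
  if (!parameter %in% c("tauG", "tauF", "tauS", "etaC", "etaRRatio",
                        "etaBRatio"))
    .stopConfig("unknown parameter: ", parameter)
  params[[parameter]]
}

#' Likelihood surface over weed size and bottleneck intensity
#'
#' Two-dimensional acceptance density of the accepted draws over the
#' current-weed-size ratio \code{etaRRatio} and the bottleneck intensity
#' (percent decline in population size during the bottleneck,
#' \eqn{100(1 - \eta_b/\eta_r)}, clipped to [0, 100]).
#'
#' @param result an \code{\link{ABCResult}}.
#' @param bins length-2 number of bins for (x = etaRRatio,
#'   y = intensity).
#' @param scenario restrict to one scenario (default: pool all).
#' @return list with \code{x}, \code{y} (bin midpoints), \code{z}
#'   (density matrix), \code{mode} (midpoints of the densest cell) and
#'   \code{empty} flag.
#' @export
likelihoodSurface <- function(result, bins = c(10, 10), scenario = NULL) {
  all <- .pooledParams(result, scenario)
  acc <- all[all$accepted, , drop = FALSE]
  bx <- seq(0, 1, length.out = bins[1] + 1L)
  by <- seq(0, 100, length.out = bins[2] + 1L)
  mx <- (bx[-1] + bx[-length(bx)]) / 2
  my <- (by[-1] + by[-length(by)]) / 2
  z <- matrix(0, bins[1], bins[2])
  empty <- nrow(acc) == 0L
  if (!empty) {
    xi <- pmin(pmax(findInterval(acc$etaRRatio, bx, all.inside = TRUE),
                    1L), bins[1])
    yi <- pmin(pmax(findInterval(pmin(pmax(100 * (1 - acc$etaBRatio), 0),
                                      100), by, all.inside = TRUE), 1L),
               bins[2])
    for (k in seq_len(nrow(acc))) z[xi[k], yi[k]] <- z[xi[k], yi[k]] + 1
    z <- z / sum(z) / ((bx[2] - bx[1]) * (by[2] - by[1]))
  } else {
    warning("no accepted draws; likelihood surface is empty")
  }
  modeIdx <- which(z == max(z), arr.ind = TRUE)[1, ]
  list(x = mx, y = my, z = z,
       mode = c(etaRRatio = mx[modeIdx[1]], intensity = my[modeIdx[2]]),
       empty = empty)
}

#' Plot a marginal posterior density with its prior
#'
#' @param density a \code{\link{posteriorDensity}} result.
#' @param main plot title.
#' @param xlab x label.
#' @return invisibly, the density.
#' @export
plotPosterior <- function(density, main = "", xlab = "parameter") {
  plot(density$mid, density$density, type = "l", col = "red", lwd = 2,
       xlab = xlab, ylab = "density", main = main)
  lines(density$mid, density$prior, lty = 2)
  legend("topright", c("posterior", "prior"), lty = c(1, 2),
         col = c("red", "black"), bty = "n")
  invisible(density)
}

#' Contour plot of the bottleneck-intensity likelihood surface
#'
#' @param surface a \code{\link{likelihoodSurface}} result.
#' @param main plot title.
#' @return invisibly, the surface.
#' @export
plotSurface <- function(surface, main = "") {
  contour(surface$x, surface$y, surface$z,
          xlab = "current weed size ratio (etaR / etaC)",
          ylab = "bottleneck intensity (% decline)", main = main)
  invisible(surface)
}
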