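# Wrappers around the compiled ancestral-recombination-graph coalescent.
# All randomness is driven by explicit seeds; per-locus streams are derived
# deterministically from (seed, locus index) so changing the locus count
# never reshuffles earlier loci.

.eventsToCpp <- function(events) {
  if (is.null(events) || nrow(events) == 0L)
    return(list(time = numeric(0), type = integer(0), pop = integer(0),
                param = numeric(0)))
  o <- order(events$time)
  events <- events[o, , drop = FALSE]
  list(time = as.numeric(events$time),
       type = ifelse(events$type == "join", 1L, 0L),
       pop = as.integer(events$pop),
       param = as.numeric(events$param))
}

#' Simulate one locus under the coalescent with recombination
#'
#' Hudson-style ancestral recombination graph in MS units: \code{theta}
#' and \code{rho} are per-locus population-scaled rates, sizes are
#' relative to the reference size and event times are in units of
#' \eqn{4 N_{ref}} generations.  Mutations follow the infinite-sites
#' model on the continuous unit interval.  Output is deterministic given
#' the seed.
#'
#' @param nSamples integer vector of haploid sample sizes, one entry per
#'   population (sampled at time 0).
#' @param theta per-locus population mutation rate \eqn{4 N_{ref}\mu L}.
#' @param rho per-locus population recombination rate.
#' @param sizes relative population sizes at present.
#' @param events data.frame(time, type, pop, param) of demographic
#'   events, \code{type} in \code{"size"}, \code{"join"}; may be NULL.
#' @param seed integer seed.
#' @param locusIndex optional 0-based locus index; when supplied the
#'   per-locus stream is derived from (seed, locusIndex) exactly as in
#'   \code{\link{simulateDataset}}.
#' @return list with \code{positions} (sorted, in (0,1)),
#'   \code{genotypes} (sites x haplotypes 0/1 matrix, 1 = derived) and
#'   \code{populations} (per-haplotype population index).
#' @export
simulateLocus <- function(nSamples, theta, rho, sizes = rep(1, length(nSamples)),
                          events = NULL, seed = 1L, locusIndex = NULL) {
  if (!all(is.finite(c(theta, rho))) || theta < 0 || rho < 0)
    .stopConfig("theta and rho must be finite and >= 0")
  ev <- .eventsToCpp(events)
  nSamples <- as.integer(nSamples)
  out <- if (is.null(locusIndex)) {
    .simLocusCpp(nSamples, theta, rho, as.numeric(sizes), ev$time, ev$type,
                 ev$pop, ev$param, as.numeric(seed))
  } else {
    .simLocusMasterCpp(nSamples, theta, rho, as.numeric(sizes), ev$time,
                       ev$type, ev$pop, ev$param, as.numeric(seed),
                       as.integer(locusIndex))
  }
  out$populations <- rep(seq_along(nSamples) - 1L, nSamples)
  out
}

#' SimulatedDataset: a multi-locus coalescent dataset
#'
#' Holds per-locus segregating-site matrices simulated under a
#' \code{\link{DemographicModel}}, plus everything needed to rescale,
#' rerun or render the dataset (model, scaling, sampling configuration
#' and seed).  Convert to an \code{\link{SNPMatrix}} with
#' \code{asSNPMatrix} or to FASTA-ready alignments with
#' \code{renderAlignments}.
#'
#' @slot loci list of per-locus results (positions, genotypes).
#' @slot model the generating \code{\link{DemographicModel}}.
#' @slot scaling the \code{\link{ScalingConfig}} used.
#' @slot config the \code{\link{CoalescentConfig}} used.
#' @slot seed master seed.
#' @param x a \code{SimulatedDataset}.
#' @param ... further arguments (unused).
#' @aliases asSNPMatrix renderAlignments
#' @export
setClass("SimulatedDataset",
  representation(loci = "list", model = "DemographicModel",
                 scaling = "ScalingConfig", config = "CoalescentConfig",
                 seed = "numeric"))

setMethod("show", "SimulatedDataset", function(object) {
  S <- vapply(object@loci, function(l) nrow(l$genotypes), integer(1))
  cat("SimulatedDataset:", length(object@loci), "loci,",
      sum(S), "segregating sites, seed", object@seed, "\n")
})

#' Simulate a multi-locus dataset under a demographic model
#'
#' Loci are unlinked and independent; per-locus
#' \eqn{\theta = 4 N_{ref} \mu L} and \eqn{\rho = (\rho/\theta)\,\theta}.
#' Simulated mutations are assigned site classes by the configured
#' proportions.  Population 0 is the weed, population 1 the progenitor.
#'
#' @param model a \code{\link{DemographicModel}}.
#' @param scaling a \code{\link{ScalingConfig}}.
#' @param config a \code{\link{CoalescentConfig}}.
#' @param seed master seed; locus i uses a stream derived from
#'   (seed, i).
#' @return a \code{\link{SimulatedDataset}}.
#' @export
simulateDataset <- function(model, scaling = ScalingConfig(),
                            config = CoalescentConfig(), seed = 1L) {
  sc <- toCoalescentUnits(model, scaling)
  ev <- .eventsToCpp(sc$events)
  ns <- c(config@nWeed, config@nProgenitor)
  loci <- vector("list", nrow(config@loci))
  names(loci) <- config@loci$locusId
  for (i in seq_along(loci)) {
    L <- config@loci$lengthBp[i]
    theta <- sc$thetaPerSite * L
    out <- .simLocusMasterCpp(ns, theta, sc$rhoOverTheta * theta,
                              as.numeric(sc$sizes), ev$time, ev$type,
                              ev$pop, ev$param, as.numeric(seed),
                              i - 1L)
    loci[[i]] <- out
  }
  new("SimulatedDataset", loci = loci, model = model, scaling = scaling,
      config = config, seed = as.numeric(seed))
}

#' @describeIn SimulatedDataset-class convert to an
#'   \code{\link{SNPMatrix}}; site classes are drawn from the configured
#'   proportions with a stream derived from the dataset seed, and sites
#'   keep the simulator's ancestral/derived coding (0 = ancestral).
#' @export
setMethod("asSNPMatrix", "SimulatedDataset", function(x, ...) {
  cfg <- x@config
  ids <- c(sprintf("%s_%02d", cfg@weedLabel, seq_len(cfg@nWeed)),
           sprintf("%s_%02d", cfg@progenitorLabel,
                   seq_len(cfg@nProgenitor)))
  pops <- c(rep(cfg@weedLabel, cfg@nWeed),
            rep(cfg@progenitorLabel, cfg@nProgenitor))
  props <- cfg@classProportions
  geno <- list()
  siteInfo <- list()
  lociRows <- list()
  for (i in seq_along(x@loci)) {
    out <- x@loci[[i]]
    L <- cfg@loci$lengthBp[i]
    lid <- cfg@loci$locusId[i]
    S <- nrow(out$genotypes)
    cls <- withSeed(deriveSeed(x@seed, 7000L + i), {
      sample(names(props), S, replace = TRUE, prob = props)
    })
    nClass <- round(L * props)
    lociRows[[i]] <- data.frame(
      locus = lid, lengthBp = L,
      nNoncoding = .propCount(nClass, "noncoding"),
      nSynonymous = .propCount(nClass, "synonymous"),
      nNonsynonymous = .propCount(nClass, "nonsynonymous"),
      nUnclassified = .propCount(nClass, "unclassified"))
    if (S > 0) {
      geno[[length(geno) + 1L]] <- out$genotypes
      siteInfo[[length(siteInfo) + 1L]] <- data.frame(
        locus = lid, column = seq_len(S) - 1L, siteClass = cls,
        allele0 = "0", allele1 = "1")
    }
  }
  loci <- do.call(rbind, c(lociRows, list(make.row.names = FALSE)))
  if (length(geno)) {
    g <- do.call(rbind, geno)
    si <- do.call(rbind, c(siteInfo, list(make.row.names = FALSE)))
  } else {
    g <- matrix(integer(0), 0L, length(ids))
    si <- data.frame(locus = character(0), column = integer(0),
                     siteClass = character(0))
  }
  colnames(g) <- ids
  SNPMatrix(g, si, data.frame(sample = ids, population = pops), loci)
})

.propCount <- function(nClass, cl) {
  if (cl %in% names(nClass)) as.integer(nClass[[cl]]) else 0L
}

#' Write a simulated dataset as an MS-style segregating-sites block
#'
#' One block per locus in the classic coalescent-simulator text layout
#' (\code{//}, \code{segsites:}, \code{positions:} on (0,1), then one
#' 0/1 haplotype row per sample), enabling cross-checks against external
#' coalescent simulators' post-processing tools.
#'
#' @param x a \code{\link{SimulatedDataset}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMsBlock <- function(x, path) {
  stopifnot(is(x, "SimulatedDataset"))
  con <- file(path, "w")
  on.exit(close(con))
  nTot <- x@config@nWeed + x@config@nProgenitor
  writeLines(sprintf("stsDemog %d %d", nTot, length(x@loci)), con)
  for (out in x@loci) {
    S <- nrow(out$genotypes)
    writeLines("//", con)
    writeLines(sprintf("segsites: %d", S), con)
    if (S > 0) {
      writeLines(paste("positions:",
                       paste(sprintf("%.6f", out$positions),
                             collapse = " ")), con)
      haps <- apply(out$genotypes, 2L, paste, collapse = "")
      writeLines(haps, con)
    }
  }
  invisible(path)
}

#' @describeIn SimulatedDataset-class render the dataset as a list of
#'   \code{\link{STSAlignment}} objects plus a
#'   \code{\link{PopulationPanel}}: a random ancestral sequence is drawn
#'   per locus, segregating sites are mapped to distinct integer columns
#'   (collisions resolved by redraw) and derived alleles substituted.
#' @export
setMethod("renderAlignments", "SimulatedDataset", function(x, ...) {
  cfg <- x@config
  snp <- asSNPMatrix(x)
  ids <- colnames(snp)
  pops <- populations(snp)
  rd <- SummarizedExperiment::rowData(snp)
  alns <- vector("list", nrow(cfg@loci))
  names(alns) <- cfg@loci$locusId
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(cfg@loci))) {
    lid <- cfg@loci$locusId[i]
    L <- cfg@loci$lengthBp[i]
    rows <- which(rd$locus == lid)
    mat <- withSeed(deriveSeed(x@seed, 9000L + i), {
      anc <- sample(bases, L, replace = TRUE)
      m <- matrix(rep(anc, each = length(ids)), nrow = length(ids))
      if (length(rows) > 0) {
        # distinct integer positions for the segregating sites ("redraw"
        # on collision is equivalent to sampling without replacement)
        colsAt <- sort(sample.int(L, length(rows)))
        for (k in seq_along(rows)) {
          derived <- sample(setdiff(bases, anc[colsAt[k]]), 1L)
          carriers <- genotypes(snp)[rows[k], ] == 1L
          m[carriers, colsAt[k]] <- derived
        }
      }
      m
    })
    seqs <- apply(mat, 1L, paste, collapse = "")
    names(seqs) <- ids
    alns[[i]] <- STSAlignment(lid, seqs)
  }
  list(alignments = alns,
       panel = PopulationPanel(stats::setNames(unname(pops), ids)))
})
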