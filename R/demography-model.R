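#' DemographicModel: two-population founder-bottleneck model
#'
#' Parameterises the divergence of a weedy population from its progenitor:
#' the weed founder lineage (size \code{etaP}, constrained equal to the
#' progenitor size \code{etaC}) splits from the progenitor \code{tauS}
#' years before present; at \code{tauF} founder lineages are introduced to
#' the new range and pass through a bottleneck of size \code{etaB}; the
#' population recovers instantaneously to its current size \code{etaR} at
#' \code{tauG}.  The progenitor remains at constant size \code{etaC}
#' throughout.  All sizes are effective numbers of individuals, all times
#' years before present, with \code{tauS >= tauF >= tauG >= 0}.
#'
#' Weedy populations are treated as effectively completely selfing:
#' with \code{weedSelfing = TRUE} (default) every weed-lineage effective
#' size is halved in coalescent units (equivalent to scaling weed timing
#' by 2N rather than 4N); the progenitor is left unscaled.
#'
#' @slot etaC progenitor (and founder-lineage) effective size.
#' @slot etaB bottleneck size.
#' @slot etaR current weed size.
#' @slot tauS split time (years before present).
#' @slot tauF founding/introduction time (ybp).
#' @slot tauG expansion (recovery) time (ybp).
#' @slot weedSelfing logical.
#' @seealso \code{\link{toCoalescentUnits}}, \code{\link{simulateDataset}}
#' @export
setClass("DemographicModel",
  representation(etaC = "numeric", etaB = "numeric", etaR = "numeric",
                 tauS = "numeric", tauF = "numeric", tauG = "numeric",
                 weedSelfing = "logical"))

setValidity("DemographicModel", function(object) {
  msg <- character()
  for (s in c("etaC", "etaB", "etaR"))
    if (slot(object, s) < 1) msg <- c(msg, paste(s, "must be >= 1"))
  if (!(object@tauS >= object@tauF && object@tauF >= object@tauG &&
        object@tauG >= 0))
    msg <- c(msg, "time ordering tauS >= tauF >= tauG >= 0 violated")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a DemographicModel
#'
#' @param etaC,etaB,etaR effective sizes (individuals); the founder
#'   lineage size etaP is constrained equal to etaC.
#' @param tauS,tauF,tauG event times in years before present,
#'   \code{tauS >= tauF >= tauG >= 0}.
#' @param weedSelfing halve weed-lineage effective sizes (full-selfing
#'   correction)?  Default \code{TRUE}.
#' @return a \code{DemographicModel}.
#' @examples
#' DemographicModel(etaC = 55000, etaB = 50, etaR = 5000,
#'                  tauS = 300, tauF = 300, tauG = 100)
#' @export
DemographicModel <- function(etaC, etaB, etaR, tauS, tauF, tauG,
                             weedSelfing = TRUE) {
  new("DemographicModel", etaC = etaC, etaB = etaB, etaR = etaR,
      tauS = tauS, tauF = tauF, tauG = tauG, weedSelfing = weedSelfing)
}

#' @describeIn DemographicModel-class founder-lineage size (equal to etaC).
#' @param object,x a \code{DemographicModel}.
#' @export
etaP <- function(x) x@etaC

setMethod("show", "DemographicModel", function(object) {
  cat("DemographicModel (founder-bottleneck)\n")
  cat(sprintf("  sizes: etaC = etaP = %.0f, etaB = %.0f, etaR = %.0f%s\n",
              object@etaC, object@etaB, object@etaR,
              if (object@weedSelfing) " [weed selfing: sizes halved]" else ""))
  cat(sprintf("  times (ybp): tauS = %.0f, tauF = %.0f, tauG = %.0f\n",
              object@tauS, object@tauF, object@tauG))
})

# -- scaling ------------------------------------------------------------------

#' ScalingConfig: unit conversion between natural and coalescent units
#'
#' @slot mu per-nucleotide per-generation neutral mutation rate.
#' @slot generationTime generation time in years.
#' @slot nRef reference effective size (the coalescent size unit),
#'   typically derived from a reference silent-site diversity via
#'   \code{\link{deriveReference4N}}.
#' @slot rhoOverTheta ratio of the population recombination rate to the
#'   population mutation rate (default 1).
#' @export
setClass("ScalingConfig",
  representation(mu = "numeric", generationTime = "numeric",
                 nRef = "numeric", rhoOverTheta = "numeric"))

setValidity("ScalingConfig", function(object) {
  if (object@mu <= 0) return("mu must be > 0")
  if (object@generationTime <= 0) return("generationTime must be > 0")
  if (object@nRef <= 0) return("nRef must be > 0")
  if (object@rhoOverTheta < 0) return("rhoOverTheta must be >= 0")
  TRUE
})

#' Construct a ScalingConfig
#'
#' Defaults encode an annual selfing grass: mutation rate
#' \eqn{10^{-8}} per site per generation, one-year generations, and a
#' reference size derived from the progenitor's wild relative
#' (silent-site Watterson's theta of 7.787/kb), with the population
#' recombination rate equal to the mutation rate.
#'
#' @param mu mutation rate per site per generation.
#' @param generationTime years per generation.
#' @param nRef reference effective size; if missing, derived from
#'   \code{referenceThetaPerKb}.
#' @param rhoOverTheta rho/theta ratio.
#' @param referenceThetaPerKb silent-site Watterson's theta per kb used to
#'   derive \code{nRef} when not supplied.
#' @return a \code{ScalingConfig}.
#' @export
ScalingConfig <- function(mu = 1e-8, generationTime = 1, nRef = NULL,
                          rhoOverTheta = 1, referenceThetaPerKb = 7.787) {
  if (is.null(nRef))
    nRef <- deriveReference4N(referenceThetaPerKb, mu)$nRef
  new("ScalingConfig", mu = mu, generationTime = generationTime,
      nRef = nRef, rhoOverTheta = rhoOverTheta)
}

setMethod("show", "ScalingConfig", function(object) {
  cat(sprintf(paste0("ScalingConfig: mu = %g /site/gen, generation = %g y,",
                     " N_ref = %.0f (4N_ref = %.0f), rho/theta = %g\n"),
              object@mu, object@generationTime, object@nRef,
              4 * object@nRef, object@rhoOverTheta))
})

#' Reference population size from a reference diversity
#'
#' Inverts \eqn{\theta = 4 N \mu} at the per-site scale:
#' \eqn{N_{ref} = (\theta / 1000) / (4\mu)} for \code{thetaPerKb}.
#'
#' @param thetaPerKb reference (e.g. wild progenitor silent-site)
#'   Watterson's theta per kb.
#' @param mu mutation rate per site per generation.
#' @return list with \code{nRef}, \code{fourNRef} and
#'   \code{thetaPerSite}.
#' @examples
#' deriveReference4N(7.787)  # N_ref ~ 194,675
#' @export
deriveReference4N <- function(thetaPerKb, mu = 1e-8) {
  if (!is.finite(thetaPerKb) || thetaPerKb <= 0)
    .stopConfig("reference theta must be > 0")
  thetaSite <- thetaPerKb / 1000
  nRef <- thetaSite / (4 * mu)
  list(nRef = nRef, fourNRef = 4 * nRef, thetaPerSite = thetaSite)
}

#' CoalescentConfig: sampling design for simulated datasets
#'
#' @slot nWeed,nProgenitor haploid sample sizes (>= 2).
#' @slot loci data.frame with columns \code{locusId} and \code{lengthBp}.
#' @slot classProportions named numeric proportions used to label
#'   simulated mutations with site classes.
#' @slot weedLabel,progenitorLabel population labels used in rendered
#'   datasets.
#' @export
setClass("CoalescentConfig",
  representation(nWeed = "integer", nProgenitor = "integer",
                 loci = "data.frame", classProportions = "numeric",
                 weedLabel = "character", progenitorLabel = "character"))

setValidity("CoalescentConfig", function(object) {
  msg <- character()
  if (object@nWeed < 2L || object@nProgenitor < 2L)
    msg <- c(msg, "sample sizes must be >= 2")
  if (!all(c("locusId", "lengthBp") %in% colnames(object@loci)))
    msg <- c(msg, "loci needs columns locusId and lengthBp")
  else if (any(object@loci$lengthBp <= 0))
    msg <- c(msg, "locus lengths must be > 0")
  if (abs(sum(object@classProportions) - 1) > 1e-8)
    msg <- c(msg, "classProportions must sum to 1")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a CoalescentConfig
#'
#' Defaults describe a straw-hull-weed versus \emph{indica}-shaped panel:
#' 24 weed and 22 progenitor haplotypes over 48 unlinked STS loci of
#' 500 bp.  Mutations are labelled noncoding/synonymous/nonsynonymous
#' with proportions 0.5/0.125/0.375 (half the fragment noncoding, coding
#' sites 1:3 synonymous:nonsynonymous); the labels partition simulated
#' sites for class-restricted statistics and carry no selective effect.
#'
#' @param nWeed,nProgenitor haploid sample sizes.
#' @param nLoci,lengthBp used to build a default locus table.
#' @param loci optional explicit data.frame(locusId, lengthBp).
#' @param classProportions named proportions over site classes.
#' @param weedLabel,progenitorLabel population labels.
#' @return a \code{CoalescentConfig}.
#' @export
CoalescentConfig <- function(nWeed = 24, nProgenitor = 22, nLoci = 48,
                             lengthBp = 500, loci = NULL,
                             classProportions = c(noncoding = 0.5,
                                                  synonymous = 0.125,
                                                  nonsynonymous = 0.375),
                             weedLabel = "weed",
                             progenitorLabel = "progenitor") {
  if (is.null(loci))
    loci <- data.frame(locusId = sprintf("L%02d", seq_len(nLoci)),
                       lengthBp = rep(lengthBp, nLoci))
  new("CoalescentConfig", nWeed = as.integer(nWeed),
      nProgenitor = as.integer(nProgenitor), loci = loci,
      classProportions = classProportions, weedLabel = weedLabel,
      progenitorLabel = progenitorLabel)
}

setMethod("show", "CoalescentConfig", function(object) {
  cat(sprintf("CoalescentConfig: %d weed + %d progenitor haplotypes, %d loci (mean %.0f bp)\n",
              object@nWeed, object@nProgenitor, nrow(object@loci),
              mean(object@loci$lengthBp)))
})

# -- unit conversion ----------------------------------------------------------

#' Convert a demographic model to coalescent (MS) units
#'
#' Times are expressed in units of \eqn{4 N_{ref}} generations and sizes
#' as ratios to \eqn{N_{ref}}.  With \code{weedSelfing} the weed-lineage
#' sizes (current, bottleneck, founder) are halved.  The returned event
#' list is ordered present-to-past: the weed recovery at tauG (size drops
#' to the bottleneck size backwards in time), the founding at tauF (size
#' becomes the founder size), and the split at tauS (weed lineages join
#' the progenitor).  When \code{tauS == tauF} the founder phase has zero
#' length and collapses into the join.
#'
#' @param model a \code{\link{DemographicModel}}.
#' @param scaling a \code{\link{ScalingConfig}}.
#' @return list with \code{sizes} (weed, progenitor relative sizes at
#'   present), \code{events} (data.frame time/type/pop/param; type
#'   \code{"size"} or \code{"join"}; populations 0 = weed,
#'   1 = progenitor), \code{thetaPerSite} and \code{rhoOverTheta}.
#' @examples
#' m <- DemographicModel(55000, 50, 5000, 400, 400, 100)
#' toCoalescentUnits(m, ScalingConfig())[["events"]]
#' @export
toCoalescentUnits <- function(model, scaling) {
  stopifnot(is(model, "DemographicModel"), is(scaling, "ScalingConfig"))
  nRef <- scaling@nRef
  half <- if (model@weedSelfing) 0.5 else 1
  xC <- model@etaC / nRef
  xR <- model@etaR / nRef * half
  xB <- model@etaB / nRef * half
  xP <- model@etaC / nRef * half   # founder lineage size, etaP = etaC
  toT <- function(years) years / scaling@generationTime / (4 * nRef)
  ev <- data.frame(time = toT(model@tauG), type = "size", pop = 0L,
                   param = xB)
  if (model@tauS > model@tauF)
    ev <- rbind(ev, data.frame(time = toT(model@tauF), type = "size",
                               pop = 0L, param = xP))
  ev <- rbind(ev, data.frame(time = toT(model@tauS), type = "join",
                             pop = 0L, param = 1))
  if (is.unsorted(ev$time))
    .stopConfig("event ordering violation in coalescent conversion")
  list(sizes = c(weed = xR, progenitor = xC), events = ev,
       thetaPerSite = 4 * nRef * scaling@mu,
       rhoOverTheta = scaling@rhoOverTheta)
}

#' Rescale a coalescent-scaled estimate to natural units
#'
#' Sizes: \eqn{N = \hat\theta / (4u)}; times:
#' \eqn{\mathrm{years} = (\hat t / u) \times \mathrm{generation\ time}},
#' with \eqn{u} the per-locus per-generation mutation rate.
#'
#' @param value scaled estimate (theta-like for sizes, t-like =
#'   mutation-scaled time for times).
#' @param locusMutationRate per-locus per-generation mutation rate,
#'   typically mu times the mean locus length.
#' @param scaling a \code{\link{ScalingConfig}} (supplies generation
#'   time).
#' @param kind \code{"size"} or \code{"time"}.
#' @return individuals or years.
#' @examples
#' rescaleEstimate(0.004, 1e-8 * 500, ScalingConfig(), "size")  # 200000
#' @export
rescaleEstimate <- function(value, locusMutationRate, scaling,
                            kind = c("size", "time")) {
  kind <- match.arg(kind)
  if (!is.finite(locusMutationRate) || locusMutationRate <= 0)
    .stopConfig("locus mutation rate must be > 0")
  switch(kind,
         size = value / (4 * locusMutationRate),
         time = value / locusMutationRate * scaling@generationTime)
}
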