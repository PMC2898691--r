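# Generators for pseudo-observed panels with known truth and small
# hand-checkable fixtures.  The presets encode the qualitative structure
# of the two main U.S. weedy rice groups as illustrative parameter sets
# (not estimates): the straw-hull group as a very recent divergence at
# introduction with a severe (99% decline) founding bottleneck, and the
# black-hull-awned group as an older post-domestication divergence with a
# milder bottleneck.

#' Preset demographic models for pseudo-observed data
#'
#' \code{shPresetModel}: straw-hull-shaped — divergence at founding
#' (\code{tauS = tauF = 300} ybp), progenitor at 0.285 of the reference
#' size (the observed crop-to-wild silent diversity ratio for the
#' relevant crop group), current weed size a tenth of the progenitor and
#' a 99\% founding decline (\code{etaB/etaR = 0.01}), expansion 100 ybp.
#'
#' \code{bha1PresetModel}: black-hull-awned-shaped — older divergence
#' (\code{tauS = 7000} ybp), progenitor at 0.18 of the reference size,
#' milder bottleneck (\code{etaB/etaR = 0.3}), founding 200 ybp,
#' expansion 100 ybp.
#'
#' @param scaling a \code{\link{ScalingConfig}} supplying the reference
#'   size.
#' @return a \code{\link{DemographicModel}}.
#' @export
shPresetModel <- function(scaling = ScalingConfig()) {
  etaC <- 0.285 * scaling@nRef
  etaR <- 0.1 * etaC
  DemographicModel(etaC = etaC, etaB = max(1, 0.01 * etaR), etaR = etaR,
                   tauS = 300, tauF = 300, tauG = 100, weedSelfing = TRUE)
}

#' @rdname shPresetModel
#' @export
bha1PresetModel <- function(scaling = ScalingConfig()) {
  etaC <- 0.18 * scaling@nRef
  etaR <- 0.3 * etaC
  DemographicModel(etaC = etaC, etaB = max(1, 0.3 * etaR), etaR = etaR,
                   tauS = 7000, tauF = 200, tauG = 100, weedSelfing = TRUE)
}

#' Named presets
#' @return named list of preset constructor functions.
#' @export
datasetPresets <- function() {
  list("SH-shaped" = shPresetModel, "BHA1-shaped" = bha1PresetModel)
}

#' Generate a pseudo-observed dataset with known truth
#'
#' Simulates a dataset under a known model and, optionally, writes it to
#' disk in the package's exchange formats (one FASTA per locus, a
#' population-map TSV and a truth-record JSON holding the generating
#' parameters, seeds and expected qualitative signatures).
#'
#' @param model a \code{\link{DemographicModel}}, or NULL to use a
#'   preset.
#' @param scaling a \code{\link{ScalingConfig}}.
#' @param config a \code{\link{CoalescentConfig}}.
#' @param seed integer seed (byte-identical outputs for equal seeds).
#' @param preset preset name (see \code{\link{datasetPresets}}) used when
#'   \code{model} is NULL.
#' @param dir optional output directory.
#' @return list with \code{dataset} (a
#'   \code{\link{SimulatedDataset}}) and \code{truth} (list).
#' @export
makePseudoObserved <- function(model = NULL, scaling = ScalingConfig(),
                               config = CoalescentConfig(), seed = 1L,
                               preset = "SH-shaped", dir = NULL) {
  if (is.null(model)) {
    presets <- datasetPresets()
    if (!preset %in% names(presets))
      .stopConfig("unknown preset '", preset, "'; available: ",
                  paste(names(presets), collapse = ", "))
    model <- presets[[preset]](scaling)
  }
  ds <- simulateDataset(model, scaling, config, seed)
  truth <- list(
    preset = if (is.null(preset)) NA_character_ else preset,
    seed = seed,
    model = list(etaC = model@etaC, etaP = etaP(model), etaB = model@etaB,
                 etaR = model@etaR, tauS = model@tauS, tauF = model@tauF,
                 tauG = model@tauG, weedSelfing = model@weedSelfing),
    scaling = list(mu = scaling@mu,
                   generationTime = scaling@generationTime,
                   nRef = scaling@nRef,
                   rhoOverTheta = scaling@rhoOverTheta),
    expected = list(
      weedDiversityFraction = model@etaR / model@etaC,
      bottleneckIntensityPct = 100 * (1 - model@etaB / model@etaR)))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rend <- renderAlignments(ds)
    for (aln in rend$alignments)
      writeSTSFasta(aln, file.path(dir, paste0(locusId(aln), ".fasta")))
    writePopulationPanel(rend$panel, file.path(dir, "popmap.tsv"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(dataset = ds, truth = truth)
}

#' Construct a toy alignment with a planted site partition
#'
#' Builds a two-population alignment whose
#' \code{\link{sitePartition}} between the populations equals the
#' planted counts exactly: shared sites are polymorphic in both
#' populations, private sites in exactly one, and fixed sites differ
#' between monomorphic populations.  Requires \code{n1, n2 >= 2} and
#' enough columns for the planted sites.
#'
#' @param shared,private1,private2,fixed planted site counts.
#' @param n1,n2 haplotypes per population.
#' @param L alignment length in bp.
#' @param pop1,pop2 population labels.
#' @return list with \code{alignment} (an \code{\link{STSAlignment}})
#'   and \code{panel} (a \code{\link{PopulationPanel}}).
#' @export
makeToyAlignment <- function(shared = 0, private1 = 0, private2 = 0,
                             fixed = 0, n1 = 4, n2 = 4, L = 50,
                             pop1 = "pop1", pop2 = "pop2") {
  total <- shared + private1 + private2 + fixed
  if (total > L)
    .stopConfig("planted sites (", total, ") exceed alignment length ", L)
  if (n1 < 2 || n2 < 2)
    .stopConfig("need at least 2 haplotypes per population")
  mat <- matrix("A", n1 + n2, L)
  i1 <- seq_len(n1)
  i2 <- n1 + seq_len(n2)
  col <- 0L
  put <- function(mat, col, rows) {
    mat[rows, col] <- "C"
    mat
  }
  for (k in seq_len(shared)) {
    col <- col + 1L
    mat <- put(mat, col, c(i1[1L], i2[1L]))
  }
  for (k in seq_len(private1)) {
    col <- col + 1L
    mat <- put(mat, col, i1[1L])
  }
  for (k in seq_len(private2)) {
    col <- col + 1L
    mat <- put(mat, col, i2[1L])
  }
  for (k in seq_len(fixed)) {
    col <- col + 1L
    mat <- put(mat, col, i1)
  }
  ids <- c(sprintf("%s_%02d", pop1, i1), sprintf("%s_%02d", pop2,
                                                 seq_len(n2)))
  seqs <- stats::setNames(apply(mat, 1L, paste, collapse = ""), ids)
  list(alignment = STSAlignment("toy", seqs),
       panel = PopulationPanel(stats::setNames(
         c(rep(pop1, n1), rep(pop2, n2)), ids)))
}

#' Generate a synthetic cytotype marker panel
#'
#' Draws each population's samples from a multinomial over cytotypes
#' with the given frequencies and splits the drawn cytotype strings back
#' into the three marker calls.
#'
#' @param frequencies numeric matrix, populations x cytotypes (rows must
#'   sum to 1; small rounding deviations up to 0.025 are renormalised).
#' @param nPerPop samples per population (single value or named vector).
#' @param seed integer seed.
#' @param path optional TSV output path (sample_id, orf100, ssv500,
#'   ssv39).
#' @return list with \code{records} (marker data.frame) and \code{panel}
#'   (a \code{\link{PopulationPanel}}).
#' @export
makeCytotypePanel <- function(frequencies, nPerPop = 20, seed = 1L,
                              path = NULL) {
  rs <- rowSums(frequencies)
  if (any(abs(rs - 1) > 0.025))
    .stopConfig("cytotype frequency rows must sum to 1")
  frequencies <- sweep(frequencies, 1L, rs, "/")
  pops <- rownames(frequencies)
  if (length(nPerPop) == 1L)
    nPerPop <- stats::setNames(rep(nPerPop, length(pops)), pops)
  rows <- list()
  labels <- character(0)
  withSeed(seed, {
    for (pop in pops) {
      n <- nPerPop[[pop]]
      if (n == 0L) next
      cyto <- sample(colnames(frequencies), n, replace = TRUE,
                     prob = frequencies[pop, ])
      parts <- do.call(rbind, strsplit(cyto, ".", fixed = TRUE))
      ids <- sprintf("%s_%03d", pop, seq_len(n))
      rows[[pop]] <- data.frame(sample_id = ids, orf100 = parts[, 1L],
                                ssv500 = parts[, 2L], ssv39 = parts[, 3L])
      labels <- c(labels, stats::setNames(rep(pop, n), ids))
    }
  })
  records <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL
  if (is.null(records))
    records <- data.frame(sample_id = character(0), orf100 = character(0),
                          ssv500 = character(0), ssv39 = character(0))
  if (!is.null(path))
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(records = records,
       panel = PopulationPanel(labels))
}
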