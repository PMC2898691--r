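#' @rdname STSAlignment-class
#' @export
setGeneric("locusId", function(x) standardGeneric("locusId"))

#' @rdname STSAlignment-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname STSAlignment-class
#' @export
setGeneric("lengthBp", function(x) standardGeneric("lengthBp"))

#' @rdname STSAlignment-class
#' @export
setGeneric("siteClasses", function(x) standardGeneric("siteClasses"))

#' @rdname STSAlignment-class
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname PopulationPanel-class
#' @export
setGeneric("populationOf", function(panel, ids) standardGeneric("populationOf"))

#' @rdname SNPMatrix-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname SNPMatrix-class
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname SNPMatrix-class
#' @export
setGeneric("lociInfo", function(x) standardGeneric("lociInfo"))

#' @rdname SimulatedDataset-class
#' @export
setGeneric("asSNPMatrix", function(x, ...) standardGeneric("asSNPMatrix"))

#' @rdname SimulatedDataset-class
#' @export
setGeneric("renderAlignments", function(x, ...)
  standardGeneric("renderAlignments"))

#' @rdname ABCResult-class
#' @export
setGeneric("approximateLikelihood", function(result, scenario = NULL)
  standardGeneric("approximateLikelihood"))

#' @rdname ABCResult-class
#' @export
setGeneric("acceptedDraws", function(result, scenario = NULL)
  standardGeneric("acceptedDraws"))
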