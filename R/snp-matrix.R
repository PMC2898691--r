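#' SNPMatrix: biallelic haploid site-by-sample matrix
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} holding the
#' biallelic segregating sites of a multi-locus STS panel.  Rows are
#' retained SNPs (assay \code{"genotype"} coded 0/1 with \code{NA} for
#' missing), columns are haploid samples.  \code{rowData} carries the
#' locus id, the 0-based alignment column, the site class and the two
#' allele states; \code{colData} carries each sample's population label.
#' Per-locus alignment metadata (the non-indel column counts by site
#' class, used as per-kb denominators) lives in
#' \code{metadata(x)$loci}.
#'
#' @param x an \code{SNPMatrix}.
#' @aliases genotypes populations lociInfo
#' @seealso \code{\link{buildSNPMatrix}}, \code{\link{wattersonTheta}}
#' @export
setClass("SNPMatrix", contains = "SummarizedExperiment")

setValidity("SNPMatrix", function(object) {
  msg <- character()
  if (!"genotype" %in% SummarizedExperiment::assayNames(object))
    return("assay 'genotype' is required")
  g <- SummarizedExperiment::assay(object, "genotype")
  if (!all(g %in% c(0L, 1L, NA)))
    msg <- c(msg, "genotype codes must be 0, 1 or NA")
  need <- c("locus", "column", "siteClass")
  if (!all(need %in% colnames(SummarizedExperiment::rowData(object))))
    msg <- c(msg, "rowData needs columns: ", paste(need, collapse = ", "))
  if (!"population" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData needs a 'population' column")
  li <- S4Vectors::metadata(object)$loci
  if (is.null(li) || !all(c("locus", "lengthBp") %in% colnames(li)))
    msg <- c(msg, "metadata(x)$loci needs columns locus and lengthBp")
  rd <- SummarizedExperiment::rowData(object)
  if (nrow(rd) > 1) {
    o <- order(match(rd$locus, unique(rd$locus)), rd$column)
    if (!identical(o, seq_len(nrow(rd))))
      msg <- c(msg, "sites must be ordered by locus with strictly ",
               "increasing column indices")
    if (anyDuplicated(paste(rd$locus, rd$column)))
      msg <- c(msg, "duplicated (locus, column) site entries")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct an SNPMatrix from parts
#'
#' @param genotypes integer matrix, sites x samples, values 0/1/NA.
#' @param siteInfo data.frame with columns \code{locus}, \code{column}
#'   (0-based), \code{siteClass}, and optionally \code{allele0},
#'   \code{allele1}.
#' @param sampleInfo data.frame with columns \code{sample} and
#'   \code{population}.
#' @param loci data.frame with per-locus columns \code{locus},
#'   \code{lengthBp} (non-indel columns) and the per-class column counts
#'   \code{nNoncoding}, \code{nSynonymous}, \code{nNonsynonymous},
#'   \code{nUnclassified}.
#' @return an \code{SNPMatrix}.
#' @export
SNPMatrix <- function(genotypes, siteInfo, sampleInfo, loci) {
  genotypes <- as.matrix(genotypes)
  mode(genotypes) <- "integer"
  if (is.null(siteInfo$allele0)) siteInfo$allele0 <- rep("0", nrow(siteInfo))
  if (is.null(siteInfo$allele1)) siteInfo$allele1 <- rep("1", nrow(siteInfo))
  for (cl in c("nNoncoding", "nSynonymous", "nNonsynonymous",
               "nUnclassified"))
    if (is.null(loci[[cl]]))
      loci[[cl]] <- if (cl == "nUnclassified") loci$lengthBp else 0L
  rownames(genotypes) <- paste(siteInfo$locus, siteInfo$column, sep = ":")
  colnames(genotypes) <- sampleInfo$sample
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(genotype = genotypes),
    rowData = S4Vectors::DataFrame(siteInfo),
    colData = S4Vectors::DataFrame(sampleInfo, row.names = sampleInfo$sample))
  S4Vectors::metadata(se)$loci <- loci
  new("SNPMatrix", se)
}

#' @rdname SNPMatrix-class
#' @export
setMethod("genotypes", "SNPMatrix",
          function(x) SummarizedExperiment::assay(x, "genotype"))

#' @rdname SNPMatrix-class
#' @export
setMethod("populations", "SNPMatrix", function(x)
  stats::setNames(as.character(SummarizedExperiment::colData(x)$population),
                  colnames(x)))

#' @rdname SNPMatrix-class
#' @export
setMethod("lociInfo", "SNPMatrix",
          function(x) as.data.frame(S4Vectors::metadata(x)$loci))

#' @describeIn SNPMatrix-class per-site classes of the retained SNPs.
#' @export
setMethod("siteClasses", "SNPMatrix",
          function(x) as.character(SummarizedExperiment::rowData(x)$siteClass))

setMethod("show", "SNPMatrix", function(object) {
  cat("SNPMatrix:", nrow(object), "biallelic sites x", ncol(object),
      "haploid samples over", nrow(lociInfo(object)), "loci\n")
  tab <- table(populations(object))
  cat("  populations:",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
})

# number of alignment columns of a site class, per locus (per-kb denominators)
.classLength <- function(loci, siteClass) {
  switch(siteClass,
    all = loci$lengthBp,
    silent = loci$nNoncoding + loci$nSynonymous,
    noncoding = loci$nNoncoding,
    synonymous = loci$nSynonymous,
    nonsynonymous = loci$nNonsynonymous,
    unclassified = loci$nUnclassified,
    .stopConfig("unknown site class: ", siteClass))
}

# logical row selector for a site class ("silent" = synonymous + noncoding)
.classRows <- function(x, siteClass) {
  cls <- siteClasses(x)
  switch(siteClass,
    all = rep(TRUE, length(cls)),
    silent = cls %in% c("synonymous", "noncoding"),
    cls == siteClass)
}

.popCols <- function(x, population) {
  sel <- populations(x) %in% population
  if (!any(sel))
    .stopConfig("no samples with population label '",
                paste(population, collapse = ","), "' in the SNP matrix")
  sel
}

# -- builder ------------------------------------------------------------------

#' Build the biallelic SNP matrix from locus alignments
#'
#' Scans every alignment column and retains the biallelic SNPs, applying
#' the panel's filtering conventions: columns overlapping an indel
#' (\code{"-"} in any sample) are excluded entirely (also from the per-kb
#' length denominators), and columns showing more than two allele states
#' among the \emph{targeted} groups are excluded, so that third alleles
#' contributed only by outgroups never remove a site.  Retained sites are
#' coded 0 for the major allele among the targeted samples and 1 for the
#' minor (alphabetical order breaks 50/50 ties); samples carrying neither
#' allele state are coded \code{NA}.  Ambiguity codes (rare heterozygous
#' calls in a haploid panel) were mapped to \code{N} on reading and are
#' treated as missing.
#'
#' @param alignments list of \code{\link{STSAlignment}} objects.
#' @param panel a \code{\link{PopulationPanel}} covering every sample.
#' @param targetedGroups character vector of population labels whose
#'   samples define polymorphism, allele count filtering and coding
#'   polarity; defaults to all populations in the panel.
#' @return an \code{\link{SNPMatrix}}.
#' @export
buildSNPMatrix <- function(alignments, panel, targetedGroups = NULL) {
  if (is(alignments, "STSAlignment")) alignments <- list(alignments)
  labels <- panel@labels
  if (is.null(targetedGroups)) targetedGroups <- unique(unname(labels))
  siteInfo <- list()
  genoRows <- list()
  lociRows <- list()
  sampleIdsAll <- unique(unlist(lapply(alignments, sampleIds)))
  pops <- populationOf(panel, sampleIdsAll)
  for (aln in alignments) {
    mat <- .alignmentMatrix(aln)
    ids <- sampleIds(aln)
    targeted <- populationOf(panel, ids) %in% targetedGroups
    keepCol <- !apply(mat == "-", 2L, any)
    cls <- siteClasses(aln)[keepCol]
    lociRows[[locusId(aln)]] <- data.frame(
      locus = locusId(aln), lengthBp = sum(keepCol),
      nNoncoding = sum(cls == "noncoding"),
      nSynonymous = sum(cls == "synonymous"),
      nNonsynonymous = sum(cls == "nonsynonymous"),
      nUnclassified = sum(cls == "unclassified"))
    for (j in which(keepCol)) {
      col <- mat[, j]
      obsT <- col[targeted]
      alleles <- sort(unique(obsT[obsT %in% c("A", "C", "G", "T")]))
      if (length(alleles) != 2L) next
      counts <- c(sum(obsT == alleles[1L]), sum(obsT == alleles[2L]))
      # major allele first; alphabetical order already breaks exact ties
      if (counts[2L] > counts[1L]) alleles <- rev(alleles)
      code <- rep(NA_integer_, length(sampleIdsAll))
      names(code) <- sampleIdsAll
      code[ids[col == alleles[1L]]] <- 0L
      code[ids[col == alleles[2L]]] <- 1L
      genoRows[[length(genoRows) + 1L]] <- code
      siteInfo[[length(siteInfo) + 1L]] <- data.frame(
        locus = locusId(aln), column = j - 1L,
        siteClass = siteClasses(aln)[j],
        allele0 = alleles[1L], allele1 = alleles[2L])
    }
  }
  loci <- do.call(rbind, c(lociRows, list(make.row.names = FALSE)))
  if (length(genoRows) == 0L) {
    geno <- matrix(integer(0), 0L, length(sampleIdsAll),
                   dimnames = list(NULL, sampleIdsAll))
    si <- data.frame(locus = character(0), column = integer(0),
                     siteClass = character(0), allele0 = character(0),
                     allele1 = character(0))
  } else {
    geno <- do.call(rbind, genoRows)
    si <- do.call(rbind, c(siteInfo, list(make.row.names = FALSE)))
  }
  SNPMatrix(geno, si,
            data.frame(sample = sampleIdsAll, population = pops), loci)
}

.alignmentMatrix <- function(aln) {
  seqs <- as.character(sequences(aln))
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- sampleIds(aln)
  mat
}
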