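#' STSAlignment: one sequence-tagged-site locus alignment
#'
#' Holds the aligned haplotype sequences of a single STS locus (one
#' sequence per sampled haplotype, alphabet \code{A,C,G,T,-,N}) together
#' with an optional per-column site-class annotation.  STS loci are short
#' (typically 400-900 bp) PCR-amplified fragments; in highly selfing
#' species a single haplotype per individual is carried, so the alignment
#' is treated as haploid.
#'
#' @slot locusId single locus identifier.
#' @slot sequences a \link[Biostrings]{DNAStringSet} of equal width; names
#'   are the sample identifiers (unique within the locus).
#' @slot siteClasses character vector with one entry per alignment column,
#'   each of \code{"noncoding"}, \code{"synonymous"}, \code{"nonsynonymous"}
#'   or \code{"unclassified"}.
#'
#' @param x an \code{STSAlignment}.
#' @aliases locusId sampleIds lengthBp siteClasses
#' @seealso \code{\link{readSTSFasta}}, \code{\link{buildSNPMatrix}}
#' @export
setClass("STSAlignment",
  representation(locusId = "character", sequences = "DNAStringSet",
                 siteClasses = "character"))

.SITE_CLASSES <- c("noncoding", "synonymous", "nonsynonymous", "unclassified")

setValidity("STSAlignment", function(object) {
  msg <- character()
  if (length(object@locusId) != 1L || !nzchar(object@locusId))
    msg <- c(msg, "locusId must be a single non-empty string")
  w <- Biostrings::width(object@sequences)
  if (length(w) == 0L)
    msg <- c(msg, "alignment holds no sequences")
  else if (length(unique(w)) != 1L)
    msg <- c(msg, "all sequences must share the same aligned length")
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    msg <- c(msg, "sample ids must be present and unique within the locus")
  if (length(object@siteClasses) != w[1L])
    msg <- c(msg, "siteClasses must have one entry per alignment column")
  if (!all(object@siteClasses %in% .SITE_CLASSES))
    msg <- c(msg, "siteClasses entries must be one of: ",
             paste(.SITE_CLASSES, collapse = ", "))
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct an STSAlignment
#'
#' @param locusId locus identifier.
#' @param sequences named character vector or
#'   \link[Biostrings]{DNAStringSet} of aligned sequences.  Residues are
#'   uppercased; characters outside \code{A,C,G,T,-} (including IUPAC
#'   ambiguity codes) are mapped to \code{N}.
#' @param siteClasses optional per-column classes; defaults to
#'   \code{"unclassified"}.
#' @return an \code{STSAlignment}.
#' @examples
#' aln <- STSAlignment("L1", c(s1 = "ACGT", s2 = "ACGA"))
#' lengthBp(aln)
#' @export
STSAlignment <- function(locusId, sequences, siteClasses = NULL) {
  if (is.character(sequences)) {
    if (length(sequences) == 0L)
      .stopData("no sequences supplied for locus ", locusId)
    seqs <- toupper(sequences)
    seqs <- vapply(seqs, function(s) {
      gsub("[^ACGT-]", "N", s)
    }, character(1))
    sequences <- Biostrings::DNAStringSet(seqs)
  } else {
    sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
    seqs <- as.character(sequences)
    cleaned <- gsub("[^ACGT-]", "N", seqs)
    if (!identical(cleaned, seqs))
      sequences <- Biostrings::DNAStringSet(stats::setNames(cleaned,
                                                            names(seqs)))
  }
  if (length(unique(Biostrings::width(sequences))) > 1L)
    .stopData("locus ", locusId, ": sequences differ in aligned length (",
              paste(unique(Biostrings::width(sequences)), collapse = ", "),
              ")")
  if (is.null(siteClasses))
    siteClasses <- rep("unclassified", Biostrings::width(sequences)[1L])
  new("STSAlignment", locusId = as.character(locusId),
      sequences = sequences, siteClasses = siteClasses)
}

#' @rdname STSAlignment-class
#' @export
setMethod("locusId", "STSAlignment", function(x) x@locusId)

#' @rdname STSAlignment-class
#' @export
setMethod("sampleIds", "STSAlignment", function(x) names(x@sequences))

#' @rdname STSAlignment-class
#' @export
setMethod("lengthBp", "STSAlignment",
          function(x) Biostrings::width(x@sequences)[1L])

#' @rdname STSAlignment-class
#' @export
setMethod("siteClasses", "STSAlignment", function(x) x@siteClasses)

#' @describeIn STSAlignment-class aligned sequences as a DNAStringSet.
#' @export
setMethod("sequences", "STSAlignment", function(x) x@sequences)

setMethod("show", "STSAlignment", function(object) {
  cat("STSAlignment", object@locusId, "-",
      length(object@sequences), "haplotypes x",
      lengthBp(object), "bp\n")
  cls <- table(object@siteClasses)
  cat("  site classes:",
      paste(names(cls), as.integer(cls), sep = "=", collapse = ", "), "\n")
})

#' Read one STS locus alignment from a FASTA file
#'
#' All records must have the same aligned length.  Residues are uppercased
#' and characters outside \code{A,C,G,T,-} are mapped to \code{N}.
#'
#' @param path path to a FASTA file (one record per haplotype).
#' @param locusId locus identifier; defaults to the file name without
#'   extension.
#' @param siteClasses optional per-column classes.
#' @return an \code{\link{STSAlignment}}.
#' @export
readSTSFasta <- function(path, locusId = NULL, siteClasses = NULL) {
  if (!file.exists(path)) .stopData("FASTA file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) .stopData("empty FASTA file: ", path)
  if (is.null(locusId))
    locusId <- sub("\\.(fa|fasta|fas)$", "", basename(path),
                   ignore.case = TRUE)
  STSAlignment(locusId, stats::setNames(as.character(seqs), names(seqs)),
               siteClasses = siteClasses)
}

#' Write an STS locus alignment to FASTA
#'
#' @param x an \code{\link{STSAlignment}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSTSFasta <- function(x, path) {
  stopifnot(is(x, "STSAlignment"))
  Biostrings::writeXStringSet(x@sequences, filepath = path, width = 80L)
  invisible(path)
}

# -- population panel ---------------------------------------------------------

#' PopulationPanel: sample-to-population map
#'
#' A validated mapping from sample identifiers to population labels
#' (free strings such as \code{"SH"} or \code{"indica"}).
#'
#' @slot labels named character vector; names are sample ids, values are
#'   non-empty population labels.
#' @param panel a \code{PopulationPanel}.
#' @param ids sample identifiers to look up.
#' @aliases populationOf
#' @export
setClass("PopulationPanel", representation(labels = "character"))

setValidity("PopulationPanel", function(object) {
  if (length(object@labels) == 0L) return(TRUE)
  ids <- names(object@labels)
  if (is.null(ids) || anyDuplicated(ids))
    return("sample ids must be present and unique")
  if (any(!nzchar(object@labels)))
    return("population labels must be non-empty")
  TRUE
})

#' Construct a PopulationPanel
#'
#' @param labels named character vector (names = sample ids, values =
#'   population labels), or a two-column data.frame
#'   (\code{sample_id}, \code{population}).
#' @return a \code{PopulationPanel}.
#' @export
PopulationPanel <- function(labels) {
  if (is.data.frame(labels)) {
    if (ncol(labels) < 2L)
      .stopData("population map needs sample_id and population columns")
    labels <- stats::setNames(as.character(labels[[2L]]),
                              as.character(labels[[1L]]))
  }
  new("PopulationPanel", labels = labels)
}

#' @rdname PopulationPanel-class
#' @export
setMethod("populationOf", "PopulationPanel", function(panel, ids) {
  out <- panel@labels[ids]
  if (anyNA(out))
    .stopData("samples missing from population panel: ",
              paste(ids[is.na(out)], collapse = ", "))
  unname(out)
})

#' @describeIn PopulationPanel-class sample identifiers in the panel.
#' @export
setMethod("sampleIds", "PopulationPanel", function(x) names(x@labels))

setMethod("show", "PopulationPanel", function(object) {
  tab <- table(object@labels)
  cat("PopulationPanel with", length(object@labels), "samples in",
      length(tab), "populations\n")
  cat(" ", paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
      "\n")
})

#' Read a sample-to-population map from TSV
#'
#' Expects two tab-separated columns, \code{sample_id} and
#' \code{population}; a header line is detected and skipped.
#'
#' @param path TSV path.
#' @return a \code{\link{PopulationPanel}}.
#' @export
readPopulationPanel <- function(path) {
  if (!file.exists(path)) .stopData("population map not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) && identical(tolower(df[1, 1]), "sample_id"))
    df <- df[-1, , drop = FALSE]
  PopulationPanel(df)
}

#' Write a population panel to TSV
#' @param panel a \code{\link{PopulationPanel}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePopulationPanel <- function(panel, path) {
  utils::write.table(
    data.frame(sample_id = names(panel@labels),
               population = unname(panel@labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-column site classes from TSV
#'
#' Columns: \code{locus_id}, \code{column} (0-based alignment column) and
#' \code{class} (one of noncoding/synonymous/nonsynonymous/unclassified).
#'
#' @param path TSV path.
#' @return data.frame with columns \code{locus_id}, \code{column},
#'   \code{class}.
#' @export
readSiteClasses <- function(path) {
  if (!file.exists(path)) .stopData("site-class file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("locus_id", "column", "class"))
  if (nrow(df) && identical(tolower(df[1, 1]), "locus_id"))
    df <- df[-1, , drop = FALSE]
  df$column <- as.integer(df$column)
  if (!all(df$class %in% .SITE_CLASSES))
    .stopData("unknown site class: ",
              paste(setdiff(df$class, .SITE_CLASSES), collapse = ", "))
  df
}

#' Attach site classes from an annotation table to an alignment
#'
#' @param x an \code{\link{STSAlignment}}.
#' @param classes data.frame as returned by \code{\link{readSiteClasses}}.
#' @return the alignment with \code{siteClasses} filled in; columns absent
#'   from the table stay \code{"unclassified"}.
#' @export
applySiteClasses <- function(x, classes) {
  stopifnot(is(x, "STSAlignment"))
  sel <- classes$locus_id == locusId(x)
  cls <- rep("unclassified", lengthBp(x))
  idx <- classes$column[sel]
  if (any(idx < 0 | idx >= lengthBp(x)))
    .stopData("site-class column index out of range for locus ", locusId(x))
  cls[idx + 1L] <- classes$class[sel]
  initialize(x, siteClasses = cls)
}

# -- codon classifier ---------------------------------------------------------

#' Classify a single-nucleotide codon change as synonymous or not
#'
#' Utility for users supplying coding-frame information: compares the
#' standard-genetic-code translations of two codons differing at exactly
#' one position.
#'
#' @param codonBefore,codonAfter 3-mers over \code{A,C,G,T}.
#' @return \code{"synonymous"} or \code{"nonsynonymous"}, with attribute
#'   \code{stopCodon = TRUE} when either codon is a stop.
#' @examples
#' classifySite("GGG", "GGA")  # synonymous
#' classifySite("GGG", "AGG")  # nonsynonymous
#' @export
classifySite <- function(codonBefore, codonAfter) {
  codonBefore <- toupper(codonBefore)
  codonAfter <- toupper(codonAfter)
  ok <- function(x) nchar(x) == 3L && !grepl("[^ACGT]", x)
  if (!ok(codonBefore) || !ok(codonAfter))
    .stopData("codons must be 3-mers over A,C,G,T")
  diffs <- sum(strsplit(codonBefore, "")[[1]] != strsplit(codonAfter, "")[[1]])
  if (diffs != 1L)
    .stopData("codons must differ at exactly one position (got ", diffs, ")")
  aaB <- Biostrings::GENETIC_CODE[[codonBefore]]
  aaA <- Biostrings::GENETIC_CODE[[codonAfter]]
  out <- if (identical(aaB, aaA)) "synonymous" else "nonsynonymous"
  if (aaB == "*" || aaA == "*") attr(out, "stopCodon") <- TRUE
  out
}
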