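#' Combine cytoplasm marker calls into cytotypes
#'
#' The cytoplasm of each sample is genotyped at one chloroplast (Orf100)
#' and two mitochondrial (SSV500, SSV39) indel markers, each scored as
#' deletion present (\code{D}) or absent (\code{N}).  Assuming maternal
#' inheritance, the three calls are combined into a single dot-joined
#' cytotype string such as \code{"D.D.N"}.  A missing marker call (empty,
#' \code{NA} or \code{"missing"}) leaves the cytotype undefined; the
#' record is retained and flagged.
#'
#' @param records data.frame with columns \code{sample_id},
#'   \code{orf100}, \code{ssv500}, \code{ssv39}.
#' @return the input with added columns \code{cytotype} (NA when
#'   undefined) and \code{defined} (logical).
#' @examples
#' combineCytotype(data.frame(sample_id = "w1", orf100 = "D",
#'                            ssv500 = "D", ssv39 = "N"))
#' @export
combineCytotype <- function(records) {
  need <- c("sample_id", "orf100", "ssv500", "ssv39")
  if (!all(need %in% colnames(records)))
    .stopData("cytotype records need columns: ", paste(need, collapse = ", "))
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "" | tolower(x) == "missing"] <- NA_character_
    bad <- !is.na(x) & !x %in% c("D", "N")
    if (any(bad))
      .stopData("unknown cytoplasm marker state: ",
                paste(unique(x[bad]), collapse = ", "))
    x
  }
  m <- cbind(norm(records$orf100), norm(records$ssv500),
             norm(records$ssv39))
  defined <- !apply(is.na(m), 1L, any)
  cyto <- rep(NA_character_, nrow(m))
  cyto[defined] <- paste(m[defined, 1L], m[defined, 2L], m[defined, 3L],
                         sep = ".")
  records$cytotype <- cyto
  records$defined <- defined
  records
}

#' Cytotype frequencies by population
#'
#' Frequencies are computed over samples with a defined cytotype;
#' populations in which no sample has a defined cytotype are omitted with
#' a warning.  Each returned row sums to 1.
#'
#' @param records data.frame as returned by \code{\link{combineCytotype}}.
#' @param panel a \code{\link{PopulationPanel}}.
#' @return numeric matrix, populations x cytotypes.
#' @export
cytotypeFrequencies <- function(records, panel) {
  if (is.null(records$cytotype)) records <- combineCytotype(records)
  pop <- populationOf(panel, records$sample_id)
  def <- records$defined
  popsAll <- unique(pop)
  empty <- setdiff(popsAll, unique(pop[def]))
  if (length(empty))
    warning("populations with no defined cytotype omitted: ",
            paste(empty, collapse = ", "))
  tab <- table(pop[def], records$cytotype[def])
  freq <- sweep(unclass(tab), 1L, rowSums(tab), "/")
  freq[rowSums(tab) > 0, , drop = FALSE]
}

#' Read cytoplasm marker calls from TSV
#'
#' Columns: \code{sample_id}, \code{orf100}, \code{ssv500}, \code{ssv39}.
#'
#' @param path TSV path.
#' @return data.frame of marker calls with cytotypes combined.
#' @export
readCytotypeMarkers <- function(path) {
  if (!file.exists(path)) .stopData("cytotype marker file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("sample_id", "orf100", "ssv500",
                                        "ssv39"))
  if (nrow(df) && identical(tolower(df[1, 1]), "sample_id"))
    df <- df[-1, , drop = FALSE]
  combineCytotype(df)
}

#' Published cytotype frequencies for weedy rice and related Oryza groups
#'
#' The observed cytotype frequency table for the U.S. weedy rice
#' populations (straw-hull SH, black-hull-awned BHA1/BHA2, brown-hull
#' BRH) and candidate source groups, used as input frequencies for
#' synthetic cytotype panels (\code{\link{makeCytotypePanel}}).  Rows are
#' renormalised to sum to exactly 1 (the published values are rounded to
#' two decimals).
#'
#' @return numeric matrix, populations x cytotypes.
#' @export
weedyCytotypeFrequencies <- function() {
  cyto <- c("N.N.D", "N.N.N", "D.N.N", "N.D.D", "D.D.D", "D.D.N")
  m <- rbind(
    BHA1              = c(0.60, 0,    0,    0.20, 0.13, 0.07),
    BHA2              = c(0.71, 0,    0,    0.29, 0,    0),
    BRH               = c(0,    0,    0,    0,    0,    1),
    SH                = c(0,    0,    0,    0,    0,    1),
    aus               = c(0,    0,    0.50, 0.17, 0,    0.33),
    indica            = c(0.20, 0,    0,    0.20, 0,    0.60),
    tropical_japonica = c(0.63, 0.13, 0,    0.13, 0,    0.13),
    us_cultivars      = c(1,    0,    0,    0,    0,    0),
    rufipogon         = c(0.07, 0,    0,    0.37, 0.03, 0.53))
  colnames(m) <- cyto
  sweep(m, 1L, rowSums(m), "/")
}
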