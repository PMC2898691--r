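# Diversity, differentiation and site-partition statistics for haploid STS
# panels.  Aggregation conventions follow the panel's reporting style:
# per-kb values are per-locus, using the non-indel column count of the
# requested site class as denominator; panel-level values are means over
# loci; F_st uses the haploid two-population Weir-Cockerham estimator with
# union-sample singletons dropped, negative per-SNP values clamped to zero,
# and non-polymorphic loci counted as zeros in the grand mean.

# per-site derived/minor counts and effective sample sizes for a genotype
# sub-matrix (sites x samples)
.siteCounts <- function(g) {
  if (nrow(g) == 0L)
    return(list(c1 = integer(0), n = integer(0)))
  list(c1 = rowSums(g == 1L, na.rm = TRUE), n = rowSums(!is.na(g)))
}

.segregating <- function(cnt) cnt$c1 > 0L & cnt$c1 < cnt$n & cnt$n >= 2L

# -- per-locus engine ---------------------------------------------------------

# per-locus S, sum of per-site Watterson weights and pairwise diversity for
# one population and site class
.locusDiversity <- function(x, population, siteClass) {
  rows <- .classRows(x, siteClass)
  cols <- .popCols(x, population)
  g <- genotypes(x)[rows, cols, drop = FALSE]
  locus <- as.character(SummarizedExperiment::rowData(x)$locus)[rows]
  li <- lociInfo(x)
  len <- .classLength(li, siteClass)
  cnt <- .siteCounts(g)
  seg <- .segregating(cnt)
  nmax <- max(cnt$n, sum(cols), 2L)
  aTab <- cumsum(1 / seq_len(nmax))         # aTab[k] = a_k
  wW <- ifelse(seg, 1 / aTab[pmax(cnt$n - 1L, 1L)], 0)
  wPi <- ifelse(seg,
                2 * cnt$c1 * (cnt$n - cnt$c1) /
                  (cnt$n * pmax(cnt$n - 1L, 1L)), 0)
  sumBy <- function(v) {
    out <- stats::setNames(numeric(nrow(li)), li$locus)
    if (length(v)) {
      s <- tapply(v, factor(locus, levels = li$locus), sum)
      out[names(s)[!is.na(s)]] <- s[!is.na(s)]
    }
    out
  }
  list(S = sumBy(as.numeric(seg)), thetaWsum = sumBy(wW),
       piSum = sumBy(wPi), len = stats::setNames(len, li$locus),
       nHap = sum(cols))
}

#' Watterson's theta per kb
#'
#' Per locus, each segregating site contributes \eqn{1/a_{n-1}} with
#' \eqn{n} the site's effective (non-missing) sample size and
#' \eqn{a_k = \sum_{i=1}^k 1/i}; the sum is divided by the number of
#' alignment columns of the requested site class (indel columns excluded)
#' and scaled to per kb.
#'
#' @param x an \code{\link{SNPMatrix}}.
#' @param population population label (or vector of labels pooled into one
#'   sample).
#' @param siteClass one of \code{"all"}, \code{"silent"} (noncoding +
#'   synonymous), \code{"noncoding"}, \code{"synonymous"},
#'   \code{"nonsynonymous"}, \code{"unclassified"}.
#' @param by \code{"mean"} (default): mean of per-locus values over loci
#'   with a positive class denominator; \code{"locus"}: per-locus vector.
#' @return numeric; \code{NA} where undefined (no sites of the class).
#' @export
wattersonTheta <- function(x, population, siteClass = "all",
                           by = c("mean", "locus")) {
  by <- match.arg(by)
  d <- .locusDiversity(x, population, siteClass)
  if (d$nHap < 2L)
    .stopData("need at least 2 haplotypes in population '", population, "'")
  per <- ifelse(d$len > 0, d$thetaWsum / d$len * 1000, NA_real_)
  if (by == "locus") per else
    if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE)
}

#' Pairwise nucleotide diversity (theta_pi) per kb
#'
#' Mean pairwise difference per site, scaled to per kb; pairwise
#' denominators use only haplotype pairs with both alleles observed
#' (per-site effective sample size).
#'
#' @inheritParams wattersonTheta
#' @return numeric; \code{NA} where undefined.
#' @export
piTheta <- function(x, population, siteClass = "all",
                    by = c("mean", "locus")) {
  by <- match.arg(by)
  d <- .locusDiversity(x, population, siteClass)
  if (d$nHap < 2L)
    .stopData("need at least 2 haplotypes in population '", population, "'")
  per <- ifelse(d$len > 0, d$piSum / d$len * 1000, NA_real_)
  if (by == "locus") per else
    if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE)
}

#' Tajima's D
#'
#' The standardised difference between pairwise diversity and Watterson's
#' estimator (Tajima 1989), computed per locus from S and the per-locus sum
#' of pairwise differences, then averaged over loci with at least one
#' segregating site.  Undefined (NA) when no locus segregates.
#'
#' @inheritParams wattersonTheta
#' @export
tajimasD <- function(x, population, siteClass = "all",
                     by = c("mean", "locus")) {
  by <- match.arg(by)
  d <- .locusDiversity(x, population, siteClass)
  n <- d$nHap
  if (n < 4L)
    .stopData("Tajima's D needs at least 4 haplotypes (got ", n, ")")
  per <- .tajimaFromSandPi(d$S, d$piSum, n)
  if (by == "locus") per else
    if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE)
}

.tajimaFromSandPi <- function(S, piSum, n) {
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  ifelse(S >= 1L & v > 0, (piSum - S / a1) / sqrt(v), NA_real_)
}

#' Per-locus and mean diversity report
#'
#' Long-format table of per-locus diversity statistics for one or more
#' populations and site classes, with a \code{"mean"} row per
#' population/class combination mirroring the usual multi-locus reporting
#' layout (mean theta_W and theta_pi per kb over loci, mean Tajima's D over
#' polymorphic loci, total S and polymorphic-locus count).
#'
#' @param x an \code{\link{SNPMatrix}}.
#' @param populations character vector of population labels.
#' @param siteClasses character vector of site classes.
#' @return data.frame with columns population, siteClass, locus, thetaW,
#'   thetaPi, tajimasD, S, polymorphic.
#' @export
diversitySummary <- function(x, populations = unique(populations(x)),
                             siteClasses = c("all", "silent",
                                             "synonymous",
                                             "nonsynonymous")) {
  out <- list()
  for (pop in populations) {
    for (cl in siteClasses) {
      d <- .locusDiversity(x, pop, cl)
      tw <- ifelse(d$len > 0, d$thetaWsum / d$len * 1000, NA_real_)
      tp <- ifelse(d$len > 0, d$piSum / d$len * 1000, NA_real_)
      td <- .tajimaFromSandPi(d$S, d$piSum, max(d$nHap, 4L))
      loci <- names(d$S)
      out[[length(out) + 1L]] <- data.frame(
        population = pop, siteClass = cl,
        locus = c(loci, "mean"),
        thetaW = c(tw, mean(tw, na.rm = TRUE)),
        thetaPi = c(tp, mean(tp, na.rm = TRUE)),
        tajimasD = c(td, if (all(is.na(td))) NA_real_ else
          mean(td, na.rm = TRUE)),
        S = c(d$S, sum(d$S)),
        polymorphic = c(d$S > 0, sum(d$S > 0)))
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# -- site partition -----------------------------------------------------------

#' Partition sites into shared, private and fixed categories
#'
#' Each site with data in both populations is classified by its
#' within-population polymorphism status: \emph{shared} (polymorphic in
#' both), \emph{private} to either population (polymorphic in exactly
#' one), or a \emph{fixed difference} (each population monomorphic for a
#' different allele).  A parallel classification excluding singletons
#' (sites whose minor allele is observed exactly once in the pooled
#' two-population sample) is also returned.
#'
#' @param x an \code{\link{SNPMatrix}}.
#' @param pop1,pop2 population labels.
#' @param siteClass site class filter (default all sites).
#' @return list with components \code{shared}, \code{private1},
#'   \code{private2}, \code{fixed}, \code{total} and
#'   \code{excludingSingletons} (same four counts).
#' @export
sitePartition <- function(x, pop1, pop2, siteClass = "all") {
  rows <- .classRows(x, siteClass)
  g1 <- genotypes(x)[rows, .popCols(x, pop1), drop = FALSE]
  g2 <- genotypes(x)[rows, .popCols(x, pop2), drop = FALSE]
  cnt1 <- .siteCounts(g1)
  cnt2 <- .siteCounts(g2)
  use <- cnt1$n >= 1L & cnt2$n >= 1L
  poly1 <- cnt1$c1 > 0L & cnt1$c1 < cnt1$n
  poly2 <- cnt2$c1 > 0L & cnt2$c1 < cnt2$n
  # for monomorphic-in-both sites, the observed allele per population
  al1 <- ifelse(cnt1$c1 == cnt1$n, 1L, 0L)
  al2 <- ifelse(cnt2$c1 == cnt2$n, 1L, 0L)
  fixedDiff <- !poly1 & !poly2 & al1 != al2
  c1u <- cnt1$c1 + cnt2$c1
  nu <- cnt1$n + cnt2$n
  minor <- pmin(c1u, nu - c1u)
  classify <- function(keep) {
    k <- use & keep
    list(shared = sum(k & poly1 & poly2),
         private1 = sum(k & poly1 & !poly2),
         private2 = sum(k & !poly1 & poly2),
         fixed = sum(k & fixedDiff))
  }
  base <- classify(TRUE)
  base$total <- base$shared + base$private1 + base$private2 + base$fixed
  base$excludingSingletons <- classify(minor >= 2L)
  base$populations <- c(pop1, pop2)
  base
}

# -- Weir-Cockerham F_st ------------------------------------------------------

# haploid two-population Weir-Cockerham estimator from allele frequencies
.wcHaploid <- function(c1a, n1, c1b, n2) {
  p1 <- c1a / n1
  p2 <- c1b / n2
  nt <- n1 + n2
  pbar <- (c1a + c1b) / nt
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2       # df = r - 1 = 1
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nt - 2)
  nc <- nt - (n1^2 + n2^2) / nt                        # df = r - 1 = 1
  denom <- msp + (nc - 1) * msg
  ifelse(denom > 0, (msp - msg) / denom, NA_real_)
}

#' Two-population Weir-Cockerham F_st with panel conventions
#'
#' Per-SNP haploid Weir-Cockerham (1984) estimates between two
#' populations, with three aggregation rules: SNPs whose minor allele is
#' observed exactly once in the pooled two-population sample (singletons)
#' are dropped; negative per-SNP values are set to zero before averaging;
#' the per-locus value is the mean over retained SNPs and the grand mean
#' (and median) over loci count non-polymorphic or empty loci as zeros.
#'
#' @param x an \code{\link{SNPMatrix}}.
#' @param pop1,pop2 population labels.
#' @param siteClass site class filter.
#' @return an object of class \code{FstSummary}: list with
#'   \code{perSNP} (data.frame locus/column/raw/fst), \code{perLocus}
#'   (named vector over all loci), \code{grandMean} and \code{median}.
#' @export
weirCockerhamFst <- function(x, pop1, pop2, siteClass = "all") {
  rows <- .classRows(x, siteClass)
  g1 <- genotypes(x)[rows, .popCols(x, pop1), drop = FALSE]
  g2 <- genotypes(x)[rows, .popCols(x, pop2), drop = FALSE]
  locus <- as.character(SummarizedExperiment::rowData(x)$locus)[rows]
  column <- SummarizedExperiment::rowData(x)$column[rows]
  cnt1 <- .siteCounts(g1)
  cnt2 <- .siteCounts(g2)
  c1u <- cnt1$c1 + cnt2$c1
  nu <- cnt1$n + cnt2$n
  minor <- pmin(c1u, nu - c1u)
  use <- cnt1$n >= 2L & cnt2$n >= 2L & minor >= 2L
  raw <- rep(NA_real_, length(use))
  raw[use] <- .wcHaploid(cnt1$c1[use], cnt1$n[use],
                         cnt2$c1[use], cnt2$n[use])
  use <- use & !is.na(raw)
  fst <- pmin(pmax(raw, 0), 1)
  li <- lociInfo(x)
  perLocus <- stats::setNames(numeric(nrow(li)), li$locus)
  if (any(use)) {
    m <- tapply(fst[use], factor(locus[use], levels = li$locus), mean)
    perLocus[names(m)[!is.na(m)]] <- m[!is.na(m)]
  } else {
    warning("no SNPs retained for F_st; grand mean reported as 0")
  }
  structure(list(
    perSNP = data.frame(locus = locus[use], column = column[use],
                        raw = raw[use], fst = fst[use]),
    perLocus = perLocus,
    grandMean = mean(perLocus),
    median = stats::median(perLocus),
    populations = c(pop1, pop2)), class = "FstSummary")
}

#' @export
print.FstSummary <- function(x, ...) {
  cat("Weir-Cockerham F_st:", x$populations[1], "vs", x$populations[2],
      "\n  SNPs retained:", nrow(x$perSNP),
      "\n  grand mean over", length(x$perLocus), "loci:",
      signif(x$grandMean, 4), " median:", signif(x$median, 4), "\n")
  invisible(x)
}

# -- most-frequent haplotype sharing ------------------------------------------

#' Fraction of loci sharing the most frequent haplotype
#'
#' For each locus alignment, indel columns are removed and the most
#' frequent complete (gap- and N-free) full-locus haplotype is determined
#' per population (ties broken by the lexicographically smallest
#' sequence).  Returns the fraction of loci at which the two populations
#' share the same most-frequent haplotype; loci without a complete
#' haplotype in either population are excluded with a warning.
#'
#' @param alignments list of \code{\link{STSAlignment}} objects.
#' @param panel a \code{\link{PopulationPanel}}.
#' @param pop1,pop2 population labels.
#' @return list with \code{fraction} and per-locus logical \code{perLocus}.
#' @export
mfhShare <- function(alignments, panel, pop1, pop2) {
  if (is(alignments, "STSAlignment")) alignments <- list(alignments)
  res <- logical(0)
  skipped <- character(0)
  for (aln in alignments) {
    mat <- .alignmentMatrix(aln)
    keep <- !apply(mat == "-", 2L, any)
    mat <- mat[, keep, drop = FALSE]
    haps <- apply(mat, 1L, paste, collapse = "")
    complete <- !grepl("N", haps, fixed = TRUE)
    pops <- populationOf(panel, sampleIds(aln))
    mfh <- function(pop) {
      h <- haps[complete & pops == pop]
      if (length(h) == 0L) return(NA_character_)
      tab <- table(h)
      cand <- names(tab)[tab == max(tab)]
      sort(cand)[1L]
    }
    m1 <- mfh(pop1)
    m2 <- mfh(pop2)
    if (is.na(m1) || is.na(m2)) {
      skipped <- c(skipped, locusId(aln))
      next
    }
    res[locusId(aln)] <- m1 == m2
  }
  if (length(skipped))
    warning("loci without a complete haplotype excluded: ",
            paste(skipped, collapse = ", "))
  list(fraction = if (length(res)) mean(res) else NA_real_, perLocus = res)
}

# -- ABC summary vector -------------------------------------------------------

#' The pooled eight-statistic ABC summary vector
#'
#' Statistics are pooled over all loci: pairwise diversity of the combined
#' (union) sample per kb, segregating sites within the weed and within the
#' progenitor, fixed differences, sites private to each population, sites
#' shared (polymorphic in both), and a configurable eighth slot
#' (default: segregating sites in the union sample).
#'
#' @param x an \code{\link{SNPMatrix}}.
#' @param weed,progenitor population labels.
#' @param siteClass site class filter; default \code{"all"} pools every
#'   retained site.
#' @param eighth eighth statistic: \code{"sUnion"} (default) or
#'   \code{"wattersonPooled"} (pooled Watterson's theta per kb of the
#'   union sample).
#' @return named numeric vector of length 8, in the order pooledPi,
#'   sWeed, sProgenitor, fixed, privateWeed, privateProgenitor, shared,
#'   plus the chosen eighth statistic.
#' @export
abcSummaryVector <- function(x, weed, progenitor, siteClass = "all",
                             eighth = c("sUnion", "wattersonPooled")) {
  eighth <- match.arg(eighth)
  rows <- .classRows(x, siteClass)
  gw <- genotypes(x)[rows, .popCols(x, weed), drop = FALSE]
  gp <- genotypes(x)[rows, .popCols(x, progenitor), drop = FALSE]
  cw <- .siteCounts(gw)
  cp <- .siteCounts(gp)
  c1u <- cw$c1 + cp$c1
  nu <- cw$n + cp$n
  segU <- c1u > 0L & c1u < nu & nu >= 2L
  lTot <- sum(.classLength(lociInfo(x), siteClass))
  piSum <- sum(ifelse(segU, 2 * c1u * (nu - c1u) /
                        (nu * pmax(nu - 1L, 1L)), 0))
  part <- sitePartition(x, weed, progenitor, siteClass)
  segW <- cw$c1 > 0L & cw$c1 < cw$n & cw$n >= 2L
  segP <- cp$c1 > 0L & cp$c1 < cp$n & cp$n >= 2L
  e8 <- switch(eighth,
    sUnion = sum(segU),
    wattersonPooled = {
      nmax <- max(nu, 2L)
      aTab <- cumsum(1 / seq_len(nmax))
      sum(ifelse(segU, 1 / aTab[pmax(nu - 1L, 1L)], 0)) / lTot * 1000
    })
  out <- c(piSum / lTot * 1000, sum(segW), sum(segP),
           part$fixed, part$private1, part$private2, part$shared, e8)
  names(out) <- c("pooledPi", "sWeed", "sProgenitor", "fixed",
                  "privateWeed", "privateProgenitor", "shared", eighth)
  out
}
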