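# Fixture builders and independent brute-force oracles used across the
# suite.  The oracles deliberately take the slow road (explicit loops,
# per-pair enumeration, ANOVA sums of squares) so they share no code with
# the implementations they check.

# random SNPMatrix: two populations, arbitrary 0/1/NA patterns
randomSNPMatrix <- function(n1 = 5, n2 = 5, nLoci = 3, maxSites = 8,
                            lengthBp = 50, missingProb = 0) {
  nSamp <- n1 + n2
  ids <- c(sprintf("a%02d", seq_len(n1)), sprintf("b%02d", seq_len(n2)))
  pops <- c(rep("pop1", n1), rep("pop2", n2))
  geno <- list()
  si <- list()
  for (l in seq_len(nLoci)) {
    S <- sample.int(maxSites, 1)
    cols <- sort(sample.int(lengthBp, S)) - 1L
    for (k in seq_len(S)) {
      g <- rbinom(nSamp, 1L, runif(1, 0.1, 0.9))
      if (missingProb > 0)
        g[runif(nSamp) < missingProb] <- NA_integer_
      geno[[length(geno) + 1L]] <- g
      si[[length(si) + 1L]] <- data.frame(
        locus = sprintf("L%d", l), column = cols[k],
        siteClass = sample(c("noncoding", "synonymous", "nonsynonymous"),
                           1))
    }
  }
  SNPMatrix(do.call(rbind, geno), do.call(rbind, si),
            data.frame(sample = ids, population = pops),
            data.frame(locus = sprintf("L%d", seq_len(nLoci)),
                       lengthBp = lengthBp,
                       nNoncoding = 0L, nSynonymous = 0L,
                       nNonsynonymous = 0L, nUnclassified = lengthBp))
}

# a small complete-data SNPMatrix from an explicit genotype matrix
snpFromMatrix <- function(g, n1, lengthBp = 100, siteClass = "unclassified") {
  n <- ncol(g)
  ids <- sprintf("s%02d", seq_len(n))
  pops <- c(rep("pop1", n1), rep("pop2", n - n1))
  SNPMatrix(g,
            data.frame(locus = rep("L1", nrow(g)),
                       column = seq_len(nrow(g)) - 1L,
                       siteClass = rep(siteClass, nrow(g))),
            data.frame(sample = ids, population = pops),
            data.frame(locus = "L1", lengthBp = lengthBp,
                       nNoncoding = 0L, nSynonymous = 0L,
                       nNonsynonymous = 0L, nUnclassified = lengthBp))
}

# brute-force Watterson theta per kb for one population: explicit per-site
# loop with harmonic numbers computed by summation
oracleWatterson <- function(x, pop, lengthTotal) {
  g <- genotypes(x)[, populations(x) == pop, drop = FALSE]
  tot <- 0
  for (i in seq_len(nrow(g))) {
    v <- g[i, ]
    v <- v[!is.na(v)]
    if (length(v) >= 2 && length(unique(v)) == 2) {
      a <- 0
      for (k in seq_len(length(v) - 1)) a <- a + 1 / k
      tot <- tot + 1 / a
    }
  }
  tot / lengthTotal * 1000
}

# brute-force pi per kb: enumerate every haplotype pair per site
oraclePi <- function(x, pop, lengthTotal) {
  g <- genotypes(x)[, populations(x) == pop, drop = FALSE]
  tot <- 0
  for (i in seq_len(nrow(g))) {
    diffs <- 0
    pairs <- 0
    v <- g[i, ]
    for (a in seq_len(length(v) - 1)) {
      for (b in (a + 1):length(v)) {
        if (!is.na(v[a]) && !is.na(v[b])) {
          pairs <- pairs + 1
          if (v[a] != v[b]) diffs <- diffs + 1
        }
      }
    }
    if (pairs > 0) tot <- tot + diffs / pairs
  }
  tot / lengthTotal * 1000
}

# raw (unclamped) Weir-Cockerham estimate for one SNP via ANOVA sums of
# squares on the 0/1 haplotype values
oracleWcRaw <- function(v1, v2) {
  v1 <- v1[!is.na(v1)]
  v2 <- v2[!is.na(v2)]
  n1 <- length(v1)
  n2 <- length(v2)
  p1 <- mean(v1)
  p2 <- mean(v2)
  pbar <- mean(c(v1, v2))
  ssp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
  ssg <- sum((v1 - p1)^2) + sum((v2 - p2)^2)
  msp <- ssp / 1
  msg <- ssg / (n1 + n2 - 2)
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  denom <- msp + (nc - 1) * msg
  if (denom <= 0) return(NA_real_)
  (msp - msg) / denom
}

# per-site partition classification via table()
oraclePartition <- function(x, pop1, pop2) {
  g1 <- genotypes(x)[, populations(x) == pop1, drop = FALSE]
  g2 <- genotypes(x)[, populations(x) == pop2, drop = FALSE]
  out <- c(shared = 0L, private1 = 0L, private2 = 0L, fixed = 0L)
  for (i in seq_len(nrow(g1))) {
    a <- unique(stats::na.omit(g1[i, ]))
    b <- unique(stats::na.omit(g2[i, ]))
    if (length(a) == 0 || length(b) == 0) next
    if (length(a) == 2 && length(b) == 2)
      out["shared"] <- out["shared"] + 1L
    else if (length(a) == 2) out["private1"] <- out["private1"] + 1L
    else if (length(b) == 2) out["private2"] <- out["private2"] + 1L
    else if (a != b) out["fixed"] <- out["fixed"] + 1L
  }
  out
}

# brute-force biallelic column scan of alignments (independent of
# buildSNPMatrix): counts retained sites per the panel's filtering rules
oracleSnpCount <- function(alignments, panel, targeted) {
  count <- 0
  for (aln in alignments) {
    seqs <- strsplit(as.character(sequences(aln)), "")
    ids <- sampleIds(aln)
    inT <- populationOf(panel, ids) %in% targeted
    L <- lengthBp(aln)
    for (j in seq_len(L)) {
      col <- vapply(seqs, `[`, "", j)
      if (any(col == "-")) next
      obs <- col[inT]
      obs <- obs[obs %in% c("A", "C", "G", "T")]
      if (length(unique(obs)) == 2) count <- count + 1
    }
  }
  count
}

# deterministic small alignment pair for pipeline tests
writeToyPanel <- function(dir, nLoci = 2) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  toy <- makeToyAlignment(shared = 2, private1 = 1, private2 = 1,
                          fixed = 1, n1 = 4, n2 = 4, L = 40,
                          pop1 = "weed", pop2 = "progenitor")
  for (l in seq_len(nLoci)) {
    aln <- STSAlignment(sprintf("L%02d", l),
                        stats::setNames(
                          as.character(sequences(toy$alignment)),
                          sampleIds(toy$alignment)))
    writeSTSFasta(aln, file.path(dir, sprintf("L%02d.fasta", l)))
  }
  writePopulationPanel(toy$panel, file.path(dir, "popmap.tsv"))
  invisible(toy)
}
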