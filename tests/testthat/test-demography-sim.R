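test_that("reference size derivation inverts theta = 4 N mu", {
  ref <- deriveReference4N(7.787, mu = 1e-8)
  expect_equal(ref$nRef, 0.007787 / (4e-8), tolerance = 1e-12)
  expect_equal(ref$nRef, 194675, tolerance = 1e-6)
  expect_equal(deriveReference4N(4e-5 * 1000, mu = 1e-5)$nRef, 1)
  expect_error(deriveReference4N(0), "theta")
})

test_that("model conversion to coalescent units scales times and sizes", {
  sc <- ScalingConfig()  # N_ref = 194675
  m <- DemographicModel(etaC = 55000, etaB = 50, etaR = 5000,
                        tauS = 1000, tauF = 400, tauG = 100,
                        weedSelfing = TRUE)
  u <- toCoalescentUnits(m, sc)
  expect_equal(u$events$time[u$events$type == "size"][2],
               400 / (4 * 194675), tolerance = 1e-10)
  expect_equal(u$events$time[2], 5.137e-4, tolerance = 1e-3)
  # selfing halves weed-lineage sizes only
  expect_equal(unname(u$sizes["weed"]), 5000 / 194675 / 2)
  expect_equal(unname(u$sizes["progenitor"]), 55000 / 194675)
  mOut <- DemographicModel(etaC = 55000, etaB = 50, etaR = 5000,
                           tauS = 1000, tauF = 400, tauG = 100,
                           weedSelfing = FALSE)
  uOut <- toCoalescentUnits(mOut, sc)
  expect_equal(unname(uOut$sizes["weed"] / u$sizes["weed"]), 2)

  # split at the founding collapses the founder phase into the join
  mEq <- DemographicModel(etaC = 55000, etaB = 50, etaR = 5000,
                          tauS = 400, tauF = 400, tauG = 100)
  uEq <- toCoalescentUnits(mEq, sc)
  expect_equal(nrow(uEq$events), 2L)
  expect_equal(uEq$events$type, c("size", "join"))

  # invalid orderings are rejected at construction
  expect_error(DemographicModel(55000, 50, 5000, tauS = 100, tauF = 400,
                                tauG = 10), "ordering")
})

test_that("locus simulation is deterministic and honours theta = 0", {
  out1 <- simulateLocus(c(4, 4), theta = 3, rho = 3, sizes = c(1, 0.5),
                        events = data.frame(time = 0.01, type = "join",
                                            pop = 0, param = 1),
                        seed = 42)
  out2 <- simulateLocus(c(4, 4), theta = 3, rho = 3, sizes = c(1, 0.5),
                        events = data.frame(time = 0.01, type = "join",
                                            pop = 0, param = 1),
                        seed = 42)
  expect_identical(out1, out2)
  out3 <- simulateLocus(c(4, 4), theta = 3, rho = 3, sizes = c(1, 0.5),
                        events = data.frame(time = 0.01, type = "join",
                                            pop = 0, param = 1),
                        seed = 43)
  expect_false(identical(out1$positions, out3$positions))

  mono <- simulateLocus(10, theta = 0, rho = 0, seed = 1)
  expect_equal(nrow(mono$genotypes), 0L)
  expect_error(simulateLocus(5, theta = NaN, rho = 0), "finite")
  expect_true(all(diff(out1$positions) >= 0))
})

test_that("pairwise diversity matches the analytic expectation for n = 2", {
  theta <- 2.5
  pis <- vapply(seq_len(2000), function(i) {
    out <- simulateLocus(2, theta = theta, rho = 0, seed = 10000 + i)
    nrow(out$genotypes)  # with n = 2 every segregating site is a difference
  }, numeric(1))
  se <- stats::sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - theta), 3 * se)
})

test_that("datasets convert to SNP matrices and match the compiled summary path", {
  sc <- ScalingConfig()
  cfg <- CoalescentConfig(nWeed = 8, nProgenitor = 6, nLoci = 12)
  m <- shPresetModel(sc)
  ds <- simulateDataset(m, sc, cfg, seed = 21)
  snp <- asSNPMatrix(ds)
  expect_s4_class(snp, "SNPMatrix")
  expect_equal(ncol(snp), 14L)
  expect_equal(nrow(lociInfo(snp)), 12L)
  sv <- abcSummaryVector(snp, "weed", "progenitor")

  u <- toCoalescentUnits(m, sc)
  ev <- stsDemog:::.eventsToCpp(u$events)
  svC <- stsDemog:::.simSummaryCpp(8L, 6L, rep(500, 12), u$thetaPerSite,
                                   u$rhoOverTheta, as.numeric(u$sizes),
                                   ev$time, ev$type, ev$pop, ev$param, 21)
  expect_equal(unname(sv), unname(svC), tolerance = 1e-12)

  # same seed -> identical dataset; different locus streams differ
  ds2 <- simulateDataset(m, sc, cfg, seed = 21)
  expect_identical(ds@loci, ds2@loci)
})

test_that("summary statistics are invariant to relabelling within populations", {
  sc <- ScalingConfig()
  cfg <- CoalescentConfig(nWeed = 6, nProgenitor = 6, nLoci = 8)
  ds <- simulateDataset(bha1PresetModel(sc), sc, cfg, seed = 31)
  snp <- asSNPMatrix(ds)
  sv <- abcSummaryVector(snp, "weed", "progenitor")
  g <- genotypes(snp)
  set.seed(99)
  perm <- c(sample(1:6), 6 + sample(1:6))
  g2 <- g[, perm, drop = FALSE]
  colnames(g2) <- colnames(g)
  rd <- SummarizedExperiment::rowData(snp)
  snp2 <- SNPMatrix(g2, data.frame(locus = rd$locus, column = rd$column,
                                   siteClass = rd$siteClass),
                    data.frame(sample = colnames(g),
                               population = unname(populations(snp))),
                    lociInfo(snp))
  expect_equal(abcSummaryVector(snp2, "weed", "progenitor"), sv)
})

test_that("a split at time zero with equal sizes leaves no differentiation", {
  # two samples from what is effectively one panmictic population; the
  # zero-clamped estimator has a small positive O(1/n) bias, so samples
  # are large enough that the expectation is the dominant term
  fsts <- vapply(seq_len(200), function(i) {
    out <- simulateLocus(c(30, 30), theta = 4, rho = 4, sizes = c(1, 1),
                         events = data.frame(time = 1e-9, type = "join",
                                             pop = 0, param = 1),
                         seed = 5000 + i)
    g <- out$genotypes
    if (nrow(g) == 0) return(0)
    x <- snpFromMatrix(g, n1 = 30, lengthBp = 500)
    suppressWarnings(
      weirCockerhamFst(x, "pop1", "pop2")$grandMean)
  }, numeric(1))
  expect_lte(mean(fsts), 0.02)
})

test_that("expected weed diversity is non-increasing in bottleneck intensity", {
  sc <- ScalingConfig()
  cfg <- CoalescentConfig(nWeed = 10, nProgenitor = 4, nLoci = 6)
  meanPi <- vapply(c(0.5, 0.1, 0.01), function(bRatio) {
    etaC <- 0.3 * sc@nRef
    etaR <- 0.3 * etaC
    m <- DemographicModel(etaC = etaC, etaB = max(1, bRatio * etaR),
                          etaR = etaR, tauS = 300, tauF = 300, tauG = 100)
    mean(vapply(seq_len(300), function(r) {
      ds <- simulateDataset(m, sc, cfg, seed = 40000 + r)
      piTheta(asSNPMatrix(ds), "weed")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanPi) <= 0))
})

test_that("recombination does not change the expected site-frequency spectrum", {
  # mutations within one replicate share a genealogy and are correlated,
  # so the comparison is made at the replicate level: per frequency
  # class, a two-sample t-test across 1,000 independent replicates per
  # condition, Bonferroni-adjusted at family level 0.01
  n <- 10
  sfsMat <- function(rho, base, reps = 1000) {
    m <- matrix(0, reps, n - 1)
    for (i in seq_len(reps)) {
      out <- simulateLocus(n, theta = 4, rho = rho, seed = base + i)
      if (nrow(out$genotypes))
        m[i, ] <- tabulate(rowSums(out$genotypes), nbins = n - 1)
    }
    m
  }
  m0 <- sfsMat(0, 60000)
  m1 <- sfsMat(4, 70000)
  pv <- vapply(seq_len(n - 1), function(k)
    stats::t.test(m0[, k], m1[, k])$p.value, numeric(1))
  expect_gt(min(pv), 0.01 / (n - 1))
  # and the mean class counts match the neutral expectation theta / i
  z <- abs(colMeans(m0) - 4 / (1:9)) /
    (apply(m0, 2, stats::sd) / sqrt(nrow(m0)))
  expect_lt(max(z), 4)
})

test_that("estimates rescale to individuals and years", {
  sc <- ScalingConfig()
  u <- 1e-8 * 500
  expect_equal(rescaleEstimate(0.004, u, sc, "size"), 0.004 / (4 * u),
               tolerance = 1e-12)
  expect_equal(rescaleEstimate(0, u, sc, "time"), 0)
  expect_equal(rescaleEstimate(0.001, u, sc, "time"), 0.001 / u)
  expect_error(rescaleEstimate(0.1, 0, sc, "size"), "rate")
  expect_error(rescaleEstimate(0.1, u, sc, "volume"))
})
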