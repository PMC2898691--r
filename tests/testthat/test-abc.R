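test_that("prior grids honour each scenario's split-time rule", {
  res5 <- c(tauG = 5, tauF = 5, tauS = 5, etaC = 5)
  gF <- buildPriorGrid(scenarioSpec("founding_us"), res5)
  expect_true(all(gF@cells$tauS == gF@cells$tauF))
  expect_true(all(gF@cells$tauF > gF@cells$tauG))
  expect_true(all(gF@cells$tauF <= 400))

  gPre <- buildPriorGrid(scenarioSpec("pre_domestication"), res5)
  expect_true(all(gPre@cells$tauS >= 12000 & gPre@cells$tauS <= 50000))
  expect_equal(range(gPre@cells$tauS), c(12000, 50000))

  gPost <- buildPriorGrid(scenarioSpec("post_domestication"), res5)
  expect_true(all(gPost@cells$tauS > gPost@cells$tauF &
                    gPost@cells$tauS <= 12000))

  gDom <- buildPriorGrid(scenarioSpec("domestication"), res5)
  expect_true(all(gDom@cells$tauS == 12000))

  expect_gt(gF@nExcluded, 0)
  expect_error(buildPriorGrid(scenarioSpec("founding_us"),
                              c(tauG = 1, tauF = 5, tauS = 5, etaC = 5)),
               "resolution")
  expect_error(scenarioSpec("martian"), "unknown scenario")
})

test_that("parameter draws cover the priors and respect ordering", {
  g <- buildPriorGrid(scenarioSpec("post_domestication"),
                      c(tauG = 4, tauF = 4, tauS = 4, etaC = 4))
  p <- drawParameters(g, 500, seed = 8)
  expect_equal(nrow(p), 500)
  expect_true(all(p$tauF > p$tauG & p$tauS >= p$tauF))
  expect_true(all(p$etaRRatio > 0 & p$etaRRatio <= 1))
  expect_true(all(p$etaBRatio > 0 & p$etaBRatio <= 1))
  expect_identical(p, drawParameters(g, 500, seed = 8))
})

test_that("the inlined reference-table fast path matches the model-object path", {
  sc <- ScalingConfig()
  cfg <- CoalescentConfig(nWeed = 6, nProgenitor = 6, nLoci = 6)
  spec <- scenarioSpec("post_domestication")
  tab <- scenarioReferenceTable(spec, 5, sc, cfg, seed = 77)
  scSeed <- stsDemog:::deriveSeed(77, match("post_domestication",
                                            stsDemog:::.SCENARIOS))
  simSeeds <- stsDemog:::withSeed(stsDemog:::deriveSeed(scSeed, 2L),
                                  sample.int(2147483646L, 5,
                                             replace = TRUE))
  for (i in 1:5) {
    m <- stsDemog:::.paramsToModel(tab$params[i, ], sc@nRef, TRUE)
    u <- toCoalescentUnits(m, sc)
    ev <- stsDemog:::.eventsToCpp(u$events)
    svC <- stsDemog:::.simSummaryCpp(6L, 6L, rep(500, 6), u$thetaPerSite,
                                     u$rhoOverTheta, as.numeric(u$sizes),
                                     ev$time, ev$type, ev$pop, ev$param,
                                     as.numeric(simSeeds[i]))
    expect_equal(unname(tab$stats[i, ]), unname(svC), tolerance = 1e-12)
  }
})

test_that("acceptance behaves correctly at the tolerance extremes", {
  sc <- ScalingConfig()
  cfg <- CoalescentConfig(nWeed = 4, nProgenitor = 4, nLoci = 4)
  obs <- c(pooledPi = 1, sWeed = 5, sProgenitor = 50, fixed = 0,
           privateWeed = 1, privateProgenitor = 40, shared = 4,
           sUnion = 50)
  tabs <- lapply(c("founding_us", "pre_domestication"), function(s)
    scenarioReferenceTable(s, 60, sc, cfg, seed = 5))
  resInf <- runABC(obs, tolerance = Inf, seed = 5, refTables = tabs,
                   scaling = sc, config = cfg)
  expect_equal(unname(approximateLikelihood(resInf)), c(1, 1))
  res0 <- runABC(obs, tolerance = 0, seed = 5, refTables = tabs,
                 scaling = sc, config = cfg)
  expect_equal(unname(approximateLikelihood(res0)), c(0, 0))
  expect_error(runABC(c(obs[-1], NA), refTables = tabs, seed = 5),
               "finite")
})

test_that("approximate likelihood is non-decreasing in tolerance", {
  sc <- ScalingConfig()
  cfg <- CoalescentConfig(nWeed = 6, nProgenitor = 6, nLoci = 6)
  tabs <- lapply(c("founding_us", "post_domestication"), function(s)
    scenarioReferenceTable(s, 150, sc, cfg, seed = 6))
  ds <- simulateDataset(shPresetModel(sc), sc, cfg, seed = 66)
  obs <- abcSummaryVector(asSNPMatrix(ds), "weed", "progenitor")
  lls <- sapply(c(0.25, 0.5, 1, 2, 4, 8, Inf), function(tol) {
    approximateLikelihood(runABC(obs, tolerance = tol, seed = 6,
                                 refTables = tabs, scaling = sc,
                                 config = cfg))
  })
  expect_true(all(apply(lls, 1, function(v) all(diff(v) >= 0))))
  expect_equal(unname(lls[, ncol(lls)]), c(1, 1))
})

test_that("identical seeds give bit-identical results; scenario order is immaterial", {
  sc <- ScalingConfig()
  cfg <- CoalescentConfig(nWeed = 4, nProgenitor = 4, nLoci = 4)
  obs <- c(1, 5, 50, 0, 1, 40, 4, 50)
  r1 <- runABC(obs, c("founding_us", "pre_domestication"),
               simsPerScenario = 40, tolerance = 2, scaling = sc,
               config = cfg, seed = 12)
  r2 <- runABC(obs, c("founding_us", "pre_domestication"),
               simsPerScenario = 40, tolerance = 2, scaling = sc,
               config = cfg, seed = 12)
  expect_identical(r1@scenarios, r2@scenarios)
  r3 <- runABC(obs, c("pre_domestication", "founding_us"),
               simsPerScenario = 40, tolerance = 2, scaling = sc,
               config = cfg, seed = 12)
  expect_identical(r1@scenarios[["founding_us"]],
                   r3@scenarios[["founding_us"]])
  expect_identical(r1@scenarios[["pre_domestication"]],
                   r3@scenarios[["pre_domestication"]])
})

test_that("rejection on a one-statistic toy recovers the analytic posterior mean", {
  # prior mu ~ N(0, 1); one observation x ~ N(mu, 1); observed x = 1.
  # Analytic posterior mean = 0.5.  Rejection with a narrow window around
  # the observed value approximates it.
  set.seed(314)
  n <- 100000
  mu <- rnorm(n, 0, 1)
  x <- rnorm(n, mu, 1)
  rej <- abcReject(observed = 1, stats = matrix(x, ncol = 1),
                   tolerance = 0.05, scales = 1)
  expect_gt(sum(rej$accepted), 500)
  postMean <- mean(mu[rej$accepted])
  expect_lt(abs(postMean - 0.5) / 0.5, 0.05)
})

test_that("posterior densities integrate to one and track the prior under uniform acceptance", {
  sc <- ScalingConfig()
  cfg <- CoalescentConfig(nWeed = 4, nProgenitor = 4, nLoci = 2)
  tab <- scenarioReferenceTable("founding_us", 5000, sc, cfg, seed = 15)
  res <- runABC(c(1, 5, 50, 0, 1, 40, 4, 50), tolerance = Inf, seed = 15,
                refTables = list(tab), scaling = sc, config = cfg)
  # tolerance Inf accepts everything: posterior must equal the prior
  d <- posteriorDensity(res, "tauG", bins = 10)
  w <- diff(d$mid[1:2])
  expect_equal(sum(d$density) * w, 1, tolerance = 1e-9)
  expect_equal(d$density, d$prior)

  # thin to an independent uniform 5000-subset: KS distance to the prior
  # marginal stays small
  res2 <- res
  p <- res2@scenarios[["founding_us"]]$params
  set.seed(16)
  keep <- sample.int(nrow(p), 5000)
  p$accepted <- seq_len(nrow(p)) %in% keep
  res2@scenarios[["founding_us"]]$params <- p
  d2 <- posteriorDensity(res2, "etaRRatio", bins = 20)
  w2 <- diff(d2$mid[1:2])
  ks <- max(abs(cumsum(d2$density) * w2 - cumsum(d2$prior) * w2))
  expect_lt(ks, 0.1)

  expect_error(posteriorDensity(res, "notAParameter"), "unknown")
})

test_that("the likelihood surface localises bottleneck intensity", {
  sc <- ScalingConfig()
  cfg <- CoalescentConfig(nWeed = 4, nProgenitor = 4, nLoci = 2)
  tab <- scenarioReferenceTable("founding_us", 200, sc, cfg, seed = 18)
  res <- runABC(c(1, 5, 50, 0, 1, 40, 4, 50), tolerance = Inf, seed = 18,
                refTables = list(tab), scaling = sc, config = cfg)
  # force all accepted draws to no decline: mass must sit at intensity 0
  p <- res@scenarios[["founding_us"]]$params
  p$etaBRatio <- 1
  res@scenarios[["founding_us"]]$params <- p
  surf <- likelihoodSurface(res, bins = c(5, 5))
  expect_equal(unname(surf$mode["intensity"]), 10)  # lowest bin midpoint
  expect_false(surf$empty)

  # zero acceptances flag an empty surface
  res0 <- runABC(c(1, 5, 50, 0, 1, 40, 4, 50), tolerance = 0, seed = 18,
                 refTables = list(tab), scaling = sc, config = cfg)
  expect_warning(s0 <- likelihoodSurface(res0), "no accepted")
  expect_true(s0$empty)
  expect_warning(posteriorDensity(res0, "tauG"), "no accepted")
})
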