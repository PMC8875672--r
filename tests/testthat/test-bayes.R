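# Log-posterior, gradient contract, NUTS sampling, MAP estimation, and
# convergence diagnostics.

quickSettings <- function(seed = 1L)
  samplerSettings(chains = 2L, warmup = 300L, samples = 300L, seed = seed)

test_that("log-posterior equals hand-summed normal log-densities", {
  cov <- stdCov()
  # single observation: C at 1 h from the prior-typical amikacin patient
  sp <- deriveStructuralParams("amikacin",
                               c(CLslope = 0.815, CLnr = 0.0417, Vnr = 0.27),
                               cov)
  cpred <- conc1CmtInfusion(sp$cl, sp$v, doseFrame(0, 500, 1000), 1)
  y <- 30
  ds <- onePatientDataset("amikacin", eventFrame(500, 1000, 8, 1, y))
  sig <- 0.15 * cpred + 0.25
  om <- cvToOmega(c(0.4, 0.25, 0.3))
  byHand <- sum(dnorm(0, 0, om, log = TRUE)) +
    dnorm(y, cpred, sig, log = TRUE)
  expect_equal(logPosterior("amikacin", ds, eta = c(0, 0, 0)), byHand,
               tolerance = 1e-10)
  # sigma follows the prediction: C_pred 10 -> sigma 1.75
  expect_equal(0.15 * 10 + 0.25, 1.75)
})

test_that("gradient matches central finite differences", {
  cov <- stdCov()
  ds <- onePatientDataset("amikacin",
                          eventFrame(500, 1000, 8, c(1, 4, 8),
                                     c(31, 15, 6)))
  set.seed(5)
  for (rep in 1:3) {
    eta <- rnorm(3, 0, 0.3)
    g <- gradLogPosterior("amikacin", ds, eta = eta)
    fd <- sapply(1:3, function(k) {
      h <- 1e-5
      e1 <- eta; e2 <- eta
      e1[k] <- e1[k] + h; e2[k] <- e2[k] - h
      (logPosterior("amikacin", ds, eta = e1) -
         logPosterior("amikacin", ds, eta = e2)) / (2 * h)
    })
    expect_equal(g, fd, tolerance = 1e-4)
  }
  # phenytoin (ODE model) gradient contract, looser tolerance
  dsp <- onePatientDataset("phenytoin", eventFrame(100, 50, 8, 8, 1.8))
  eta <- c(0.2, -0.1, 0.15)
  g <- gradLogPosterior("phenytoin", dsp, eta = eta)
  fd <- sapply(1:3, function(k) {
    h <- 1e-5
    e1 <- eta; e2 <- eta
    e1[k] <- e1[k] + h; e2[k] <- e2[k] - h
    (logPosterior("phenytoin", dsp, eta = e1) -
       logPosterior("phenytoin", dsp, eta = e2)) / (2 * h)
  })
  expect_equal(g, fd, tolerance = 1e-3)
  # prior-only gradient is zero at the mode
  dsNoObs <- onePatientDataset("amikacin",
                               eventFrame(500, 1000, 8, numeric(0),
                                          numeric(0)))
  expect_equal(gradLogPosterior("amikacin", dsNoObs, eta = c(0, 0, 0)),
               c(0, 0, 0))
})

test_that("the prediction-dependent sigma contributes to the gradient", {
  # against a variant with sigma frozen at its eta-value: the analytic
  # gradient must differ because sigma moves with the prediction
  cov <- stdCov()
  ds <- onePatientDataset("amikacin", eventFrame(500, 1000, 8, 1, 30))
  eta <- c(0.3, 0, -0.2)
  g <- gradLogPosterior("amikacin", ds, eta = eta)
  # fixed-sigma gradient: d/deta of prior + 0.5 z^2 with constant sigma
  h <- 1e-6
  sigAt <- function(e) {
    v <- c(CLslope = 0.815, CLnr = 0.0417, Vnr = 0.27) * exp(e)
    sp <- deriveStructuralParams("amikacin", v, cov)
    cp <- conc1CmtInfusion(sp$cl, sp$v, doseFrame(0, 500, 1000), 1)
    list(cp = cp, sig = 0.15 * cp + 0.25)
  }
  s0 <- sigAt(eta)
  om <- cvToOmega(c(0.4, 0.25, 0.3))
  fixedSigLp <- function(e) {
    s <- sigAt(e)
    sum(dnorm(e, 0, om, log = TRUE)) + dnorm(30, s$cp, s0$sig, log = TRUE)
  }
  gFixed <- sapply(1:3, function(k) {
    e1 <- eta; e2 <- eta
    e1[k] <- e1[k] + h; e2[k] <- e2[k] - h
    (fixedSigLp(e1) - fixedSigLp(e2)) / (2 * h)
  })
  expect_gt(max(abs(g - gFixed)), 1e-3)
})

test_that("prior-only sampling recovers the lognormal prior", {
  fit <- hmcFit("amikacin", priorOnly = TRUE, settings = quickSettings(11))
  est <- TDMBayes:::.estimatedParams(defaultPrior("amikacin"))
  dg <- mcmcDiagnostics(fit)
  eta <- do.call(rbind, fit@etaDraws)
  for (k in seq_len(nrow(est))) {
    om <- cvToOmega(est$cv[k])
    se <- om / sqrt(dg$essBulk[k])
    ess2 <- TDMBayes:::.bulkEss(TDMBayes:::.rankNorm(
      sapply(fit@etaDraws, function(m) m[, k]^2)))
    expect_lt(abs(mean(eta[, k])), 3 * se)
    expect_lt(abs(sd(eta[, k]) - om), 3 * om / sqrt(2 * ess2))
  }
})

test_that("dense low-noise data recover the generating clearance", {
  cov <- stdCov()
  truth <- c(CLslope = 0.9, CLnr = 0.05, Vnr = 0.3)
  sp <- deriveStructuralParams("amikacin", truth, cov)
  tt <- seq(1, 8, by = 1)
  ctrue <- conc1CmtInfusion(sp$cl, sp$v, doseFrame(0, 500, 1000), tt)
  # nearly noise-free observations
  lowNoise <- defaultPrior("amikacin")
  lowNoise@cvAssay <- 1e-3
  lowNoise@sAssay <- 0.01
  ds <- onePatientDataset("amikacin", eventFrame(500, 1000, 8, tt, ctrue))
  fit <- suppressWarnings(hmcFit("amikacin", ds, prior = lowNoise,
                                 settings = quickSettings(3)))
  spHat <- deriveStructuralParams("amikacin",
                                  TDMBayes:::.fullValues(lowNoise, pointEstimate(fit)),
                                  cov)
  expect_lt(abs(spHat$cl - sp$cl) / sp$cl, 0.05)
})

test_that("sampling is reproducible for a fixed seed", {
  ds <- onePatientDataset("amikacin", eventFrame(500, 1000, 8, c(1, 8),
                                                 c(30, 6)))
  f1 <- hmcFit("amikacin", ds, settings = quickSettings(99))
  f2 <- hmcFit("amikacin", ds, settings = quickSettings(99))
  expect_identical(f1@etaDraws, f2@etaDraws)
  f3 <- hmcFit("amikacin", ds, settings = quickSettings(100))
  expect_false(identical(f1@etaDraws, f3@etaDraws))
  # draws serialize to CSV, one row per draw
  path <- tempfile(fileext = ".csv")
  writeDraws(f1, path)
  dr <- read.csv(path)
  expect_equal(nrow(dr), 2 * 300)
  expect_true(all(c("chain", "iteration", "CLslope") %in% names(dr)))
  unlink(path)
})

test_that("MAP with no observations returns the prior means exactly", {
  ds <- onePatientDataset("amikacin",
                          eventFrame(500, 1000, 8, numeric(0), numeric(0)))
  m <- mapFit("amikacin", ds)
  expect_identical(unname(pointEstimate(m)), c(0.815, 0.0417, 0.27))
  expect_equal(m@phi, 0)
})

test_that("MAP matches a dense grid-search oracle on a single free parameter", {
  # shrink two amikacin CVs to (effectively) pin those parameters, leaving
  # CLslope as the single free coordinate
  pr <- defaultPrior("amikacin")
  pr@parameters$cv[pr@parameters$name %in% c("CLnr", "Vnr")] <- 1e-3
  ds <- onePatientDataset("amikacin", eventFrame(500, 1000, 8, 8, 5.2))
  m <- mapFit("amikacin", ds, prior = pr, starts = 3L)
  om <- cvToOmega(0.4)
  grid <- seq(-4 * om, 4 * om, length.out = 4001)
  phiGrid <- vapply(grid, function(e)
    mapObjective("amikacin", ds, prior = pr, eta = c(e, 0, 0)), numeric(1))
  etaStar <- grid[which.min(phiGrid)]
  expect_lt(abs(m@eta[["CLslope"]] - etaStar), diff(grid[1:2]) * 1.01)
  expect_lte(m@phi, min(phiGrid) + 1e-8)
})

test_that("Phi at the optimum never exceeds Phi at the prior means", {
  ds <- onePatientDataset("vancomycin",
                          eventFrame(1000, 500, 12, c(2, 12), c(28, 8)))
  m <- mapFit("vancomycin", ds, starts = 3L)
  expect_lte(m@phi, mapObjective("vancomycin", ds, eta = rep(0, 5)))
})

test_that("diagnostics behave on synthetic draw sets", {
  set.seed(42)
  # iid normal chains: R-hat ~ 1, ESS <= total and large
  chains <- lapply(1:4, function(i)
    matrix(rnorm(500 * 2), 500, 2, dimnames = list(NULL, c("a", "b"))))
  d <- mcmcDiagnostics(chains)
  expect_true(all(abs(d$rhat - 1) < 0.02))
  expect_true(all(d$essBulk <= 4 * 500 + 1e-9))
  expect_true(all(d$essBulk > 1000))
  # constant chains: degenerate variance flagged as NA
  const <- lapply(1:4, function(i)
    matrix(1, 100, 1, dimnames = list(NULL, "a")))
  dc <- mcmcDiagnostics(const)
  expect_true(is.na(dc$rhat))
  # far-apart chains: R-hat clearly above 1
  apart <- lapply(1:4, function(i)
    matrix(rnorm(200, mean = i * 5), 200, 1, dimnames = list(NULL, "a")))
  da <- mcmcDiagnostics(apart)
  expect_gt(da$rhat, 1.5)
})

test_that("non-convergence is flagged, not raised", {
  ds <- onePatientDataset("amikacin", eventFrame(500, 1000, 8, c(1, 8),
                                                 c(30, 6)))
  # absurdly short run with almost no adaptation often trips R-hat; either
  # way the call must return a PosteriorResult, never error
  fit <- suppressWarnings(
    hmcFit("amikacin", ds,
           settings = samplerSettings(chains = 2L, warmup = 10L,
                                      samples = 10L, seed = 2)))
  expect_s4_class(fit, "PosteriorResult")
  expect_type(fit@converged, "logical")
})
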