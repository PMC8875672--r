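# Virtual cohort: demographics, parameter sampling, residual simulation,
# external models, scenario enumeration.

test_that("demographics follow the stated distributions and truncation", {
  d <- generateDemographics(1000, seed = 7)
  expect_equal(nrow(d), 1000)
  expect_lt(abs(mean(d$height) - 165.1), 3 * 8.7 / sqrt(1000))
  expect_lt(abs(mean(d$weight) - 65.1), 3 * 10.2 / sqrt(1000))
  expect_lt(abs(mean(d$age) - 50.2), 3 * 17.1 / sqrt(1000))
  expect_true(all(d$height >= 140 & d$height <= 200))
  expect_true(all(d$weight >= 35 & d$weight <= 120))
  expect_true(all(d$age >= 18 & d$age <= 90))
  expect_true(all(d$scr >= 0.4 & d$scr <= 3.0))
  expect_true(all(d$sex %in% 0:1))
  expect_identical(d, generateDemographics(1000, seed = 7))
  expect_error(generateDemographics(0), ">= 1")
})

test_that("individual parameters are bounded lognormal draws", {
  pr <- defaultPrior("amikacin")
  p <- priorParameters(pr)
  draws <- replicate(400, sampleIndividualParams(pr, seed = sample.int(1e6, 1))@values)
  for (k in which(!p$fixed)) {
    expect_true(all(draws[p$name[k], ] >= p$lower[k] &
                    draws[p$name[k], ] <= p$upper[k]))
  }
  # fixed parameters are copied exactly
  php <- sampleIndividualParams(defaultPrior("phenytoin"), seed = 3)
  expect_equal(php@values[["CLslope"]], 0.01)
  expect_equal(php@values[["F"]], 0.92)
  # lognormal median equals the typical value (Monte Carlo)
  set.seed(12)
  med <- median(draws["CLslope", ])
  expect_lt(abs(med - 0.815) / 0.815, 0.1)
})

test_that("residual simulation follows sigma = cv*C + s and stays positive", {
  # frozen sigma values
  expect_equal(0.15 * 10 + 0.25, 1.75)
  expect_equal(0.1 * 2 + 1.0, 1.2)
  set.seed(9)
  obs <- simulateObservations(rep(10, 4000),
                              list(cvAssay = 0.15, sAssay = 0.25), seed = 5)
  expect_true(all(obs > 0))
  expect_lt(abs(sd(obs) - 1.75), 0.1)
  expect_lt(abs(mean(obs) - 10), 0.1)
  # degenerate noise returns the truth
  tiny <- simulateObservations(c(5, 10), list(cvAssay = 1e-12,
                                              sAssay = 1e-12), seed = 1)
  expect_equal(tiny, c(5, 10), tolerance = 1e-9)
})

test_that("all 32 scenarios enumerate exactly once with the printed regimens", {
  tab <- scenarioTable()
  expect_equal(nrow(tab), 32)
  expect_equal(anyDuplicated(tab[, c("drug", "doseCase", "samplingSet")]), 0L)
  a <- scenarioFor("amikacin", "single", "peak")
  expect_equal(a$samplingTimes, 1)
  expect_equal(c(a$amt, a$rate, a$ii), c(500, 1000, 8))
  expect_equal(scenarioFor("amikacin", "single", "q1h")$samplingTimes,
               as.numeric(1:8))
  expect_equal(scenarioFor("vancomycin", "steady", "peak_trough")$samplingTimes,
               c(2, 12))
  expect_equal(scenarioFor("phenytoin", "single", "trough")$samplingTimes, 8)
  expect_equal(scenarioFor("theophylline", "single", "peak")$samplingTimes, 4)
})

test_that("external models reproduce their typical values", {
  covTypical <- list(weight = 57, height = 165.1, age = 50, sex = 0L,
                     scr = 1.0)
  # vancomycin at CrCl 72 and eta 0: CL = 2.82 L/h
  ext <- externalTruth("vancomycin", stdCov(), seed = 1)
  expect_true(all(c("CL", "VC", "Q", "VP") %in% names(ext@values)))
  expect_equal(ext@values[["VC"]], 31.8)
  expect_equal(ext@values[["Q"]], 11.7)
  # eta = 0 typical values via many-draw medians
  set.seed(31)
  cls <- replicate(600, externalTruth("vancomycin",
                                      stdCov(), seed = sample.int(1e6, 1))@values[["CL"]])
  dc <- TDMBayes:::.derivedCov(stdCov())
  expect_lt(abs(median(cls) - 2.82 * (dc$crclMlMin / 72)^0.836) /
            (2.82 * (dc$crclMlMin / 72)^0.836), 0.15)
  # theophylline elderly factor and fixed ka
  old <- stdCov(); old$age <- 70
  young <- stdCov(); young$age <- 40
  set.seed(8)
  clOld <- median(replicate(400, externalTruth("theophylline", old,
                                               seed = sample.int(1e6, 1))@values[["CL"]]))
  clYoung <- median(replicate(400, externalTruth("theophylline", young,
                                                 seed = sample.int(1e6, 1))@values[["CL"]]))
  expect_lt(abs(clOld / clYoung - 0.876), 0.08)
  expect_equal(externalTruth("theophylline", old, seed = 2)@values[["ka"]],
               0.0773)
  # amikacin at the normalizing covariates: CL = 1.40 + 1.42 at eta 0
  covAm <- stdCov()
  dcAm <- TDMBayes:::.derivedCov(covAm)
  set.seed(13)
  clsAm <- replicate(600, externalTruth("amikacin", covAm,
                                        seed = sample.int(1e6, 1))@values[["CL"]])
  expect_lt(abs(median(clsAm) - (1.40 + 1.42 * dcAm$crclMlMin / 71.2)) /
            (1.40 + 1.42 * dcAm$crclMlMin / 71.2), 0.1)
})

test_that("scenario datasets carry observations, truth, and reproducibility", {
  sc <- scenarioFor("amikacin", "single", "peak_trough")
  sim <- buildScenarioDataset(sc, 5, "internal", seed = 17)
  expect_equal(nPatients(sim$dataset), 5L)
  ev <- tdmEvents(sim$dataset, 1)
  expect_equal(ev$time[ev$evid == 0L], c(1, 8))
  expect_equal(dim(sim$truth$trueConc), c(5, 2))
  expect_true(all(sim$truth$trueConc > 0))
  sim2 <- buildScenarioDataset(sc, 5, "internal", seed = 17)
  expect_equal(sim$dataset@events$dv, sim2$dataset@events$dv)
  # external source uses the literature parameterization
  simE <- buildScenarioDataset(sc, 3, "external", seed = 17)
  expect_true("CL" %in% names(simE$truth$params[[1]]@values))
})

test_that("cohort means of the clearance components match the study scale", {
  # products CLnr*LBW and CLslope*CrCl over 1000 patients, in mL/min
  d <- generateDemographics(1000, seed = 5)
  pr <- defaultPrior("amikacin")
  set.seed(6)
  clnrLbw <- clsCrcl <- numeric(1000)
  for (i in 1:1000) {
    ip <- TDMBayes:::.samplePriorOnce(pr)
    dc <- TDMBayes:::.derivedCov(as.list(d[i, ]))
    clnrLbw[i] <- ip@values[["CLnr"]] * dc$lbw
    clsCrcl[i] <- ip@values[["CLslope"]] * dc$crclMlMin
  }
  expect_lt(abs(mean(clnrLbw) - 2.5) / 2.5, 0.25)
  expect_lt(abs(mean(clsCrcl) - 45.3) / 45.3, 0.25)
})

test_that("noise-free generation is recovered by the full pipeline", {
  # inter-individual variability and residual noise switched off: the fit
  # must recover the typical patient to sampler tolerance
  cov <- stdCov()
  p <- c(CLslope = 0.815, CLnr = 0.0417, Vnr = 0.27)
  sp <- deriveStructuralParams("amikacin", p, cov)
  tt <- 1:8
  ctrue <- conc1CmtInfusion(sp$cl, sp$v, doseFrame(0, 500, 1000), tt)
  ds <- onePatientDataset("amikacin", eventFrame(500, 1000, 8, tt, ctrue))
  m <- mapFit("amikacin", ds)
  expect_equal(unname(pointEstimate(m)), unname(p), tolerance = 0.02)
})
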