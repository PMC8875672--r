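# Virtual cohort: demographics, true individual parameters, true and
# observed concentrations for the internal (estimation-prior) and external
# (literature) population models under the standard validation scenarios.

#' Validation scenario table
#'
#' The full grid of 32 scenarios: four drugs x two dose cases (single
#' dose, steady state) x four sampling sets (peak, trough, peak+trough,
#' hourly), with the standard regimens (amikacin 500 mg infused at
#' 1000 mg/h q8h; vancomycin 1000 mg at 500 mg/h q12h; theophylline
#' 200 mg oral q12h; phenytoin 100 mg delivered zero-order at 50 mg/h q8h).
#'
#' @return data.frame with one row per scenario; the `samplingTimes`
#'   column is a list of numeric vectors.
#' @export
scenarioTable <- function() {
  reg <- list(
    amikacin = list(amt = 500, rate = 1000, ii = 8,
                    peak = 1, trough = 8, q1h = 1:8),
    vancomycin = list(amt = 1000, rate = 500, ii = 12,
                      peak = 2, trough = 12, q1h = 1:12),
    theophylline = list(amt = 200, rate = 0, ii = 12,
                        peak = 4, trough = 12, q1h = 1:12),
    phenytoin = list(amt = 100, rate = 50, ii = 8,
                     peak = 2, trough = 8, q1h = 1:8))
  sets <- c("peak", "trough", "peak_trough", "q1h")
  rows <- list()
  for (d in .drugs) for (case in c("single", "steady")) for (s in sets) {
    r <- reg[[d]]
    tt <- switch(s, peak = r$peak, trough = r$trough,
                 peak_trough = c(r$peak, r$trough), q1h = as.numeric(r$q1h))
    rows[[length(rows) + 1]] <-
      data.frame(drug = d, doseCase = case, samplingSet = s,
                 amt = r$amt, rate = r$rate, ii = r$ii,
                 stringsAsFactors = FALSE)
    rows[[length(rows)]]$samplingTimes <- list(tt)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Look up one scenario
#'
#' @param drug drug name.
#' @param doseCase "single" or "steady".
#' @param samplingSet "peak", "trough", "peak_trough", or "q1h".
#' @return one-row scenario (as a list).
#' @export
scenarioFor <- function(drug, doseCase, samplingSet) {
  d <- .matchDrug(drug)
  tab <- scenarioTable()
  i <- which(tab$drug == d & tab$doseCase == doseCase &
             tab$samplingSet == samplingSet)
  if (!length(i)) stop("unknown scenario", call. = FALSE)
  r <- as.list(tab[i, c("drug", "doseCase", "samplingSet", "amt", "rate",
                        "ii")])
  r$samplingTimes <- tab$samplingTimes[[i]]
  r
}

#' Generate virtual-patient demographics
#'
#' Height ~ N(165.1, 8.7^2) cm truncated to \[140, 200\], weight ~
#' N(65.1, 10.2^2) kg truncated to \[35, 120\], age ~ N(50.2, 17.1^2) y
#' truncated to \[18, 90\] (truncation by resampling); sex Bernoulli(0.5)
#' (0 = male); serum creatinine lognormal with median 1.1 mg/dL and
#' log-SD 0.2, truncated to \[0.4, 3.0\].
#'
#' @param n number of patients (>= 1).
#' @param seed RNG seed.
#' @return data.frame with id, weight, height, age, sex, scr.
#' @export
generateDemographics <- function(n, seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  rtnorm <- function(n, mean, sd, lo, hi) {
    x <- rnorm(n, mean, sd)
    while (any(bad <- x < lo | x > hi))
      x[bad] <- rnorm(sum(bad), mean, sd)
    x
  }
  .withSeed(seed, {
    height <- rtnorm(n, 165.1, 8.7, 140, 200)
    weight <- rtnorm(n, 65.1, 10.2, 35, 120)
    age <- rtnorm(n, 50.2, 17.1, 18, 90)
    sex <- rbinom(n, 1, 0.5)
    scr <- rlnorm(n, log(1.1), 0.2)
    while (any(bad <- scr < 0.4 | scr > 3.0))
      scr[bad] <- rlnorm(sum(bad), log(1.1), 0.2)
    data.frame(id = seq_len(n), weight = weight, height = height, age = age,
               sex = sex, scr = scr)
  })
}

#' Sample individual parameters from a population prior
#'
#' Each estimated parameter is Mean * e^eta with eta ~ N(0, omega^2),
#' omega = [cvToOmega()] of the printed CV, rejected and resampled until
#' the natural value lies within the printed bounds; fixed parameters are
#' copied unchanged.
#'
#' @param prior a [PriorSpec-class].
#' @param seed RNG seed.
#' @return an [IndividualParams-class].
#' @export
sampleIndividualParams <- function(prior, seed = 1L) {
  .withSeed(seed, .samplePriorOnce(prior))
}

.samplePriorOnce <- function(prior) {
  p <- prior@parameters
  vals <- setNames(p$mean, p$name)
  etas <- c()
  for (i in which(!p$fixed)) {
    w <- cvToOmega(p$cv[i])
    ok <- FALSE
    for (tries in seq_len(1000)) {
      e <- rnorm(1, 0, w)
      v <- p$mean[i] * exp(e)
      if ((!is.finite(p$lower[i]) || v >= p$lower[i]) &&
          (!is.finite(p$upper[i]) || v <= p$upper[i])) { ok <- TRUE; break }
    }
    if (!ok) stop("prior configuration error: bounds reject all draws for ",
                  p$name[i], call. = FALSE)
    vals[p$name[i]] <- v
    etas[p$name[i]] <- e
  }
  new("IndividualParams", drug = prior@drug, values = vals, eta = etas)
}

#' Add residual assay error to true concentrations
#'
#' Cobs = Ctrue + eps with eps ~ N(0, sigma^2), sigma = cv_assay * Ctrue +
#' s_assay; eps is redrawn until Cobs > 0 (assays report positive values).
#'
#' @param trueConc noise-free concentrations (mg/L, >= 0).
#' @param error list with cvAssay and sAssay (see [errorModel()]).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return observed concentrations (mg/L, > 0).
#' @export
simulateObservations <- function(trueConc, error, seed = NULL) {
  draw <- function() {
    sig <- error$cvAssay * trueConc + error$sAssay
    obs <- rnorm(length(trueConc), trueConc, sig)
    while (any(bad <- obs <= 0))
      obs[bad] <- rnorm(sum(bad), trueConc[bad], sig[bad])
    obs
  }
  if (is.null(seed)) draw() else .withSeed(seed, draw())
}

# Observation times and simulation layout for a scenario.
# Returns absolute observation times and the dose schedule used for truth.
.scenarioLayout <- function(sc) {
  if (sc$doseCase == "single") {
    list(obsTimes = sc$samplingTimes, ss = FALSE,
         doses = data.frame(time = 0, amt = sc$amt, rate = sc$rate),
         addl = 0L)
  } else if (sc$drug == "phenytoin") {
    list(obsTimes = 19 * sc$ii + sc$samplingTimes, ss = FALSE,
         doses = data.frame(time = (0:19) * sc$ii, amt = sc$amt,
                            rate = sc$rate),
         addl = 19L)
  } else {
    list(obsTimes = sc$samplingTimes, ss = TRUE,
         doses = data.frame(time = 0, amt = sc$amt, rate = sc$rate),
         addl = 0L)
  }
}

#' Build a simulated estimation dataset for one scenario
#'
#' Generates demographics, true individual parameters (from the estimation
#' prior or the external literature model), noise-free true concentrations
#' at the scenario's sampling times, and observed concentrations with
#' residual error. Steady-state sampling uses the analytic accumulation
#' for the linear drugs and the 20th consecutive dose for phenytoin.
#'
#' @param scenario a [scenarioFor()] record.
#' @param n number of virtual patients.
#' @param modelSource "internal" (estimation prior) or "external"
#'   (literature model).
#' @param seed RNG seed.
#' @return list with `dataset` (a [TDMDataset-class] carrying the observed
#'   concentrations) and `truth` (list with params, trueConc, cov, ss).
#' @export
buildScenarioDataset <- function(scenario, n,
                                 modelSource = c("internal", "external"),
                                 seed = 1L) {
  modelSource <- match.arg(modelSource)
  sc <- scenario
  prior <- defaultPrior(sc$drug)
  lay <- .scenarioLayout(sc)
  cov <- generateDemographics(n, seed = seed)
  .withSeed(as.numeric(seed) + 104729, {
    params <- vector("list", n)
    trueConc <- matrix(0, n, length(lay$obsTimes))
    obsConc <- matrix(0, n, length(lay$obsTimes))
    for (i in seq_len(n)) {
      ci <- as.list(cov[i, ])
      if (modelSource == "internal") {
        ip <- .samplePriorOnce(prior)
        sm <- .structuralModel(sc$drug, ip@values, ci)
      } else {
        ip <- .externalTruthOnce(sc$drug, ci)
        sm <- .externalStructural(sc$drug, ip@values)
      }
      params[[i]] <- ip
      trueConc[i, ] <- .kernelConc(sm, lay$doses, lay$obsTimes,
                                   ss = lay$ss, tau = sc$ii)
      obsConc[i, ] <- if (modelSource == "internal")
        simulateObservations(trueConc[i, ], errorModel(prior))
      else .externalObserve(sc$drug, trueConc[i, ])
    }
    events <- do.call(rbind, lapply(seq_len(n), function(i) {
      rbind(data.frame(id = i, time = 0, evid = 1L, amt = sc$amt, cmt = 1L,
                       rate = sc$rate, ii = sc$ii, addl = lay$addl,
                       dv = NA_real_),
            data.frame(id = i, time = lay$obsTimes, evid = 0L,
                       amt = NA_real_, cmt = 1L, rate = 0, ii = NA_real_,
                       addl = NA_real_, dv = obsConc[i, ]))
    }))
    list(dataset = tdmDataset(sc$drug, cov, events),
         truth = list(params = params, trueConc = trueConc, cov = cov,
                      ss = lay$ss, scenario = sc))
  })
}
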