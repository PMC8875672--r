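# Validation harness: runs the simulation studies (internal, external,
# MAP comparison) and scores concentration and parameter recovery by mean
# percentage error (MPE) and root mean squared error (RMSE).

#' Concentration-scoring times for a scenario
#'
#' Predictions are scored one dosing interval after the observations:
#' samples drawn after dose 1 are scored at the same offsets after dose 2;
#' steady-state samples are scored within the following interval (for the
#' linear drugs the periodic steady-state profile repeats, so only the
#' offset within the interval matters); phenytoin steady state is observed
#' within the 20th dosing interval and scored within the 21st.
#'
#' @param scenario a [scenarioFor()] record.
#' @return absolute evaluation times (h from the first dose).
#' @export
evaluationTimes <- function(scenario) {
  if (scenario$doseCase == "steady" && scenario$drug == "phenytoin")
    20 * scenario$ii + scenario$samplingTimes
  else
    scenario$ii + scenario$samplingTimes
}

#' MPE and RMSE of estimates against truth
#'
#' MPE = mean((est - true)/true) x 100; RMSE = sqrt(mean((est - true)^2)).
#' Elements with zero truth are excluded from the MPE (with a warning) but
#' kept in the RMSE.
#'
#' @param est estimated values.
#' @param truth true values (same length).
#' @return list with mpe (percent), rmse (units of the inputs), n.
#' @export
computeMetrics <- function(est, truth) {
  stopifnot(length(est) == length(truth))
  nz <- truth != 0
  if (any(!nz))
    warning(sum(!nz), " zero-truth element(s) excluded from MPE",
            call. = FALSE)
  list(mpe = mean((est[nz] - truth[nz]) / truth[nz]) * 100,
       rmse = sqrt(mean((est - truth)^2)),
       n = length(est))
}

# Predicted concentrations at the evaluation times from a structural-model
# record, honoring the scenario's dosing layout.
.predictAtEval <- function(sm, sc, evalT, odeStep = 0.005) {
  if (sc$doseCase == "single") {
    doses <- data.frame(time = c(0, sc$ii), amt = sc$amt, rate = sc$rate)
    .kernelConc(sm, doses, evalT, ss = FALSE, odeStep = odeStep)
  } else if (sm$model == 4L) {
    doses <- data.frame(time = (0:20) * sc$ii, amt = sc$amt, rate = sc$rate)
    .kernelConc(sm, doses, evalT, ss = FALSE, odeStep = odeStep)
  } else {
    doses <- data.frame(time = 0, amt = sc$amt, rate = sc$rate)
    .kernelConc(sm, doses, evalT, ss = TRUE, tau = sc$ii)
  }
}

# Map internal-estimate or external-truth parameter values onto the shared
# comparable quantities for parameter-level scoring.

#' Comparable parameter set for external validation scoring
#'
#' Maps internal-parameterization estimates (CLslope/CLnr/Vnr/...) and
#' external-model truths onto the shared quantities: CL (L/h) and V (L)
#' for the linear drugs (vancomycin: central volume; its peripheral
#' parameters have no faithful mapping and are excluded), and Vmax (mg/d),
#' km (mg/L), V (L) for phenytoin.
#'
#' @param drug drug name.
#' @param params an [IndividualParams-class] or named value vector (either
#'   parameterization).
#' @param cov covariate list/row.
#' @return named numeric vector of comparable quantities.
#' @export
recalcExternalParams <- function(drug, params, cov) {
  d <- .matchDrug(drug)
  v <- if (is(params, "IndividualParams")) params@values else params
  internal <- any(c("CLslope", "CLnr", "Vnr") %in% names(v))
  if (internal) {
    sp <- deriveStructuralParams(d, v, cov)
    if (d == "phenytoin")
      c(Vmax = unname(v[["Vmax"]]), km = unname(v[["km"]]), V = unname(sp$v))
    else c(CL = unname(sp$cl), V = unname(sp$v))
  } else {
    if (d == "phenytoin")
      c(Vmax = unname(v[["Vmax"]]), km = unname(v[["km"]]), V = unname(v[["V"]]))
    else if (d == "vancomycin")
      c(CL = unname(v[["CL"]]), V = unname(v[["VC"]]))
    else c(CL = unname(v[["CL"]]), V = unname(v[["V"]]))
  }
}

#' Run a simulation-based validation study
#'
#' For each requested scenario: simulates `n` virtual patients (internal
#' prior model or external literature model), fits each patient with the
#' internal prior (HMC or MAP), predicts concentrations one dosing
#' interval after the sampling times from the estimated parameters,
#' computes the noise-free true concentrations at the same times from the
#' true parameters, and scores MPE/RMSE over all patients and times.
#' Parameter-level metrics are scored directly (internal) or on the
#' recalculated comparable quantities (external). Non-converged fits are
#' excluded and counted.
#'
#' The virtual-patient data for a scenario depend only on `seed` and the
#' scenario, never on the estimator, so HMC and MAP runs over the same
#' grid see identical patients.
#'
#' @param drugs drug names to include.
#' @param doseCases subset of c("single", "steady").
#' @param samplingSets subset of c("peak", "trough", "peak_trough", "q1h").
#' @param n virtual patients per scenario.
#' @param estimator "hmc" or "map".
#' @param source "internal" or "external".
#' @param settings a [SamplerSettings-class] (HMC).
#' @param starts MAP optimization starts.
#' @param seed base RNG seed.
#' @param odeStep in-sampler phenytoin integration step (h).
#' @param verbose print per-scenario progress.
#' @return data.frame with one row per scenario (concMpe, concRmse,
#'   nonConverged, ...); per-parameter metrics are attached as the
#'   "paramMetrics" attribute (a named list of data.frames).
#' @export
runValidation <- function(drugs = drugList(),
                          doseCases = c("single", "steady"),
                          samplingSets = c("peak", "trough", "peak_trough", "q1h"),
                          n = 200,
                          estimator = c("hmc", "map"),
                          source = c("internal", "external"),
                          settings = samplerSettings(preset = "reduced"),
                          starts = 3L, seed = 1L, odeStep = 0.1,
                          verbose = FALSE) {
  estimator <- match.arg(estimator)
  source <- match.arg(source)
  fullTab <- scenarioTable()
  rows <- list()
  paramMetrics <- list()
  for (d in drugs) for (case in doseCases) for (sset in samplingSets) {
    sc <- scenarioFor(d, case, sset)
    sIdx <- which(fullTab$drug == sc$drug & fullTab$doseCase == case &
                  fullTab$samplingSet == sset)
    scSeed <- (as.numeric(seed) * 131 + sIdx * 100003 +
               ifelse(source == "external", 7, 0)) %% 2147483647
    sim <- buildScenarioDataset(sc, n, modelSource = source, seed = scSeed)
    prior <- defaultPrior(d)
    evalT <- evaluationTimes(sc)
    lay <- .scenarioLayout(sc)
    ssFit <- lay$ss
    estConc <- trueConc <- matrix(NA_real_, n, length(evalT))
    estPar <- truePar <- NULL
    nonConv <- 0L
    for (i in seq_len(n)) {
      pd <- .patientData(sim$dataset, i)
      fit <- tryCatch({
        if (estimator == "hmc") {
          st <- samplerSettings(chains = settings@chains,
                                warmup = settings@warmup,
                                samples = settings@samples,
                                seed = as.integer((scSeed + i * 97) %% 2147483647),
                                targetAccept = settings@targetAccept,
                                maxTreedepth = settings@maxTreedepth)
          suppressWarnings(hmcFit(d, pd, prior, st, ss = ssFit,
                                  odeStep = odeStep))
        } else {
          mapFit(d, pd, prior, starts = starts, ss = ssFit,
                 seed = as.integer((scSeed + i * 97) %% 2147483647),
                 odeStep = odeStep)
        }
      }, error = function(e) NULL)
      if (is.null(fit) ||
          (is(fit, "PosteriorResult") && !fit@converged)) {
        nonConv <- nonConv + 1L
        next
      }
      est <- pointEstimate(fit)
      ci <- as.list(sim$truth$cov[i, ])
      smEst <- .structuralModel(d, .fullValues(prior, est), ci)
      estConc[i, ] <- .predictAtEval(smEst, sc, evalT)
      tp <- sim$truth$params[[i]]
      smTrue <- if (source == "internal")
        .structuralModel(d, tp@values, ci) else .externalStructural(d, tp@values)
      trueConc[i, ] <- .predictAtEval(smTrue, sc, evalT)
      if (source == "internal") {
        ep <- est
        tpv <- tp@values[names(est)]
      } else {
        ep <- recalcExternalParams(d, .fullValues(prior, est), ci)
        tpv <- recalcExternalParams(d, tp@values, ci)
      }
      estPar <- rbind(estPar, ep)
      truePar <- rbind(truePar, tpv)
    }
    ok <- !is.na(estConc[, 1])
    if (!any(ok)) stop("all fits failed for scenario ", d, "/", case, "/",
                       sset, call. = FALSE)
    cm <- computeMetrics(as.numeric(estConc[ok, , drop = FALSE]),
                         as.numeric(trueConc[ok, , drop = FALSE]))
    pm <- do.call(rbind, lapply(seq_len(ncol(estPar)), function(k) {
      m <- computeMetrics(estPar[, k], truePar[, k])
      data.frame(parameter = colnames(estPar)[k], mpe = m$mpe, rmse = m$rmse)
    }))
    key <- paste(d, case, sset, sep = ".")
    paramMetrics[[key]] <- pm
    rows[[key]] <- data.frame(drug = d, doseCase = case, samplingSet = sset,
                              estimator = estimator, source = source,
                              n = sum(ok), nonConverged = nonConv,
                              concMpe = cm$mpe, concRmse = cm$rmse,
                              stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("%-12s %-6s %-11s MPE %7.2f%%  RMSE %6.3f  (excl %d)",
                      d, case, sset, cm$mpe, cm$rmse, nonConv))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "paramMetrics") <- paramMetrics
  out
}

# Full natural-value vector (estimated values merged over fixed constants).
.fullValues <- function(prior, est) {
  p <- prior@parameters
  vals <- setNames(p$mean, p$name)
  vals[names(est)] <- est
  vals
}

#' Render a validation grid as a compact table
#'
#' One row per drug and dose case, MPE/RMSE columns per sampling set,
#' mirroring the standard presentation of the validation results.
#'
#' @param grid output of [runValidation()].
#' @return data.frame in wide format.
#' @export
formatValidationTable <- function(grid) {
  sets <- unique(grid$samplingSet)
  rows <- list()
  for (d in unique(grid$drug)) for (case in unique(grid$doseCase)) {
    g <- grid[grid$drug == d & grid$doseCase == case, , drop = FALSE]
    if (!nrow(g)) next
    r <- data.frame(drug = d, doseCase = case)
    for (s in sets) {
      gi <- g[g$samplingSet == s, , drop = FALSE]
      r[[paste0(s, "_MPE")]] <- if (nrow(gi)) round(gi$concMpe, 2) else NA
      r[[paste0(s, "_RMSE")]] <- if (nrow(gi)) round(gi$concRmse, 2) else NA
    }
    rows[[length(rows) + 1]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
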