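# S4 classes for the central objects: prior specifications, datasets,
# individual parameters, estimation results, and dose recommendations.

#' Population prior specification for one drug
#'
#' Holds the population PK typical values, coefficients of variation,
#' truncation bounds, fixed constants, and the residual assay error model
#' for one of the supported drugs.
#'
#' @slot drug drug name.
#' @slot modelId structural model tag ("1cmt_inf", "2cmt_inf", "1cmt_oral",
#'   "mm_oral0").
#' @slot parameters data.frame with columns name, mean, cv, lower, upper,
#'   fixed, unit.
#' @slot cvAssay proportional assay coefficient of variation.
#' @slot sAssay additive assay SD (mg/L).
#' @export
setClass("PriorSpec",
         representation(drug = "character", modelId = "character",
                        parameters = "data.frame",
                        cvAssay = "numeric", sAssay = "numeric"))

setValidity("PriorSpec", function(object) {
  p <- object@parameters
  msg <- character()
  if (!all(c("name", "mean", "cv", "lower", "upper", "fixed", "unit") %in%
           names(p)))
    msg <- c(msg, "parameters must have columns name/mean/cv/lower/upper/fixed/unit")
  else {
    if (any(p$mean <= 0)) msg <- c(msg, "parameter means must be positive")
    if (any(p$cv < 0)) msg <- c(msg, "cv must be non-negative")
    if (any(p$fixed & p$cv != 0)) msg <- c(msg, "fixed parameters must have cv = 0")
    bounded <- is.finite(p$lower) & is.finite(p$upper)
    if (any(bounded & (p$lower > p$mean | p$mean > p$upper)))
      msg <- c(msg, "bounds must bracket the mean")
  }
  if (object@cvAssay <= 0 || object@sAssay <= 0)
    msg <- c(msg, "assay error constants must be positive")
  if (length(msg)) msg else TRUE
})

#' NONMEM-style TDM dataset
#'
#' Event records (dosing and observation rows) plus one covariate set per
#' patient, for one drug.
#'
#' @slot drug drug name.
#' @slot covariates data.frame: id, weight (kg), height (cm), age (y),
#'   sex (0 = male, 1 = female), scr (mg/dL).
#' @slot events data.frame: id, time (h), evid (0 obs / 1 dose), amt (mg),
#'   cmt, rate (mg/h), ii (h), addl, dv (mg/L).
#' @export
setClass("TDMDataset",
         representation(drug = "character", covariates = "data.frame",
                        events = "data.frame"))

setValidity("TDMDataset", function(object) {
  ev <- object@events
  cv <- object@covariates
  msg <- character()
  need <- c("id", "time", "evid", "amt", "cmt", "rate", "ii", "addl", "dv")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns", paste(need, collapse = ", ")))
  if (nrow(ev)) {
    if (!all(ev$evid %in% c(0L, 1L))) msg <- c(msg, "evid must be 0 or 1")
    if (any(ev$time < 0, na.rm = TRUE)) msg <- c(msg, "times must be non-negative")
    dose <- ev$evid == 1L
    if (any(dose & (is.na(ev$amt) | ev$amt <= 0)))
      msg <- c(msg, "dose rows must have amt > 0")
    if (any(dose & !is.na(ev$addl) & ev$addl > 0 &
            (is.na(ev$ii) | ev$ii <= 0)))
      msg <- c(msg, "addl > 0 requires ii > 0")
    if (any(!dose & is.na(ev$dv)))
      msg <- c(msg, "observation rows must have dv")
    if (any(!dose & ev$dv < 0, na.rm = TRUE))
      msg <- c(msg, "observed concentrations must be non-negative")
    ids <- unique(ev$id)
    if (!all(ids %in% cv$id)) msg <- c(msg, "every event id needs covariates")
    if (anyDuplicated(cv$id)) msg <- c(msg, "one covariate row per id")
    ndose <- tapply(dose, ev$id, sum)
    if (any(ndose == 0)) msg <- c(msg, "every patient needs at least one dose row")
  }
  if (length(msg)) msg else TRUE
})

#' Individual PK parameter vector
#'
#' Natural-scale parameter values for one patient together with the
#' log-scale deviations (eta) of the estimated parameters.
#'
#' @slot drug drug name.
#' @slot values named numeric vector of natural-scale values.
#' @slot eta named numeric vector of log-scale deviations (estimated
#'   parameters only; empty for fixed-only or external parameterizations).
#' @export
setClass("IndividualParams",
         representation(drug = "character", values = "numeric",
                        eta = "numeric"))

setValidity("IndividualParams", function(object) {
  if (any(object@values <= 0)) "parameter values must be positive" else TRUE
})

#' HMC sampler settings
#'
#' @slot chains number of independent chains.
#' @slot warmup warmup iterations per chain.
#' @slot samples post-warmup iterations per chain.
#' @slot seed integer RNG seed.
#' @slot targetAccept dual-averaging target acceptance probability.
#' @slot maxTreedepth maximum NUTS tree depth.
#' @export
setClass("SamplerSettings",
         representation(chains = "integer", warmup = "integer",
                        samples = "integer", seed = "integer",
                        targetAccept = "numeric", maxTreedepth = "integer"))

setValidity("SamplerSettings", function(object) {
  if (object@chains < 1L || object@warmup < 1L || object@samples < 1L)
    "chains, warmup and samples must all be >= 1" else TRUE
})

#' Posterior sampling result
#'
#' @slot drug drug name.
#' @slot draws list of per-chain matrices of natural-scale draws.
#' @slot etaDraws list of per-chain matrices of eta draws.
#' @slot pointEstimate named vector of pooled posterior medians (natural scale).
#' @slot intervals matrix of central 90 percent credible intervals.
#' @slot diagnostics data.frame with rhat, essBulk, divergences per parameter.
#' @slot converged logical convergence flag.
#' @slot settings the SamplerSettings used.
#' @export
setClass("PosteriorResult",
         representation(drug = "character", draws = "list",
                        etaDraws = "list", pointEstimate = "numeric",
                        intervals = "matrix", diagnostics = "data.frame",
                        converged = "logical", settings = "SamplerSettings"))

#' MAP estimation result
#'
#' @slot drug drug name.
#' @slot estimate named vector of Phi-minimizing natural-scale values.
#' @slot eta eta at the optimum.
#' @slot phi objective value at the optimum.
#' @slot converged optimizer convergence flag.
#' @slot nRestartsUsed number of optimization starts attempted.
#' @export
setClass("MAPResult",
         representation(drug = "character", estimate = "numeric",
                        eta = "numeric", phi = "numeric",
                        converged = "logical", nRestartsUsed = "integer"))

#' Dose recommendation
#'
#' @slot mode target mode ("ct", "auc", or "cavg").
#' @slot currentDose current dose (mg).
#' @slot currentStatus target-metric value under the current regimen.
#' @slot target requested target value.
#' @slot recommendedDose proportionally scaled dose (mg).
#' @slot note character note (e.g. nonlinearity caveat), possibly empty.
#' @export
setClass("DoseRecommendation",
         representation(mode = "character", currentDose = "numeric",
                        currentStatus = "numeric", target = "numeric",
                        recommendedDose = "numeric", note = "character"))

# ---- show methods ---------------------------------------------------------

#' @export
#' @noRd
setMethod("show", "PriorSpec", function(object) {
  cat("Population prior:", object@drug, sprintf("(%s)\n", object@modelId))
  print(object@parameters, row.names = FALSE)
  cat(sprintf("residual error: sigma = %.3g * Cpred + %.3g mg/L\n",
              object@cvAssay, object@sAssay))
})

#' @export
#' @noRd
setMethod("show", "TDMDataset", function(object) {
  cat(sprintf("TDM dataset: %s, %d patient(s), %d dose row(s), %d observation(s)\n",
              object@drug, nrow(object@covariates),
              sum(object@events$evid == 1L), sum(object@events$evid == 0L)))
})

#' @export
#' @noRd
setMethod("show", "IndividualParams", function(object) {
  cat("Individual parameters:", object@drug, "\n")
  print(signif(object@values, 4))
})

#' @export
#' @noRd
setMethod("show", "PosteriorResult", function(object) {
  cat("Posterior result:", object@drug,
      if (object@converged) "(converged)\n" else "(NOT converged)\n")
  est <- cbind(median = object@pointEstimate, object@intervals)
  print(signif(est, 4))
  print(object@diagnostics)
})

#' @export
#' @noRd
setMethod("show", "MAPResult", function(object) {
  cat("MAP result:", object@drug,
      sprintf("Phi = %.4g, %s\n", object@phi,
              if (object@converged) "converged" else "NOT converged"))
  print(signif(object@estimate, 4))
})

#' @export
#' @noRd
setMethod("show", "DoseRecommendation", function(object) {
  cat(sprintf("Dose recommendation (%s): %.4g mg -> %.4g mg (status %.4g, target %.4g)\n",
              object@mode, object@currentDose, object@recommendedDose,
              object@currentStatus, object@target))
  if (nzchar(object@note)) cat("note:", object@note, "\n")
})

# ---- accessors ------------------------------------------------------------

#' @rdname accessors
#' @param x an object with a drug slot.
#' @export
setGeneric("drugName", function(x) standardGeneric("drugName"))

#' Accessors for TDMBayes objects
#' @name accessors
#' @export
setMethod("drugName", "PriorSpec", function(x) x@drug)

#' @rdname accessors
#' @export
setMethod("drugName", "TDMDataset", function(x) x@drug)

#' @rdname accessors
#' @export
setMethod("drugName", "IndividualParams", function(x) x@drug)

#' Prior parameter table
#' @param prior a PriorSpec.
#' @return data.frame of parameter definitions.
#' @export
priorParameters <- function(prior) prior@parameters

#' Residual error model constants
#' @param prior a PriorSpec.
#' @return list with cvAssay and sAssay.
#' @export
errorModel <- function(prior) list(cvAssay = prior@cvAssay, sAssay = prior@sAssay)

#' Point estimate of a fit
#' @param x a PosteriorResult or MAPResult.
#' @return named numeric vector of natural-scale estimates.
#' @export
setGeneric("pointEstimate", function(x) standardGeneric("pointEstimate"))

#' @rdname pointEstimate
#' @export
setMethod("pointEstimate", "PosteriorResult", function(x) x@pointEstimate)

#' @rdname pointEstimate
#' @export
setMethod("pointEstimate", "MAPResult", function(x) x@estimate)

#' Pooled posterior draws (natural scale)
#' @param x a PosteriorResult.
#' @return matrix of pooled post-warmup draws.
#' @export
posteriorDraws <- function(x) do.call(rbind, x@draws)

#' Events for one patient
#' @param ds a TDMDataset.
#' @param id patient id (default: all rows).
#' @return data.frame of event records.
#' @export
tdmEvents <- function(ds, id = NULL) {
  ev <- ds@events
  if (!is.null(id)) ev <- ev[ev$id == id, , drop = FALSE]
  ev
}

#' Covariate table
#' @param ds a TDMDataset.
#' @return data.frame of patient covariates.
#' @export
tdmCovariates <- function(ds) ds@covariates

#' Number of patients in a dataset
#' @param ds a TDMDataset.
#' @export
nPatients <- function(ds) nrow(ds@covariates)
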