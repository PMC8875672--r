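# Dose advisor: steady-state dose-target prediction under a maintained
# regimen and the proportionally scaled recommended dose.

#' Target specification
#'
#' @param mode "ct" (steady-state concentration at time t after the dose),
#'   "auc" (AUC over one steady-state dosing interval), or "cavg" (average
#'   steady-state concentration, AUC/tau).
#' @param t time after the start of the dosing interval (h; "ct" only).
#' @param value target magnitude (mg/L or mg*h/L); optional for
#'   [predictTarget()].
#' @return list describing the target.
#' @export
targetSpec <- function(mode = c("ct", "auc", "cavg"), t = NULL,
                       value = NULL) {
  mode <- match.arg(mode)
  if (mode == "ct" && is.null(t)) stop("mode 'ct' requires t", call. = FALSE)
  list(mode = mode, t = t, value = value)
}

#' Predict a steady-state dose-target value
#'
#' Evaluates the target metric under the maintained regimen at steady
#' state: the concentration at time t, the AUC over one dosing interval
#' (trapezoid on a 0.05 h grid so one code path serves linear and
#' nonlinear models), or the average concentration AUC/tau. Phenytoin
#' steady state is represented by the 20th consecutive dose.
#'
#' @param drug drug name.
#' @param params an [IndividualParams-class] or named natural-scale vector.
#' @param cov covariate list/row.
#' @param regimen list with amt (mg), rate (mg/h; 0 for oral first-order),
#'   ii (h).
#' @param spec a [targetSpec()].
#' @return the target metric value.
#' @export
predictTarget <- function(drug, params, cov, regimen, spec) {
  d <- .matchDrug(drug)
  stopifnot(regimen$amt > 0, regimen$ii > 0)
  ev <- data.frame(id = 1, time = 0, evid = 1L, amt = regimen$amt, cmt = 1L,
                   rate = if (is.null(regimen$rate)) 0 else regimen$rate,
                   ii = regimen$ii, addl = 0, dv = NA_real_)
  tau <- regimen$ii
  if (spec$mode == "ct") {
    if (spec$t < 0 || spec$t > tau)
      stop("t must lie within [0, tau]", call. = FALSE)
    return(simulateProfile(d, params, cov, ev, spec$t,
                           atSteadyState = TRUE)$conc)
  }
  grid <- seq(0, tau, by = 0.05)
  if (grid[length(grid)] < tau) grid <- c(grid, tau)
  conc <- simulateProfile(d, params, cov, ev, grid, atSteadyState = TRUE)$conc
  auc <- sum(diff(grid) * (head(conc, -1) + conc[-1]) / 2)
  if (spec$mode == "auc") auc else auc / tau
}

#' Proportional dose recommendation
#'
#' Recommended dose = current dose x target / current status, identically
#' for the concentration, AUC, and average-concentration target modes.
#' For phenytoin (Michaelis-Menten elimination) the proportional rule does
#' not close the loop; a nonlinearity warning is attached.
#'
#' @param mode "ct", "auc", or "cavg".
#' @param target requested target value (> 0).
#' @param currentDose currently administered dose (mg, > 0).
#' @param currentStatus target-metric value under the current regimen (> 0).
#' @param drug optional drug name; "phenytoin" triggers the nonlinearity
#'   warning.
#' @return a [DoseRecommendation-class].
#' @examples
#' recommendDose("ct", target = 4, currentDose = 500, currentStatus = 8)
#' @export
recommendDose <- function(mode = c("ct", "auc", "cavg"), target,
                          currentDose, currentStatus, drug = NULL) {
  mode <- match.arg(mode)
  if (target <= 0 || currentDose <= 0 || currentStatus <= 0)
    stop("target, currentDose and currentStatus must all be positive",
         call. = FALSE)
  note <- ""
  if (!is.null(drug) && .matchDrug(drug) == "phenytoin") {
    note <- paste("phenytoin follows Michaelis-Menten elimination:",
                  "concentrations scale more than proportionally with dose,",
                  "so the proportional recommendation is approximate and",
                  "should be rechecked by re-prediction")
    warning("nonlinear kinetics: proportional dose scaling is approximate ",
            "for phenytoin", call. = FALSE)
  }
  new("DoseRecommendation", mode = mode, currentDose = currentDose,
      currentStatus = currentStatus, target = target,
      recommendedDose = currentDose * target / currentStatus, note = note)
}
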