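# Forward concentration prediction: event expansion, closed-form kernels
# for the linear models, the Michaelis-Menten ODE kernel, and the
# drug-level dispatcher including analytic steady state.

#' Expand addl/ii dose records into explicit doses
#'
#' Each dose row with `addl = k` expands into k + 1 identical doses spaced
#' `ii` hours apart; observation rows pass through untouched.
#'
#' @param events data.frame of event records (columns time, evid, amt,
#'   rate, ii, addl at least).
#' @return data.frame of explicit dose rows (time, amt, rate, cmt), sorted
#'   by time.
#' @export
expandEvents <- function(events) {
  dose <- events[events$evid == 1L, , drop = FALSE]
  if (!nrow(dose))
    return(data.frame(time = numeric(), amt = numeric(), rate = numeric(),
                      cmt = integer()))
  rows <- lapply(seq_len(nrow(dose)), function(i) {
    r <- dose[i, ]
    addl <- if (is.na(r$addl)) 0L else as.integer(r$addl)
    ii <- if (is.na(r$ii)) 0 else r$ii
    if (addl > 0 && ii <= 0)
      stop("schedule error: addl > 0 requires ii > 0", call. = FALSE)
    data.frame(time = r$time + (0:addl) * ii,
               amt = r$amt,
               rate = if (is.na(r$rate)) 0 else r$rate,
               cmt = if (is.null(r$cmt) || is.na(r$cmt)) 1L else as.integer(r$cmt))
  })
  out <- do.call(rbind, rows)
  out[order(out$time), , drop = FALSE]
}

.doseMatrix <- function(doses) {
  m <- cbind(doses$time, doses$amt, doses$rate)
  storage.mode(m) <- "double"
  m
}

#' One-compartment IV infusion model (closed form)
#'
#' During an infusion of rate R, C = (R/CL)(1 - e^(-k t)); post-infusion
#' the concentration decays with k = CL/V. Multiple doses superpose.
#'
#' @param cl clearance (L/h).
#' @param v volume of distribution (L).
#' @param doses data.frame with time, amt (mg), rate (mg/h; 0 = bolus).
#' @param times observation times (h).
#' @param ss evaluate the tau-periodic steady state of the first dose row.
#' @param tau dosing interval (h), required when `ss`.
#' @return concentrations (mg/L).
#' @export
conc1CmtInfusion <- function(cl, v, doses, times, ss = FALSE, tau = 0) {
  stopifnot(cl > 0, v > 0)
  cpp_conc_linear(1L, c(cl, v), .doseMatrix(doses), as.numeric(times), ss, tau)
}

#' Two-compartment IV infusion model (closed form)
#'
#' Bi-exponential disposition with hybrid rate constants, the roots of
#' lambda^2 - (k10 + k12 + k21) lambda + k10 k21 with k10 = CL/V.
#'
#' @inheritParams conc1CmtInfusion
#' @param k12,k21 inter-compartmental first-order rate constants (1/h).
#' @return central-compartment concentrations (mg/L).
#' @export
conc2CmtInfusion <- function(cl, v, k12, k21, doses, times, ss = FALSE, tau = 0) {
  stopifnot(cl > 0, v > 0, k12 >= 0, k21 > 0)
  cpp_conc_linear(2L, c(cl, v, k12, k21), .doseMatrix(doses),
                  as.numeric(times), ss, tau)
}

#' One-compartment first-order absorption model (closed form)
#'
#' Bateman equation C = F D ka / (V (ka - ke)) (e^(-ke t) - e^(-ka t)) with
#' ke = CL/V, superposed over doses; the ka = ke limiting form
#' F D ka t e^(-ka t) / V is used when the rates coincide numerically.
#'
#' @inheritParams conc1CmtInfusion
#' @param ka first-order absorption rate constant (1/h).
#' @param f bioavailable fraction.
#' @export
conc1CmtOral <- function(cl, v, ka, f, doses, times, ss = FALSE, tau = 0) {
  stopifnot(cl > 0, v > 0, ka > 0, f > 0, f <= 1)
  cpp_conc_linear(3L, c(cl, v, ka, f), .doseMatrix(doses),
                  as.numeric(times), ss, tau)
}

#' Michaelis-Menten elimination with zero-order input (numeric)
#'
#' Integrates dA/dt = input(t) F - [Vmax C/(km + C) + CLlin C] with
#' C = A/V using a fixed-step classical Runge-Kutta scheme marched exactly
#' through every input breakpoint. Each dose delivers F * amt at zero-order
#' rate `rate` for duration amt/rate.
#'
#' @param vmax maximum elimination rate (mg/h).
#' @param km Michaelis constant (mg/L).
#' @param v volume of distribution (L).
#' @param clLin additional linear clearance (L/h).
#' @param f bioavailable fraction.
#' @param doses data.frame with time, amt, rate (rate > 0 for zero-order
#'   delivery; rate = 0 treated as an instantaneous depot dose).
#' @param times observation times (h).
#' @param step maximum integration step (h).
#' @export
concMichaelisMenten <- function(vmax, km, v, clLin, f, doses, times,
                                step = 0.005) {
  stopifnot(vmax > 0, km > 0, v > 0, clLin >= 0, f > 0, f <= 1, step > 0)
  cpp_conc_mm(c(vmax, km, v, clLin, f), .doseMatrix(doses),
              as.numeric(times), step)
}

#' Time of peak concentration after a single oral dose
#'
#' tmax = ln(ka/ke) / (ka - ke) for first-order absorption and elimination.
#'
#' @param ka absorption rate constant (1/h).
#' @param ke elimination rate constant (1/h).
#' @return tmax (h).
#' @examples
#' oralTmax(0.27, 0.08)
#' @export
oralTmax <- function(ka, ke) {
  stopifnot(ka > 0, ke > 0, ka != ke)
  log(ka / ke) / (ka - ke)
}

#' Simulate a concentration profile for one patient
#'
#' Dispatches to the drug's structural model. For the linear drugs,
#' `atSteadyState = TRUE` evaluates the analytic tau-periodic steady state
#' of the regimen in the first dose row (per-exponential accumulation
#' factor 1/(1 - e^(-lambda tau))), with `times` interpreted within the
#' dosing interval. For phenytoin, steady state is represented by the 20th
#' consecutive dose: the regimen is expanded to 20 doses and `times` are
#' offsets within the 20th dosing interval.
#'
#' @param drug drug name.
#' @param params an [IndividualParams-class] or named natural-scale vector.
#' @param cov covariate list/row (weight, height, age, sex, scr).
#' @param events event records (data.frame with evid, time, amt, rate, ii,
#'   addl).
#' @param times observation times (h).
#' @param atSteadyState logical steady-state flag (see Details).
#' @param odeStep integration step for the phenytoin kernel (h).
#' @return data.frame with columns time and conc (mg/L).
#' @export
simulateProfile <- function(drug, params, cov, events, times,
                            atSteadyState = FALSE, odeStep = 0.005) {
  d <- .matchDrug(drug)
  sm <- .structuralModel(d, if (is(params, "IndividualParams")) params@values
                         else params, cov)
  doses <- expandEvents(events)
  if (!nrow(doses)) stop("no dose records", call. = FALSE)
  tt <- as.numeric(times)
  if (sm$model == 4L) {
    if (atSteadyState) {
      ii <- events$ii[events$evid == 1L][1]
      if (is.na(ii) || ii <= 0)
        stop("steady state requires a dosing interval ii", call. = FALSE)
      d20 <- data.frame(time = (0:19) * ii, amt = doses$amt[1],
                        rate = doses$rate[1])
      conc <- concMichaelisMenten(sm$pars[1], sm$pars[2], sm$pars[3],
                                  sm$pars[4], sm$pars[5], d20, 19 * ii + tt,
                                  step = odeStep)
    } else {
      conc <- concMichaelisMenten(sm$pars[1], sm$pars[2], sm$pars[3],
                                  sm$pars[4], sm$pars[5], doses, tt,
                                  step = odeStep)
    }
  } else {
    tau <- 0
    if (atSteadyState) {
      tau <- events$ii[events$evid == 1L][1]
      if (is.na(tau) || tau <= 0)
        stop("steady state requires a dosing interval ii", call. = FALSE)
    }
    conc <- cpp_conc_linear(sm$model, sm$pars, .doseMatrix(doses), tt,
                            atSteadyState, tau)
  }
  data.frame(time = tt, conc = conc)
}

# Low-level kernel dispatch on a structural-model record (.structuralModel
# or .externalStructural output); used by the cohort and validation code.
.kernelConc <- function(sm, doses, times, ss = FALSE, tau = 0,
                        odeStep = 0.005) {
  if (sm$model == 4L) {
    cpp_conc_mm(sm$pars, .doseMatrix(doses), as.numeric(times), odeStep)
  } else {
    cpp_conc_linear(sm$model, sm$pars, .doseMatrix(doses),
                    as.numeric(times), ss, tau)
  }
}
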