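# External validation population models (literature models used only to
# generate virtual patients; estimation always uses the internal prior).
#
# Amikacin:    CL (L/h) = 1.40 + 1.42 * (CrCl/71.2) * e^eta1, omega 0.303
#              V (L)    = 10.8 + 7.24 * (TBW/57)
#              Cobs = Cpred * (1 + eps), sd 0.307; CrCl in mL/min.
# Vancomycin:  CL = 2.82 * (CrCl/72)^0.836 * e^eta1 (omega 0.828),
#              Vc 31.8 L, Q 11.7 L/h, Vp = 75.4 * (TBW/60) * e^eta2
#              (omega 0.466); Cobs = Cpred * (1 + eps), sd 0.253.
# Theophylline: ka 0.0773 1/h fixed; CL/F (L/h/kg) = 0.0539 * 0.876^elderly
#              * e^eta1 (omega 0.313, elderly = age >= 65); V/F (L/kg) =
#              0.320 * e^eta2 (omega 0.284); per-kg values scaled by TBW;
#              Cobs = Cpred * e^eps, sd 0.178.
# Phenytoin:   Vmax (mg/d) = 9.80 * 42 * (TBW/42)^0.463 * (1 + eta1)
#              (sd 0.150); km (mg/L) = 9.19 * (1 + eta2) (sd 0.306);
#              V (L/kg) = 1.23 * (1 + eta3) (sd 0.433), scaled by TBW;
#              Cobs = Cpred * (1 + eps), sd 0.181. (1 + eta) <= 0 redrawn.

.extResidual <- list(amikacin = list(type = "prop", sd = 0.307),
                     vancomycin = list(type = "prop", sd = 0.253),
                     theophylline = list(type = "exp", sd = 0.178),
                     phenytoin = list(type = "prop", sd = 0.181))

.rposfac <- function(sd) {
  repeat {
    f <- 1 + rnorm(1, 0, sd)
    if (f > 0) return(f)
  }
}

.externalTruthOnce <- function(drug, cov) {
  dc <- .derivedCov(cov)
  if (drug == "amikacin") {
    cl <- 1.40 + 1.42 * (dc$crclMlMin / 71.2) * exp(rnorm(1, 0, 0.303))
    v <- 10.8 + 7.24 * (dc$tbw / 57)
    vals <- c(CL = cl, V = v)
  } else if (drug == "vancomycin") {
    cl <- 2.82 * (dc$crclMlMin / 72)^0.836 * exp(rnorm(1, 0, 0.828))
    vp <- 75.4 * (dc$tbw / 60) * exp(rnorm(1, 0, 0.466))
    vals <- c(CL = cl, VC = 31.8, Q = 11.7, VP = vp)
  } else if (drug == "theophylline") {
    elderly <- as.numeric(cov$age >= 65)
    clkg <- 0.0539 * 0.876^elderly * exp(rnorm(1, 0, 0.313))
    vkg <- 0.320 * exp(rnorm(1, 0, 0.284))
    vals <- c(ka = 0.0773, CL = clkg * dc$tbw, V = vkg * dc$tbw)
  } else {
    vmax <- 9.80 * 42 * (dc$tbw / 42)^0.463 * .rposfac(0.150)
    km <- 9.19 * .rposfac(0.306)
    v <- 1.23 * dc$tbw * .rposfac(0.433)
    vals <- c(Vmax = vmax, km = km, V = v)
  }
  new("IndividualParams", drug = drug, values = vals, eta = numeric(0))
}

#' Sample true parameters from an external literature model
#'
#' Draws one virtual patient's parameters from the external population
#' model of the drug (used to generate external-validation data; these
#' models are never used for estimation).
#'
#' @param drug drug name.
#' @param cov covariate list/row (weight, height, age, sex, scr).
#' @param seed RNG seed.
#' @return an [IndividualParams-class] in the external parameterization.
#' @export
externalTruth <- function(drug, cov, seed = 1L) {
  d <- .matchDrug(drug)
  .withSeed(seed, .externalTruthOnce(d, cov))
}

# Kernel dispatch for external parameterizations.
.externalStructural <- function(drug, vals) {
  switch(drug,
    amikacin = list(model = 1L, pars = c(vals[["CL"]], vals[["V"]])),
    vancomycin = list(model = 2L,
                      pars = c(vals[["CL"]], vals[["VC"]],
                               vals[["Q"]] / vals[["VC"]],
                               vals[["Q"]] / vals[["VP"]])),
    theophylline = list(model = 3L,
                        pars = c(vals[["CL"]], vals[["V"]], vals[["ka"]], 1.0)),
    phenytoin = list(model = 4L,
                     pars = c(vals[["Vmax"]] / 24, vals[["km"]],
                              vals[["V"]], 0, 1.0)))
}

# Residual-error draw for external models (proportional or exponential),
# redrawn while non-positive.
.externalObserve <- function(drug, trueConc) {
  r <- .extResidual[[drug]]
  obs <- numeric(length(trueConc))
  for (i in seq_along(trueConc)) {
    if (r$type == "exp") {
      obs[i] <- trueConc[i] * exp(rnorm(1, 0, r$sd))
    } else {
      obs[i] <- trueConc[i] * .rposfac(r$sd)
    }
  }
  obs
}
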