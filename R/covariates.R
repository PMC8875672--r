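# Covariate engine: lean body weight, creatinine clearance, and the
# parameter equations mapping priors + covariates to structural CL and V.
# All internal computation is in L, h, mg, mg/L; creatinine clearance is
# carried in both mL/min and L/h (x 0.06).

.sexCode <- function(sex) {
  if (is.character(sex) || is.factor(sex)) {
    s <- tolower(as.character(sex))
    out <- ifelse(s %in% c("male", "m", "0"), 0L,
                  ifelse(s %in% c("female", "f", "1"), 1L, NA_integer_))
  } else out <- as.integer(sex)
  if (any(is.na(out) | !out %in% c(0L, 1L)))
    stop("sex must be coded 0/\"male\" or 1/\"female\"", call. = FALSE)
  out
}

#' Lean body weight
#'
#' Sex-specific lean-body-weight equations:
#' male 1.10 W - 128 (W/H)^2, female 1.07 W - 148 (W/H)^2
#' (W total body weight in kg, H height in cm).
#'
#' @param weight total body weight (kg).
#' @param height height (cm).
#' @param sex 0/"male" or 1/"female".
#' @return lean body weight (kg).
#' @examples
#' leanBodyWeight(65.1, 165.1, "male")
#' @export
leanBodyWeight <- function(weight, height, sex) {
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive", call. = FALSE)
  s <- .sexCode(sex)
  r <- (weight / height)^2
  lbw <- ifelse(s == 0L, 1.10 * weight - 128 * r, 1.07 * weight - 148 * r)
  if (any(lbw <= 0))
    stop("invalid anthropometry: lean body weight non-positive", call. = FALSE)
  lbw
}

#' Creatinine clearance (Cockcroft-Gault, lean body weight)
#'
#' CrCl (mL/min) = (140 - age) * LBW / (72 * sCr), times 0.85 for females.
#'
#' @param age age in years (< 140).
#' @param scr serum creatinine (mg/dL, > 0).
#' @param lbw lean body weight (kg); either supply `lbw` directly or
#'   `weight` and `height` so it can be derived.
#' @param sex 0/"male" or 1/"female".
#' @param weight,height used to derive `lbw` when it is missing.
#' @return list with `mlMin` and `lH` (the same clearance in L/h, x 0.06).
#' @examples
#' creatinineClearance(50.2, 1.0, sex = "male", weight = 65.1, height = 165.1)
#' @export
creatinineClearance <- function(age, scr, lbw = NULL, sex,
                                weight = NULL, height = NULL) {
  if (any(scr <= 0)) stop("serum creatinine must be positive", call. = FALSE)
  if (any(age >= 140) || any(age < 0))
    stop("age must be in [0, 140)", call. = FALSE)
  s <- .sexCode(sex)
  if (is.null(lbw)) lbw <- leanBodyWeight(weight, height, s)
  crcl <- (140 - age) * lbw / (72 * scr)
  crcl <- ifelse(s == 1L, 0.85 * crcl, crcl)
  list(mlMin = crcl, lH = crcl * 0.06)
}

# Derived per-patient quantities from a covariate row (list or 1-row df).
.derivedCov <- function(cov) {
  s <- .sexCode(cov$sex)
  lbw <- leanBodyWeight(cov$weight, cov$height, s)
  crcl <- creatinineClearance(cov$age, cov$scr, lbw = lbw, sex = s)
  list(lbw = lbw, crclMlMin = crcl$mlMin, crclLh = crcl$lH, tbw = cov$weight)
}

#' Structural PK parameters from priors and covariates
#'
#' Applies the parameter equations: for the linear drugs
#' CL (L/h) = CLslope * CrCl (L/h) + CLnr * LBW (unit-converted) and
#' V (L) = Vnr * LBW; for phenytoin only the volume
#' V = Vnr * 70 * (TBW/70)^0.6 is returned (its concentration-dependent
#' clearance lives in the forward model).
#'
#' @param drug drug name.
#' @param params an [IndividualParams-class] or named numeric vector of
#'   natural-scale parameter values.
#' @param cov covariate list/row with weight, height, age, sex, scr.
#' @return list with lbw, crclMlMin, crclLh, and cl/v (plus k12/k21, ka, F
#'   or vmax/km/clLin as appropriate).
#' @export
deriveStructuralParams <- function(drug, params, cov) {
  d <- .matchDrug(drug)
  v <- if (is(params, "IndividualParams")) params@values else params
  dc <- .derivedCov(cov)
  out <- dc
  if (d == "amikacin" || d == "vancomycin") {
    out$cl <- v[["CLslope"]] * dc$crclLh + v[["CLnr"]] * dc$lbw * 0.06
    out$v <- v[["Vnr"]] * dc$lbw
    if (d == "vancomycin") { out$k12 <- v[["k12"]]; out$k21 <- v[["k21"]] }
  } else if (d == "theophylline") {
    out$cl <- v[["CLnr"]] * dc$lbw * 0.001
    out$v <- v[["Vnr"]] * dc$lbw
    out$ka <- if ("ka" %in% names(v)) v[["ka"]] else 0.27
    out$f <- if ("F" %in% names(v)) v[["F"]] else 1.0
  } else {
    out$v <- v[["Vnr"]] * 70 * (dc$tbw / 70)^0.6
    out$vmaxH <- v[["Vmax"]] / 24          # mg/day -> mg/h
    out$km <- v[["km"]]
    out$clLin <- 0.01 * dc$crclLh          # fixed CLslope term
    out$f <- 0.92
  }
  out
}

# Kernel dispatch record: model code + parameter vector for the compiled
# concentration kernels, from internal-parameterization values.
.structuralModel <- function(drug, values, cov) {
  sp <- deriveStructuralParams(drug, values, cov)
  switch(drug,
    amikacin = list(model = 1L, pars = c(sp$cl, sp$v)),
    vancomycin = list(model = 2L, pars = c(sp$cl, sp$v, sp$k12, sp$k21)),
    theophylline = list(model = 3L, pars = c(sp$cl, sp$v, sp$ka, sp$f)),
    phenytoin = list(model = 4L, pars = c(sp$vmaxH, sp$km, sp$v, sp$clLin, sp$f)))
}
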