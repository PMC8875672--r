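# Population prior registry.
#
# Typical values, interindividual CVs, truncation bounds, fixed constants,
# and assay error constants for the four supported drugs. CLslope is the
# dimensionless slope of clearance versus creatinine clearance (both L/h);
# CLnr and Vnr are per-kg lean-body-weight terms in the printed units;
# phenytoin Vmax is carried in mg/day (total) and converted to mg/h at the
# model boundary.

.priorRegistry <- list(
  amikacin = list(
    modelId = "1cmt_inf",
    parameters = data.frame(
      name  = c("CLslope", "CLnr", "Vnr"),
      mean  = c(0.815, 0.0417, 0.27),
      cv    = c(0.4, 0.25, 0.3),
      lower = c(0.3, 0.0001, 0.15),
      upper = c(1.7, 0.17, 0.65),
      fixed = c(FALSE, FALSE, FALSE),
      unit  = c("", "mL/min/kg", "L/kg"),
      stringsAsFactors = FALSE),
    cvAssay = 0.15, sAssay = 0.25),
  vancomycin = list(
    modelId = "2cmt_inf",
    parameters = data.frame(
      name  = c("CLslope", "CLnr", "Vnr", "k12", "k21"),
      mean  = c(0.75, 0.05, 0.21, 1.12, 0.48),
      cv    = c(0.33, 0.2, 0.2, 0.25, 0.25),
      lower = c(0.3, 0.01, 0.08, 0.6, 0.2),
      upper = c(1.7, 0.2, 0.4, 1.6, 1.0),
      fixed = c(FALSE, FALSE, FALSE, FALSE, FALSE),
      unit  = c("", "mL/min/kg", "L/kg", "1/h", "1/h"),
      stringsAsFactors = FALSE),
    cvAssay = 0.15, sAssay = 0.25),
  theophylline = list(
    modelId = "1cmt_oral",
    parameters = data.frame(
      name  = c("CLnr", "Vnr", "ka", "F"),
      mean  = c(40.0, 0.5, 0.27, 1.0),
      cv    = c(0.5, 0.2, 0, 0),
      lower = c(15.0, 0.35, NA, NA),
      upper = c(90.0, 0.65, NA, NA),
      fixed = c(FALSE, FALSE, TRUE, TRUE),
      unit  = c("mL/h/kg", "L/kg", "1/h", ""),
      stringsAsFactors = FALSE),
    cvAssay = 0.15, sAssay = 0.25),
  phenytoin = list(
    modelId = "mm_oral0",
    parameters = data.frame(
      name  = c("Vmax", "km", "Vnr", "CLslope", "F"),
      mean  = c(500, 5.0, 0.8, 0.01, 0.92),
      cv    = c(0.3, 0.5, 0.2, 0, 0),
      lower = c(250, 2.0, 0.3, NA, NA),
      upper = c(2000, 9.0, 1.4, NA, NA),
      fixed = c(FALSE, FALSE, FALSE, TRUE, TRUE),
      unit  = c("mg/d", "mg/L", "L/kg", "", ""),
      stringsAsFactors = FALSE),
    cvAssay = 0.1, sAssay = 1.0)
)

#' Default population prior for a drug
#'
#' Returns the full population prior specification: typical values
#' (lognormal medians), interindividual coefficients of variation,
#' truncation bounds used when sampling virtual patients, fixed constants,
#' and the residual assay error constants.
#'
#' @param drug one of `drugList()` (case-insensitive).
#' @return a [PriorSpec-class] object.
#' @examples
#' defaultPrior("amikacin")
#' @export
defaultPrior <- function(drug) {
  d <- .matchDrug(drug)
  r <- .priorRegistry[[d]]
  new("PriorSpec", drug = d, modelId = r$modelId, parameters = r$parameters,
      cvAssay = r$cvAssay, sAssay = r$sAssay)
}

#' Convert a coefficient of variation to a log-scale SD
#'
#' Lognormal interindividual variability: omega^2 = ln(cv^2 + 1).
#'
#' @param cv coefficient of variation (dimensionless, >= 0).
#' @return omega, the SD of the log-scale deviation eta.
#' @examples
#' cvToOmega(0.4)
#' @export
cvToOmega <- function(cv) {
  if (any(cv < 0)) stop("cv must be non-negative", call. = FALSE)
  sqrt(log(cv^2 + 1))
}

# Estimated (non-fixed) parameter rows, in registry order.
.estimatedParams <- function(prior) {
  p <- prior@parameters
  p[!p$fixed, , drop = FALSE]
}

# Named value lookup from a prior table.
.priorValue <- function(prior, name) {
  p <- prior@parameters
  p$mean[match(name, p$name)]
}

#' Prior specification as a plain list
#'
#' Human-readable representation (for serialization to YAML/JSON config
#' files and the command-line `show-prior` command).
#'
#' @param prior a [PriorSpec-class].
#' @return nested list mirroring the printed prior table.
#' @export
priorAsList <- function(prior) {
  p <- prior@parameters
  pars <- lapply(seq_len(nrow(p)), function(i) {
    x <- list(mean = p$mean[i])
    if (!p$fixed[i]) {
      x$cv <- p$cv[i]; x$lower <- p$lower[i]; x$upper <- p$upper[i]
    } else x$fixed <- TRUE
    if (nzchar(p$unit[i])) x$unit <- p$unit[i]
    x
  })
  names(pars) <- p$name
  list(drug = prior@drug, model = prior@modelId, parameters = pars,
       error = list(cv_assay = prior@cvAssay, s_assay = prior@sAssay))
}
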