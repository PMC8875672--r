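# Reading and writing NONMEM-style TDM datasets (CSV) and packaged
# example datasets. Missing numeric cells may be "." or empty; headers are
# case-insensitive; SEX is coded 0 = male, 1 = female.

.requiredCols <- c("ID", "TIME", "EVID", "AMT", "CMT", "RATE", "II", "ADDL",
                   "DV", "WT", "HT", "AGE", "SEX", "SCR")

.parseNum <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c(".", "", "NA")] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Construct a TDM dataset
#'
#' @param drug drug name.
#' @param covariates data.frame with id, weight, height, age, sex, scr.
#' @param events data.frame with id, time, evid, amt, cmt, rate, ii, addl, dv.
#' @return a validated [TDMDataset-class].
#' @export
tdmDataset <- function(drug, covariates, events) {
  d <- .matchDrug(drug)
  ev <- events[order(events$id, events$time, -events$evid), , drop = FALSE]
  rownames(ev) <- NULL
  rownames(covariates) <- NULL
  new("TDMDataset", drug = d, covariates = covariates, events = ev)
}

#' Read a TDM dataset from CSV
#'
#' Expects columns ID, TIME, EVID, AMT, CMT, RATE, II, ADDL, DV, WT, HT,
#' AGE, SEX, SCR (case-insensitive). Missing numeric cells may be written
#' as "." or left empty. Rows are sorted by (ID, TIME) with doses before
#' same-time observations.
#'
#' @param path CSV file path.
#' @param drug drug name.
#' @return a [TDMDataset-class].
#' @export
readTdmDataset <- function(path, drug) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  names(raw) <- toupper(trimws(names(raw)))
  missing <- setdiff(.requiredCols, names(raw))
  if (length(missing))
    stop("schema error: missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  num <- lapply(raw[.requiredCols], .parseNum)
  evid <- num$EVID
  bad <- which(!(evid %in% c(0, 1)))
  if (length(bad))
    stop("value error: EVID must be 0 or 1 (row ", bad[1], ")", call. = FALSE)
  badAmt <- which(evid == 1 & (is.na(num$AMT) | num$AMT <= 0))
  if (length(badAmt))
    stop("value error: dose row with AMT <= 0 (row ", badAmt[1], ")",
         call. = FALSE)
  ev <- data.frame(id = num$ID, time = num$TIME, evid = as.integer(evid),
                   amt = num$AMT, cmt = as.integer(ifelse(is.na(num$CMT), 1, num$CMT)),
                   rate = ifelse(is.na(num$RATE), 0, num$RATE),
                   ii = num$II, addl = num$ADDL, dv = num$DV)
  ids <- unique(ev$id)
  cov <- do.call(rbind, lapply(ids, function(i) {
    r <- which(ev$id == i)[1]
    data.frame(id = i, weight = num$WT[r], height = num$HT[r],
               age = num$AGE[r], sex = as.integer(num$SEX[r]),
               scr = num$SCR[r])
  }))
  tdmDataset(drug, cov, ev)
}

#' Write a TDM dataset to CSV
#'
#' Numeric cells are written with enough digits for a bit-exact round trip
#' through [readTdmDataset()]; missing values are written as ".".
#'
#' @param ds a [TDMDataset-class].
#' @param path output CSV path.
#' @export
writeTdmDataset <- function(ds, path) {
  ev <- ds@events
  cov <- ds@covariates
  fmt <- function(x) {
    vapply(x, function(v) {
      if (is.na(v)) return(".")
      s <- sprintf("%.15g", v)                # shortest-ish representation
      if (as.numeric(s) != v) s <- sprintf("%.17g", v)
      s
    }, character(1))
  }
  covMatch <- cov[match(ev$id, cov$id), , drop = FALSE]
  out <- data.frame(ID = fmt(ev$id), TIME = fmt(ev$time), EVID = fmt(ev$evid),
                    AMT = fmt(ev$amt), CMT = fmt(ev$cmt), RATE = fmt(ev$rate),
                    II = fmt(ev$ii), ADDL = fmt(ev$addl), DV = fmt(ev$dv),
                    WT = fmt(covMatch$weight), HT = fmt(covMatch$height),
                    AGE = fmt(covMatch$age), SEX = fmt(covMatch$sex),
                    SCR = fmt(covMatch$scr))
  if (!nrow(ev))
    out <- out[0, , drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Packaged example dataset for a drug
#'
#' A small simulated single-patient dataset following the drug's standard
#' validation regimen (e.g. amikacin: 500 mg infused at 1000 mg/h every
#' 8 h with peak and trough samples). The concentrations are synthetic,
#' generated from the population prior model.
#'
#' @param drug drug name.
#' @return a [TDMDataset-class].
#' @export
sampleData <- function(drug) {
  d <- .matchDrug(drug)
  path <- system.file("extdata", paste0("sample_", d, ".csv"),
                      package = "TDMBayes")
  if (!nzchar(path)) stop("packaged sample data not found for ", d,
                          call. = FALSE)
  readTdmDataset(path, d)
}

# Single-patient view used by the fitting code.
.patientData <- function(ds, id) {
  ev <- ds@events[ds@events$id == id, , drop = FALSE]
  cov <- ds@covariates[ds@covariates$id == id, , drop = FALSE]
  if (!nrow(cov)) stop("unknown patient id ", id, call. = FALSE)
  list(events = ev, cov = as.list(cov[1, ]))
}
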