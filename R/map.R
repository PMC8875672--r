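# Maximum a posteriori estimation: minimize the penalized least-squares
# objective
#   Phi = sum_i (Cobs_i - Cest_i)^2 / sigma_i^2 + sum_k eta_k^2 / omega_k^2
# over the log-scale deviations eta, with sigma_i recomputed from the
# current prediction at every objective evaluation. Quasi-Newton (BFGS)
# with multiple jittered starts; the best Phi wins.

#' Fit individual PK parameters by MAP estimation
#'
#' @param drug drug name.
#' @param data single-patient [TDMDataset-class]; `NULL` returns the prior
#'   means exactly (the prior term is minimized at eta = 0).
#' @param prior a [PriorSpec-class].
#' @param starts number of optimization starts (prior mode plus
#'   `starts - 1` jittered starts, jitter SD = 0.5 omega).
#' @param ss treat observation times as lying in a steady-state interval.
#' @param seed seed for the start jitter.
#' @param odeStep integration step for the phenytoin kernel (h).
#' @return a [MAPResult-class].
#' @export
mapFit <- function(drug, data = NULL, prior = defaultPrior(drug),
                   starts = 5L, ss = FALSE, seed = 1L, odeStep = 0.1) {
  d <- .matchDrug(drug)
  est <- .estimatedParams(prior)
  L <- nrow(est)
  omega <- cvToOmega(est$cv)
  if (is.null(data) ||
      (is(data, "TDMDataset") && !any(data@events$evid == 0L))) {
    val <- setNames(est$mean, est$name)
    return(new("MAPResult", drug = d, estimate = val,
               eta = setNames(numeric(L), est$name), phi = 0,
               converged = TRUE, nRestartsUsed = 0L))
  }
  ld <- .lpData(d, data, prior, ss, odeStep)
  code <- .drugCode(d)
  fn <- function(eta) cpp_phi(code, eta, ld)
  gr <- function(eta) cpp_phi_grad(code, eta, ld)
  startMat <- rbind(rep(0, L),
                    .withSeed(as.numeric(seed) * 11 + 5,
                              matrix(rnorm((starts - 1) * L, 0,
                                           rep(0.5 * omega, each = starts - 1)),
                                     starts - 1, L, byrow = FALSE)))
  if (starts == 1L) startMat <- startMat[1, , drop = FALSE]
  best <- NULL
  nTried <- 0L
  for (i in seq_len(nrow(startMat))) {
    nTried <- nTried + 1L
    opt <- tryCatch(optim(startMat[i, ], fn, gr, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12)),
                    error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("MAP optimization failed from every start", call. = FALSE)
  eta <- setNames(best$par, est$name)
  val <- setNames(est$mean * exp(best$par), est$name)
  new("MAPResult", drug = d, estimate = val, eta = eta, phi = best$value,
      converged = best$convergence == 0L, nRestartsUsed = nTried)
}

#' MAP objective value
#'
#' Evaluates the penalized least-squares objective Phi at a given eta.
#'
#' @inheritParams mapFit
#' @param eta numeric vector of log-scale deviations.
#' @return scalar objective value.
#' @export
mapObjective <- function(drug, data, prior = defaultPrior(drug), eta,
                         ss = FALSE, odeStep = 0.1) {
  d <- .matchDrug(drug)
  ld <- .lpData(d, data, prior, ss, odeStep)
  stopifnot(length(eta) == length(ld$omega))
  cpp_phi(.drugCode(d), as.numeric(eta), ld)
}
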