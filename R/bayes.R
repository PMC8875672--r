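# Bayesian engine: log-posterior construction, NUTS/HMC sampling, and
# convergence diagnostics for the individual PK parameters.
#
# The individual posterior combines independent Normal(0, omega_k^2) priors
# on the log-scale deviations eta with heteroscedastic Normal observation
# densities, sigma_i = cv_assay * Cpred_i + s_assay.

#' Sampler settings
#'
#' Defaults follow the standard full profile (4 chains, 2500 warmup + 2500
#' sampling iterations). The "reduced" preset (500/500) is intended for
#' desk-scale validation sweeps.
#'
#' @param chains number of chains.
#' @param warmup warmup iterations per chain.
#' @param samples post-warmup iterations per chain.
#' @param seed integer RNG seed.
#' @param targetAccept dual-averaging target acceptance probability.
#' @param maxTreedepth maximum NUTS tree depth.
#' @param preset "full" (2500/2500) or "reduced" (500/500); explicit
#'   `warmup`/`samples` override the preset.
#' @return a [SamplerSettings-class].
#' @export
samplerSettings <- function(chains = 4L, warmup = NULL, samples = NULL,
                            seed = 1L, targetAccept = 0.8,
                            maxTreedepth = 10L,
                            preset = c("full", "reduced")) {
  preset <- match.arg(preset)
  def <- if (preset == "full") 2500L else 500L
  new("SamplerSettings", chains = as.integer(chains),
      warmup = as.integer(if (is.null(warmup)) def else warmup),
      samples = as.integer(if (is.null(samples)) def else samples),
      seed = as.integer(seed), targetAccept = targetAccept,
      maxTreedepth = as.integer(maxTreedepth))
}

# Assemble the data list consumed by the compiled log-posterior for one
# patient. `ss = TRUE` marks the observation times as lying within a
# steady-state dosing interval (linear models, analytic accumulation).
.lpData <- function(drug, data, prior, ss = FALSE, odeStep = 0.1) {
  if (is(data, "TDMDataset")) {
    ids <- unique(data@events$id)
    if (length(ids) != 1)
      stop("fitting expects a single-patient dataset; got ", length(ids),
           " ids", call. = FALSE)
    pd <- .patientData(data, ids[1])
  } else pd <- data  # list(events, cov)
  ev <- pd$events
  obs <- ev[ev$evid == 0L, , drop = FALSE]
  doses <- expandEvents(ev)
  est <- .estimatedParams(prior)
  dc <- .derivedCov(pd$cov)
  tau <- 0
  if (ss) {
    tau <- ev$ii[ev$evid == 1L][1]
    if (is.na(tau) || tau <= 0)
      stop("ss = TRUE requires a dose row with ii > 0", call. = FALSE)
  }
  list(doses = .doseMatrix(doses),
       obs_t = as.numeric(obs$time), obs_y = as.numeric(obs$dv),
       prior_mean = est$mean, omega = cvToOmega(est$cv),
       crcl_lh = dc$crclLh, lbw = dc$lbw, tbw = dc$tbw,
       ss = ss, tau = as.numeric(tau),
       err_cv = prior@cvAssay, err_s = prior@sAssay,
       ode_step = odeStep,
       names = est$name)
}

#' Individual log-posterior
#'
#' Sum of Normal(eta_k; 0, omega_k^2) log-densities and Normal(Cobs;
#' Cpred, sigma_i^2) log-densities with sigma_i = cv_assay * Cpred_i +
#' s_assay (all normalizing constants included).
#'
#' @param drug drug name.
#' @param data single-patient [TDMDataset-class].
#' @param prior a [PriorSpec-class] (default the drug's registry prior).
#' @param eta numeric vector of log-scale deviations, one per estimated
#'   parameter.
#' @param ss treat observation times as lying in a steady-state interval.
#' @return scalar log-posterior value.
#' @export
logPosterior <- function(drug, data, prior = defaultPrior(drug), eta,
                         ss = FALSE) {
  d <- .matchDrug(drug)
  ld <- .lpData(d, data, prior, ss)
  stopifnot(length(eta) == length(ld$omega))
  cpp_logpost(.drugCode(d), as.numeric(eta), ld, FALSE)$value
}

#' Gradient of the individual log-posterior
#'
#' Computed by complex-step differentiation of the compiled model (exact
#' to machine precision).
#'
#' @inheritParams logPosterior
#' @return gradient vector with respect to eta.
#' @export
gradLogPosterior <- function(drug, data, prior = defaultPrior(drug), eta,
                             ss = FALSE) {
  d <- .matchDrug(drug)
  ld <- .lpData(d, data, prior, ss)
  stopifnot(length(eta) == length(ld$omega))
  cpp_logpost(.drugCode(d), as.numeric(eta), ld, TRUE)$grad
}

#' Fit individual PK parameters by Hamiltonian Monte Carlo
#'
#' Runs independent chains of a dynamic (No-U-Turn) HMC sampler with
#' leapfrog integration, dual-averaging step-size adaptation, and diagonal
#' mass-matrix estimation during warmup. The posterior median of the
#' pooled post-warmup draws is the point estimate. A result with split
#' R-hat above 1.1 on any parameter is returned flagged as non-converged
#' (with a warning), not raised as an error.
#'
#' @param drug drug name.
#' @param data single-patient [TDMDataset-class]; may be `NULL` when
#'   `priorOnly = TRUE`.
#' @param prior a [PriorSpec-class].
#' @param settings a [SamplerSettings-class].
#' @param ss treat observation times as lying in a steady-state interval
#'   (linear drugs).
#' @param priorOnly sample the prior (no observations).
#' @param odeStep in-sampler integration step for the phenytoin kernel (h).
#' @return a [PosteriorResult-class].
#' @export
hmcFit <- function(drug, data = NULL, prior = defaultPrior(drug),
                   settings = samplerSettings(), ss = FALSE,
                   priorOnly = FALSE, odeStep = 0.1) {
  d <- .matchDrug(drug)
  if (priorOnly) {
    cov0 <- list(weight = 65.1, height = 165.1, age = 50.2, sex = 0L, scr = 1.0)
    ev0 <- data.frame(id = 1, time = 0, evid = 1L, amt = 1, cmt = 1L,
                      rate = 0, ii = NA_real_, addl = NA_real_, dv = NA_real_)
    ld <- .lpData(d, list(events = ev0, cov = cov0), prior, FALSE, odeStep)
  } else {
    if (is.null(data)) stop("data required unless priorOnly = TRUE",
                            call. = FALSE)
    ld <- .lpData(d, data, prior, ss, odeStep)
    if (length(ld$obs_t) < 1)
      stop("at least one observation required (or set priorOnly = TRUE)",
           call. = FALSE)
  }
  L <- length(ld$omega)
  inits <- .withSeed(as.numeric(settings@seed) * 7 + 13,
                     matrix(rnorm(settings@chains * L, 0, 0.1),
                            settings@chains, L))
  fit <- cpp_nuts(.drugCode(d), ld, settings@chains, settings@warmup,
                  settings@samples, settings@targetAccept,
                  settings@maxTreedepth, settings@seed, inits)
  nm <- ld$names
  etaByChain <- lapply(seq_len(settings@chains), function(c) {
    m <- fit$draws[(c - 1) * settings@samples + seq_len(settings@samples), ,
                   drop = FALSE]
    colnames(m) <- nm
    m
  })
  natByChain <- lapply(etaByChain, function(m)
    sweep(exp(m), 2, ld$prior_mean, `*`))
  pooled <- do.call(rbind, natByChain)
  pe <- apply(pooled, 2, median)
  ci <- t(apply(pooled, 2, quantile, probs = c(0.05, 0.95)))
  colnames(ci) <- c("q5", "q95")
  diag <- .chainDiagnostics(etaByChain, fit$divergences)
  conv <- all(is.na(diag$rhat) | diag$rhat < 1.1) &&
    sum(fit$divergences) < 0.5 * settings@chains * settings@samples
  if (!conv)
    warning("HMC fit flagged non-converged (max R-hat ",
            signif(max(diag$rhat, na.rm = TRUE), 4), ", ",
            sum(fit$divergences), " divergences)", call. = FALSE)
  new("PosteriorResult", drug = d, draws = natByChain, etaDraws = etaByChain,
      pointEstimate = pe, intervals = ci, diagnostics = diag,
      converged = conv, settings = settings)
}

# ---- convergence diagnostics ---------------------------------------------

# Rank-normalized values, pooled over chains (matrix iterations x chains).
.rankNorm <- function(x) {
  S <- length(x)
  z <- qnorm((rank(x, ties.method = "average") - 3 / 8) / (S - 1 / 4))
  array(z, dim = dim(x))
}

# Split R-hat on a (iterations x chains) matrix.
.splitRhat <- function(x) {
  n <- nrow(x)
  if (n < 4 || ncol(x) < 1) return(NA_real_)
  half <- floor(n / 2)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  mu <- colMeans(sp)
  W <- mean(apply(sp, 2, var))
  if (!is.finite(W) || W <= 0) return(NA_real_)
  B <- nn * var(mu)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Bulk effective sample size via split-chain autocorrelations (Geyer
# initial positive sequence) on rank-normalized draws.
.bulkEss <- function(x) {
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  W <- mean(apply(sp, 2, var))
  mu <- colMeans(sp)
  varPlus <- W * (nn - 1) / nn + var(mu)
  if (!is.finite(varPlus) || varPlus <= 0) return(NA_real_)
  maxLag <- min(nn - 1, 200)
  acs <- sapply(seq_len(m), function(j)
    as.numeric(acf(sp[, j], lag.max = maxLag, plot = FALSE,
                   demean = TRUE)$acf))
  acVar <- apply(sp, 2, var)
  rho <- 1 - (W - colMeans(t(acs[-1, , drop = FALSE]) * acVar)) / varPlus
  # Geyer: sum consecutive pairs while positive
  tauSum <- 0
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    tauSum <- tauSum + pair
    k <- k + 2
  }
  ess <- m * nn / (1 + 2 * tauSum)
  min(ess, m * nn)
}

.chainDiagnostics <- function(etaByChain, divergences) {
  nm <- colnames(etaByChain[[1]])
  L <- ncol(etaByChain[[1]])
  rhat <- ess <- numeric(L)
  for (k in seq_len(L)) {
    x <- sapply(etaByChain, function(m) m[, k])
    if (is.null(dim(x))) x <- matrix(x, ncol = length(etaByChain))
    if (var(as.numeric(x)) <= .Machine$double.eps) {
      rhat[k] <- NA_real_; ess[k] <- NA_real_
    } else {
      z <- .rankNorm(x)
      rhat[k] <- if (ncol(x) >= 2) .splitRhat(z) else NA_real_
      ess[k] <- .bulkEss(z)
    }
  }
  data.frame(parameter = nm, rhat = rhat, essBulk = ess,
             divergences = sum(divergences), stringsAsFactors = FALSE)
}

#' Convergence diagnostics of a posterior result
#'
#' Rank-normalized split R-hat, bulk effective sample size, and divergence
#' counts. With a single chain R-hat is reported as `NA`.
#'
#' @param result a [PosteriorResult-class], or a list of per-chain draw
#'   matrices.
#' @return data.frame with parameter, rhat, essBulk, divergences.
#' @export
mcmcDiagnostics <- function(result) {
  if (is(result, "PosteriorResult")) return(result@diagnostics)
  .chainDiagnostics(result, 0L)
}

#' Write posterior draws to CSV
#'
#' One row per draw with chain and iteration indices, natural-scale
#' parameter columns.
#'
#' @param x a [PosteriorResult-class].
#' @param path output CSV path.
#' @export
writeDraws <- function(x, path) {
  m <- do.call(rbind, lapply(seq_along(x@draws), function(c)
    data.frame(chain = c, iteration = seq_len(nrow(x@draws[[c]])),
               x@draws[[c]])))
  write.csv(m, path, row.names = FALSE)
  invisible(NULL)
}
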