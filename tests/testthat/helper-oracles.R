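# Independent numerical oracles and small construction helpers used across
# the test files. The oracles deliberately avoid the package's compiled
# kernels: linear models are integrated with deSolve::lsoda, the
# Michaelis-Menten model with a plain R fixed-step RK4.

doseFrame <- function(time, amt, rate = 0) {
  data.frame(time = time, amt = amt, rate = rate)
}

stdCov <- function(sex = 0L) {
  list(weight = 65.1, height = 165.1, age = 50.2, sex = sex, scr = 1.0)
}

# One-patient event frame: one dose row plus observation rows.
eventFrame <- function(doseAmt, doseRate, ii, obsTimes, dv,
                       addl = 0L, doseTime = 0) {
  rbind(data.frame(id = 1, time = doseTime, evid = 1L, amt = doseAmt,
                   cmt = 1L, rate = doseRate, ii = ii, addl = addl,
                   dv = NA_real_),
        if (length(obsTimes))
          data.frame(id = 1, time = obsTimes, evid = 0L, amt = NA_real_,
                     cmt = 1L, rate = 0, ii = NA_real_, addl = NA_real_,
                     dv = dv))
}

onePatientDataset <- function(drug, events, cov = stdCov()) {
  tdmDataset(drug, data.frame(id = 1, weight = cov$weight,
                              height = cov$height, age = cov$age,
                              sex = cov$sex, scr = cov$scr), events)
}

# Segment-wise lsoda integration of the linear compartment models.
# model 1: central amount;        pars (CL, V)
# model 2: central + peripheral;  pars (CL, V, k12, k21)
# model 3: depot + central;       pars (CL, V, ka, F); doses enter the depot
odeOracleLinear <- function(model, pars, doses, times,
                            rtol = 1e-11, atol = 1e-13) {
  cl <- pars[1]; v <- pars[2]
  k10 <- cl / v
  k12 <- if (model == 2) pars[3] else 0
  k21 <- if (model == 2) pars[4] else 0
  ka <- if (model == 3) pars[3] else 0
  f <- if (model == 3) pars[4] else 1
  ends <- ifelse(doses$rate > 0, doses$time + doses$amt / doses$rate,
                 doses$time)
  nodes <- sort(unique(c(0, doses$time, ends, times)))
  y <- c(0, 0)
  out <- numeric(length(times))
  for (s in seq_len(length(nodes))) {
    tcur <- nodes[s]
    # instantaneous doses at tcur
    hit <- which(doses$rate <= 0 & abs(doses$time - tcur) < 1e-12)
    for (k in hit) {
      if (model == 3) y[1] <- y[1] + f * doses$amt[k]
      else y[1] <- y[1] + doses$amt[k]
    }
    if (any(abs(times - tcur) < 1e-12))
      out[abs(times - tcur) < 1e-12] <- y[if (model == 3) 2 else 1] / v
    if (s == length(nodes)) break
    tnext <- nodes[s + 1]
    tmid <- (tcur + tnext) / 2
    rin <- sum(doses$rate[doses$rate > 0 & doses$time < tmid & ends > tmid])
    rhs <- function(t, y, p) {
      if (model == 3)
        list(c(-ka * y[1], ka * y[1] - k10 * y[2]))
      else
        list(c(rin - (k10 + k12) * y[1] + k21 * y[2],
               k12 * y[1] - k21 * y[2]))
    }
    sol <- deSolve::lsoda(y, c(tcur, tnext), rhs, parms = NULL,
                          rtol = rtol, atol = atol)
    y <- as.numeric(sol[nrow(sol), -1])
  }
  out
}

# Fixed-step RK4 oracle for Michaelis-Menten elimination with zero-order
# input; pars (vmaxH mg/h, km, V, clLin, F).
rk4OracleMm <- function(pars, doses, times, h = 1e-3) {
  vmax <- pars[1]; km <- pars[2]; v <- pars[3]; clLin <- pars[4]
  f <- pars[5]
  ends <- ifelse(doses$rate > 0, doses$time + doses$amt / doses$rate,
                 doses$time)
  nodes <- sort(unique(c(0, doses$time, ends, times)))
  rhs <- function(a, rin) rin - vmax * (a / v) / (km + a / v) - clLin * a / v
  a <- 0
  out <- numeric(length(times))
  for (s in seq_len(length(nodes))) {
    tcur <- nodes[s]
    hit <- which(doses$rate <= 0 & abs(doses$time - tcur) < 1e-12)
    for (k in hit) a <- a + f * doses$amt[k]
    if (any(abs(times - tcur) < 1e-12))
      out[abs(times - tcur) < 1e-12] <- a / v
    if (s == length(nodes)) break
    tnext <- nodes[s + 1]
    tmid <- (tcur + tnext) / 2
    rin <- f * sum(doses$rate[doses$rate > 0 & doses$time < tmid &
                              ends > tmid])
    span <- tnext - tcur
    nstep <- max(1L, ceiling(span / h))
    hh <- span / nstep
    for (m in seq_len(nstep)) {
      k1 <- rhs(a, rin)
      k2 <- rhs(a + hh / 2 * k1, rin)
      k3 <- rhs(a + hh / 2 * k2, rin)
      k4 <- rhs(a + hh * k3, rin)
      a <- a + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (a < 0) a <- 0
  }
  out
}

# Profile-relative discrepancy (relative to the profile maximum, so that
# near-zero tails do not blow up the ratio).
relErr <- function(a, b) max(abs(a - b)) / max(abs(b))
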