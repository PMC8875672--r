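# Forward models: event expansion, closed-form kernels against frozen
# hand-derived values and the independent ODE oracle, steady state,
# superposition, and the Michaelis-Menten kernel.

test_that("addl/ii dose records expand correctly", {
  ev <- eventFrame(500, 1000, ii = 8, obsTimes = numeric(0), dv = numeric(0),
                   addl = 2L)
  d <- expandEvents(ev)
  expect_equal(d$time, c(0, 8, 16))
  expect_equal(d$amt, rep(500, 3))
  ev0 <- eventFrame(500, 1000, ii = 8, obsTimes = numeric(0),
                    dv = numeric(0), addl = 0L)
  expect_equal(nrow(expandEvents(ev0)), 1L)
  bad <- eventFrame(500, 1000, ii = 0, obsTimes = numeric(0),
                    dv = numeric(0), addl = 3L)
  expect_error(expandEvents(bad), "schedule error")
})

test_that("one-compartment infusion matches the analytic hand values", {
  # 1000 mg/h for 0.5 h, CL 5, V 20: C(0.5) = 200 (1 - e^-0.125)
  d <- doseFrame(0, 500, 1000)
  expect_equal(conc1CmtInfusion(5, 20, d, 0.5), 200 * (1 - exp(-0.125)),
               tolerance = 1e-10)
  expect_equal(conc1CmtInfusion(5, 20, d, 0), 0)
  # continuous infusion approaches R/CL
  dInf <- doseFrame(0, 1e7, 1000)
  expect_equal(conc1CmtInfusion(5, 20, dInf, 200), 200, tolerance = 1e-4)
})

test_that("two-compartment hybrid constants and limits are correct", {
  # CL 3, V 10, k12 1.12, k21 0.48 -> lambda 1.82092 / 0.0790845
  k10 <- 0.3; k12 <- 1.12; k21 <- 0.48
  s <- k10 + k12 + k21
  l1 <- (s + sqrt(s^2 - 4 * k10 * k21)) / 2
  l2 <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
  expect_equal(l1, 1.820919, tolerance = 1e-6)
  expect_equal(l2, 0.07908095, tolerance = 1e-6)
  expect_equal(l1 * l2, k10 * k21)
  # k12 = 0 collapses to the one-compartment profile
  d <- doseFrame(0, 500, 1000)
  tt <- seq(0.25, 24, by = 0.25)
  expect_equal(conc2CmtInfusion(3, 10, 1e-12, 0.48, d, tt),
               conc1CmtInfusion(3, 10, d, tt), tolerance = 1e-8)
  # bolus initial condition C(0+) = Dose/V
  db <- doseFrame(0, 500, 0)
  expect_equal(conc2CmtInfusion(3, 10, 1.12, 0.48, db, 1e-9), 50,
               tolerance = 1e-6)
})

test_that("oral model matches the Bateman equation and printed tmax", {
  d <- doseFrame(0, 200, 0)
  # F D 200, V 30, ka 0.27, ke 0.08: C(4) = 9.4737 (e^-0.32 - e^-1.08)
  expect_equal(conc1CmtOral(0.08 * 30, 30, 0.27, 1, d, 4),
               200 * 0.27 / (30 * 0.19) * (exp(-0.32) - exp(-1.08)),
               tolerance = 1e-10)
  expect_equal(conc1CmtOral(0.08 * 30, 30, 0.27, 1, d, 0), 0)
  expect_equal(oralTmax(0.27, 0.08), log(0.27 / 0.08) / 0.19,
               tolerance = 1e-12)
  # ka ~= ke limiting form stays finite and continuous
  cNear <- conc1CmtOral(0.27 * 30 * (1 + 1e-9), 30, 0.27, 1, d, 4)
  cLim <- 200 * 0.27 * 4 * exp(-0.27 * 4) / 30
  expect_equal(cNear, cLim, tolerance = 1e-4)
})

test_that("closed forms agree with the independent ODE oracle", {
  set.seed(81)
  for (rep in 1:12) {
    cl <- runif(1, 1, 10); v <- runif(1, 10, 50)
    k12 <- runif(1, 0.5, 1.5); k21 <- runif(1, 0.2, 1.0)
    ka <- runif(1, 0.05, 0.5)
    nd <- sample(1:3, 1)
    dtimes <- sort(runif(nd, 0, 12))
    amts <- runif(nd, 100, 1000)
    rates <- ifelse(runif(nd) < 0.5, 0, runif(nd, 200, 1500))
    doses <- doseFrame(dtimes, amts, rates)
    tt <- sort(runif(8, 0.5, 36))
    a1 <- conc1CmtInfusion(cl, v, doses, tt)
    expect_lt(relErr(a1, odeOracleLinear(1, c(cl, v), doses, tt)), 1e-6)
    a2 <- conc2CmtInfusion(cl, v, k12, k21, doses, tt)
    expect_lt(relErr(a2, odeOracleLinear(2, c(cl, v, k12, k21), doses, tt)),
              1e-6)
    dOral <- doseFrame(dtimes, amts, 0)
    a3 <- conc1CmtOral(cl, v, ka, 0.9, dOral, tt)
    expect_lt(relErr(a3, odeOracleLinear(3, c(cl, v, ka, 0.9), dOral, tt)),
              1e-6)
  }
})

test_that("analytic steady state equals brute-force superposition", {
  d1 <- doseFrame(0, 500, 1000)
  tt <- c(0.25, 1, 4, 8)
  css <- conc1CmtInfusion(3.28, 14, d1, tt, ss = TRUE, tau = 8)
  d30 <- doseFrame((0:29) * 8, 500, 1000)
  csup <- conc1CmtInfusion(3.28, 14, d30, 29 * 8 + tt)
  expect_equal(css, csup, tolerance = 1e-6)
  css2 <- conc2CmtInfusion(3, 25, 1.12, 0.48, doseFrame(0, 1000, 500),
                           c(2, 6, 12), ss = TRUE, tau = 12)
  d40 <- doseFrame((0:39) * 12, 1000, 500)
  csup2 <- conc2CmtInfusion(3, 25, 1.12, 0.48, d40, 39 * 12 + c(2, 6, 12))
  expect_equal(css2, csup2, tolerance = 1e-6)
  cssO <- conc1CmtOral(2, 25, 0.27, 1, doseFrame(0, 200, 0), c(4, 12),
                       ss = TRUE, tau = 12)
  d60 <- doseFrame((0:59) * 12, 200, 0)
  csupO <- conc1CmtOral(2, 25, 0.27, 1, d60, 59 * 12 + c(4, 12))
  expect_equal(cssO, csupO, tolerance = 1e-6)
})

test_that("linear superposition holds; phenytoin is super-linear", {
  cov <- stdCov()
  tt <- c(2, 6, 8)
  ev1 <- eventFrame(500, 1000, 8, numeric(0), numeric(0))
  ev2 <- eventFrame(1000, 2000, 8, numeric(0), numeric(0))
  p <- c(CLslope = 0.815, CLnr = 0.0417, Vnr = 0.27)
  c1 <- simulateProfile("amikacin", p, cov, ev1, tt)$conc
  c2 <- simulateProfile("amikacin", p, cov, ev2, tt)$conc
  expect_equal(c2, 2 * c1, tolerance = 1e-10)
  php <- c(Vmax = 500, km = 5, Vnr = 0.8)
  evp1 <- eventFrame(100, 50, 8, numeric(0), numeric(0), addl = 4L)
  evp2 <- eventFrame(200, 100, 8, numeric(0), numeric(0), addl = 4L)
  t1 <- simulateProfile("phenytoin", php, cov, evp1, 40)$conc
  t2 <- simulateProfile("phenytoin", php, cov, evp2, 40)$conc
  expect_gt(t2, 2 * t1) # saturable elimination accumulates more than 2x
})

test_that("Michaelis-Menten kernel matches the fixed-step RK4 oracle", {
  pars <- c(500 / 24, 5, 45, 0.04, 1)
  doses <- doseFrame(c(0, 8), 100, 50)
  tt <- c(1, 2, 4, 8, 8.5, 12, 16)
  mine <- concMichaelisMenten(pars[1], pars[2], pars[3], pars[4], pars[5],
                              doses, tt, step = 0.005)
  orc <- rk4OracleMm(pars, doses, tt, h = 1e-3)
  expect_lt(relErr(mine, orc), 1e-6)
  # mass balance: delivered = remaining + eliminated (integrate elimination)
  grid <- seq(0, 16, by = 0.002)
  cg <- concMichaelisMenten(pars[1], pars[2], pars[3], pars[4], pars[5],
                            doses, grid, step = 0.005)
  elim <- pars[1] * cg / (pars[2] + cg) + pars[4] * cg
  eliminated <- sum((elim[-1] + elim[-length(elim)]) / 2 * diff(grid))
  delivered <- 200 # F = 1, both doses delivered by 10 h
  remaining <- cg[length(cg)] * pars[3]
  expect_equal(delivered, remaining + eliminated, tolerance = 1e-3)
  # km -> infinity with Vmax/km fixed approaches the linear model
  km <- 1e6; clEq <- 2.0; vmax <- clEq * km
  lin <- concMichaelisMenten(vmax, km, 45, 0, 1, doseFrame(0, 100, 50), tt,
                             step = 0.005)
  linRef <- conc1CmtInfusion(clEq, 45, doseFrame(0, 100, 50), tt)
  expect_equal(lin, linRef, tolerance = 1e-5)
})

test_that("profiles are continuous across infusion boundaries", {
  d <- doseFrame(0, 500, 1000) # infusion ends at 0.5 h
  eps <- 1e-7
  c1 <- conc1CmtInfusion(5, 20, d, c(0.5 - eps, 0.5, 0.5 + eps))
  expect_lt(max(abs(diff(c1))), 1e-4)
  c2 <- conc2CmtInfusion(5, 20, 1.1, 0.5, d, c(0.5 - eps, 0.5, 0.5 + eps))
  expect_lt(max(abs(diff(c2))), 1e-4)
})

test_that("simulateProfile dispatches and respects conventions", {
  cov <- stdCov()
  p <- c(CLslope = 0.815, CLnr = 0.0417, Vnr = 0.27)
  # a dose expressed via addl equals the same doses given explicitly
  evA <- eventFrame(500, 1000, 8, numeric(0), numeric(0), addl = 2L)
  evB <- rbind(eventFrame(500, 1000, 8, numeric(0), numeric(0)),
               transform(eventFrame(500, 1000, 8, numeric(0), numeric(0)),
                         time = 8),
               transform(eventFrame(500, 1000, 8, numeric(0), numeric(0)),
                         time = 16))
  tt <- c(1, 9, 17)
  expect_equal(simulateProfile("amikacin", p, cov, evA, tt)$conc,
               simulateProfile("amikacin", p, cov, evB, tt)$conc)
  # observation before the first dose is zero
  evLate <- eventFrame(500, 1000, 8, numeric(0), numeric(0), doseTime = 4)
  expect_equal(simulateProfile("amikacin", p, cov, evLate, 2)$conc, 0)
  # steady state flag equals 30-dose superposition
  ev <- eventFrame(500, 1000, 8, numeric(0), numeric(0))
  css <- simulateProfile("amikacin", p, cov, ev, c(1, 8),
                         atSteadyState = TRUE)$conc
  ev30 <- eventFrame(500, 1000, 8, numeric(0), numeric(0), addl = 29L)
  csup <- simulateProfile("amikacin", p, cov, ev30, 29 * 8 + c(1, 8))$conc
  expect_equal(css, csup, tolerance = 1e-6)
})
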