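# Multiple-dose simulator and PK metrics: closed-form oracles for the
# one-compartment reduction, trapezoid/trough bookkeeping, unit conversion,
# and solver-convergence audits.

test_that("one-compartment reduction matches the Bateman closed form", {
  ka <- 2; k <- 0.1; F <- 0.7; Vc <- 70
  p <- oneCompartmentParams(ka = ka, k = k, F = F, Vc = Vc)
  reg <- DoseRegimen(data.frame(time = 0, drug = "dabrafenib_hpmc",
                                dose_mg = 150),
                     horizon = 48, grid = seq(0, 48, by = 0.25))
  tr <- simulateRegimen(reg, p)
  exact <- batemanCurve(tr@times, 150, ka, k, F, Vc)
  expect_lt(max(abs(tr@states[, "D0c"] - exact)) / max(exact), 1e-6)
})

test_that("zero-dose regimen from drug-free equilibrium stays flat", {
  p <- defaultParameters()
  reg <- DoseRegimen(data.frame(time = numeric(0), drug = character(0),
                                dose_mg = numeric(0)), horizon = 48)
  tr <- simulateRegimen(reg, p)
  drugCols <- setdiff(stateNames(), c("Ef", "EB"))
  expect_true(all(abs(tr@states[, drugCols]) < 1e-10))
  expect_lt(max(abs(tr@states[, "Ef"] - tr@states[1, "Ef"])), 1e-6)
})

test_that("repeated-dose accumulation matches the superposition closed form", {
  ka <- 2000; k <- 0.05; tau <- 24; n <- 12
  p <- oneCompartmentParams(ka = ka, k = k)
  doseT <- (seq_len(n) - 1) * tau
  reg <- DoseRegimen(data.frame(time = doseT, drug = "dabrafenib_hpmc",
                                dose_mg = 75),
                     horizon = n * tau,
                     grid = denseDoseGrid(doseT, n * tau))
  tr <- simulateRegimen(reg, p)
  m <- pkMetrics(tr, "D0", unit = "nM")
  expect_lt(abs(m$accumulation_ratio - 1 / (1 - exp(-k * tau))), 1e-4)
})

test_that("PK metrics on a hand-specified profile are exact", {
  tr <- toyTrajectory(c(0, 1, 2), c(0, 10, 5))
  m <- pkMetrics(tr, "D0", unit = "nM")
  expect_equal(m$Cmax, 10)
  expect_equal(m$Tmax, 1)
  expect_equal(m$AUC, 12.5)   # trapezoid by hand
  z <- pkMetrics(toyTrajectory(c(0, 1, 2), c(0, 0, 0)), "D0", unit = "nM")
  expect_equal(z$Cmax, 0)
  expect_equal(z$AUC, 0)
  dec <- pkMetrics(toyTrajectory(c(0, 1, 2), c(9, 6, 3)), "D0", unit = "nM")
  expect_equal(dec$Tmax, 0)   # strictly decreasing: peak at grid start
  expect_error(pkMetrics(tr, "nosuch"), "unknown analyte")
})

test_that("time to steady state follows the trough contract", {
  expect_equal(timeToSteadyState(c(1, 2, 3, 4, 4, 4), doseTimes = 1:6), 4)
  r <- 0.5
  troughs <- (1 - r^(1:12))
  expect_equal(timeToSteadyState(troughs, doseTimes = 1:12), 5)
  expect_equal(timeToSteadyState(rep(2, 6), doseTimes = 11:16), 11)
  expect_error(timeToSteadyState(c(1, 2, 4, 8), doseTimes = 1:4),
               "not reached")
})

test_that("washout time matches the exponential closed form", {
  k <- 0.2; thalf <- log(2) / k
  tt <- seq(0, 60, by = 0.01)
  tr <- toyTrajectory(tt, 100 * exp(-k * tt))
  wo <- washoutTime(tr, "D0", thresholdFraction = 0.01)
  expect_lt(abs(wo - log2(100) * thalf) / (log2(100) * thalf), 0.01)
  expect_equal(washoutTime(tr, "D0", thresholdFraction = 1.0), 0)
  expect_equal(washoutTime(toyTrajectory(tt, rep(0, length(tt))), "D0"), 0)
})

test_that("concentration unit conversion is exact", {
  expect_equal(round(convertConcentration(6000, "ng/mL", "uM", 531.4), 2),
               11.29)
  expect_identical(convertConcentration(0, "ng/mL", "nM", 500), 0)
  expect_equal(convertConcentration(519.6, "ng/mL", "uM", 519.6), 1)
  expect_equal(convertConcentration(1, "uM", "ng/mL", 531.4), 531.4)
  expect_error(convertConcentration(1, "mg/dL", "nM", 500), "unknown unit")
  expect_error(convertConcentration(1, "nM", "uM", -1), "mw")
})

test_that("halving solver tolerances leaves metrics unchanged to 0.1%", {
  p <- defaultParameters()
  reg <- DoseRegimen(data.frame(time = 0, drug = "dabrafenib_solution",
                                dose_mg = 95), horizon = 96)
  m1 <- pkMetrics(simulateRegimen(reg, p, rtol = 1e-8, atol = 1e-10), "DC")
  m2 <- pkMetrics(simulateRegimen(reg, p, rtol = 5e-9, atol = 5e-11), "DC")
  expect_lt(abs(m1$Cmax - m2$Cmax) / m2$Cmax, 1e-3)
  expect_lt(abs(m1$AUC - m2$AUC) / m2$AUC, 1e-3)
})

test_that("grid refinement x4 changes the trapezoid AUC by < 0.5%", {
  p <- defaultParameters()
  g1 <- seq(0, 96, by = 1)
  g4 <- seq(0, 96, by = 0.25)
  ev <- data.frame(time = 0, drug = "dabrafenib_solution", dose_mg = 95)
  a1 <- pkMetrics(simulateRegimen(DoseRegimen(ev, 96, g1), p), "DH")$AUC
  a4 <- pkMetrics(simulateRegimen(DoseRegimen(ev, 96, g4), p), "DH")$AUC
  expect_lt(abs(a1 - a4) / a4, 5e-3)
})

test_that("metabolite troughs accumulate monotonically at 150 mg b.d.", {
  p <- defaultParameters()
  tr <- simulateRegimen(bdRegimen(150, endDay = 14, horizon = 14 * 24 + 12),
                        p, rtol = 1e-6, atol = 1e-8)
  for (an in c("DC", "DD")) {
    ser <- trajSeries(tr, an, unit = "nM",
                      times = seq(1, 14) * 24 - 1e-6)
    expect_true(all(diff(ser$value) > 0))
  }
})

test_that("trajectory export is tidy and round-trips", {
  p <- defaultParameters()
  reg <- DoseRegimen(data.frame(time = 0, drug = "dabrafenib_hpmc",
                                dose_mg = 75), horizon = 24)
  tr <- simulateRegimen(reg, p)
  f <- tempfile(fileext = ".csv")
  exportTrajectoryCSV(tr, f)
  d <- utils::read.csv(f)
  expect_setequal(names(d), c("time_h", "species", "value", "unit"))
  expect_equal(nrow(d), length(tr@times) * 21)
  d0 <- d[d$species == "D0c", ]
  expect_equal(d0$value, unname(tr@states[, "D0c"]))
})
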