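# Calibration workflow: RSS objective, the four stages on small synthetic
# problems, the evolutionary optimizer, and local sensitivity.

noiselessDatasetA <- function(params) {
  tpl <- designTemplates(cv = 0, nReplicates = 1)
  generate(tpl$single_dose_solution, params, seed = 1)
}

test_that("log-scale RSS matches a hand-evaluated residual", {
  p <- defaultParameters()
  # zero-dose regimen: model predicts 0; one observation of 90 with floor 10
  # gives (log 10 - log 100)^2 = (ln 0.1)^2
  reg <- DoseRegimen(data.frame(time = numeric(0), drug = character(0),
                                dose_mg = numeric(0)), horizon = 24)
  ds <- new("PKDataset", studyId = "hand", arms = list(
    a1 = list(regimen = reg,
              data = data.frame(analyte = "D0", time_h = 2, value = 90,
                                unit = "ng/mL", replicate = 1))),
    provenance = list())
  r <- rss(ds, p, delta = 10)
  expect_lt(abs(as.numeric(r) - log(0.1)^2), 1e-10)
})

test_that("RSS vanishes on noiseless self-generated data", {
  p <- defaultParameters()
  ds <- noiselessDatasetA(p)
  expect_lt(as.numeric(rss(ds, p)), 1e-10)
})

test_that("an arm without observations does not change the RSS", {
  p <- defaultParameters()
  ds <- noiselessDatasetA(p)
  r0 <- as.numeric(rss(ds, p, delta = 10))
  ds@arms$empty <- list(
    regimen = ds@arms[[1]]$regimen,
    data = data.frame(analyte = character(0), time_h = numeric(0),
                      value = numeric(0), unit = character(0),
                      replicate = integer(0)))
  expect_equal(as.numeric(rss(ds, p, delta = 10)), r0)
})

test_that("RSS is a pure function of the parameters", {
  p <- defaultParameters()
  ds <- noiselessDatasetA(p)
  p2 <- p
  param(p2, "kcat_D0") <- 2 * param(p, "kcat_D0")
  r2 <- as.numeric(rss(ds, p2))
  param(p2, "kcat_D0") <- param(p, "kcat_D0")
  expect_identical(as.numeric(rss(ds, p2)), as.numeric(rss(ds, p)))
  expect_gt(r2, as.numeric(rss(ds, p)))
})

test_that("differential evolution is seeded-deterministic and finds minima", {
  sphere <- function(x) sum((x - c(1, -2, 0.5))^2)
  r1 <- deOptim(sphere, rep(-5, 3), rep(5, 3), seed = 9, popSize = 20,
                generations = 60)
  r2 <- deOptim(sphere, rep(-5, 3), rep(5, 3), seed = 9, popSize = 20,
                generations = 60)
  expect_identical(r1$par, r2$par)
  expect_lt(r1$value, 1e-4)
  r3 <- deOptim(sphere, rep(-5, 3), rep(5, 3), seed = 10, popSize = 20,
                generations = 60)
  expect_false(identical(r1$par, r3$par))
})

test_that("stage 1 with collapsed bounds returns the pinned parameters", {
  p <- defaultParameters()
  p0 <- p; param(p0, "kr") <- 0   # stage-1 conditions: induction off
  ds <- noiselessDatasetA(p0)
  free <- c("kcat_D0", "ka_sol")
  x <- log10(param(p, free))
  fit <- fitStage1(list(ds), p, free = free,
                   bounds = list(lower = x, upper = x), seed = 1)
  expect_equal(unname(param(fit@params, free)), unname(10^x))
  expect_lt(fit@rss, 1e-10)
  expect_true("bounds collapsed to a point" %in% fit@flags)
})

test_that("stage 1 refuses induction parameters and is seed-reproducible", {
  p <- defaultParameters()
  ds <- noiselessDatasetA(p)
  expect_error(fitStage1(list(ds), p, free = c("kr", "kcat_D0"), seed = 1),
               "induction disabled")
  free <- c("kcat_D0", "Vmax_pH")
  b <- list(lower = stats::setNames(log10(param(p, free)) - 0.3, free),
            upper = stats::setNames(log10(param(p, free)) + 0.3, free))
  ctl <- list(popSize = 8, generations = 5, polish = FALSE)
  f1 <- fitStage1(list(ds), p, free = free, bounds = b, seed = 5, control = ctl)
  f2 <- fitStage1(list(ds), p, free = free, bounds = b, seed = 5, control = ctl)
  expect_identical(param(f1@params), param(f2@params))
})

test_that("stage 2 recovers a constant enzyme level within 2%", {
  p <- defaultParameters()
  param(p, "kr") <- 0
  reg <- bdRegimen(75, endDay = 6, horizon = 6 * 24 + 12)
  tr <- simulateRegimen(reg, p)
  tt <- seq(1, 6) * 24 - 0.001
  td <- data.frame(time_h = tt,
                   value = trajSeries(tr, "D0", "ng/mL", times = tt)$value,
                   unit = "ng/mL", analyte = "D0")
  prof <- fitStage2EnzymeProfile(p, td, reg)
  fitted <- prof@intervals$E_total[prof@intervals$flag == ""]
  expect_true(all(abs(fitted - param(p, "E0")) / param(p, "E0") < 0.02))
})

test_that("stage 2 recovers a mid-study enzyme step within 5%", {
  p <- defaultParameters()
  param(p, "kr") <- 0
  E0 <- unname(param(p, "E0")); Ehi <- 2 * E0
  reg <- bdRegimen(75, endDay = 10, horizon = 10 * 24 + 12)
  trLo <- simulateRegimen(reg, p)
  # splice: continue from the day-5 state with doubled total enzyme
  y5 <- stats::setNames(pmax(trLo@states[which.min(abs(trLo@times - 120)), ], 0),
                        stateNames())
  s <- (Ehi - sum(y5[c("ED0", "EDH", "EDD", "EK")])) / (y5["Ef"] + y5["EB"])
  y5[c("Ef", "EB")] <- y5[c("Ef", "EB")] * s
  ev2 <- reg@events[reg@events$time >= 120, ]
  ev2$time <- ev2$time - 120
  pHi <- p; param(pHi, "E0") <- Ehi
  trHi <- simulateRegimen(DoseRegimen(ev2, horizon = 132), pHi, init = y5)
  tt <- seq(1, 10) * 24 - 0.001
  vals <- c(trajSeries(trLo, "D0", "ng/mL", times = tt[1:5])$value,
            trajSeries(trHi, "D0", "ng/mL", times = tt[6:10] - 120)$value)
  td <- data.frame(time_h = tt, value = vals, unit = "ng/mL", analyte = "D0")
  prof <- fitStage2EnzymeProfile(p, td, reg)
  E <- prof@intervals$E_total
  expect_true(all(abs(E[1:5] - E0) / E0 < 0.05))
  # settled post-step intervals (the transition day itself mixes both levels)
  expect_true(all(abs(E[8:10] - Ehi) / Ehi < 0.05))
})

test_that("stage 2 without any trough data errors; gaps are carried forward", {
  p <- defaultParameters()
  reg <- bdRegimen(75, endDay = 3, horizon = 3 * 24 + 12)
  expect_error(fitStage2EnzymeProfile(
    p, data.frame(time_h = numeric(0), value = numeric(0),
                  unit = character(0), analyte = character(0)), reg),
    "no trough")
  tr <- simulateRegimen(reg, p)
  tt <- c(24, 72) - 0.001   # no observation on day 2
  td <- data.frame(time_h = tt,
                   value = trajSeries(tr, "D0", "ng/mL", times = tt)$value,
                   unit = "ng/mL", analyte = "D0")
  prof <- fitStage2EnzymeProfile(p, td, reg)
  expect_identical(prof@intervals$flag[2], "carried_forward")
  expect_equal(prof@intervals$E_total[2], prof@intervals$E_total[1])
})

test_that("stage 3 recovers induction parameters and flags degenerate cases", {
  p <- defaultParameters()
  v <- param(p)
  p1 <- p; param(p1, "kr") <- 0
  tr <- simulateRegimen(bdRegimen(150, endDay = 14, horizon = 14 * 24 + 12), p1,
                        rtol = 1e-6, atol = 1e-8)
  eb <- data.frame(time_h = tr@times, EB = tr@states[, "EB"])
  ebf <- stats::approxfun(eb$time_h, eb$EB, rule = 2)
  tEnd <- seq(1, 14) * 24
  Et <- mcpk:::.simulateMotif(v[["kr"]], v[["TE"]], v[["kdeg"]], v[["kt"]],
                              v[["kEdeg"]], v[["E0"]], v[["eps_hinge"]],
                              ebf, c(0, tEnd))[-1]
  prof <- new("EnzymeProfile",
              intervals = data.frame(start = c(0, tEnd[-14]), end = tEnd,
                                     E_total = Et, flag = ""))
  fit <- fitStage3Induction(prof, eb, p, seed = 3,
                            control = list(popSize = 25, generations = 60))
  est <- param(fit@params, c("kr", "TE", "kdeg"))
  expect_true(all(abs(est - v[c("kr", "TE", "kdeg")]) /
                    v[c("kr", "TE", "kdeg")] < 0.2))
  # flat profile: kr -> 0, flagged unidentifiable
  flat <- new("EnzymeProfile",
              intervals = data.frame(start = c(0, tEnd[-14]), end = tEnd,
                                     E_total = rep(v[["E0"]], 14), flag = ""))
  f0 <- fitStage3Induction(flat, eb, p, seed = 3)
  expect_identical(unname(param(f0@params, "kr")), 0)
  expect_true("induction unidentifiable" %in% f0@flags)
  # TE forced above max(EB): release always active, boundary reported
  fb <- fitStage3Induction(prof, eb, p, seed = 3,
                           free = c("kr", "TE"),
                           bounds = list(lower = c(TE = log10(60)),
                                         upper = c(TE = log10(61))),
                           control = list(popSize = 10, generations = 10))
  expect_true(any(grepl("TE above max", fb@flags)) ||
                any(grepl("bound", fb@flags)))
})

test_that("stage 4 is monotone and returns the warm start when optimal", {
  p <- defaultParameters()
  ds <- noiselessDatasetA(p)
  free <- c("kcat_D0", "Vmax_pH")
  fit <- fitStage4Joint(list(ds), p, free = free, seed = 2,
                        control = list(generations = 0))
  expect_lte(fit@rss, 1e-10)
  expect_lt(max(abs(log(param(fit@params, free) / param(p, free)))), 1e-3)
  # a perturbed warm start is improved, never worsened
  p2 <- p; param(p2, "kcat_D0") <- 1.5 * param(p, "kcat_D0")
  warmRss <- as.numeric(rss(list(ds), p2))
  fit2 <- fitStage4Joint(list(ds), p2, free = free, seed = 2,
                         control = list(generations = 0))
  expect_lte(fit2@rss, warmRss)
})

test_that("local sensitivity matches an analytic derivative and zeroes out", {
  p <- defaultParameters()
  f <- function(pp) 3 * log(unname(param(pp, "kcat_D0")))
  s <- localSensitivity(p, f, parameters = c("kcat_D0", "Vmax_2C8"))
  expect_lt(abs(s$S[s$parameter == "kcat_D0"] - 3), 1e-6)
  # disabled pathway: parameter is 0, sensitivity exactly 0
  expect_identical(s$S[s$parameter == "Vmax_2C8"], 0)
  # non-finite output is flagged undefined
  s2 <- localSensitivity(p, function(pp) NaN, parameters = "kcat_D0")
  expect_identical(s2$flag, "undefined")
})
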