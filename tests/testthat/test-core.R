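# Reaction-network right-hand side: hand-evaluated fluxes, conservation,
# occupancy, induction hinge, and agreement between the R and compiled
# implementations.

test_that("mass-action binding fluxes match hand evaluation", {
  p <- defaultParameters()
  p@values[c("kon_D0", "koff_D0", "kcat_D0")] <- c(0.01, 1, 2)
  p@values[c("q_D0", "ke_D0", "kEdeg", "kBon", "kBoff", "kr", "kt")] <- 0
  y <- stats::setNames(numeric(21), stateNames())
  y["D0c"] <- 100; y["Ef"] <- 10
  d <- mcpkRHS(y, p)
  expect_equal(unname(d["ED0"]), 0.01 * 100 * 10)   # = 10 nM/h
  expect_equal(unname(d["D0c"]), -10)               # pure binding loss
  expect_equal(unname(d["Ef"]), -10)
})

test_that("drug-free baseline equilibrium has exactly zero derivatives", {
  p <- defaultParameters()
  p@values["kEdeg"] <- 0
  p@values["eps_hinge"] <- 0
  v <- param(p)
  y <- stats::setNames(numeric(21), stateNames())
  # EB at threshold, detailed balance with Ef
  y["EB"] <- v[["TE"]]
  y["Ef"] <- v[["kBoff"]] * y["EB"] / v[["kBon"]]
  p@values["E0"] <- y["Ef"] + y["EB"]
  d <- mcpkRHS(y, p)
  expect_true(all(d == 0))
})

test_that("dabrafenib drug moiety has zero net derivative without dosing", {
  p <- defaultParameters()
  v <- param(p)
  set.seed(42)
  for (i in 1:20) {
    y <- randomState()
    d <- mcpkRHS(y, p)
    dTot <- d[["D0s"]] + d[["D0cap"]] +
      (d[["D0c"]] + d[["DHc"]] + d[["DCc"]] + d[["DDc"]]) * v[["Vc"]] +
      (d[["D0p"]] + d[["DHp"]] + d[["DCp"]] + d[["DDp"]]) * v[["Vp"]] +
      (d[["ED0"]] + d[["EDH"]] + d[["EDD"]]) * v[["Vc"]] +
      d[["M"]] + d[["U"]]
    scale <- max(abs(d)) * v[["Vc"]]
    expect_lt(abs(dTot), 1e-9 * max(scale, 1))
  }
})

test_that("derivatives of empty pools are never negative", {
  p <- defaultParameters()
  set.seed(7)
  for (i in 1:10) {
    y <- randomState()
    empty <- sample(stateNames(), 5)
    y[empty] <- 0
    d <- mcpkRHS(y, p)
    expect_true(all(d[empty] >= 0))
  }
})

test_that("negative states and non-finite derivatives are rejected", {
  p <- defaultParameters()
  y <- initialState(p)
  y["D0c"] <- -1
  expect_error(mcpkRHS(y, p), "negative state")
})

test_that("occupancy fractions sum to one and split correctly", {
  p <- defaultParameters()
  set.seed(1)
  for (i in 1:10) {
    y <- randomState()
    f <- occupancyFractions(y)
    expect_lt(abs(sum(f) - 1), 1e-12)
  }
  # drug-free: complexes exactly zero
  f0 <- occupancyFractions(initialState(p))
  expect_identical(unname(f0[c("ED0", "EDH", "EDD", "EK")]), c(0, 0, 0, 0))
  # symmetric state
  y <- stats::setNames(numeric(21), stateNames())
  y[c("Ef", "EB", "ED0", "EDH", "EDD", "EK")] <- 1
  expect_equal(unname(occupancyFractions(y)), rep(1 / 6, 6))
  # zero enzyme undefined
  expect_error(occupancyFractions(stats::setNames(numeric(21), stateNames())),
               "undefined")
})

test_that("induction release follows the threshold hinge", {
  p <- defaultParameters()
  p@values["eps_hinge"] <- 0
  p@values[c("kr", "TE")] <- c(0.5, 10)
  expect_identical(inductionReleaseRate(10, p), 0)    # EB = TE
  expect_identical(inductionReleaseRate(20, p), 0)    # EB = 2 TE
  expect_equal(inductionReleaseRate(0, p), 5.0)       # kr * TE
  expect_error(inductionReleaseRate(-1, p), "EB")
  # strictly increasing in the deficit
  r <- inductionReleaseRate(seq(9.5, 0, by = -0.5), p)
  expect_true(all(diff(r) > 0))
  # softplus smoothing stays close to the hinge and vanishes above threshold
  ps <- p; ps@values["eps_hinge"] <- 0.1
  expect_lt(abs(inductionReleaseRate(0, ps) - 5.0), 1e-3)
  expect_lt(inductionReleaseRate(20, ps), 1e-12)
})

test_that("compiled and reference right-hand sides integrate identically", {
  p <- defaultParameters()
  reg <- DoseRegimen(data.frame(time = c(0, 12),
                                drug = c("dabrafenib_hpmc", "ketoconazole"),
                                dose_mg = c(75, 200)), horizon = 36)
  trC <- simulateRegimen(reg, p, useCompiled = TRUE)
  trR <- simulateRegimen(reg, p, useCompiled = FALSE)
  scale <- max(abs(trC@states))
  expect_lt(max(abs(trC@states - trR@states)) / scale, 1e-7)
})

test_that("mass-balance residual is zero-dose safe and rate-independent", {
  p <- defaultParameters()
  empty <- DoseRegimen(data.frame(time = numeric(0), drug = character(0),
                                  dose_mg = numeric(0)), horizon = 24)
  tr0 <- simulateRegimen(empty, p)
  expect_identical(massBalanceResidual(tr0), 0)
  reg <- DoseRegimen(data.frame(time = 0, drug = "dabrafenib_solution",
                                dose_mg = 95), horizon = 96)
  expect_lt(massBalanceResidual(simulateRegimen(reg, p)), 1e-6)
  p2 <- p
  param(p2, "Vmax_pH") <- 2 * param(p, "Vmax_pH")  # conservation is rate-free
  expect_lt(massBalanceResidual(simulateRegimen(reg, p2)), 1e-6)
})

test_that("states remain non-negative and enzyme is conserved without turnover", {
  p <- defaultParameters()
  p@values[c("kt", "kEdeg")] <- 0
  reg <- bdRegimen(150, endDay = 7, horizon = 8 * 24)
  tr <- simulateRegimen(reg, p)
  expect_gt(min(tr@states), -1e-8)
  Etot <- rowSums(tr@states[, c("Ef", "EB", "ED0", "EDH", "EDD", "EK")])
  expect_lt(max(abs(Etot - Etot[1])) / Etot[1], 1e-6)
})

test_that("total enzyme at day 7 is non-decreasing in dabrafenib dose", {
  p <- defaultParameters()
  e7 <- vapply(c(50, 75, 150), function(d) {
    tr <- simulateRegimen(bdRegimen(d, endDay = 7, horizon = 7 * 24 + 12), p,
                          rtol = 1e-6, atol = 1e-8)
    i <- which.min(abs(tr@times - 7 * 24))
    sum(tr@states[i, c("Ef", "EB", "ED0", "EDH", "EDD", "EK")])
  }, numeric(1))
  expect_true(all(diff(e7) >= 0))
})

test_that("hydroxy-dabrafenib formation flux is non-increasing in ketoconazole dose", {
  p <- defaultParameters()
  flux <- vapply(c(0, 200, 400), function(kd) {
    dab <- bdRegimen(75, endDay = 5, horizon = 5 * 24 + 12)
    reg <- if (kd > 0)
      combineRegimens(dab, odRegimen(kd, startDay = 4, endDay = 5,
                                     horizon = 5 * 24 + 12))
    else dab
    tr <- simulateRegimen(reg, p, rtol = 1e-6, atol = 1e-8)
    i <- which.min(abs(tr@times - (4 * 24 + 6)))
    param(p, "kcat_D0") * tr@states[i, "ED0"]
  }, numeric(1))
  expect_true(all(diff(flux) <= 1e-10))
})
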