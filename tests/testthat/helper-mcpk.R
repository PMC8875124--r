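# Shared fixtures for the suite. All synthetic inputs are built in code.

# Reduce the full network to a one-compartment, first-order model: no
# enzymes, no exchange, no saturable routes; elimination solely ke_D0 = k.
oneCompartmentParams <- function(ka = 2, k = 0.1, F = 0.7, Vc = 70) {
  p <- defaultParameters()
  zero <- c("kon_D0", "kon_DH", "kon_DD", "kon_K", "kBon", "kBoff",
            "Vmax_pH", "Vmax_2C19", "q_D0", "q_DH", "q_DC", "q_DD",
            "kr", "kt", "kEdeg", "ke_DH", "ke_DC", "ke_DD")
  p@values[zero] <- 0
  p@values["E0"] <- 0
  p@values[c("ka_cap", "ka_sol")] <- ka
  p@values[c("F_cap", "F_sol")] <- F
  p@values["Vc"] <- Vc
  p@values["ke_D0"] <- k
  p@values["eps_hinge"] <- 0
  validObject(p)
  p
}

batemanCurve <- function(t, dose_mg, ka, k, F, Vc) {
  dose <- F * dose_mg * 1e6 / molarMass("D0")
  dose * ka / (Vc * (ka - k)) * (exp(-k * t) - exp(-ka * t))
}

# A Trajectory carrying one analyte profile (nM) and zeros elsewhere, for
# metric tests that need a hand-specified curve.
toyTrajectory <- function(times, values, analyte = "D0c",
                          regimen = NULL) {
  if (is.null(regimen))
    regimen <- DoseRegimen(data.frame(time = 0, drug = "dabrafenib_hpmc",
                                      dose_mg = 1),
                           horizon = max(times) + 1, grid = times)
  st <- matrix(0, nrow = length(times), ncol = 21,
               dimnames = list(NULL, stateNames()))
  st[, analyte] <- values
  st[, "Ef"] <- 1  # keep occupancy defined
  new("Trajectory", times = times, states = st, regimen = regimen,
      params = defaultParameters(), diagnostics = list())
}

randomState <- function() {
  y <- stats::setNames(runif(21, 0, 50), stateNames())
  y
}

# dense early grid for peak capture in closed-form accumulation checks
denseDoseGrid <- function(doseTimes, horizon, fine = seq(0, 0.02, by = 5e-4)) {
  g <- sort(unique(c(outer(fine, doseTimes, "+"),
                     seq(0, horizon, length.out = 400),
                     doseTimes - 1e-6, horizon)))
  g[g >= 0 & g <= horizon]
}
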