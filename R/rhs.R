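## ODE right-hand side of the MCPK reaction network (reference R version).
## simulate() uses the compiled C twin "mcpk_rhs" (src/mcpk.c); the two are
## cross-checked in the test suite.

#' Drug-free initial state
#'
#' All drug pools empty; CYP3A4 at its drug-free steady state: total enzyme
#' E0 split between free (Ef) and baseline-bound (EB) forms according to
#' kBon/kBoff, no mRNA.
#'
#' @param params A \code{ParameterSet}.
#' @return Named numeric state vector (see \code{\link{stateNames}}).
#' @export
initialState <- function(params) {
  v <- param(params)
  y <- stats::setNames(numeric(21), stateNames())
  ## drug-free steady state with protein turnover: total = E0, and
  ## EB/Ef = kBon/(kBoff + kEdeg)
  den <- v["kBon"] + v["kBoff"] + v["kEdeg"]
  fB <- if (den > 0) v["kBon"] / den else 0
  y["EB"] <- unname(v["E0"] * fB)
  y["Ef"] <- unname(v["E0"] - y["EB"])
  y
}

#' Threshold-triggered mRNA release rate
#'
#' The induction motif releases CYP3A4 mRNA only when the baseline-bound
#' enzyme EB falls below the threshold TE: rate = kr * max(0, TE - EB), with
#' an optional softplus smoothing of the hinge (width `eps_hinge`;
#' 0 = exact hinge) for stiff-solver robustness.
#'
#' @param EB Baseline-bound CYP3A4 (nM), scalar or vector, >= 0.
#' @param params A \code{ParameterSet} (uses kr, TE, eps_hinge).
#' @return Release rate (nM/h).
#' @export
inductionReleaseRate <- function(EB, params) {
  if (any(EB < 0)) stop("EB must be >= 0")
  v <- param(params)
  unname(v["kr"] * .hinge(v["TE"] - EB, v["eps_hinge"]))
}

## softplus-smoothed positive part; eps = 0 gives the exact hinge
.hinge <- function(x, eps) {
  if (eps <= 0) return(pmax(0, x))
  z <- x / eps
  out <- ifelse(z > 30, x, eps * log1p(exp(pmin(z, 30))))
  # guard against underflow noise far below threshold
  ifelse(z < -30, 0, out)
}

#' Time-derivative of the MCPK state (reference implementation)
#'
#' Implements the full reaction network: first-order oral absorption from
#' formulation-specific depots; central/peripheral exchange for dabrafenib
#' and each metabolite; mass-action CYP3A4 cycles for dabrafenib (-> hydroxy),
#' hydroxy (-> carboxy), desmethyl (-> metabolite sink) and ketoconazole
#' (cleared); pH-dependent Michaelis-Menten conversion carboxy -> desmethyl;
#' a CYP2C19+ Michaelis-Menten sink for desmethyl; first-order excretion into
#' the cumulative pool U; the baseline occupancy exchange Ef <-> EB; and the
#' threshold-triggered induction motif (mRNA release, translation, protein
#' turnover with zero-order baseline synthesis kEdeg*E0). Degradation of a
#' drug-bound complex releases its substrate moiety back to the central
#' compartment, so the dabrafenib drug moiety is conserved exactly.
#' The CYP2C8 route dabrafenib -> hydroxy is disabled unless `use_2C8` is 1.
#'
#' @param state Named numeric state vector (non-negative), see
#'   \code{\link{stateNames}}.
#' @param params A \code{ParameterSet}.
#' @param t Time (h); the system is autonomous, `t` is accepted for solver
#'   compatibility.
#' @param dosing_input Optional continuous depot inflow, named numeric with
#'   any of `D0s`, `D0cap`, `K_oral` (nmol/h); dose events in
#'   \code{\link{simulateRegimen}} are handled as depot increments instead.
#' @return Named numeric vector of derivatives.
#' @export
mcpkRHS <- function(state, params, t = 0, dosing_input = NULL) {
  if (any(state < 0)) stop("negative state component: ",
                           paste(names(state)[state < 0], collapse = ", "))
  v <- param(params)
  y <- as.list(state)
  with(c(as.list(v), y), {
    rvK <- Vc / V_K

    b0 <- kon_D0 * D0c * Ef; u0 <- koff_D0 * ED0; c0 <- kcat_D0 * ED0
    bH <- kon_DH * DHc * Ef; uH <- koff_DH * EDH; cH <- kcat_DH * EDH
    bD <- kon_DD * DDc * Ef; uD <- koff_DD * EDD; cD <- kcat_DD * EDD
    bK <- kon_K  * Kc  * Ef; uK <- koff_K  * EK;  cK <- kcat_K  * EK

    vpH <- Vmax_pH * DCc / (Km_pH + DCc)
    v19 <- Vmax_2C19 * DDc / (Km_2C19 + DDc)
    v8  <- if (use_2C8 > 0) Vmax_2C8 * D0c / (Km_2C8 + D0c) else 0

    rel <- kr * .hinge(TE - EB, eps_hinge)

    d <- numeric(21); names(d) <- stateNames()
    d["D0s"]   <- -ka_sol * D0s
    d["D0cap"] <- -ka_cap * D0cap
    d["D0c"] <- (ka_sol * D0s + ka_cap * D0cap) / Vc - b0 + u0 + kEdeg * ED0 -
      q_D0 * (D0c - D0p) - ke_D0 * D0c - v8
    d["D0p"] <- q_D0 * (Vc / Vp) * (D0c - D0p)
    d["DHc"] <- c0 + v8 - bH + uH + kEdeg * EDH - q_DH * (DHc - DHp) - ke_DH * DHc
    d["DHp"] <- q_DH * (Vc / Vp) * (DHc - DHp)
    d["DCc"] <- cH - vpH - q_DC * (DCc - DCp) - ke_DC * DCc
    d["DCp"] <- q_DC * (Vc / Vp) * (DCc - DCp)
    d["DDc"] <- vpH - v19 - bD + uD + kEdeg * EDD - q_DD * (DDc - DDp) - ke_DD * DDc
    d["DDp"] <- q_DD * (Vc / Vp) * (DDc - DDp)
    d["M"]   <- (cD + v19) * Vc
    d["U"]   <- (ke_D0 * D0c + ke_DH * DHc + ke_DC * DCc + ke_DD * DDc) * Vc
    d["K_oral"] <- -ka_K * K_oral
    d["Kc"]  <- ka_K * K_oral / V_K - (bK - uK - kEdeg * EK) * rvK
    d["Ef"]  <- (-b0 + u0 + c0) + (-bH + uH + cH) + (-bD + uD + cD) +
      (-bK + uK + cK) - kBon * Ef + kBoff * EB +
      kt * EmRNA + kEdeg * (E0 - Ef)
    d["EB"]  <- kBon * Ef - kBoff * EB - kEdeg * EB
    d["ED0"] <- b0 - u0 - c0 - kEdeg * ED0
    d["EDH"] <- bH - uH - cH - kEdeg * EDH
    d["EDD"] <- bD - uD - cD - kEdeg * EDD
    d["EK"]  <- bK - uK - cK - kEdeg * EK
    d["EmRNA"] <- rel - kdeg * EmRNA

    if (!is.null(dosing_input)) {
      ok <- intersect(names(dosing_input), c("D0s", "D0cap", "K_oral"))
      d[ok] <- d[ok] + dosing_input[ok]
    }
    if (any(!is.finite(d)))
      stop("non-finite derivative for: ",
           paste(names(d)[!is.finite(d)], collapse = ", "))
    d
  })
}

#' CYP3A4 occupancy fractions
#'
#' Splits the total enzyme among free (Ef), baseline-bound (EB) and the four
#' drug complexes (ED0, EDH, EDD, EK).
#'
#' @param state Named numeric state vector or a \code{Trajectory} (then a
#'   matrix with one row per output time is returned).
#' @return Named numeric vector (or matrix) of fractions summing to 1.
#' @export
setGeneric("occupancyFractions", function(state) standardGeneric("occupancyFractions"))

#' @rdname occupancyFractions
#' @export
setMethod("occupancyFractions", "numeric", function(state) {
  forms <- c("Ef", "EB", "ED0", "EDH", "EDD", "EK")
  e <- state[forms]
  tot <- sum(e)
  if (tot <= 0) stop("occupancy undefined: total enzyme is zero")
  e / tot
})

#' @rdname occupancyFractions
#' @export
setMethod("occupancyFractions", "Trajectory", function(state) {
  forms <- c("Ef", "EB", "ED0", "EDH", "EDD", "EK")
  e <- state@states[, forms, drop = FALSE]
  tot <- rowSums(e)
  if (any(tot <= 0)) stop("occupancy undefined: total enzyme is zero")
  sweep(e, 1, tot, "/")
})

#' Total dabrafenib drug-equivalents in a state (nmol)
#'
#' Depots + central/peripheral pools (x volume) + drug moiety of the CYP3A4
#' complexes (x Vc) + metabolite sink + excreted pool.
#'
#' @param state Named state vector or state matrix (columns = species).
#' @param params A \code{ParameterSet}.
#' @return nmol (scalar or vector).
#' @export
drugMoietyTotal <- function(state, params) {
  v <- param(params)
  if (is.matrix(state)) {
    g <- function(n) state[, n]
  } else {
    g <- function(n) state[[n]]
  }
  g("D0s") + g("D0cap") +
    (g("D0c") + g("DHc") + g("DCc") + g("DDc")) * v[["Vc"]] +
    (g("D0p") + g("DHp") + g("DCp") + g("DDp")) * v[["Vp"]] +
    (g("ED0") + g("EDH") + g("EDD")) * v[["Vc"]] +
    g("M") + g("U")
}

#' Relative mass-balance residual of a simulated trajectory
#'
#' Audits drug-moiety conservation: at every output time, total dabrafenib
#' drug-equivalents must equal the cumulative absorbed (bioavailable) dose.
#' Returns the maximum over the grid of the absolute relative error; 0 by
#' convention for a zero-dose run.
#'
#' @param traj A \code{Trajectory}.
#' @return Dimensionless relative residual.
#' @export
massBalanceResidual <- function(traj) {
  params <- traj@params
  v <- param(params)
  ev <- traj@regimen@events
  dab <- ev[ev$drug != "ketoconazole", , drop = FALSE]
  if (nrow(dab) == 0) return(0)
  Fd <- ifelse(dab$drug == "dabrafenib_solution", v[["F_sol"]], v[["F_cap"]])
  doseNmol <- Fd * dab$dose_mg * 1e6 / molarMass("D0")
  cumDose <- vapply(traj@times, function(t) sum(doseNmol[dab$time <= t + 1e-9]),
                    numeric(1))
  tot <- drugMoietyTotal(traj@states, params)
  idx <- cumDose > 0
  if (!any(idx)) return(0)
  max(abs(tot[idx] - cumDose[idx]) / cumDose[idx])
}
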