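## PK summary metrics on simulated trajectories.

#' Unit conversion for concentrations
#'
#' Exact linear conversion between mass and molar concentration units.
#'
#' @param value Numeric value(s).
#' @param unit_in,unit_out One of `"ng/mL"`, `"nM"`, `"uM"`.
#' @param mw Molar mass (g/mol), > 0.
#' @return Converted value(s).
#' @export
#' @examples
#' convertConcentration(6000, "ng/mL", "uM", mw = 531.4)  # ketoconazole Cmax
convertConcentration <- function(value, unit_in, unit_out, mw) {
  if (mw <= 0) stop("mw must be > 0")
  units <- c("ng/mL", "nM", "uM")
  if (!unit_in %in% units) stop("unknown unit: ", unit_in)
  if (!unit_out %in% units) stop("unknown unit: ", unit_out)
  ## convert to nM first: 1 nM = mw ng/L = mw/1000 ng/mL
  nM <- switch(unit_in,
               "ng/mL" = value * 1000 / mw,
               "nM" = value,
               "uM" = value * 1000)
  switch(unit_out,
         "ng/mL" = nM * mw / 1000,
         "nM" = nM,
         "uM" = nM / 1000)
}

#' PK summary metrics for one analyte
#'
#' Cmax/Tmax from the grid maximum; troughs sampled just before each dose
#' (at dose time minus 1e-6 h); AUC by the trapezoid rule on the output
#' grid; accumulation ratio = Cmax within the last dosing interval divided
#' by Cmax within the first.
#'
#' @param traj A \code{Trajectory}.
#' @param analyte Analyte tag (see \code{\link{trajSeries}}).
#' @param dosing Optional \code{DoseRegimen} defining the dose intervals;
#'   defaults to the trajectory's own regimen (dabrafenib events).
#' @param window AUC window `c(t0, t1)` (h); default the full grid.
#' @param unit Output concentration unit, default `"ng/mL"`.
#' @return List: `Cmax`, `Cmax_nM`, `Tmax`, `troughs` (data.frame time/value),
#'   `AUC`, `accumulation_ratio` (NA for < 2 doses), `unit`.
#' @export
pkMetrics <- function(traj, analyte, dosing = NULL, window = NULL,
                      unit = "ng/mL") {
  if (is.null(dosing)) dosing <- traj@regimen
  ser <- trajSeries(traj, analyte, unit = unit)
  tt <- ser$time_h; val <- ser$value
  dt <- .doseTimes(dosing, if (analyte %in% c("K", "Kc")) "ketoconazole" else "dabrafenib")
  if (!length(dt)) dt <- .doseTimes(dosing, "any")
  if (length(dt) && (max(tt) < min(dt) + 1e-9))
    stop("trajectory shorter than one dosing interval")
  imax <- which.max(val)
  Cmax <- val[imax]; Tmax <- tt[imax]
  if (is.null(window)) window <- range(tt)
  inw <- tt >= window[1] & tt <= window[2]
  AUC <- .trapz(tt[inw], val[inw])
  troughT <- dt[-1] - 1e-6
  troughs <- data.frame(time_h = troughT,
                        value = stats::approx(tt, val, xout = troughT, rule = 2)$y)
  acc <- NA_real_
  if (length(dt) >= 2) {
    tau <- dt[2] - dt[1]
    first <- tt >= dt[1] & tt <= dt[1] + tau
    last <- tt >= dt[length(dt)] & tt <= dt[length(dt)] + tau
    c1 <- max(val[first]); c2 <- max(val[last])
    if (c1 > 0) acc <- c2 / c1
  }
  nMval <- if (unit == "ng/mL" && !analyte %in% "excretion")
    convertConcentration(Cmax, "ng/mL", "nM", molarMass(analyteState(analyte))) else Cmax
  list(Cmax = Cmax, Cmax_nM = unname(nMval), Tmax = Tmax, troughs = troughs,
       AUC = AUC, accumulation_ratio = acc, unit = unit)
}

.trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Time to steady state under repeated dosing
#'
#' Earliest dosing time whose pre-dose trough is within `tol` (relative) of
#' the final trough. Errors if the final two troughs still differ by more
#' than `tol` ("steady state not reached").
#'
#' @param traj A \code{Trajectory}, or a numeric vector of troughs (one per
#'   dose, in dose order) for direct use.
#' @param analyte Analyte tag (Trajectory method).
#' @param doseTimes Dose times (h) matching the trough vector (numeric
#'   method); for a Trajectory taken from its regimen.
#' @param tol Relative tolerance, default 0.05.
#' @return Time (h) of the first steady-state dose.
#' @export
setGeneric("timeToSteadyState", function(traj, analyte, doseTimes, tol = 0.05)
  standardGeneric("timeToSteadyState"))

#' @rdname timeToSteadyState
#' @export
setMethod("timeToSteadyState", "numeric",
          function(traj, analyte, doseTimes, tol = 0.05) {
  troughs <- traj
  n <- length(troughs)
  if (n < 2) stop("need at least two troughs")
  if (missing(doseTimes) || is.null(doseTimes)) doseTimes <- seq_len(n)
  tf <- troughs[n]
  if (tf <= 0) stop("final trough is zero; steady state undefined")
  if (abs(troughs[n - 1] - tf) > tol * tf) stop("steady state not reached")
  k <- which(abs(troughs - tf) <= tol * tf)[1]
  doseTimes[k]
})

#' @rdname timeToSteadyState
#' @export
setMethod("timeToSteadyState", "Trajectory",
          function(traj, analyte, doseTimes, tol = 0.05) {
  dt <- .doseTimes(traj@regimen,
                   if (analyte %in% c("K", "Kc")) "ketoconazole" else "dabrafenib")
  if (length(dt) < 2) stop("regimen has fewer than two doses")
  ser <- trajSeries(traj, analyte, unit = "nM")
  ## trough k = concentration just before dose k+1 (exact pre-dose samples on
  ## the output grid)
  troughT <- dt[-1] - 1e-6
  troughT <- troughT[troughT <= max(ser$time_h)]
  troughs <- stats::approx(ser$time_h, ser$value, xout = troughT, rule = 2)$y
  timeToSteadyState(troughs, doseTimes = dt[seq_along(troughs)], tol = tol)
})

#' Washout time after the last dose
#'
#' Time after the last dose at which the analyte first falls below
#' `thresholdFraction` of its global Cmax and stays below it for the rest of
#' the trajectory.
#'
#' @param traj A \code{Trajectory}.
#' @param analyte Analyte tag.
#' @param thresholdFraction Fraction of global Cmax, default 0.01.
#' @return Time since last dose (h).
#' @export
washoutTime <- function(traj, analyte, thresholdFraction = 0.01) {
  ser <- trajSeries(traj, analyte, unit = "nM")
  tt <- ser$time_h; val <- ser$value
  dt <- .doseTimes(traj@regimen, "any")
  tLast <- if (length(dt)) max(dt) else tt[1]
  Cmax <- max(val)
  if (Cmax <= 0) return(0)
  thr <- thresholdFraction * Cmax
  post <- which(tt >= tLast)
  below <- val[post] <= thr + 1e-300
  ## first index after last dose from which the profile stays below threshold
  stays <- rev(cumprod(rev(below))) > 0
  if (!any(stays)) stop("analyte never falls below threshold within horizon")
  k <- post[which(stays)[1]]
  max(0, tt[k] - tLast)
}
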