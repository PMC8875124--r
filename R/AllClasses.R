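#' @import methods
NULL

#' ParameterSet: the full MCPK parameter registry
#'
#' Holds every rate constant, volume, threshold and Michaelis constant of the
#' model together with per-parameter metadata: unit, box bounds used in
#' calibration, whether the parameter is fixed, and its role in the model
#' ("base" = reproduced two-compartment dabrafenib PK, "extension" = the
#' mechanistically coupled additions, "structural" = unit conversions and
#' numerical switches, "pruned" = the optional CYP2C8 route that sensitivity
#' analysis removes).
#'
#' @slot values Named numeric vector of parameter values (natural scale).
#' @slot unit Named character vector of units.
#' @slot lower,upper Named numeric vectors of box bounds (natural scale).
#' @slot fixed Named logical vector; fixed parameters are excluded from fits.
#' @slot role Named character vector in
#'   \code{c("base","extension","structural","pruned")}.
#' @export
setClass("ParameterSet", representation(
  values = "numeric", unit = "character",
  lower = "numeric", upper = "numeric",
  fixed = "logical", role = "character"
))

setValidity("ParameterSet", function(object) {
  v <- object@values
  nm <- names(v)
  msgs <- character()
  for (s in c("unit", "lower", "upper", "fixed", "role")) {
    if (!identical(names(slot(object, s)), nm))
      msgs <- c(msgs, sprintf("slot '%s' names must match values", s))
  }
  if (anyNA(v) || any(!is.finite(v))) msgs <- c(msgs, "non-finite parameter value")
  pos <- grepl("^(ka|kon|koff|kcat|kB|ke|kdeg|kt|kEdeg|Vmax|Km|V|q|kr|TE|E0|MW)", nm) &
    !grepl("^(ke_|Vmax_2C8)", nm)
  if (any(v[pos] < 0)) msgs <- c(msgs, "negative rate/volume/threshold")
  if (any(v[names(v) %in% c("ke_D0","ke_DH","ke_DC","ke_DD")] < 0))
    msgs <- c(msgs, "negative excretion rate")
  for (f in c("F_sol", "F_cap")) if (f %in% nm && (v[f] <= 0 || v[f] > 1))
    msgs <- c(msgs, sprintf("%s must lie in (0, 1]", f))
  for (k in grep("^Km", nm, value = TRUE)) if (v[k] <= 0)
    msgs <- c(msgs, sprintf("%s must be > 0", k))
  if (!all(object@role %in% c("base", "extension", "structural", "pruned")))
    msgs <- c(msgs, "role must be base/extension/structural/pruned")
  if (any(object@lower > object@upper)) msgs <- c(msgs, "lower bound exceeds upper bound")
  if (length(msgs)) msgs else TRUE
})

#' DoseRegimen: timed oral dose events plus simulation grid
#'
#' @slot events data.frame with columns `time` (h), `drug` (one of
#'   "dabrafenib_solution", "dabrafenib_hpmc", "ketoconazole"), `dose_mg`.
#' @slot horizon Simulation horizon (h).
#' @slot grid Strictly increasing output time grid (h).
#' @export
setClass("DoseRegimen", representation(
  events = "data.frame", horizon = "numeric", grid = "numeric"
))

setValidity("DoseRegimen", function(object) {
  ev <- object@events
  msgs <- character()
  if (!all(c("time", "drug", "dose_mg") %in% names(ev)))
    msgs <- c(msgs, "events needs columns time, drug, dose_mg")
  else {
    if (nrow(ev) && (any(ev$time < 0) || any(ev$time >= object@horizon)))
      msgs <- c(msgs, "event times must lie in [0, horizon)")
    if (nrow(ev) && any(ev$dose_mg <= 0)) msgs <- c(msgs, "doses must be > 0")
    ok <- c("dabrafenib_solution", "dabrafenib_hpmc", "ketoconazole")
    if (nrow(ev) && !all(ev$drug %in% ok)) msgs <- c(msgs, "unknown drug in events")
  }
  if (length(object@grid) < 2 || any(diff(object@grid) <= 0))
    msgs <- c(msgs, "grid must be strictly increasing with >= 2 points")
  if (length(msgs)) msgs else TRUE
})

#' Trajectory: a simulated concentration-time course
#'
#' @slot times Output grid (h).
#' @slot states Matrix (length(times) x 21) of state values, columns named as
#'   \code{\link{stateNames}}.
#' @slot regimen The \code{DoseRegimen} simulated.
#' @slot params The \code{ParameterSet} used.
#' @slot diagnostics List: solver tolerances, per-segment step counts.
#' @export
setClass("Trajectory", representation(
  times = "numeric", states = "matrix", regimen = "DoseRegimen",
  params = "ParameterSet", diagnostics = "list"
))

setValidity("Trajectory", function(object) {
  msgs <- character()
  if (nrow(object@states) != length(object@times))
    msgs <- c(msgs, "states rows must match times")
  if (any(!is.finite(object@states))) msgs <- c(msgs, "non-finite state values")
  if (length(msgs)) msgs else TRUE
})

#' PKDataset: observed or synthetic concentration/excretion tables per arm
#'
#' @slot studyId Character study identifier.
#' @slot arms Named list; each arm is a list with elements `regimen`
#'   (DoseRegimen), `data` (data.frame: analyte, time_h, value, unit,
#'   replicate).
#' @slot provenance List (e.g. generator seed, CV, design id, or source file).
#' @export
setClass("PKDataset", representation(
  studyId = "character", arms = "list", provenance = "list"
))

setValidity("PKDataset", function(object) {
  msgs <- character()
  for (a in names(object@arms)) {
    arm <- object@arms[[a]]
    if (!is(arm$regimen, "DoseRegimen")) msgs <- c(msgs, sprintf("arm '%s': missing regimen", a))
    d <- arm$data
    if (!is.data.frame(d) || !all(c("analyte", "time_h", "value", "unit") %in% names(d))) {
      msgs <- c(msgs, sprintf("arm '%s': bad data table", a)); next
    }
    if (nrow(d)) {
      if (any(d$time_h < 0)) msgs <- c(msgs, sprintf("arm '%s': negative times", a))
      if (any(d$value < 0)) msgs <- c(msgs, sprintf("arm '%s': negative values", a))
      o <- order(d$analyte, d$time_h)
      if (is.unsorted(d$time_h[o][d$analyte[o] == d$analyte[o][1]]))
        msgs <- c(msgs, sprintf("arm '%s': times not sorted within analyte", a))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' EnzymeProfile: piecewise-constant total-CYP3A4 estimates per dose interval
#'
#' @slot intervals data.frame with columns `start`, `end` (h), `E_total` (nM),
#'   `flag` (character; "" or "carried_forward").
#' @export
setClass("EnzymeProfile", representation(intervals = "data.frame"))

setValidity("EnzymeProfile", function(object) {
  iv <- object@intervals
  msgs <- character()
  if (!all(c("start", "end", "E_total") %in% names(iv)))
    msgs <- c(msgs, "intervals needs start, end, E_total")
  else {
    if (any(iv$E_total <= 0)) msgs <- c(msgs, "E_total must be > 0")
    if (nrow(iv) > 1 && any(abs(iv$start[-1] - iv$end[-nrow(iv)]) > 1e-9))
      msgs <- c(msgs, "intervals must tile the horizon")
  }
  if (length(msgs)) msgs else TRUE
})

#' FitResult: outcome of one calibration stage
#'
#' @slot params Estimated \code{ParameterSet}.
#' @slot rss Total residual sum of squares (log scale).
#' @slot rssPerArm Named numeric per-arm breakdown.
#' @slot trace data.frame optimizer trace (iteration, best RSS).
#' @slot stage Integer stage label (1-4).
#' @slot seed Integer random seed used.
#' @slot bounds List with named `lower`/`upper` (log10 scale) for free params.
#' @slot flags Character vector of diagnostics (e.g. "induction unidentifiable").
#' @export
setClass("FitResult", representation(
  params = "ParameterSet", rss = "numeric", rssPerArm = "numeric",
  trace = "data.frame", stage = "integer", seed = "integer",
  bounds = "list", flags = "character"
))

setValidity("FitResult", function(object) {
  msgs <- character()
  if (length(object@rss) != 1 || object@rss < 0) msgs <- c(msgs, "rss must be a scalar >= 0")
  if (!object@stage %in% 1:4) msgs <- c(msgs, "stage must be 1..4")
  if (length(msgs)) msgs else TRUE
})

#' StudyDesign: template for one synthetic clinical study
#'
#' @slot id One of "single_dose_solution", "dabrafenib_escalation",
#'   "keto_escalation", "ddi_study".
#' @slot arms Named list; each arm: list(regimen, analytes, schedule) where
#'   schedule is a named list of sampling times (h) per analyte.
#' @slot cv Proportional (lognormal) coefficient of variation of the noise.
#' @slot nReplicates Number of replicate noisy profiles per arm.
#' @export
setClass("StudyDesign", representation(
  id = "character", arms = "list", cv = "numeric", nReplicates = "numeric"
))

setValidity("StudyDesign", function(object) {
  msgs <- character()
  if (object@cv < 0) msgs <- c(msgs, "cv must be >= 0")
  if (object@nReplicates < 1) msgs <- c(msgs, "nReplicates must be >= 1")
  for (a in names(object@arms)) {
    arm <- object@arms[[a]]
    if (!is(arm$regimen, "DoseRegimen")) { msgs <- c(msgs, sprintf("arm '%s': missing regimen", a)); next }
    hor <- arm$regimen@horizon
    for (an in names(arm$schedule)) {
      tt <- arm$schedule[[an]]
      if (any(tt < 0) || any(tt > hor))
        msgs <- c(msgs, sprintf("arm '%s' analyte '%s': schedule outside [0, horizon]", a, an))
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ParameterSet", function(object) {
  free <- sum(!object@fixed & object@role %in% c("base", "extension"))
  cat(sprintf("ParameterSet: %d parameters (%d free; %d extension free)\n",
              length(object@values), free,
              sum(!object@fixed & object@role == "extension")))
  invisible(object)
})

setMethod("show", "DoseRegimen", function(object) {
  cat(sprintf("DoseRegimen: %d dose events over %.1f h (%d output times)\n",
              nrow(object@events), object@horizon, length(object@grid)))
  if (nrow(object@events)) {
    tab <- table(object@events$drug)
    for (d in names(tab)) cat(sprintf("  %s: %d doses\n", d, tab[[d]]))
  }
  invisible(object)
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d species x %d times, t in [%.3g, %.3g] h\n",
              ncol(object@states), length(object@times),
              min(object@times), max(object@times)))
  invisible(object)
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (stage %d): RSS = %.6g, seed = %d\n",
              object@stage, object@rss, object@seed))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
  invisible(object)
})

setMethod("show", "PKDataset", function(object) {
  cat(sprintf("PKDataset '%s': %d arm(s)\n", object@studyId, length(object@arms)))
  for (a in names(object@arms))
    cat(sprintf("  %s: %d observations\n", a, nrow(object@arms[[a]]$data)))
  invisible(object)
})

setMethod("show", "EnzymeProfile", function(object) {
  cat(sprintf("EnzymeProfile: %d intervals, E_total in [%.3g, %.3g] nM\n",
              nrow(object@intervals), min(object@intervals$E_total),
              max(object@intervals$E_total)))
  invisible(object)
})
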