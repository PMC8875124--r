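## Dose regimens: constructors and schedule helpers. Time base: hours.

#' Construct a DoseRegimen
#'
#' @param events data.frame with columns `time` (h), `drug`
#'   ("dabrafenib_solution", "dabrafenib_hpmc" or "ketoconazole"),
#'   `dose_mg` (> 0).
#' @param horizon Simulation horizon (h); defaults to 24 h past the last dose.
#' @param grid Output time grid; if `NULL` a default grid is built with at
#'   least 20 points per dosing interval, dense sampling just after each dose
#'   (peak capture), and a pre-dose trough sample at each dose time minus
#'   1e-6 h.
#' @return A \code{DoseRegimen}.
#' @export
DoseRegimen <- function(events, horizon = NULL, grid = NULL) {
  if (nrow(events)) events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  if (is.null(horizon))
    horizon <- if (nrow(events)) max(events$time) + 24 else 24
  if (is.null(grid)) grid <- .defaultGrid(events$time, horizon)
  new("DoseRegimen", events = events, horizon = horizon, grid = grid)
}

.defaultGrid <- function(doseTimes, horizon) {
  knots <- sort(unique(c(0, doseTimes, horizon)))
  pts <- lapply(seq_len(length(knots) - 1), function(i) {
    a <- knots[i]; b <- knots[i + 1]
    # dense post-dose sampling at fixed offsets (peak capture at a common
    # phase across intervals) plus >= 20 points spread over the segment
    early <- a + c(0.05, 0.1, 0.2, 0.3, 0.5, 0.75, 1, 1.5, 2, 3)
    c(seq(a, b, length.out = 21), early[early < b])
  })
  troughs <- doseTimes[doseTimes > 0] - 1e-6
  g <- sort(unique(c(unlist(pts), troughs, horizon)))
  g[g >= 0 & g <= horizon]
}

#' Repeated-dosing regimen builders
#'
#' `bdRegimen()` builds twice-daily dosing (12 h interval), `odRegimen()`
#' once-daily dosing, starting at `startDay` (day 1 = t 0 h) through
#' `endDay` inclusive.
#'
#' @param dose_mg Dose per administration (mg).
#' @param drug Drug/formulation label.
#' @param startDay,endDay First and last dosing day (1-based).
#' @param horizon Optional horizon (h).
#' @param grid Optional output grid.
#' @return A \code{DoseRegimen} (or, for `doseEvents`, its events table).
#' @export
bdRegimen <- function(dose_mg, drug = "dabrafenib_hpmc", startDay = 1,
                      endDay = 14, horizon = NULL, grid = NULL) {
  ev <- doseEvents(dose_mg, drug, startDay, endDay, interval = 12)
  DoseRegimen(ev, horizon = horizon, grid = grid)
}

#' @rdname bdRegimen
#' @export
odRegimen <- function(dose_mg, drug = "ketoconazole", startDay = 1,
                      endDay = 14, horizon = NULL, grid = NULL) {
  ev <- doseEvents(dose_mg, drug, startDay, endDay, interval = 24)
  DoseRegimen(ev, horizon = horizon, grid = grid)
}

#' @rdname bdRegimen
#' @param interval Dosing interval within a day (h): 12 for b.d., 24 for o.d.
#' @export
doseEvents <- function(dose_mg, drug, startDay, endDay, interval = 12) {
  stopifnot(endDay >= startDay, dose_mg > 0, interval %in% c(12, 24))
  tt <- unlist(lapply(seq(startDay, endDay), function(d) {
    t0 <- (d - 1) * 24
    if (interval == 12) c(t0, t0 + 12) else t0
  }))
  data.frame(time = tt, drug = drug, dose_mg = dose_mg,
             stringsAsFactors = FALSE)
}

#' Combine regimens
#'
#' Merges the dose events of several regimens into one, rebuilding the grid.
#'
#' @param ... \code{DoseRegimen} objects.
#' @param horizon Optional horizon; default max of inputs.
#' @return A \code{DoseRegimen}.
#' @export
combineRegimens <- function(..., horizon = NULL) {
  rs <- list(...)
  ev <- do.call(rbind, lapply(rs, function(r) r@events))
  if (is.null(horizon)) horizon <- max(vapply(rs, function(r) r@horizon, numeric(1)))
  DoseRegimen(ev, horizon = horizon)
}

#' Read a regimen YAML file
#'
#' The file holds a list of entries `{drug, dose_mg, schedule: single|bid|od,
#' start_day, end_day}` and optionally a top-level `horizon_h`.
#'
#' @param path File path.
#' @return A \code{DoseRegimen}.
#' @export
readRegimenYAML <- function(path) {
  y <- yaml::read_yaml(path)
  horizon <- y$horizon_h
  entries <- if (!is.null(y$doses)) y$doses else y[!names(y) %in% "horizon_h"]
  ev <- do.call(rbind, lapply(entries, function(e) {
    sched <- if (is.null(e$schedule)) "single" else e$schedule
    if (sched == "single") {
      t0 <- if (is.null(e$time_h)) 0 else e$time_h
      data.frame(time = t0, drug = e$drug, dose_mg = e$dose_mg,
                 stringsAsFactors = FALSE)
    } else {
      doseEvents(e$dose_mg, e$drug, e$start_day, e$end_day,
                 interval = if (sched == "bid") 12 else 24)
    }
  }))
  DoseRegimen(ev, horizon = horizon)
}

## dose times of a given drug family (dabrafenib by default); used for
## trough/interval bookkeeping in PK metrics
.doseTimes <- function(regimen, drug = c("dabrafenib", "ketoconazole", "any")) {
  drug <- match.arg(drug)
  ev <- regimen@events
  keep <- switch(drug,
                 dabrafenib = ev$drug %in% c("dabrafenib_solution", "dabrafenib_hpmc"),
                 ketoconazole = ev$drug == "ketoconazole",
                 any = rep(TRUE, nrow(ev)))
  sort(unique(ev$time[keep]))
}
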