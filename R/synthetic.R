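## Synthetic clinical-study generator: four study designs mirroring the
## clinical datasets the model is calibrated on, generated from ground-truth
## parameters with proportional lognormal noise.

.profileTimes <- c(0.5, 1, 2, 4, 6, 8, 10, 24)

#' Synthetic study-design templates
#'
#' Returns the four designs used throughout the calibration workflow:
#' \describe{
#'   \item{single_dose_solution}{95 mg dabrafenib oral solution, single dose;
#'     plasma profiles of dabrafenib and all three metabolites over
#'     0.5-96 h plus cumulative relative excretion.}
#'   \item{dabrafenib_escalation}{HPMC capsule b.d. dosing at 50, 75, 100 and
#'     150 mg for 18 days; first-dose and day-18 steady-state profiles of
#'     dabrafenib plus daily pre-dose troughs.}
#'   \item{keto_escalation}{single oral ketoconazole doses of 100, 200 and
#'     400 mg; plasma profiles to 48 h.}
#'   \item{ddi_study}{75 mg b.d. dabrafenib for 22 days with 400 mg o.d.
#'     ketoconazole on days 19-22; profiles of all analytes at day 18
#'     (dabrafenib alone) and day 22 (with ketoconazole).}
#' }
#'
#' @param cv Proportional noise CV (default 0.15).
#' @param nReplicates Replicates per arm (default 6).
#' @return Named list of \code{StudyDesign} objects.
#' @export
designTemplates <- function(cv = 0.15, nReplicates = 6) {
  prof <- .profileTimes
  allAnalytes <- c("D0", "DH", "DC", "DD")

  ## (a) single 95 mg solution, rich sampling + excretion
  regA <- DoseRegimen(data.frame(time = 0, drug = "dabrafenib_solution",
                                 dose_mg = 95), horizon = 120)
  schedA <- c(stats::setNames(rep(list(c(prof[prof <= 10], 12, 24, 36, 48, 72, 96)),
                                  4), allAnalytes),
              list(excretion = c(24, 48, 72, 96)))
  a <- new("StudyDesign", id = "single_dose_solution",
           arms = list(sol95 = list(regimen = regA, schedule = schedA)),
           cv = cv, nReplicates = nReplicates)

  ## (b) HPMC dose escalation, 18 days b.d.
  armsB <- lapply(c(50, 75, 100, 150), function(d) {
    reg <- bdRegimen(d, startDay = 1, endDay = 18, horizon = 18 * 24 + 12)
    troughs <- seq(1, 18) * 24 - 0.001
    list(regimen = reg,
         schedule = list(D0 = sort(unique(c(prof[prof <= 12],
                                            17 * 24 + prof[prof <= 12],
                                            troughs)))))
  })
  names(armsB) <- paste0("dab", c(50, 75, 100, 150))
  b <- new("StudyDesign", id = "dabrafenib_escalation", arms = armsB,
           cv = cv, nReplicates = nReplicates)

  ## (c) ketoconazole escalation, single doses
  armsC <- lapply(c(100, 200, 400), function(d) {
    reg <- DoseRegimen(data.frame(time = 0, drug = "ketoconazole",
                                  dose_mg = d), horizon = 72)
    list(regimen = reg, schedule = list(K = c(prof, 12, 36, 48)))
  })
  names(armsC) <- paste0("keto", c(100, 200, 400))
  cD <- new("StudyDesign", id = "keto_escalation", arms = armsC,
            cv = cv, nReplicates = nReplicates)

  ## (d) DDI: 75 mg b.d. x 22 days + 400 mg keto o.d. days 19-22
  dab <- bdRegimen(75, startDay = 1, endDay = 22, horizon = 22 * 24 + 12)
  keto <- odRegimen(400, startDay = 19, endDay = 22, horizon = 22 * 24 + 12)
  regD <- combineRegimens(dab, keto, horizon = 22 * 24 + 12)
  day18 <- 17 * 24 + prof[prof <= 12]
  day22 <- 21 * 24 + prof[prof <= 12]
  schedD <- c(stats::setNames(rep(list(sort(c(day18, day22))), 4), allAnalytes),
              list(K = sort(c(day22, 21 * 24 + c(16, 20, 24)))))
  d <- new("StudyDesign", id = "ddi_study",
           arms = list(ddi75 = list(regimen = regD, schedule = schedD)),
           cv = cv, nReplicates = nReplicates)

  list(single_dose_solution = a, dabrafenib_escalation = b,
       keto_escalation = cD, ddi_study = d)
}

#' Generate a synthetic PK dataset from a study design
#'
#' Simulates each arm under the supplied ground-truth parameters, samples the
#' scheduled analytes, and applies multiplicative lognormal noise
#' exp(N(0, sigma)) with sigma = sqrt(log(1 + CV^2)) independently per
#' replicate and observation. The cumulative-excretion observable receives
#' noise on its increments (then re-accumulated) so every replicate stays
#' non-decreasing. Concentrations are reported in ng/mL, excretion as a
#' fraction of the administered dose.
#'
#' @param design A \code{StudyDesign}.
#' @param trueParams Ground-truth \code{ParameterSet}.
#' @param seed Integer seed (recorded in the provenance).
#' @param summaryOnly If TRUE return the arm geometric mean across
#'   replicates (one row per time point, `replicate = 0`); default FALSE.
#' @param rtol,atol Solver tolerances.
#' @return A \code{PKDataset}.
#' @export
generate <- function(design, trueParams, seed = 1L, summaryOnly = FALSE,
                     rtol = 1e-8, atol = 1e-10) {
  sigma <- sqrt(log(1 + design@cv^2))
  nrep <- design@nReplicates
  arms <- .withSeed(seed, lapply(names(design@arms), function(a) {
    arm <- design@arms[[a]]
    tr <- tryCatch(
      simulateRegimen(.withTimes(arm$regimen, unlist(arm$schedule)),
                      trueParams, rtol = rtol, atol = atol),
      error = function(e) stop("simulation failed for design '", design@id,
                               "' arm '", a, "': ", conditionMessage(e)))
    rows <- lapply(names(arm$schedule), function(an) {
      tt <- arm$schedule[[an]]
      unit <- if (an == "excretion") "fraction" else "ng/mL"
      base <- trajSeries(tr, an, unit = if (an == "excretion") "ng/mL" else unit,
                         times = tt)$value
      do.call(rbind, lapply(seq_len(nrep), function(r) {
        if (sigma == 0) {
          val <- base
        } else if (an == "excretion") {
          inc <- diff(c(0, base))
          val <- cumsum(inc * exp(rnorm(length(inc), 0, sigma)))
        } else {
          val <- base * exp(rnorm(length(base), 0, sigma))
        }
        data.frame(analyte = an, time_h = tt, value = val, unit = unit,
                   replicate = r, stringsAsFactors = FALSE)
      }))
    })
    d <- do.call(rbind, rows)
    if (summaryOnly) {
      d <- do.call(rbind, lapply(split(d, list(d$analyte, d$time_h), drop = TRUE),
        function(g) data.frame(analyte = g$analyte[1], time_h = g$time_h[1],
                               value = exp(mean(log(pmax(g$value, 1e-300)))),
                               unit = g$unit[1], replicate = 0L,
                               stringsAsFactors = FALSE)))
    }
    d <- d[order(d$analyte, d$replicate, d$time_h), ]
    rownames(d) <- NULL
    list(regimen = arm$regimen, data = d)
  }))
  names(arms) <- names(design@arms)
  new("PKDataset", studyId = design@id, arms = arms,
      provenance = list(seed = as.integer(seed), cv = design@cv,
                        nReplicates = nrep, generator = "mcpk::generate"))
}

#' Ground-truth bundle: parameters plus all four synthetic datasets
#'
#' Deterministic per seed. The parameter set is the package default
#' (\code{\link{groundTruthParameters}}), chosen so the qualitative clinical
#' behaviours hold: strong metabolite accumulation at 150 mg b.d., enzyme
#' induction triggered above 50 mg b.d., and increased dabrafenib exposure
#' under ketoconazole.
#'
#' @param seed Integer seed.
#' @param cv Noise CV passed to the templates (default 0.15).
#' @param summaryOnly Generate arm-level (geometric mean) tables.
#' @return List with elements `params` (ParameterSet) and `datasets` (named
#'   list of \code{PKDataset}).
#' @export
groundTruthBundle <- function(seed = 1L, cv = 0.15, summaryOnly = FALSE) {
  p <- groundTruthParameters()
  templates <- designTemplates(cv = cv)
  ds <- lapply(seq_along(templates), function(i)
    generate(templates[[i]], p, seed = seed + i - 1L, summaryOnly = summaryOnly))
  names(ds) <- names(templates)
  list(params = p, datasets = ds)
}

#' Write a PKDataset to CSV files
#'
#' One CSV per arm (columns analyte, time_h, value, unit, replicate) plus the
#' ground-truth/provenance YAML when parameters are supplied.
#'
#' @param dataset A \code{PKDataset}.
#' @param dir Output directory (created if needed).
#' @param params Optional \code{ParameterSet} written alongside as
#'   `ground_truth_params.yaml`.
#' @return Vector of written paths, invisibly.
#' @export
writeDatasetCSV <- function(dataset, dir, params = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(dataset@arms), function(a) {
    f <- file.path(dir, paste0(dataset@studyId, "_", a, ".csv"))
    utils::write.csv(dataset@arms[[a]]$data, f, row.names = FALSE)
    f
  }, character(1))
  if (!is.null(params)) {
    f <- file.path(dir, "ground_truth_params.yaml")
    writeParamsYAML(params, f)
    paths <- c(paths, f)
  }
  invisible(paths)
}
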