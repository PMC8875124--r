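## Reporting: accumulation predictions, occupancy/induction panels,
## extension-parameter count, run manifests. All report content is tabular
## (CSV-ready); figures are optional side outputs.

#' Steady-state accumulation report
#'
#' For each dose: simulates `weeksOn` weeks of b.d. HPMC dosing followed by
#' `weeksOff` weeks of washout and reports, per analyte, the peak-
#' concentration fold-change Cmax(steady state)/Cmax(first interval), the
#' time to steady state of the pre-dose troughs, and the washout time after
#' discontinuation.
#'
#' @param params A \code{ParameterSet}.
#' @param doses Dabrafenib doses (mg b.d.), default c(50, 75, 100, 150).
#' @param weeksOn,weeksOff Weeks of dosing / washout (defaults 6 and 4).
#' @param analytes Analytes to report, default carboxy- and
#'   desmethyl-dabrafenib.
#' @param out Optional CSV path.
#' @param plot Optional: if TRUE and ggplot2 is available, attach a ggplot of
#'   the accumulation curves as attribute "plot".
#' @param rtol,atol Solver tolerances.
#' @return data.frame (dose_mg, analyte, fold_change, tss_h, washout_h,
#'   flag).
#' @export
reportAccumulation <- function(params, doses = c(50, 75, 100, 150),
                               weeksOn = 6, weeksOff = 4,
                               analytes = c("DC", "DD"), out = NULL,
                               plot = FALSE, rtol = 1e-6, atol = 1e-8) {
  rows <- list()
  curves <- list()
  for (d in doses) {
    if (d <= 0) {
      for (an in analytes)
        rows[[length(rows) + 1]] <- data.frame(
          dose_mg = d, analyte = an, fold_change = NA_real_, tss_h = NA_real_,
          washout_h = NA_real_, flag = "zero dose: undefined",
          stringsAsFactors = FALSE)
      next
    }
    reg <- bdRegimen(d, startDay = 1, endDay = weeksOn * 7,
                     horizon = (weeksOn + weeksOff) * 7 * 24)
    tr <- simulateRegimen(reg, params, rtol = rtol, atol = atol)
    for (an in analytes) {
      m <- pkMetrics(tr, an)
      tss <- tryCatch(timeToSteadyState(tr, an),
                      error = function(e) NA_real_)
      wo <- tryCatch(washoutTime(tr, an), error = function(e) NA_real_)
      flag <- if (is.na(tss)) "steady state not reached" else ""
      rows[[length(rows) + 1]] <- data.frame(
        dose_mg = d, analyte = an, fold_change = m$accumulation_ratio,
        tss_h = tss, washout_h = wo, flag = flag, stringsAsFactors = FALSE)
      curves[[paste(d, an)]] <- data.frame(
        dose_mg = d, analyte = an,
        trajSeries(tr, an, unit = "ng/mL"), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  if (isTRUE(plot) && requireNamespace("ggplot2", quietly = TRUE)) {
    cd <- do.call(rbind, curves)
    gg <- ggplot2::ggplot(cd, ggplot2::aes(x = time_h / 24, y = value,
                                           colour = factor(dose_mg))) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~analyte, scales = "free_y") +
      ggplot2::labs(x = "time (days)", y = "concentration (ng/mL)",
                    colour = "dose (mg b.d.)")
    attr(res, "plot") <- gg
  }
  res
}

#' Occupancy and induction report
#'
#' Time series of the CYP3A4 occupancy split (free, baseline-bound, four
#' drug complexes), the baseline deficit TE - EB, the mRNA level and the
#' total enzyme under a regimen: the four panels of the induction analysis.
#'
#' @param params A \code{ParameterSet}.
#' @param regimen A \code{DoseRegimen}.
#' @param out Optional CSV path.
#' @param rtol,atol Solver tolerances.
#' @return data.frame (time_h, f_Ef, f_EB, f_ED0, f_EDH, f_EDD, f_EK,
#'   EB_deficit, EmRNA, E_total).
#' @export
reportOccupancy <- function(params, regimen, out = NULL,
                            rtol = 1e-6, atol = 1e-8) {
  tr <- simulateRegimen(regimen, params, rtol = rtol, atol = atol)
  fr <- occupancyFractions(tr)
  colnames(fr) <- paste0("f_", colnames(fr))
  v <- param(params)
  res <- data.frame(time_h = tr@times, fr,
                    EB_deficit = unname(v["TE"]) - tr@states[, "EB"],
                    EmRNA = tr@states[, "EmRNA"],
                    E_total = rowSums(tr@states[, c("Ef", "EB", "ED0", "EDH",
                                                    "EDD", "EK")]))
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}

#' Count the free extension parameters of the coupled model
#'
#' Counts parameters annotated as mechanistic extensions of the reproduced
#' two-compartment dabrafenib model (metabolite kinetics, enzyme network,
#' induction motif, ketoconazole and DDI) that are free (not fixed). The
#' registry must annotate every parameter; an unannotated entry is an error.
#'
#' @param params A \code{ParameterSet}.
#' @return Integer count.
#' @export
countExtensionParameters <- function(params) {
  role <- params@role
  if (anyNA(role) || any(!nzchar(role)))
    stop("parameter registry is not total: ",
         paste(names(params@values)[is.na(role) | !nzchar(role)], collapse = ", "))
  sum(role == "extension" & !params@fixed)
}

#' Write a reproducibility manifest
#'
#' Records the package version, seed, solver tolerances and MD5 of any input
#' files, sufficient to reproduce deterministic outputs bit-identically.
#'
#' @param path Output JSON path.
#' @param seed Integer seed of the run.
#' @param inputs Character vector of input file paths (hashed if they exist).
#' @param extra Named list of additional fields.
#' @return The manifest list, invisibly.
#' @export
writeManifest <- function(path, seed, inputs = character(0), extra = list()) {
  hashes <- if (length(inputs)) {
    ex <- file.exists(inputs)
    h <- rep(NA_character_, length(inputs))
    h[ex] <- unname(tools::md5sum(inputs[ex]))
    stats::setNames(as.list(h), inputs)
  } else list()
  manifest <- c(list(package = "mcpk",
                     version = as.character(utils::packageVersion("mcpk")),
                     seed = as.integer(seed),
                     r_version = R.version.string,
                     inputs = hashes), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
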