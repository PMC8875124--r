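## Species registry: state-vector layout, display names, molar masses.
## Internal state units: nM for concentrations, nmol for depot/absorbing pools.

#' State vector species names, in canonical order
#'
#' The dynamical state of the MCPK model. Oral dabrafenib depots are split by
#' formulation (solution vs HPMC capsule) because the two have distinct
#' first-order absorption rates; `D0_oral` in reports is their sum.
#'
#' @return Character vector of the 21 state names.
#' @export
#' @examples
#' stateNames()
stateNames <- function() {
  c("D0s", "D0cap",                 # oral dabrafenib depots (nmol): solution, capsule
    "D0c", "D0p",                   # dabrafenib central/peripheral (nM)
    "DHc", "DHp",                   # hydroxy-dabrafenib (nM)
    "DCc", "DCp",                   # carboxy-dabrafenib (nM)
    "DDc", "DDp",                   # desmethyl-dabrafenib (nM)
    "M",                            # cumulative downstream metabolites (nmol, absorbing)
    "U",                            # cumulative excreted drug-equivalents (nmol, absorbing)
    "K_oral", "Kc",                 # ketoconazole depot (nmol) / central (nM)
    "Ef", "EB",                     # free CYP3A4 / baseline-bound CYP3A4 (nM)
    "ED0", "EDH", "EDD", "EK",      # CYP3A4-substrate complexes (nM)
    "EmRNA")                        # CYP3A4 mRNA (nM-equivalent a.u.)
}

#' Species tag table
#'
#' Registry mapping analyte/species tags to display names and molar masses.
#' Molar masses (g/mol): dabrafenib 519.6; hydroxy-dabrafenib (+O) 535.6;
#' carboxy-dabrafenib (further oxidation of the hydroxyl to a carboxylic acid,
#' +30) 549.6; desmethyl-dabrafenib (decarboxylation of carboxy-dabrafenib,
#' -CO2) 505.6; ketoconazole 531.4.
#'
#' @return A data.frame with columns `tag`, `display`, `mw` (g/mol; `NA` for
#'   species without a single molar mass such as the pooled metabolite sink).
#' @export
speciesTable <- function() {
  data.frame(
    tag = c("D0", "DH", "DC", "DD", "M", "U", "K",
            "Ef", "EB", "ED0", "EDH", "EDD", "EK", "EmRNA"),
    display = c("dabrafenib", "hydroxy-dabrafenib", "carboxy-dabrafenib",
                "desmethyl-dabrafenib", "downstream metabolites",
                "excreted drug-equivalents", "ketoconazole",
                "free CYP3A4", "baseline-bound CYP3A4",
                "CYP3A4:dabrafenib", "CYP3A4:hydroxy-dabrafenib",
                "CYP3A4:desmethyl-dabrafenib", "CYP3A4:ketoconazole",
                "CYP3A4 mRNA"),
    mw = c(519.6, 535.6, 549.6, 505.6, NA, NA, 531.4,
           NA, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Molar mass lookup
#'
#' @param tag Species tag (e.g. `"D0"`, `"K"`) or central-compartment state
#'   name (e.g. `"D0c"`, `"Kc"`).
#' @return Molar mass in g/mol.
#' @export
molarMass <- function(tag) {
  tab <- speciesTable()
  tag0 <- sub("[cp]$", "", tag)
  tag0[tag %in% c("Kc", "K_oral")] <- "K"
  i <- match(tag0, tab$tag)
  if (anyNA(i)) stop("unknown species tag: ", paste(tag[is.na(i)], collapse = ", "))
  mw <- tab$mw[i]
  if (anyNA(mw)) stop("no molar mass defined for: ", paste(tag[is.na(mw)], collapse = ", "))
  mw
}

## map analyte tags to central-compartment state names
analyteState <- function(analyte) {
  map <- c(D0 = "D0c", DH = "DHc", DC = "DCc", DD = "DDc", K = "Kc",
           D0c = "D0c", DHc = "DHc", DCc = "DCc", DDc = "DDc", Kc = "Kc",
           excretion = "U")
  out <- map[analyte]
  if (anyNA(out)) stop("unknown analyte: ", paste(analyte[is.na(out)], collapse = ", "))
  unname(out)
}
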