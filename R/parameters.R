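## Parameter registry: defaults, accessors, YAML round-trip.

.paramOrder <- c(
  "ka_sol", "ka_cap", "F_sol", "F_cap", "Vc", "Vp",
  "q_D0", "q_DH", "q_DC", "q_DD",
  "kon_D0", "koff_D0", "kcat_D0",
  "kon_DH", "koff_DH", "kcat_DH",
  "kon_DD", "koff_DD", "kcat_DD",
  "kon_K", "koff_K", "kcat_K",
  "kBon", "kBoff",
  "Vmax_pH", "Km_pH", "Vmax_2C19", "Km_2C19",
  "ke_D0", "ke_DH", "ke_DC", "ke_DD",
  "kr", "TE", "kdeg", "kt", "kEdeg",
  "ka_K", "V_K", "E0",
  "eps_hinge", "Vmax_2C8", "Km_2C8", "use_2C8"
)

#' Construct a ParameterSet
#'
#' @param values Named numeric vector; must cover the full registry (see
#'   \code{\link{defaultParameters}} for the canonical set).
#' @param unit,lower,upper,fixed,role Optional named vectors overriding the
#'   registry metadata for a subset of parameters.
#' @return A \code{ParameterSet}.
#' @export
ParameterSet <- function(values, unit = NULL, lower = NULL, upper = NULL,
                         fixed = NULL, role = NULL) {
  base <- defaultParameters()
  if (!all(names(values) %in% names(base@values)))
    stop("unknown parameter(s): ",
         paste(setdiff(names(values), names(base@values)), collapse = ", "))
  p <- base
  p@values[names(values)] <- values
  for (s in c("unit", "lower", "upper", "fixed", "role")) {
    ov <- get(s)
    if (!is.null(ov)) {
      sl <- slot(p, s); sl[names(ov)] <- ov; slot(p, s) <- sl
    }
  }
  validObject(p)
  p
}

#' Default (ground-truth) MCPK parameter set
#'
#' The package's reference parameterization. Values are chosen once so that
#' the model displays the clinically reported qualitative behaviour of
#' dabrafenib: parent Cmax in the low-micromolar range at 150 mg b.d.,
#' hydroxy-dabrafenib as the dominant CYP3A4 occupant, slow elimination of
#' carboxy-/desmethyl-dabrafenib with saturable conversion producing strong,
#' dose-dependent metabolite accumulation, enzyme induction triggered at
#' doses above 50 mg b.d., and a ketoconazole interaction that raises parent
#' exposure by competitive CYP3A4 occupancy. This set also serves as the
#' ground truth of the synthetic-data module.
#'
#' Roles: the reproduced two-compartment dabrafenib PK (ka_cap, F_cap, Vc,
#' Vp, q_D0) is "base"; the 28 free parameters of the mechanistic coupling
#' are "extension"; unit constants and numerical switches are "structural";
#' the CYP2C8 route (disabled by default) is "pruned".
#'
#' @return A \code{ParameterSet}.
#' @export
defaultParameters <- function() {
  def <- list(
    ##            value    unit        lower    upper    fixed  role
    ka_sol   = list(2.0,   "1/h",      0.2,     20,      FALSE, "extension"),
    ka_cap   = list(0.55,  "1/h",      0.05,    5,       FALSE, "base"),
    F_sol    = list(0.95,  "-",        0.3,     1,       FALSE, "extension"),
    F_cap    = list(0.70,  "-",        0.2,     1,       FALSE, "base"),
    Vc       = list(70,    "L",        10,      500,     FALSE, "base"),
    Vp       = list(120,   "L",        10,      1000,    FALSE, "base"),
    q_D0     = list(0.08,  "1/h",      0.001,   5,       FALSE, "base"),
    q_DH     = list(0.06,  "1/h",      0.001,   5,       FALSE, "extension"),
    q_DC     = list(0.005,  "1/h",      0.001,   5,       FALSE, "extension"),
    q_DD     = list(0.005,  "1/h",      0.001,   5,       FALSE, "extension"),
    kon_D0   = list(0.01,  "1/(nM h)", 1e-4,    1,       TRUE,  "extension"),
    koff_D0  = list(8,    "1/h",      0.1,     1e4,     FALSE, "extension"),
    kcat_D0  = list(12,     "1/h",      0.01,    1e3,     FALSE, "extension"),
    kon_DH   = list(0.01,  "1/(nM h)", 1e-4,    1,       TRUE,  "extension"),
    koff_DH  = list(2,    "1/h",      0.1,     1e4,     FALSE, "extension"),
    kcat_DH  = list(10,     "1/h",      0.01,    1e3,     FALSE, "extension"),
    kon_DD   = list(0.01,  "1/(nM h)", 1e-4,    1,       TRUE,  "extension"),
    koff_DD  = list(28,    "1/h",      0.1,     1e4,     FALSE, "extension"),
    kcat_DD  = list(2,     "1/h",      0.01,    1e3,     FALSE, "extension"),
    kon_K    = list(0.01,  "1/(nM h)", 1e-4,    1,       TRUE,  "extension"),
    koff_K   = list(20,    "1/h",      0.1,     1e4,     FALSE, "extension"),
    kcat_K   = list(20,    "1/h",      0.01,    1e3,     FALSE, "extension"),
    kBon     = list(1.0,   "1/h",      0.01,    100,     FALSE, "extension"),
    kBoff    = list(1.0,   "1/h",      0.01,    100,     FALSE, "extension"),
    Vmax_pH  = list(215,    "nM/h",     0.1,     1e4,     FALSE, "extension"),
    Km_pH    = list(950,   "nM",       1,       1e5,     FALSE, "extension"),
    Vmax_2C19= list(190,    "nM/h",     0.1,     1e4,     FALSE, "extension"),
    Km_2C19  = list(300,   "nM",       1,       1e5,     FALSE, "extension"),
    ke_D0    = list(0,     "1/h",      0,       1,       TRUE,  "extension"),
    ke_DH    = list(0,     "1/h",      0,       1,       TRUE,  "extension"),
    ke_DC    = list(0.007, "1/h",      1e-5,    1,       FALSE, "extension"),
    ke_DD    = list(0.007, "1/h",      1e-5,    1,       FALSE, "extension"),
    kr       = list(0.03,  "1/h",      1e-4,    10,      FALSE, "extension"),
    TE       = list(35,      "nM",       1,       1e3,     FALSE, "extension"),
    kdeg     = list(0.05,  "1/h",      1e-3,    10,      FALSE, "extension"),
    kt       = list(0.05,  "1/h",      1e-3,    10,      FALSE, "extension"),
    kEdeg    = list(0.0096,"1/h",      1e-4,    1,       TRUE,  "extension"),
    ka_K     = list(1.0,   "1/h",      0.05,    10,      FALSE, "extension"),
    V_K      = list(40,    "L",        5,       500,     FALSE, "extension"),
    E0       = list(90,    "nM",       1,       1e4,     FALSE, "extension"),
    eps_hinge= list(0.35,    "nM",       0,       100,     TRUE,  "structural"),
    Vmax_2C8 = list(0,     "nM/h",     0,       1e4,     TRUE,  "pruned"),
    Km_2C8   = list(5000,  "nM",       1,       1e5,     TRUE,  "pruned"),
    use_2C8  = list(0,     "-",        0,       1,       TRUE,  "structural")
  )
  stopifnot(identical(names(def), .paramOrder))
  g <- function(i, mode) vapply(def, function(x) x[[i]], mode)
  new("ParameterSet",
      values = g(1, numeric(1)), unit = g(2, character(1)),
      lower = g(3, numeric(1)), upper = g(4, numeric(1)),
      fixed = g(5, logical(1)), role = g(6, character(1)))
}

#' @rdname defaultParameters
#' @details \code{groundTruthParameters()} is an alias for
#'   \code{defaultParameters()}: the default set doubles as the ground truth
#'   of the synthetic clinical studies.
#' @export
groundTruthParameters <- function() defaultParameters()

#' Get or set parameter values
#'
#' @param object A \code{ParameterSet}.
#' @param name Parameter name(s); if missing, all values.
#' @return Named numeric vector (or modified object for the setter).
#' @export
setGeneric("param", function(object, name) standardGeneric("param"))

#' @rdname param
#' @export
setMethod("param", "ParameterSet", function(object, name) {
  if (missing(name)) return(object@values)
  miss <- setdiff(name, names(object@values))
  if (length(miss)) stop("unknown parameter(s): ", paste(miss, collapse = ", "))
  object@values[name]
})

#' @rdname param
#' @param value Replacement value(s).
#' @export
setGeneric("param<-", function(object, name, value) standardGeneric("param<-"))

#' @rdname param
#' @export
setMethod("param<-", "ParameterSet", function(object, name, value) {
  miss <- setdiff(name, names(object@values))
  if (length(miss)) stop("unknown parameter(s): ", paste(miss, collapse = ", "))
  object@values[name] <- value
  validObject(object)
  object
})

#' Names of free (estimable) parameters
#'
#' @param object A \code{ParameterSet}.
#' @param role Optional role filter.
#' @return Character vector.
#' @export
freeParams <- function(object, role = NULL) {
  ok <- !object@fixed & object@role %in% c("base", "extension")
  if (!is.null(role)) ok <- ok & object@role %in% role
  names(object@values)[ok]
}

#' Read / write a parameter YAML file
#'
#' The file maps parameter name to a mapping with keys `value`, `unit`,
#' `lower`, `upper`, `fixed` (and optionally `role`).
#'
#' @param path File path.
#' @return \code{readParamsYAML}: a \code{ParameterSet}.
#' @export
readParamsYAML <- function(path) {
  y <- yaml::read_yaml(path)
  nm <- names(y)
  vals <- vapply(y, function(x) as.numeric(x$value), numeric(1)); names(vals) <- nm
  get1 <- function(key, default, mode) {
    out <- vapply(y, function(x) {
      v <- x[[key]]
      if (is.null(v)) default else if (mode == "logical") as.logical(v)
      else if (mode == "numeric") as.numeric(v) else as.character(v)
    }, vector(mode, 1))
    names(out) <- nm
    out[!is.na(out)]
  }
  ParameterSet(vals,
               unit = get1("unit", NA_character_, "character"),
               lower = get1("lower", NA_real_, "numeric"),
               upper = get1("upper", NA_real_, "numeric"),
               fixed = get1("fixed", NA, "logical"),
               role = get1("role", NA_character_, "character"))
}

#' @rdname readParamsYAML
#' @param object A \code{ParameterSet} to serialize.
#' @export
writeParamsYAML <- function(object, path) {
  nm <- names(object@values)
  y <- lapply(nm, function(n) list(
    value = unname(object@values[n]), unit = unname(object@unit[n]),
    lower = unname(object@lower[n]), upper = unname(object@upper[n]),
    fixed = unname(object@fixed[n]), role = unname(object@role[n])))
  names(y) <- nm
  yaml::write_yaml(y, path)
  invisible(path)
}

## parameter vector in the fixed order the compiled RHS expects
.parmVector <- function(params) {
  params@values[.paramOrder]
}
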