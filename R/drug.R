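# Drug / pathway / inhibition data model and YAML configuration IO.
#
# Enzymes are identified by a fixed vocabulary; UNSPECIFIC denotes a hepatic
# clearance process not attributable to a single enzyme (insensitive to
# inhibitors, not expressed as an enzyme amount).

#' Allowed enzyme identifiers
#' @export
CYP_ENZYMES <- c("CYP1A2", "CYP2C19", "CYP2D6", "CYP3A4", "CYP2C9",
                 "UGT1A1", "UNSPECIFIC")

.check_enzyme <- function(enzyme, allow_unspecific = TRUE) {
  allowed <- if (allow_unspecific) CYP_ENZYMES else setdiff(CYP_ENZYMES, "UNSPECIFIC")
  if (!is.character(enzyme) || length(enzyme) != 1L || !enzyme %in% allowed)
    stop("unknown enzyme identifier '", enzyme, "'; allowed: ",
         paste(allowed, collapse = ", "))
  enzyme
}

#' Define a metabolic pathway
#'
#' A pathway couples one enzyme to one of three kinetic laws:
#' \describe{
#'   \item{linear}{rate = cl_int * E_active * Cu / (1 + sum(I/Ki)); `cl_int` is
#'     intrinsic clearance per µmol enzyme (L/min/µmol).}
#'   \item{saturable}{Michaelis-Menten, rate = vmax * E_active * Cu /
#'     (km * (1 + sum(I/Ki)) + Cu); `vmax` in µmol/min/µmol enzyme, `km` in µM
#'     (unbound).}
#'   \item{unspecific_hepatic}{apparent plasma clearance, rate =
#'     cl_apparent * Cu; not attached to an enzyme amount and insensitive to
#'     inhibitors.}
#' }
#' Exactly the parameters matching `kinetics` must be supplied; all must be
#' positive. Values may be given as numbers in canonical units or as
#' `"value unit"` strings.
#'
#' @param enzyme Enzyme identifier (see [CYP_ENZYMES]).
#' @param kinetics `"linear"`, `"saturable"` or `"unspecific_hepatic"`.
#' @param cl_int Intrinsic clearance, L/min/µmol enzyme (linear).
#' @param vmax Maximum rate, µmol/min/µmol enzyme (saturable).
#' @param km Michaelis constant, µM unbound (saturable).
#' @param cl_apparent Apparent clearance, L/min (unspecific_hepatic).
#' @return Object of class `pbpk_pathway`.
#' @export
pathway <- function(enzyme, kinetics, cl_int = NULL, vmax = NULL, km = NULL,
                    cl_apparent = NULL) {
  .check_enzyme(enzyme)
  kinetics <- match.arg(kinetics, c("linear", "saturable", "unspecific_hepatic"))
  given <- c(cl_int = !is.null(cl_int), vmax = !is.null(vmax),
             km = !is.null(km), cl_apparent = !is.null(cl_apparent))
  need <- switch(kinetics,
    linear = c("cl_int"),
    saturable = c("vmax", "km"),
    unspecific_hepatic = c("cl_apparent"))
  if (!setequal(names(given)[given], need))
    stop("pathway (", enzyme, ", ", kinetics, "): requires exactly {",
         paste(need, collapse = ", "), "}; got {",
         paste(names(given)[given], collapse = ", "), "}")
  if (kinetics == "unspecific_hepatic" && enzyme != "UNSPECIFIC")
    stop("unspecific_hepatic kinetics must use enzyme UNSPECIFIC")
  if (kinetics != "unspecific_hepatic" && enzyme == "UNSPECIFIC")
    stop("enzyme UNSPECIFIC requires unspecific_hepatic kinetics")
  pw <- list(enzyme = enzyme, kinetics = kinetics)
  if (kinetics == "linear")
    pw$cl_int <- parse_quantity(cl_int, "clearance", "cl_int")
  if (kinetics == "saturable") {
    pw$vmax <- parse_quantity(vmax, "rate", "vmax")
    pw$km <- parse_quantity(km, "concentration", "km")
  }
  if (kinetics == "unspecific_hepatic")
    pw$cl_apparent <- parse_quantity(cl_apparent, "clearance", "cl_apparent")
  for (p in setdiff(names(pw), c("enzyme", "kinetics")))
    if (pw[[p]] <= 0) stop("pathway (", enzyme, "): ", p, " must be > 0")
  structure(pw, class = "pbpk_pathway")
}

#' Define an enzyme inhibition
#'
#' Competitive inhibition scales the apparent Km of the target enzyme by
#' (1 + I_u/Ki). Time-dependent (mechanism-based) inhibition irreversibly
#' inactivates the enzyme at rate k_inact * I_u / (k_i_tdi + I_u), countered
#' by turnover at the enzyme's degradation rate. A single drug may carry both
#' mechanisms against the same enzyme (one entry each).
#'
#' @param target_enzyme Enzyme identifier (not UNSPECIFIC).
#' @param mechanism `"competitive"` or `"tdi"`.
#' @param ki Competitive inhibition constant, µM unbound.
#' @param k_i_tdi TDI binding constant, µM unbound.
#' @param k_inact Maximum inactivation rate, 1/min.
#' @param basis Provenance of the constant: `"in_vitro"`, `"in_vivo_unbound"`
#'   or `"optimized"`.
#' @param note Optional free-text metadata (e.g. the literature value an
#'   optimized constant replaced).
#' @return Object of class `pbpk_inhibition`.
#' @export
inhibition <- function(target_enzyme, mechanism, ki = NULL, k_i_tdi = NULL,
                       k_inact = NULL, basis = "in_vitro", note = NULL) {
  .check_enzyme(target_enzyme, allow_unspecific = FALSE)
  mechanism <- match.arg(mechanism, c("competitive", "tdi"))
  basis <- match.arg(basis, c("in_vitro", "in_vivo_unbound", "optimized"))
  inh <- list(target_enzyme = target_enzyme, mechanism = mechanism,
              basis = basis)
  if (mechanism == "competitive") {
    if (is.null(ki)) stop("competitive inhibition requires ki")
    if (!is.null(k_i_tdi) || !is.null(k_inact))
      stop("competitive inhibition must not carry TDI parameters")
    inh$ki <- parse_quantity(ki, "concentration", "ki")
    if (inh$ki <= 0) stop("ki must be > 0")
  } else {
    if (is.null(k_i_tdi) || is.null(k_inact))
      stop("tdi inhibition requires k_i_tdi and k_inact")
    if (!is.null(ki)) stop("tdi inhibition must not carry ki")
    inh$k_i_tdi <- parse_quantity(k_i_tdi, "concentration", "k_i_tdi")
    inh$k_inact <- parse_quantity(k_inact, "rate", "k_inact")
    if (inh$k_i_tdi <= 0) stop("k_i_tdi must be > 0")
    if (inh$k_inact <= 0) stop("k_inact must be > 0")
  }
  if (!is.null(note)) inh$note <- as.character(note)
  structure(inh, class = "pbpk_inhibition")
}

#' Define a drug
#'
#' @param name Drug name (unique within a simulation).
#' @param molecular_weight g/mol.
#' @param fu Fraction unbound in plasma, in (0, 1].
#' @param blood_plasma_ratio Blood-to-plasma concentration ratio (> 0).
#' @param kp_map Named list/vector of tissue-to-plasma partition coefficients
#'   (> 0); organs missing from the map fall back to the `"default"` entry if
#'   present.
#' @param pathways List of [pathway()] objects; enzymes must be unique.
#' @param inhibitions List of [inhibition()] objects.
#' @param absorption For orally dosed drugs: list with `ka` (1/min), `f_abs`
#'   in (0, 1], and optionally `weibull_scale` (min) and `weibull_shape` for
#'   Weibull-release formulations.
#' @param tags Optional character tags (e.g. `"dietary"` for compounds with
#'   possible background intake such as caffeine).
#' @return Object of class `pbpk_drug`.
#' @export
drug <- function(name, molecular_weight, fu, blood_plasma_ratio = 1,
                 kp_map = list(default = 1), pathways = list(),
                 inhibitions = list(), absorption = NULL, tags = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  mw <- as.numeric(molecular_weight)
  if (!is.finite(mw) || mw <= 0) stop("drug '", name, "': molecular_weight must be > 0")
  fu <- as.numeric(fu)
  if (!is.finite(fu) || fu <= 0 || fu > 1)
    stop("drug '", name, "': fu must be in (0, 1]")
  bp <- as.numeric(blood_plasma_ratio)
  if (!is.finite(bp) || bp <= 0)
    stop("drug '", name, "': blood_plasma_ratio must be > 0")
  kp <- vapply(kp_map, function(v) parse_quantity(v, "dimensionless", "kp"),
               numeric(1))
  if (any(kp <= 0)) stop("drug '", name, "': kp values must be > 0")
  if (is.null(names(kp)) || any(!nzchar(names(kp))))
    stop("drug '", name, "': kp_map must be named by tissue")
  pathways <- lapply(pathways, function(p) {
    if (!inherits(p, "pbpk_pathway")) stop("pathways must be pathway() objects")
    p
  })
  enz <- vapply(pathways, `[[`, character(1), "enzyme")
  if (anyDuplicated(enz))
    stop("drug '", name, "': pathway enzymes must be unique, duplicated: ",
         paste(unique(enz[duplicated(enz)]), collapse = ", "))
  inhibitions <- lapply(inhibitions, function(i) {
    if (!inherits(i, "pbpk_inhibition")) stop("inhibitions must be inhibition() objects")
    i
  })
  if (!is.null(absorption)) {
    if (is.null(absorption$ka) || is.null(absorption$f_abs))
      stop("drug '", name, "': absorption requires ka and f_abs")
    absorption$ka <- parse_quantity(absorption$ka, "rate", "ka")
    absorption$f_abs <- as.numeric(absorption$f_abs)
    if (absorption$ka <= 0) stop("ka must be > 0")
    if (absorption$f_abs <= 0 || absorption$f_abs > 1)
      stop("f_abs must be in (0, 1]")
    if (!is.null(absorption$weibull_scale)) {
      absorption$weibull_scale <- parse_quantity(absorption$weibull_scale,
                                                 "time", "weibull_scale")
      absorption$weibull_shape <- as.numeric(absorption$weibull_shape %||% 1)
      if (absorption$weibull_scale <= 0 || absorption$weibull_shape <= 0)
        stop("Weibull release parameters must be > 0")
    }
  }
  structure(list(name = name, molecular_weight = mw, fu = fu,
                 blood_plasma_ratio = bp, kp_map = kp, pathways = pathways,
                 inhibitions = inhibitions, absorption = absorption,
                 tags = as.character(tags %||% character(0))),
            class = "pbpk_drug")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pbpk_drug <- function(x, ...) {
  cat("<pbpk_drug>", x$name, " MW", x$molecular_weight, "g/mol  fu", x$fu,
      " B:P", x$blood_plasma_ratio, "\n")
  for (p in x$pathways) {
    pars <- setdiff(names(p), c("enzyme", "kinetics"))
    cat("  pathway ", format(p$enzyme, width = 10), p$kinetics, " ",
        paste(pars, signif(unlist(p[pars]), 4), sep = "=", collapse = " "), "\n")
  }
  for (i in x$inhibitions) {
    pars <- intersect(names(i), c("ki", "k_i_tdi", "k_inact"))
    cat("  inhibits", format(i$target_enzyme, width = 10), i$mechanism, " ",
        paste(pars, signif(unlist(i[pars]), 4), sep = "=", collapse = " "),
        " [", i$basis, "]\n", sep = "")
  }
  invisible(x)
}

# ---- configuration IO -------------------------------------------------------

.DRUG_SCHEMA <- "pbpkddi-drug/1"

.pathway_from_config <- function(cfg) {
  do.call(pathway, cfg[intersect(names(cfg),
    c("enzyme", "kinetics", "cl_int", "vmax", "km", "cl_apparent"))])
}

.inhibition_from_config <- function(cfg) {
  do.call(inhibition, cfg[intersect(names(cfg),
    c("target_enzyme", "mechanism", "ki", "k_i_tdi", "k_inact", "basis",
      "note"))])
}

#' Load a drug from a YAML configuration file
#'
#' The file must declare `schema: pbpkddi-drug/1`. Quantities carry explicit
#' unit strings and are normalized to canonical units (µM, µmol, L, min) at
#' load; loading is therefore idempotent with respect to units (3.6 nM and
#' 0.0036 µM produce identical drugs).
#'
#' @param path Path to a YAML drug file.
#' @return A validated [drug()] object.
#' @seealso [write_drug_config()], [load_builtin_drug()]
#' @export
load_drug_config <- function(path) {
  if (!file.exists(path)) stop("drug config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!identical(cfg$schema, .DRUG_SCHEMA))
    stop("file '", path, "': expected schema '", .DRUG_SCHEMA, "', got '",
         cfg$schema %||% "<missing>", "'")
  for (f in c("name", "molecular_weight", "fu"))
    if (is.null(cfg[[f]])) stop("file '", path, "': missing field '", f, "'")
  drug(name = cfg$name,
       molecular_weight = cfg$molecular_weight,
       fu = cfg$fu,
       blood_plasma_ratio = cfg$blood_plasma_ratio %||% 1,
       kp_map = cfg$kp_map %||% list(default = 1),
       pathways = lapply(cfg$pathways, .pathway_from_config),
       inhibitions = lapply(cfg$inhibitions, .inhibition_from_config),
       absorption = cfg$absorption, tags = cfg$tags)
}

#' Write a drug to a YAML configuration file
#'
#' Values are written in canonical units with explicit unit strings so that
#' `load_drug_config(write_drug_config(d, p))` reproduces `d` exactly.
#'
#' @param d A [drug()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_config <- function(d, path) {
  stopifnot(inherits(d, "pbpk_drug"))
  dim_of <- c(cl_int = "clearance", vmax = "rate", km = "concentration",
              cl_apparent = "clearance", ki = "concentration",
              k_i_tdi = "concentration", k_inact = "rate")
  qfmt <- function(lst) {
    for (nm in intersect(names(lst), names(dim_of)))
      lst[[nm]] <- format_quantity(lst[[nm]], dim_of[[nm]])
    lst
  }
  cfg <- list(schema = .DRUG_SCHEMA, name = d$name,
              molecular_weight = d$molecular_weight, fu = d$fu,
              blood_plasma_ratio = d$blood_plasma_ratio,
              kp_map = as.list(d$kp_map),
              pathways = lapply(d$pathways, function(p) qfmt(unclass(p))),
              inhibitions = lapply(d$inhibitions, function(i) qfmt(unclass(i))))
  if (!is.null(d$absorption)) {
    ab <- d$absorption
    ab$ka <- format_quantity(ab$ka, "rate")
    if (!is.null(ab$weibull_scale))
      ab$weibull_scale <- format_quantity(ab$weibull_scale, "time")
    cfg$absorption <- ab
  }
  if (length(d$tags)) cfg$tags <- as.list(d$tags)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# ---- interaction constant library ------------------------------------------

#' Built-in library of competitive/TDI interaction constants
#'
#' The perpetrator-victim inhibition constants used by the CYP2C19/CYP1A2 DDI
#' network. Competitive Ki values are reported per inhibitor-substrate pair;
#' omeprazole enantiomers carry separate constants, each with a CYP2C19
#' time-dependent component. TDI maximum inactivation rates (k_inact) for the
#' omeprazole and moclobemide autoinhibition are illustrative defaults (noted
#' per entry); ethinylestradiol's two candidate k_inact values (100 and
#' 200 1/min) are exposed through [compare_mechanisms()] rather than fixed
#' here (the library carries 100 1/min).
#'
#' @return A data.frame with columns `inhibitor`, `substrate`, `category` and
#'   a list-column `inhibition` of [inhibition()] objects.
#' @export
builtin_ki_library <- function() {
  e <- function(inhibitor, substrate, category, inh)
    list(inhibitor = inhibitor, substrate = substrate, category = category,
         inhibition = inh)
  entries <- list(
    e("fluvoxamine", "omeprazole", "strong CYP2C19",
      inhibition("CYP2C19", "competitive", ki = "3.6 nM",
                 basis = "in_vivo_unbound")),
    e("fluvoxamine", "s-mephenytoin", "strong CYP2C19",
      inhibition("CYP2C19", "competitive", ki = "2.6 nM",
                 basis = "in_vivo_unbound")),
    e("fluvoxamine", "caffeine", "strong CYP1A2",
      inhibition("CYP1A2", "competitive", ki = "2.97 nM",
                 basis = "in_vivo_unbound")),
    e("fluvoxamine", "tizanidine", "strong CYP1A2",
      inhibition("CYP1A2", "competitive", ki = "0.8697 nM",
                 basis = "optimized", note = "lowest literature value 0.9 nM")),
    e("fluvoxamine", "mexiletine", "strong CYP1A2",
      inhibition("CYP1A2", "competitive", ki = "2.97 nM",
                 basis = "in_vivo_unbound")),
    e("moclobemide", "omeprazole", "moderate CYP2C19",
      inhibition("CYP2C19", "competitive", ki = "203.83 uM",
                 basis = "in_vitro")),
    e("moclobemide", "omeprazole", "moderate CYP2C19",
      inhibition("CYP2C19", "tdi", k_i_tdi = "94.85 uM", k_inact = "0.05 1/min",
                 basis = "in_vitro", note = "k_inact illustrative")),
    e("esomeprazole", "moclobemide", "moderate CYP2C19",
      inhibition("CYP2C19", "competitive", ki = "3.1 uM", basis = "in_vitro")),
    e("esomeprazole", "moclobemide", "moderate CYP2C19",
      inhibition("CYP2C19", "tdi", k_i_tdi = "0.3 uM", k_inact = "0.05 1/min",
                 basis = "in_vitro", note = "k_inact illustrative")),
    e("r-omeprazole", "moclobemide", "moderate CYP2C19",
      inhibition("CYP2C19", "competitive", ki = "5.3 uM", basis = "in_vitro")),
    e("r-omeprazole", "moclobemide", "moderate CYP2C19",
      inhibition("CYP2C19", "tdi", k_i_tdi = "1.6 uM", k_inact = "0.05 1/min",
                 basis = "in_vitro", note = "k_inact illustrative")),
    e("mexiletine", "caffeine", "moderate CYP1A2",
      inhibition("CYP1A2", "competitive", ki = "0.28 uM", basis = "in_vitro")),
    e("mexiletine", "tizanidine", "moderate CYP1A2",
      inhibition("CYP1A2", "competitive", ki = "0.28 uM", basis = "in_vitro")),
    e("ethinylestradiol", "caffeine", "moderate CYP1A2",
      inhibition("CYP1A2", "competitive", ki = "0.48 uM",
                 basis = "optimized", note = "literature value 10.6 uM")),
    e("ethinylestradiol", "tizanidine", "moderate CYP1A2",
      inhibition("CYP1A2", "competitive", ki = "0.48 uM",
                 basis = "optimized", note = "literature value 10.6 uM")),
    e("ethinylestradiol", "caffeine", "moderate CYP1A2",
      inhibition("CYP1A2", "tdi", k_i_tdi = "0.48 uM", k_inact = "100 1/min",
                 basis = "optimized",
                 note = "k_inact candidates 100 and 200 1/min; KI illustrative")),
    e("ethinylestradiol", "tizanidine", "moderate CYP1A2",
      inhibition("CYP1A2", "tdi", k_i_tdi = "0.48 uM", k_inact = "200 1/min",
                 basis = "optimized",
                 note = "k_inact candidates 100 and 200 1/min; KI illustrative"))
  )
  data.frame(
    inhibitor = vapply(entries, `[[`, character(1), "inhibitor"),
    substrate = vapply(entries, `[[`, character(1), "substrate"),
    category = vapply(entries, `[[`, character(1), "category"),
    inhibition = I(lapply(entries, `[[`, "inhibition")),
    stringsAsFactors = FALSE
  )
}

#' Look up the competitive/TDI constants for one inhibitor-substrate pair
#'
#' @param inhibitor,substrate Drug names (lower case).
#' @return List of [inhibition()] objects (possibly both a competitive and a
#'   TDI entry); error if the pair is not in the library.
#' @export
ki_for_pair <- function(inhibitor, substrate) {
  lib <- builtin_ki_library()
  hit <- lib$inhibitor == tolower(inhibitor) & lib$substrate == tolower(substrate)
  if (!any(hit))
    stop("no interaction constants for pair ", inhibitor, " -> ", substrate)
  lib$inhibition[hit]
}

#' Names of the bundled illustrative drug models
#' @return Character vector of names accepted by [load_builtin_drug()].
#' @export
builtin_drug_names <- function() {
  files <- list.files(system.file("extdata", "drugs", package = "pbpkddi"),
                      pattern = "\\.yaml$")
  sub("\\.yaml$", "", files)
}

#' Load one of the bundled illustrative drug models
#'
#' The bundled files carry the network's interaction constants together with
#' literature-plausible placeholder PK parameters (clearances, Km/Vmax, fu,
#' Kp); the placeholders are illustrative, not fitted values, and are labeled
#' as such in each file.
#'
#' @param name One of [builtin_drug_names()].
#' @return A [drug()] object.
#' @export
load_builtin_drug <- function(name) {
  path <- system.file("extdata", "drugs", paste0(tolower(name), ".yaml"),
                      package = "pbpkddi")
  if (!nzchar(path) || !file.exists(path))
    stop("no bundled drug '", name, "'; available: ",
         paste(builtin_drug_names(), collapse = ", "))
  load_drug_config(path)
}
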