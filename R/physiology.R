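# Reduced whole-body physiology: 12 perfused organ compartments plus arterial
# and venous blood. Gut wall and spleen drain through the portal vein into the
# liver; all other organs return to venous blood. Reference values are
# literature-standard resting adult (70 kg) figures.

.PORTAL_ORGANS <- c("gut", "spleen")

#' Reference adult individual
#'
#' Returns the package's documented reference adult: 70 kg, cardiac output
#' 6.5 L/min, 12 perfused organs (lung, liver, gut wall, spleen, kidney,
#' muscle, adipose, skin, brain, heart, bone, rest) plus arterial and venous
#' blood. The liver receives the hepatic artery plus the portal outflow of gut
#' and spleen, so its `blood_flow` equals hepatic artery + portal vein flow.
#' All enzymes are expressed in the liver; CYP3A4 and CYP2C19 are additionally
#' expressed in the gut wall. Expression amounts (µmol enzyme per organ) are
#' derived from typical adult abundance data and are illustrative.
#'
#' @return Object of class `pbpk_individual` with fields `body_weight` (kg),
#'   `cardiac_output` (L/min), `organs` (data.frame: name, volume L,
#'   blood_flow L/min), `blood` (arterial/venous volumes L) and `expression`
#'   (list: enzyme -> named vector of µmol per organ).
#' @export
default_individual <- function() {
  # volumes (L) and flows (L/min); hepatic artery 0.45, portal 1.15
  organs <- data.frame(
    name = c("lung", "liver", "gut", "spleen", "kidney", "muscle",
             "adipose", "skin", "brain", "heart", "bone", "rest"),
    volume = c(0.5, 1.8, 1.1, 0.15, 0.31, 29, 13.5, 3.3, 1.45, 0.33, 10, 4.1),
    blood_flow = c(6.5, 1.6, 1.0, 0.15, 1.24, 0.75, 0.26, 0.30, 0.78,
                   0.24, 0.25, NA),
    stringsAsFactors = FALSE
  )
  # close the mass balance exactly: rest takes the remaining systemic flow
  co <- 6.5
  ha <- organs$blood_flow[organs$name == "liver"] -
    sum(organs$blood_flow[organs$name %in% .PORTAL_ORGANS])
  systemic <- setdiff(organs$name, c("lung", "rest"))
  arterial <- sum(organs$blood_flow[organs$name %in%
                                      setdiff(systemic, "liver")]) + ha
  organs$blood_flow[organs$name == "rest"] <- co - arterial
  ind <- structure(list(
    body_weight = 70,
    cardiac_output = co,
    organs = organs,
    blood = list(arterial_volume = 1.7, venous_volume = 3.9),
    expression = list(
      CYP1A2  = c(liver = 2.6),
      CYP2C19 = c(liver = 0.63, gut = 0.006),
      CYP2D6  = c(liver = 0.46),
      CYP3A4  = c(liver = 7.9, gut = 0.07),
      CYP2C9  = c(liver = 4.2),
      UGT1A1  = c(liver = 3.0)
    )
  ), class = "pbpk_individual")
  validate_individual(ind)
}

#' Validate an individual's physiology
#'
#' Checks positivity of volumes and flows, the portal topology (liver flow =
#' hepatic artery + portal inflow, i.e. arterial supply to the liver is
#' `blood_flow[liver] - blood_flow[gut] - blood_flow[spleen]` and must be
#' > 0), that systemic arterial flows sum to cardiac output (relative
#' tolerance 1e-9), and non-negative enzyme expression restricted to existing
#' organs.
#'
#' @param ind A `pbpk_individual`.
#' @return `ind`, invisibly usable (returned unchanged) if valid; error otherwise.
#' @export
validate_individual <- function(ind) {
  stopifnot(inherits(ind, "pbpk_individual"))
  org <- ind$organs
  if (any(org$volume <= 0) || any(org$blood_flow <= 0))
    stop("organ volumes and blood flows must be > 0")
  if (ind$blood$arterial_volume <= 0 || ind$blood$venous_volume <= 0)
    stop("blood volumes must be > 0")
  need <- c("lung", "liver", "gut", "spleen", "kidney")
  miss <- setdiff(need, org$name)
  if (length(miss)) stop("missing required organs: ", paste(miss, collapse = ", "))
  flow <- function(nm) org$blood_flow[org$name == nm]
  ha <- flow("liver") - sum(vapply(.PORTAL_ORGANS, flow, numeric(1)))
  if (ha <= 0) stop("liver blood flow must exceed portal inflow")
  systemic <- setdiff(org$name, "lung")
  arterial <- sum(org$blood_flow[org$name %in% setdiff(systemic, "liver")]) + ha
  if (abs(arterial - ind$cardiac_output) > 1e-9 * ind$cardiac_output)
    stop("systemic arterial flows (", format(arterial, digits = 12),
         " L/min) do not sum to cardiac output (", ind$cardiac_output, ")")
  if (abs(flow("lung") - ind$cardiac_output) > 1e-9 * ind$cardiac_output)
    stop("lung flow must equal cardiac output")
  for (enz in names(ind$expression)) {
    .check_enzyme(enz, allow_unspecific = FALSE)
    ex <- ind$expression[[enz]]
    if (any(ex < 0)) stop("enzyme expression must be >= 0 (", enz, ")")
    bad <- setdiff(names(ex), org$name)
    if (length(bad)) stop("expression of ", enz, " in unknown organ: ",
                          paste(bad, collapse = ", "))
  }
  ind
}

#' @export
print.pbpk_individual <- function(x, ...) {
  cat("<pbpk_individual>", x$body_weight, "kg, CO", x$cardiac_output,
      "L/min,", nrow(x$organs), "organs + arterial/venous blood\n")
  ex <- vapply(names(x$expression), function(e)
    paste0(e, ": ", paste(names(x$expression[[e]]),
                          signif(x$expression[[e]], 3),
                          sep = "=", collapse = ",")), character(1))
  cat("  expression (umol):", paste(ex, collapse = "; "), "\n")
  invisible(x)
}

#' Define a CYP phenotype as an activity multiplier
#'
#' Extensive metabolizers (EM) have multiplier 1, poor metabolizers (PM) 0;
#' intermediate multipliers model reduced-function alleles.
#'
#' @param enzyme Enzyme identifier.
#' @param activity_multiplier Non-negative scaling applied to the enzyme's
#'   expression in every organ.
#' @return Object of class `pbpk_phenotype`.
#' @export
phenotype <- function(enzyme, activity_multiplier) {
  .check_enzyme(enzyme, allow_unspecific = FALSE)
  m <- as.numeric(activity_multiplier)
  if (!is.finite(m) || m < 0) stop("activity_multiplier must be >= 0")
  structure(list(enzyme = enzyme, activity_multiplier = m),
            class = "pbpk_phenotype")
}

#' Apply a phenotype to an individual
#'
#' Multiplies the enzyme's expression by the phenotype's activity multiplier
#' in every expressing organ and returns a modified copy; the input individual
#' is unchanged. Application composes multiplicatively (0.5 twice equals 0.25
#' once).
#'
#' @param ind A `pbpk_individual`.
#' @param ph A [phenotype()].
#' @return A new `pbpk_individual`.
#' @export
apply_phenotype <- function(ind, ph) {
  stopifnot(inherits(ind, "pbpk_individual"), inherits(ph, "pbpk_phenotype"))
  if (!ph$enzyme %in% names(ind$expression))
    stop("individual does not express enzyme ", ph$enzyme)
  ind$expression[[ph$enzyme]] <- ind$expression[[ph$enzyme]] *
    ph$activity_multiplier
  validate_individual(ind)
}

#' Scale gut-wall expression of one enzyme
#'
#' Multiplies the gut-wall expression of `enzyme` by `factor`, leaving liver
#' (and all other organs) untouched. Lowering gut CYP2C19 raises the oral
#' bioavailability of gut-CYP2C19 substrates by reducing first-pass gut-wall
#' extraction.
#'
#' @param ind A `pbpk_individual`.
#' @param enzyme Enzyme identifier.
#' @param factor Non-negative scaling factor.
#' @return A new `pbpk_individual`.
#' @export
scale_gut_expression <- function(ind, enzyme, factor) {
  stopifnot(inherits(ind, "pbpk_individual"))
  .check_enzyme(enzyme, allow_unspecific = FALSE)
  factor <- as.numeric(factor)
  if (!is.finite(factor) || factor < 0) stop("factor must be >= 0")
  if (!enzyme %in% names(ind$expression))
    stop("individual does not express enzyme ", enzyme)
  ex <- ind$expression[[enzyme]]
  if ("gut" %in% names(ex)) ex[["gut"]] <- ex[["gut"]] * factor
  ind$expression[[enzyme]] <- ex
  validate_individual(ind)
}

#' Apply a physiology override file
#'
#' Reads a YAML override file (`schema: pbpkddi-physiology/1`) permitting
#' per-organ `volume`/`blood_flow` overrides, blood volume overrides,
#' `cardiac_output`, and per-enzyme per-organ expression overrides (µmol).
#' The result is re-validated, so an override set that breaks the flow
#' balance or the portal topology errors out.
#'
#' @param ind A `pbpk_individual` to start from.
#' @param path YAML override file.
#' @return A new `pbpk_individual`.
#' @export
apply_physiology_overrides <- function(ind, path) {
  stopifnot(inherits(ind, "pbpk_individual"))
  if (!file.exists(path)) stop("physiology override file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!identical(cfg$schema, "pbpkddi-physiology/1"))
    stop("file '", path, "': expected schema 'pbpkddi-physiology/1'")
  if (!is.null(cfg$cardiac_output))
    ind$cardiac_output <- parse_quantity(cfg$cardiac_output, "flow")
  if (!is.null(cfg$body_weight))
    ind$body_weight <- parse_quantity(cfg$body_weight, "mass") / 1e6 # mg->kg
  for (nm in names(cfg$organs)) {
    i <- match(nm, ind$organs$name)
    if (is.na(i)) stop("override for unknown organ: ", nm)
    o <- cfg$organs[[nm]]
    if (!is.null(o$volume))
      ind$organs$volume[i] <- parse_quantity(o$volume, "volume")
    if (!is.null(o$blood_flow))
      ind$organs$blood_flow[i] <- parse_quantity(o$blood_flow, "flow")
  }
  for (enz in names(cfg$expression)) {
    .check_enzyme(enz, allow_unspecific = FALSE)
    for (org in names(cfg$expression[[enz]])) {
      if (is.null(ind$expression[[enz]])) ind$expression[[enz]] <- numeric(0)
      ind$expression[[enz]][[org]] <-
        parse_quantity(cfg$expression[[enz]][[org]], "amount")
    }
  }
  validate_individual(ind)
}
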