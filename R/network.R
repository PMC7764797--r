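# DDI network orchestration: trial specification, victim-alone vs
# victim-plus-perpetrator runs across CYP phenotypes, qualification against
# observed ratio tables, and competing-mechanism comparison.
#
# Racemates are represented as lists of co-dosed enantiomer drugs (each at
# half the racemate dose, with mutual inhibition entries); the victim plasma
# profile is then the sum of the enantiomer concentrations.

#' Specify a DDI/DGI trial
#'
#' @param name Trial label.
#' @param victim A [drug()] or list of co-dosed drugs (e.g. two enantiomers of
#'   a racemate).
#' @param victim_regimen A [dosing_regimen()] or list matching `victim`.
#' @param perpetrator Optional [drug()] or list (NULL for victim-alone /
#'   DGI-only trials).
#' @param perp_regimen Regimen(s) for the perpetrator.
#' @param phenotypes List of [phenotype()] applied to the individual in every
#'   arm (e.g. `list(phenotype("CYP2C19", 0))` for a PM).
#' @param t_end Simulation end (min).
#' @param interval Optional endpoint interval `c(t0, t1)` (min). Use the
#'   steady-state victim dosing interval for multiple-dose designs; NULL
#'   means the whole simulated span.
#' @param extrapolate Extrapolate AUC to infinity (single-dose designs).
#' @param sampling Optional sparse clinical sampling times (min) used by the
#'   synthetic-data generator; must cover `interval` if both are given.
#' @param n_grid Output grid resolution.
#' @return Object of class `trial_spec`.
#' @export
trial_spec <- function(name, victim, victim_regimen, perpetrator = NULL,
                       perp_regimen = NULL, phenotypes = list(),
                       t_end, interval = NULL, extrapolate = FALSE,
                       sampling = NULL, n_grid = 481) {
  as_list <- function(x, cls) {
    if (is.null(x)) return(list())
    if (inherits(x, cls)) list(x) else x
  }
  victims <- as_list(victim, "pbpk_drug")
  vregs <- as_list(victim_regimen, "pbpk_regimen")
  perps <- as_list(perpetrator, "pbpk_drug")
  pregs <- as_list(perp_regimen, "pbpk_regimen")
  stopifnot(length(victims) >= 1, length(vregs) == length(victims),
            length(pregs) == length(perps))
  if (!is.null(interval)) {
    stopifnot(length(interval) == 2, interval[1] < interval[2],
              interval[2] <= t_end)
    if (!is.null(sampling) &&
        (min(sampling) > interval[1] || max(sampling) < interval[2]))
      stop("sampling schedule does not cover the endpoint interval")
  }
  structure(list(name = name, victims = victims, victim_regimens = vregs,
                 perpetrators = perps, perp_regimens = pregs,
                 phenotypes = phenotypes, t_end = t_end, interval = interval,
                 extrapolate = extrapolate, sampling = sampling,
                 n_grid = n_grid),
            class = "trial_spec")
}

#' Default trial library (physiology + solver)
#'
#' @param individual Base individual; arms of one trial always share it.
#' @param solver Solver settings for trial simulations.
#' @return List passed as `library` to [run_trial()] and friends.
#' @export
trial_library <- function(individual = default_individual(),
                          solver = solver_settings()) {
  list(individual = individual, solver = solver)
}

# combined victim plasma (sums enantiomers of a racemate)
.victim_plasma <- function(result, victims) {
  nm <- vapply(victims, `[[`, character(1), "name")
  rowSums(result$plasma[, nm, drop = FALSE])
}

#' Run one trial: victim alone vs victim plus perpetrator
#'
#' Both arms share the same phenotype-adjusted individual; the victim-alone
#' arm omits the perpetrator entirely. Victim metrics are computed on the
#' (summed, for racemates) venous plasma profile over the declared endpoint
#' interval. If the perpetrator carries no inhibition entry targeting any
#' enzyme of a victim pathway, a warning is raised (the ratio will be 1).
#'
#' @param spec A [trial_spec()].
#' @param library A [trial_library()].
#' @return List of class `trial_result`: `result_alone`, `result_combo`
#'   (NULL without perpetrator), `metrics_alone`, `metrics_combo`, `ratios`
#'   ([ddi_ratios()]; NULL without perpetrator).
#' @export
run_trial <- function(spec, library = trial_library()) {
  stopifnot(inherits(spec, "trial_spec"))
  ind <- library$individual
  for (ph in spec$phenotypes) ind <- apply_phenotype(ind, ph)
  solver <- library$solver %||% solver_settings()
  grid <- seq(0, spec$t_end, length.out = spec$n_grid)

  sys_alone <- assemble(ind, spec$victims, spec$victim_regimens,
                        solver = solver)
  res_alone <- simulate_pbpk(sys_alone, spec$t_end, grid)
  prof_alone <- .victim_plasma(res_alone, spec$victims)
  m_alone <- compute_metrics(res_alone$time, prof_alone,
                             interval = spec$interval,
                             extrapolate = spec$extrapolate)

  if (!length(spec$perpetrators))
    return(structure(list(result_alone = res_alone, result_combo = NULL,
                          metrics_alone = m_alone, metrics_combo = NULL,
                          ratios = NULL, spec = spec),
                     class = "trial_result"))

  victim_enzymes <- unique(unlist(lapply(spec$victims, function(d)
    vapply(d$pathways, `[[`, character(1), "enzyme"))))
  perp_targets <- unique(unlist(lapply(spec$perpetrators, function(d)
    vapply(d$inhibitions, `[[`, character(1), "target_enzyme"))))
  if (!length(intersect(victim_enzymes, perp_targets)))
    warning("perpetrator carries no inhibition against any victim pathway; ",
            "DDI ratios will be 1")

  sys_combo <- assemble(ind, c(spec$victims, spec$perpetrators),
                        c(spec$victim_regimens, spec$perp_regimens),
                        solver = solver)
  res_combo <- simulate_pbpk(sys_combo, spec$t_end, grid)
  prof_combo <- .victim_plasma(res_combo, spec$victims)
  m_combo <- compute_metrics(res_combo$time, prof_combo,
                             interval = spec$interval,
                             extrapolate = spec$extrapolate)
  structure(list(result_alone = res_alone, result_combo = res_combo,
                 metrics_alone = m_alone, metrics_combo = m_combo,
                 ratios = ddi_ratios(m_alone, m_combo), spec = spec),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("<trial_result>", x$spec$name, "\n  victim AUC",
      signif(x$metrics_alone$auc, 5), "uM*min")
  if (!is.null(x$ratios))
    cat("; AUC_R", signif(x$ratios$auc_ratio, 4),
        "Cmax_R", signif(x$ratios$cmax_ratio, 4))
  cat("\n")
  invisible(x)
}

# ---- builtin qualification network -----------------------------------------

# replace the perpetrator's inhibitions on the enzymes covered by the
# pair-specific interaction-constant library entries
.with_pair_inhibitions <- function(perp, substrate) {
  entries <- ki_for_pair(perp$name, substrate)
  enzymes <- unique(vapply(entries, `[[`, character(1), "target_enzyme"))
  keep <- Filter(function(i) !i$target_enzyme %in% enzymes, perp$inhibitions)
  perp$inhibitions <- c(keep, entries)
  perp
}

#' Build the 11 built-in network qualification trials
#'
#' Reconstructs the qualification panel of the CYP2C19/CYP1A2 network: two
#' strong CYP2C19 pairs (fluvoxamine against omeprazole and S-mephenytoin),
#' three strong CYP1A2 pairs (fluvoxamine against caffeine, tizanidine,
#' mexiletine), two moderate CYP2C19 pairs (omeprazole-moclobemide and
#' moclobemide-omeprazole) and four moderate CYP1A2 pairs (mexiletine and
#' ethinylestradiol against caffeine and tizanidine). Omeprazole is dosed as
#' its two enantiomers at half the racemate dose each. Perpetrator inhibition
#' constants are taken pair-specifically from [builtin_ki_library()]; drug PK
#' parameters come from the bundled illustrative files.
#'
#' All trials share one design: the perpetrator is dosed to near steady state
#' for three days, the victim dose is given on day 3, and exposure is
#' measured over the following 24 h.
#'
#' Gut-wall CYP2C19 reduction (formulation-dependent, no default claim) is
#' applied by passing `scale_gut_expression(default_individual(), "CYP2C19",
#' factor)` into [trial_library()].
#'
#' @return Named list of [trial_spec()] objects with attributes `inhibitor`,
#'   `substrate`, `category` on each element.
#' @export
network_qualification_specs <- function() {
  get <- function(nm) load_builtin_drug(nm)
  omeprazole <- function(substrate = NULL) {
    s <- get("esomeprazole"); r <- get("r-omeprazole")
    if (!is.null(substrate)) {
      s <- .with_pair_inhibitions(s, substrate)
      r <- .with_pair_inhibitions(r, substrate)
    }
    list(s, r)
  }
  t_dose <- 2880          # victim dose on day 3 of perpetrator dosing
  t_end <- t_dose + 1440
  interval <- c(t_dose, t_end)
  perp_reg <- function(drg, dose, every = 720)
    dosing_regimen(drg, "oral", dose, times = seq(0, t_end - 1, by = every))
  vict_reg <- function(drg, dose) dosing_regimen(drg, "oral", dose, t_dose)

  mk <- function(name, category, victim, vreg, perp, preg) {
    sp <- trial_spec(name, victim, vreg, perp, preg,
                     t_end = t_end, interval = interval)
    attr(sp, "inhibitor") <- sub("-.*$", "", name)
    attr(sp, "substrate") <- sub("^[^-]*-", "", name)
    attr(sp, "category") <- category
    sp
  }
  fluvo <- function(substrate)
    .with_pair_inhibitions(get("fluvoxamine"), substrate)
  mexi <- function(substrate)
    .with_pair_inhibitions(get("mexiletine"), substrate)
  ee <- function(substrate)
    .with_pair_inhibitions(get("ethinylestradiol"), substrate)
  moclo_p <- .with_pair_inhibitions(get("moclobemide"), "omeprazole")

  caffeine <- get("caffeine"); tizanidine <- get("tizanidine")
  mexiletine_v <- get("mexiletine"); moclobemide_v <- get("moclobemide")
  smeph <- get("s-mephenytoin")
  ome_v <- omeprazole(); ome_p <- omeprazole("moclobemide")
  half <- function(drgs, dose_mg)
    lapply(drgs, function(d) dosing_regimen(d$name, "oral",
      paste(dose_mg / 2, "mg"), t_dose))

  specs <- list(
    mk("fluvoxamine-omeprazole", "strong CYP2C19",
       ome_v, half(ome_v, 40),
       fluvo("omeprazole"), perp_reg("fluvoxamine", "50 mg")),
    mk("fluvoxamine-s-mephenytoin", "strong CYP2C19",
       smeph, vict_reg("s-mephenytoin", "100 mg"),
       fluvo("s-mephenytoin"), perp_reg("fluvoxamine", "50 mg")),
    mk("fluvoxamine-caffeine", "strong CYP1A2",
       caffeine, vict_reg("caffeine", "150 mg"),
       fluvo("caffeine"), perp_reg("fluvoxamine", "50 mg")),
    mk("fluvoxamine-tizanidine", "strong CYP1A2",
       tizanidine, vict_reg("tizanidine", "4 mg"),
       fluvo("tizanidine"), perp_reg("fluvoxamine", "50 mg")),
    mk("fluvoxamine-mexiletine", "strong CYP1A2",
       mexiletine_v, vict_reg("mexiletine", "200 mg"),
       fluvo("mexiletine"), perp_reg("fluvoxamine", "50 mg")),
    mk("omeprazole-moclobemide", "moderate CYP2C19",
       moclobemide_v, vict_reg("moclobemide", "300 mg"),
       ome_p, c(lapply(ome_p, function(d)
         dosing_regimen(d$name, "oral", "20 mg",
                        times = seq(0, t_end - 1, by = 1440))))),
    mk("moclobemide-omeprazole", "moderate CYP2C19",
       ome_v, half(ome_v, 40),
       moclo_p, perp_reg("moclobemide", "300 mg")),
    mk("mexiletine-caffeine", "moderate CYP1A2",
       caffeine, vict_reg("caffeine", "150 mg"),
       mexi("caffeine"), perp_reg("mexiletine", "200 mg")),
    mk("mexiletine-tizanidine", "moderate CYP1A2",
       tizanidine, vict_reg("tizanidine", "4 mg"),
       mexi("tizanidine"), perp_reg("mexiletine", "200 mg")),
    mk("ethinylestradiol-caffeine", "moderate CYP1A2",
       caffeine, vict_reg("caffeine", "150 mg"),
       ee("caffeine"), perp_reg("ethinylestradiol", "0.035 mg",
                                every = 1440)),
    mk("ethinylestradiol-tizanidine", "moderate CYP1A2",
       tizanidine, vict_reg("tizanidine", "4 mg"),
       ee("tizanidine"), perp_reg("ethinylestradiol", "0.035 mg",
                                  every = 1440))
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Qualify the DDI network against observed ratios
#'
#' Runs every trial and reports predicted AUC/Cmax ratios; when an observed
#' ratio table is supplied, predicted/observed ratios and two-fold acceptance
#' flags are added, with overall pass defined as all pairs within two-fold.
#' Pairs missing from the observed table are recorded as "prediction-only".
#'
#' @param specs List of [trial_spec()]s, e.g. [network_qualification_specs()].
#' @param observed Optional data.frame with columns `name`, `auc_ratio`,
#'   `cmax_ratio`.
#' @param library A [trial_library()].
#' @return Object of class `qualification_report`: data.frame (one row per
#'   pair) with predicted ratios, observed ratios, pred/obs, flags, category;
#'   attribute `pass`.
#' @export
qualify_network <- function(specs, observed = NULL,
                            library = trial_library()) {
  rows <- lapply(specs, function(sp) {
    tr <- run_trial(sp, library)
    row <- data.frame(
      name = sp$name,
      inhibitor = attr(sp, "inhibitor") %||% NA_character_,
      substrate = attr(sp, "substrate") %||% NA_character_,
      category = attr(sp, "category") %||% NA_character_,
      pred_auc_ratio = tr$ratios$auc_ratio,
      pred_cmax_ratio = tr$ratios$cmax_ratio,
      obs_auc_ratio = NA_real_, obs_cmax_ratio = NA_real_,
      pred_obs_auc = NA_real_, pred_obs_cmax = NA_real_,
      within_2fold = NA, status = "prediction-only",
      stringsAsFactors = FALSE
    )
    if (!is.null(observed) && sp$name %in% observed$name) {
      o <- observed[observed$name == sp$name, ][1, ]
      po <- pred_obs_ratio(tr$ratios,
                           structure(list(auc_ratio = o$auc_ratio,
                                          cmax_ratio = o$cmax_ratio),
                                     class = "ddi_ratios"))
      row$obs_auc_ratio <- o$auc_ratio
      row$obs_cmax_ratio <- o$cmax_ratio
      row$pred_obs_auc <- po$auc
      row$pred_obs_cmax <- po$cmax
      row$within_2fold <- po$auc_within_2fold && po$cmax_within_2fold
      row$status <- "compared"
    }
    row
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  compared <- report$status == "compared"
  attr(report, "pass") <- if (any(compared)) all(report$within_2fold[compared])
  else NA
  class(report) <- c("qualification_report", class(report))
  report
}

#' @export
print.qualification_report <- function(x, ...) {
  cat("<qualification_report>", nrow(x), "pair(s); overall pass:",
      format(attr(x, "pass")), "\n")
  print.data.frame(x[, c("name", "category", "pred_auc_ratio",
                         "obs_auc_ratio", "pred_obs_auc", "within_2fold")],
                   digits = 4)
  invisible(x)
}

#' Compare competing mechanistic hypotheses for one trial
#'
#' Each variant is a candidate set of perpetrator inhibition entries (e.g.
#' competitive-only vs competitive + TDI, or TDI with k_inact 100 vs
#' 200 1/min). Every variant is simulated and ranked by
#' `|log(predicted AUC_R / observed AUC_R)|`; the full ranked table is
#' returned so that near-ties can be reported alongside the winner, and ties
#' keep their input order.
#'
#' @param spec A [trial_spec()] with a perpetrator.
#' @param variants Named list; each element a list of [inhibition()] objects
#'   substituted for the perpetrator's inhibitions.
#' @param observed_auc_ratio Observed (or synthetic-truth) victim AUC ratio.
#' @param library A [trial_library()].
#' @return data.frame ranked by fit: `variant`, `auc_ratio`, `cmax_ratio`,
#'   `abs_log_error`, `rank`.
#' @export
compare_mechanisms <- function(spec, variants, observed_auc_ratio,
                               library = trial_library()) {
  stopifnot(inherits(spec, "trial_spec"), length(variants) >= 2,
            length(spec$perpetrators) >= 1, observed_auc_ratio > 0)
  if (is.null(names(variants)))
    names(variants) <- paste0("variant", seq_along(variants))
  rows <- lapply(seq_along(variants), function(i) {
    sp <- spec
    sp$perpetrators[[1]]$inhibitions <- variants[[i]]
    tr <- run_trial(sp, library)
    data.frame(variant = names(variants)[i],
               auc_ratio = tr$ratios$auc_ratio,
               cmax_ratio = tr$ratios$cmax_ratio,
               abs_log_error = abs(log(tr$ratios$auc_ratio /
                                         observed_auc_ratio)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$abs_log_error), , drop = FALSE]  # stable for ties
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# ---- parameter handles (used by trial-level sensitivity) -------------------

# handle grammar:
#   victim/fu                      victim/kp:default
#   victim/pathway:CYP1A2/cl_int   victim/absorption/ka
#   perpetrator/inhibition:CYP1A2:competitive/ki
#   regimen:victim/dose            regimen:perpetrator/dose
#   individual/organ:liver/volume  individual/organ:liver/blood_flow
.handle_access <- function(spec, library, handle, value = NULL) {
  set <- !is.null(value)
  parts <- strsplit(handle, "/", fixed = TRUE)[[1]]
  get_drug <- function(role) {
    if (role == "victim") spec$victims[[1]] else spec$perpetrators[[1]]
  }
  put_drug <- function(role, d) {
    if (role == "victim") spec$victims[[1]] <- d
    else spec$perpetrators[[1]] <- d
    spec
  }
  head <- parts[1]
  if (head %in% c("victim", "perpetrator")) {
    d <- get_drug(head)
    if (is.null(d)) stop("trial has no ", head)
    p2 <- parts[2]
    if (p2 %in% c("fu", "blood_plasma_ratio", "molecular_weight")) {
      if (!set) return(d[[p2]])
      d[[p2]] <- value
    } else if (startsWith(p2, "kp:")) {
      tissue <- sub("^kp:", "", p2)
      if (!set) return(d$kp_map[[tissue]])
      d$kp_map[[tissue]] <- value
    } else if (startsWith(p2, "pathway:")) {
      enz <- sub("^pathway:", "", p2)
      k <- which(vapply(d$pathways, `[[`, character(1), "enzyme") == enz)
      if (!length(k)) stop("no pathway for enzyme ", enz)
      if (!set) return(d$pathways[[k]][[parts[3]]])
      d$pathways[[k]][[parts[3]]] <- value
    } else if (startsWith(p2, "inhibition:")) {
      key <- strsplit(sub("^inhibition:", "", p2), ":", fixed = TRUE)[[1]]
      k <- which(vapply(d$inhibitions, function(i)
        i$target_enzyme == key[1] && i$mechanism == key[2], logical(1)))
      if (!length(k)) stop("no ", key[2], " inhibition of ", key[1])
      if (!set) return(d$inhibitions[[k[1]]][[parts[3]]])
      d$inhibitions[[k[1]]][[parts[3]]] <- value
    } else if (p2 == "absorption") {
      if (!set) return(d$absorption[[parts[3]]])
      d$absorption[[parts[3]]] <- value
    } else stop("unknown handle component: ", p2)
    return(put_drug(head, d))
  }
  if (startsWith(head, "regimen:")) {
    role <- sub("^regimen:", "", head)
    regs <- if (role == "victim") "victim_regimens" else "perp_regimens"
    if (!length(spec[[regs]])) stop("trial has no ", role, " regimen")
    if (!set) {
      r <- spec[[regs]][[1]]
      return(if (!is.na(r$dose)) r$dose else r$dose_mg)
    }
    for (i in seq_along(spec[[regs]])) {
      if (!is.na(spec[[regs]][[i]]$dose)) spec[[regs]][[i]]$dose <- value
      else spec[[regs]][[i]]$dose_mg <- value
    }
    return(spec)
  }
  if (head == "individual") {
    ind <- library$individual
    if (startsWith(parts[2], "organ:")) {
      organ <- sub("^organ:", "", parts[2])
      i <- match(organ, ind$organs$name)
      if (is.na(i)) stop("unknown organ ", organ)
      if (!set) return(ind$organs[[parts[3]]][i])
      ind$organs[[parts[3]]][i] <- value
      if (parts[3] == "blood_flow") {
        # preserve the flow balance: cardiac output follows the systemic sum
        flow <- function(nm) ind$organs$blood_flow[ind$organs$name == nm]
        ha <- flow("liver") - flow("gut") - flow("spleen")
        systemic <- setdiff(ind$organs$name, c("lung", "liver"))
        co <- ha + sum(ind$organs$blood_flow[ind$organs$name %in% systemic])
        ind$cardiac_output <- co
        ind$organs$blood_flow[ind$organs$name == "lung"] <- co
      }
      library$individual <- validate_individual(ind)
      return(library)
    }
    stop("unknown handle component: ", parts[2])
  }
  stop("unknown handle: ", handle)
}

#' Read a parameter value through its handle
#' @param spec A [trial_spec()].
#' @param library A [trial_library()].
#' @param handle Handle string, e.g. `"victim/fu"`,
#'   `"victim/pathway:CYP1A2/cl_int"`, `"regimen:victim/dose"`,
#'   `"individual/organ:liver/blood_flow"`.
#' @return Numeric value (canonical units).
#' @export
get_trial_parameter <- function(spec, library, handle)
  .handle_access(spec, library, handle)

#' Default sensitivity-parameter whitelist for a trial
#'
#' Enumerates the tunable, non-structural inputs of the trial's first victim
#' (fu, blood:plasma ratio, Kp entries, pathway rate constants, absorption),
#' the perpetrator's inhibition constants, the victim dose, and liver volume
#' and blood flow. Structural parameters (state layout, topology) are
#' excluded.
#'
#' @param spec A [trial_spec()].
#' @param library A [trial_library()].
#' @return Named numeric vector handle -> baseline value.
#' @export
default_sensitivity_parameters <- function(spec, library = trial_library()) {
  h <- character(0)
  d <- spec$victims[[1]]
  h <- c(h, "victim/fu", "victim/blood_plasma_ratio")
  h <- c(h, paste0("victim/kp:", names(d$kp_map)))
  for (pw in d$pathways) {
    pars <- setdiff(names(pw), c("enzyme", "kinetics"))
    h <- c(h, paste0("victim/pathway:", pw$enzyme, "/", pars))
  }
  if (!is.null(d$absorption))
    h <- c(h, "victim/absorption/ka", "victim/absorption/f_abs")
  h <- c(h, "regimen:victim/dose")
  if (length(spec$perpetrators)) {
    p <- spec$perpetrators[[1]]
    for (i in p$inhibitions) {
      pars <- intersect(names(i), c("ki", "k_i_tdi", "k_inact"))
      h <- c(h, paste0("perpetrator/inhibition:", i$target_enzyme, ":",
                       i$mechanism, "/", pars))
    }
  }
  h <- c(h, "individual/organ:liver/volume", "individual/organ:liver/blood_flow")
  vals <- vapply(h, function(hh) get_trial_parameter(spec, library, hh),
                 numeric(1))
  names(vals) <- h
  vals
}

#' Sensitivity of trial endpoints to model inputs
#'
#' Runs the trial's victim arm (with perpetrator, if present) once per
#' perturbation of each whitelisted parameter and assembles a
#' [sensitivity_table()] for the victim's AUC and Cmax.
#'
#' @param spec A [trial_spec()].
#' @param library A [trial_library()].
#' @param parameters Named numeric vector handle -> baseline value; default
#'   [default_sensitivity_parameters()].
#' @param endpoints `"auc"`, `"cmax"` or both.
#' @param deltas Relative perturbations.
#' @return A [sensitivity_table()].
#' @export
trial_sensitivity <- function(spec, library = trial_library(),
                              parameters = NULL,
                              endpoints = c("auc", "cmax"),
                              deltas = c(-0.1, -0.05, 0.05, 0.1)) {
  if (is.null(parameters))
    parameters <- default_sensitivity_parameters(spec, library)
  runner <- function(handle, value) {
    sp <- spec; lib <- library
    if (!is.na(value)) {
      mod <- .handle_access(sp, lib, handle, value)
      if (inherits(mod, "trial_spec")) sp <- mod else lib <- mod
    }
    tr <- run_trial(sp, lib)
    m <- if (!is.null(tr$metrics_combo)) tr$metrics_combo else tr$metrics_alone
    c(auc = m$auc, cmax = m$cmax)
  }
  sensitivity_table(runner, parameters, endpoints, deltas)
}
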