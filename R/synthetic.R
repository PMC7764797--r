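# Synthetic "observed" clinical datasets with the statistical structure the
# analysis assumes: sparse sampling (6-16 timepoints), multiplicative
# (log-normal) residual error, log-normal inter-individual variability and
# LLOQ censoring - plus least-squares parameter recovery on log
# concentrations.

#' Define a noise model for synthetic observations
#'
#' @param prop_cv Proportional residual coefficient of variation (log-normal
#'   multiplicative error), e.g. 0.2.
#' @param lloq Assay lower limit of quantification, µM; observations below it
#'   are reported at `lloq` and flagged BLQ.
#' @param iiv_cv Inter-individual log-normal CV applied as a per-subject
#'   profile scale factor (emulating clearance/volume variability).
#' @param seed Integer seed; fixed per dataset so identical seeds give
#'   identical datasets.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(prop_cv = 0.2, lloq = 0, iiv_cv = 0.3, seed = 1L) {
  stopifnot(prop_cv >= 0, iiv_cv >= 0, lloq >= 0, is.finite(seed))
  structure(list(prop_cv = prop_cv, lloq = lloq, iiv_cv = iiv_cv,
                 seed = as.integer(seed)), class = "noise_model")
}

# log-normal sdlog for a given CV
.sdlog <- function(cv) sqrt(log(1 + cv^2))

# run code with a private, seeded RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic observed dataset from a simulation
#'
#' Per subject, the model-predicted plasma profile is scaled by a log-normal
#' inter-individual factor, sampled at the sparse clinical schedule,
#' perturbed by multiplicative residual error, and censored at the LLOQ
#' (BLQ rows carry the LLOQ value and a flag). Reproducible given the noise
#' model's seed; the generating truth is attached as metadata.
#'
#' @param result A `pbpk_result`.
#' @param schedule Sparse sampling times (min), within the simulated span.
#' @param noise A [noise_model()].
#' @param n_subjects Number of subjects.
#' @param drug Drug whose plasma profile is observed (default first).
#' @param study,arm Labels stored on every row.
#' @return Object of class `observed_dataset`: data.frame with columns
#'   `study`, `arm`, `subject`, `time`, `conc`, `blq`; attributes
#'   `noise` and `truth` (list of generation metadata).
#' @export
generate_observed <- function(result, schedule, noise = noise_model(),
                              n_subjects = 12, drug = result$drugs[1],
                              study = "synthetic", arm = "arm1") {
  stopifnot(inherits(result, "pbpk_result"), inherits(noise, "noise_model"),
            n_subjects >= 1)
  schedule <- sort(as.numeric(schedule))
  if (min(schedule) < min(result$time) || max(schedule) > max(result$time))
    stop("sampling schedule outside simulated span [",
         min(result$time), ", ", max(result$time), "]")
  prof <- plasma_profile(result, drug)
  pred <- stats::approx(prof$time, prof$conc, xout = schedule)$y
  rows <- .with_seed(noise$seed, {
    do.call(rbind, lapply(seq_len(n_subjects), function(s) {
      scale <- if (noise$iiv_cv > 0)
        exp(stats::rnorm(1, 0, .sdlog(noise$iiv_cv))) else 1
      eps <- if (noise$prop_cv > 0)
        exp(stats::rnorm(length(schedule), 0, .sdlog(noise$prop_cv)))
      else rep(1, length(schedule))
      conc <- pred * scale * eps
      blq <- conc < noise$lloq
      conc[blq] <- noise$lloq
      data.frame(study = study, arm = arm, subject = s, time = schedule,
                 conc = conc, blq = blq, stringsAsFactors = FALSE)
    }))
  })
  rownames(rows) <- NULL
  structure(rows, class = c("observed_dataset", "data.frame"),
            noise = noise,
            truth = list(drug = drug, pred = pred, schedule = schedule,
                         n_subjects = n_subjects))
}

#' Write an observed dataset with its truth sidecar
#'
#' Long-format CSV plus a JSON sidecar holding the true generation
#' parameters, for recovery scoring.
#'
#' @param obs An `observed_dataset`.
#' @param csv_path Output CSV path.
#' @param truth_path Optional JSON sidecar path.
#' @param truth Optional named list of true parameter values to record in
#'   addition to the generation metadata.
#' @return `csv_path`, invisibly.
#' @export
write_observed_csv <- function(obs, csv_path, truth_path = NULL,
                               truth = NULL) {
  utils::write.csv(as.data.frame(obs), csv_path, row.names = FALSE)
  if (!is.null(truth_path)) {
    meta <- attr(obs, "truth")
    meta$pred <- NULL
    meta$true_parameters <- truth
    meta$noise <- unclass(attr(obs, "noise"))
    jsonlite::write_json(meta, truth_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(csv_path)
}

#' Synthetic observed DDI ratio table for network qualification
#'
#' Runs each trial and perturbs the true predicted ratios with log-normal
#' noise of the given CV, producing an observed table in the shape
#' [qualify_network()] consumes. With the generating model and moderate
#' noise, all pairs are expected to fall within two-fold of their own truth.
#'
#' @param specs List of [trial_spec()]s.
#' @param library A [trial_library()].
#' @param cv Log-normal CV applied to each true ratio.
#' @param seed Integer seed.
#' @return data.frame with `name`, `auc_ratio`, `cmax_ratio`.
#' @export
synthetic_observed_ratios <- function(specs, library = trial_library(),
                                      cv = 0.2, seed = 1L) {
  preds <- lapply(specs, function(sp) run_trial(sp, library)$ratios)
  .with_seed(seed, {
    data.frame(
      name = vapply(specs, `[[`, character(1), "name"),
      auc_ratio = vapply(preds, `[[`, numeric(1), "auc_ratio") *
        exp(stats::rnorm(length(preds), 0, .sdlog(cv))),
      cmax_ratio = vapply(preds, `[[`, numeric(1), "cmax_ratio") *
        exp(stats::rnorm(length(preds), 0, .sdlog(cv))),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
}

#' Synthetic caffeine dataset with protocol non-compliance
#'
#' Emulates study subjects who do not refrain completely from
#' caffeine-containing beverages: a constant exogenous background intake
#' (zero-order input into venous blood) runs over the whole study window, so
#' pre-dose concentrations are non-zero, and the study dose is given on top
#' at `t_dose`. The background rate is recoverable from the pre-dose samples
#' by [fit_parameters()].
#'
#' @param d A [drug()] tagged `"dietary"` (e.g. the bundled caffeine).
#' @param dose_regimen The study [dosing_regimen()] for the drug.
#' @param background_rate Constant intake rate, µmol/min (0 = full
#'   compliance).
#' @param t_end Simulation end (min).
#' @param schedule Sampling times (min); include pre-dose times to expose the
#'   elevated trough.
#' @param noise A [noise_model()].
#' @param n_subjects Number of subjects.
#' @param individual Physiology; default [default_individual()].
#' @param solver Optional [solver_settings()].
#' @return An `observed_dataset`; the truth metadata records
#'   `background_rate`.
#' @export
generate_noncompliance_caffeine <- function(d, dose_regimen, background_rate,
                                            t_end, schedule,
                                            noise = noise_model(),
                                            n_subjects = 12,
                                            individual = default_individual(),
                                            solver = NULL) {
  stopifnot(inherits(d, "pbpk_drug"))
  if (!"dietary" %in% d$tags)
    stop("drug '", d$name, "' is not flagged dietary; background intake ",
         "applies to dietary compounds only")
  if (background_rate < 0) stop("background_rate must be >= 0")
  res <- .simulate_with_background(d, dose_regimen, background_rate, t_end,
                                   individual, solver)
  obs <- generate_observed(res, schedule, noise, n_subjects, drug = d$name,
                           study = "noncompliance", arm = "dosed")
  tr <- attr(obs, "truth")
  tr$background_rate <- background_rate
  attr(obs, "truth") <- tr
  obs
}

.simulate_with_background <- function(d, dose_regimen, background_rate,
                                      t_end, individual, solver = NULL) {
  regs <- list(dose_regimen)
  if (background_rate > 0)
    regs <- c(regs, list(dosing_regimen(d$name, "iv_infusion",
                                        dose = background_rate * t_end,
                                        times = 0,
                                        infusion_duration = t_end)))
  sys <- assemble(individual, list(d), regs,
                  solver = solver %||% solver_settings())
  simulate_pbpk(sys, t_end)
}

# ---- least-squares parameter recovery --------------------------------------

#' Fit model parameters to an observed dataset
#'
#' Bounded derivative-based least squares (Levenberg-Marquardt) on log
#' concentrations, excluding BLQ rows. Three multi-starts are used: the
#' supplied start and the geometric means of the start with each bound; the
#' best final objective wins, ties resolved by objective then by
#' parameter-name order of the estimates. Approximate standard errors and
#' pairwise correlations come from the Jacobian at the optimum; a singular
#' Jacobian flags the fit non-identifiable with NA correlations.
#'
#' @param observed An `observed_dataset` (or data.frame with `time`, `conc`,
#'   `blq`).
#' @param predict_fn Function taking a named parameter vector and returning
#'   the predicted concentration for every row of `observed`.
#' @param start Named numeric vector of starting values (>= 1 parameter).
#' @param lower,upper Named bounds, finite, same names as `start`.
#' @return Object of class `fit_result`: `estimates`, `se`, `correlation`,
#'   `objective` (residual sum of squares on the log scale), `residual_sd`,
#'   `non_identifiable` flag, `n_obs`, `starts` (per-start objectives).
#' @export
fit_parameters <- function(observed, predict_fn, start, lower, upper) {
  stopifnot(length(start) >= 1, !is.null(names(start)),
            all(names(lower) == names(start)),
            all(names(upper) == names(start)),
            all(is.finite(lower)), all(is.finite(upper)),
            all(lower > 0), all(lower < upper))
  obs <- as.data.frame(observed)
  keep <- !obs$blq & obs$conc > 0
  if (!any(keep)) stop("no quantifiable observations to fit")
  logobs <- log(obs$conc[keep])
  resid_fn <- function(p) {
    p <- stats::setNames(pmin(pmax(p, lower), upper), names(start))
    pred <- predict_fn(p)[keep]
    pred <- pmax(pred, 1e-12)
    log(pred) - logobs
  }
  starts <- list(
    start,
    stats::setNames(sqrt(lower * start), names(start)),
    stats::setNames(sqrt(upper * start), names(start))
  )
  fits <- lapply(starts, function(s) {
    try(minpack.lm::nls.lm(par = s, fn = resid_fn, lower = lower,
                           upper = upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 100, ftol = 1e-10, ptol = 1e-10)),
        silent = TRUE)
  })
  ok <- !vapply(fits, inherits, logical(1), "try-error")
  if (!any(ok)) stop("all optimizer starts failed")
  objs <- vapply(fits, function(f)
    if (inherits(f, "try-error")) Inf else f$deviance, numeric(1))
  # ties: lowest objective, then parameter-name-ordered estimate vector
  best_i <- order(objs, vapply(fits, function(f)
    if (inherits(f, "try-error")) Inf
    else sum(unlist(f$par)[order(names(start))]), numeric(1)))[1]
  best <- fits[[best_i]]
  est <- stats::setNames(as.numeric(best$par), names(start))
  n_obs <- sum(keep)
  p <- length(start)
  dof <- max(n_obs - p, 1)
  sigma2 <- best$deviance / dof
  J <- best$hessian   # nls.lm stores J'J in $hessian
  se <- rep(NA_real_, p); names(se) <- names(start)
  corr <- matrix(NA_real_, p, p, dimnames = list(names(start), names(start)))
  non_id <- FALSE
  covm <- try(solve(J) * sigma2, silent = TRUE)
  if (inherits(covm, "try-error") || any(!is.finite(diag(covm))) ||
      any(diag(covm) < 0)) {
    non_id <- TRUE
  } else {
    se <- sqrt(diag(covm))
    denom <- outer(se, se)
    corr <- covm / denom
    diag(corr) <- 1
    if (p > 1 && any(abs(corr[upper.tri(corr)]) > 0.999)) non_id <- TRUE
  }
  structure(list(estimates = est, se = se, correlation = corr,
                 objective = best$deviance,
                 residual_sd = sqrt(sigma2),
                 non_identifiable = non_id, n_obs = n_obs,
                 starts = objs),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$n_obs, "observations; objective",
      signif(x$objective, 5),
      if (x$non_identifiable) "(NON-IDENTIFIABLE)" else "", "\n")
  print(data.frame(estimate = x$estimates, se = x$se))
  invisible(x)
}

#' Build a predictor for fitting trial parameters to observed data
#'
#' Returns a `predict_fn` for [fit_parameters()]: given a named vector of
#' parameter-handle values (see [get_trial_parameter()] for the handle
#' grammar), it applies them to the trial, simulates the
#' victim-plus-perpetrator arm (or the victim-alone arm when the trial has no
#' perpetrator), and interpolates the victim plasma profile at the observed
#' times.
#'
#' @param spec A [trial_spec()].
#' @param library A [trial_library()].
#' @param observed_times Times (min) of the observed rows, in row order.
#' @return Function mapping a named parameter vector to predicted
#'   concentrations (µM).
#' @export
trial_predict_fn <- function(spec, library = trial_library(),
                             observed_times) {
  force(observed_times)
  function(params) {
    sp <- spec; lib <- library
    for (h in names(params)) {
      mod <- .handle_access(sp, lib, h, params[[h]])
      if (inherits(mod, "trial_spec")) sp <- mod else lib <- mod
    }
    ind <- lib$individual
    for (ph in sp$phenotypes) ind <- apply_phenotype(ind, ph)
    drugs <- c(sp$victims, sp$perpetrators)
    regs <- c(sp$victim_regimens, sp$perp_regimens)
    sys <- assemble(ind, drugs, regs,
                    solver = lib$solver %||% solver_settings())
    res <- simulate_pbpk(sys, sp$t_end,
                         seq(0, sp$t_end, length.out = sp$n_grid))
    prof <- .victim_plasma(res, sp$victims)
    stats::approx(res$time, prof, xout = observed_times)$y
  }
}
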