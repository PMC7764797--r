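# Local sensitivity analysis: relative sensitivity coefficients averaged over
# several perturbation sizes, and cumulative ranking of influential inputs.

#' Relative sensitivity coefficient of an endpoint to one parameter
#'
#' For each relative perturbation Delta_k, the model is re-run at
#' `p * (1 + Delta_k)` and the coefficient
#' `S_k = ((PK(p(1+Delta_k)) - PK(p)) / PK(p)) / Delta_k`
#' is formed; the reported coefficient is the arithmetic mean over k
#' (averaging over symmetric +/-Delta cancels the leading curvature bias).
#' For a power-law response `PK = c * p^m`, S converges to m as the
#' perturbations shrink.
#'
#' Parameters with a zero baseline value are skipped: the function returns
#' `NA` with a warning, mirroring the rule that relative sensitivities are
#' undefined at 0.
#'
#' @param fn Function mapping a parameter value to a scalar endpoint (it is
#'   called once at `base` and once per perturbation).
#' @param base Baseline parameter value.
#' @param deltas Nonzero relative perturbations; default
#'   `c(-0.1, -0.05, 0.05, 0.1)`.
#' @return List of class `sensitivity_coefficient`: `S` (mean), `per_delta`
#'   (named per-perturbation coefficients), `n`.
#' @export
sensitivity_coefficient <- function(fn, base,
                                    deltas = c(-0.1, -0.05, 0.05, 0.1)) {
  if (!length(deltas) || any(deltas == 0)) stop("deltas must be nonzero")
  if (base == 0) {
    warning("baseline parameter value is 0; sensitivity not calculated")
    return(structure(list(S = NA_real_, per_delta = NULL, n = 0L),
                     class = "sensitivity_coefficient"))
  }
  pk0 <- fn(base)
  if (!is.finite(pk0) || pk0 == 0)
    stop("baseline endpoint is zero or non-finite; relative change undefined")
  per <- vapply(deltas, function(d) {
    pk <- fn(base * (1 + d))
    if (!is.finite(pk)) stop("model run failed at perturbation ", d)
    ((pk - pk0) / pk0) / d
  }, numeric(1))
  names(per) <- paste0("delta=", deltas)
  structure(list(S = mean(per), per_delta = per, n = length(per)),
            class = "sensitivity_coefficient")
}

#' @export
print.sensitivity_coefficient <- function(x, ...) {
  cat("<sensitivity_coefficient> S =", signif(x$S, 4), "over", x$n,
      "perturbation(s)\n")
  invisible(x)
}

#' Build a sensitivity table over parameters and endpoints
#'
#' @param runner Function `(parameter_name, value) -> named numeric endpoints`
#'   re-running the model with one input changed; called with `value = NA`
#'   for the baseline run.
#' @param parameters Named numeric vector of baseline parameter values.
#' @param endpoints Endpoint names to extract (e.g. `c("auc", "cmax")`).
#' @param deltas Relative perturbations, as in [sensitivity_coefficient()].
#' @return Object of class `sensitivity_table`: data.frame with columns
#'   `parameter`, `endpoint`, `S`, `n`, plus one column per perturbation.
#' @export
sensitivity_table <- function(runner, parameters,
                              endpoints = c("auc", "cmax"),
                              deltas = c(-0.1, -0.05, 0.05, 0.1)) {
  stopifnot(length(parameters) > 0, !is.null(names(parameters)))
  base_pk <- runner(NA_character_, NA_real_)
  rows <- list()
  for (p in names(parameters)) {
    pv <- parameters[[p]]
    if (pv == 0) {
      warning("parameter '", p, "' has baseline 0; skipped")
      next
    }
    per <- matrix(NA_real_, length(deltas), length(endpoints),
                  dimnames = list(NULL, endpoints))
    for (k in seq_along(deltas)) {
      pk <- runner(p, pv * (1 + deltas[k]))
      for (e in endpoints)
        per[k, e] <- ((pk[[e]] - base_pk[[e]]) / base_pk[[e]]) / deltas[k]
    }
    for (e in endpoints) {
      row <- data.frame(parameter = p, endpoint = e, S = mean(per[, e]),
                        n = length(deltas), stringsAsFactors = FALSE)
      for (k in seq_along(deltas))
        row[[paste0("S_delta_", deltas[k])]] <- per[k, e]
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("sensitivity_table", class(tab))
  tab
}

#' Rank parameters by cumulative absolute sensitivity
#'
#' Sorts |S| in decreasing order (ties broken by parameter name for
#' determinism) and returns the minimal prefix of parameters whose summed
#' |S| strictly exceeds `threshold` (default 90%) of the total summed |S|
#' for the endpoint, i.e. the parameters that together contribute (more
#' than) the threshold share; a prefix landing exactly on the threshold is
#' extended by one.
#'
#' @param table A [sensitivity_table()] (or data.frame with `parameter`,
#'   `endpoint`, `S`).
#' @param endpoint Endpoint to rank (must appear in the table).
#' @param threshold Cumulative share to cover, default 0.90.
#' @return data.frame of the selected rows with `rank` and
#'   `cumulative_share` columns; zero rows (with a warning) if all
#'   sensitivities are zero.
#' @export
rank_by_cumulative_sensitivity <- function(table, endpoint, threshold = 0.90) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  sub <- table[table$endpoint == endpoint & !is.na(table$S), , drop = FALSE]
  if (!nrow(sub)) stop("no rows for endpoint '", endpoint, "'")
  ord <- order(-abs(sub$S), sub$parameter)
  sub <- sub[ord, , drop = FALSE]
  total <- sum(abs(sub$S))
  if (total == 0) {
    warning("all sensitivities are zero; empty ranking")
    out <- sub[0, c("parameter", "endpoint", "S"), drop = FALSE]
    out$rank <- integer(0); out$cumulative_share <- numeric(0)
    return(out)
  }
  cum <- cumsum(abs(sub$S)) / total
  k <- which(cum > threshold + 1e-12)[1]
  if (is.na(k)) k <- nrow(sub)
  out <- sub[seq_len(k), c("parameter", "endpoint", "S"), drop = FALSE]
  out$rank <- seq_len(k)
  out$cumulative_share <- cum[seq_len(k)]
  rownames(out) <- NULL
  out
}

#' Write a sensitivity report CSV
#'
#' One row per (parameter, endpoint) with the averaged coefficient, rank and
#' cumulative share within its endpoint.
#'
#' @param table A [sensitivity_table()].
#' @param path Output CSV path.
#' @param threshold Cumulative threshold used to flag the influential subset.
#' @return The report data.frame, invisibly.
#' @export
write_sensitivity_report <- function(table, path, threshold = 0.90) {
  reports <- lapply(unique(table$endpoint), function(e) {
    sub <- table[table$endpoint == e & !is.na(table$S), , drop = FALSE]
    ord <- order(-abs(sub$S), sub$parameter)
    sub <- sub[ord, c("parameter", "endpoint", "S"), drop = FALSE]
    total <- sum(abs(sub$S))
    sub$rank <- seq_len(nrow(sub))
    sub$cumulative_share <- if (total > 0) cumsum(abs(sub$S)) / total else 0
    k <- which(sub$cumulative_share >= threshold)[1]
    if (is.na(k)) k <- nrow(sub)
    sub$in_top_share <- sub$rank <= k
    sub
  })
  rep <- do.call(rbind, reports)
  rownames(rep) <- NULL
  utils::write.csv(rep, path, row.names = FALSE)
  invisible(rep)
}
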