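# Non-compartmental PK endpoints and DDI exposure ratios.

#' Compute AUC, Cmax and Tmax from a concentration-time profile
#'
#' AUC uses the linear-up/log-down trapezoid: linear trapezoid where the
#' concentration is rising (or either endpoint is zero), logarithmic
#' trapezoid where it falls. With `extrapolate = TRUE` the terminal slope
#' lambda_z is estimated by log-linear regression of the final descending
#' points (at least 3, after Cmax) and `C_last / lambda_z` is added, giving
#' AUC(0, Inf). Tmax takes the first occurrence of the maximum.
#'
#' @param times Increasing sampling times (min), length >= 3.
#' @param conc Concentrations (µM), same length, >= 0.
#' @param interval Optional `c(t0, t1)` restricting the endpoint interval
#'   (profile is linearly interpolated at the interval bounds).
#' @param extrapolate Add the terminal log-linear extrapolation to infinity.
#' @return Object of class `pk_metrics`: `auc` (µM·min), `cmax` (µM), `tmax`
#'   (min), `interval`, `lambda_z` (1/min, NA unless extrapolated).
#' @export
compute_metrics <- function(times, conc, interval = NULL, extrapolate = FALSE) {
  times <- as.numeric(times); conc <- as.numeric(conc)
  if (length(times) < 3 || length(conc) != length(times))
    stop("need >= 3 matching (time, concentration) points")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  if (!is.null(interval)) {
    t0 <- interval[1]; t1 <- interval[2]
    if (t0 >= t1) stop("interval must satisfy t0 < t1")
    keep <- times >= t0 & times <= t1
    tt <- times[keep]; cc <- conc[keep]
    if (t0 < min(times) || t1 > max(times))
      stop("interval outside sampled range")
    if (!any(times == t0)) {
      tt <- c(t0, tt); cc <- c(stats::approx(times, conc, t0)$y, cc)
    }
    if (!any(times == t1)) {
      tt <- c(tt, t1); cc <- c(cc, stats::approx(times, conc, t1)$y)
    }
    times <- tt; conc <- cc
  } else interval <- c(times[1], times[length(times)])
  if (extrapolate && all(conc == 0))
    stop("cannot extrapolate an all-zero profile")

  n <- length(times)
  dt <- diff(times)
  c1 <- conc[-n]; c2 <- conc[-1]
  lin <- (c1 + c2) / 2 * dt
  logdown <- c1 > c2 & c2 > 0
  seg <- lin
  seg[logdown] <- (c1[logdown] - c2[logdown]) /
    log(c1[logdown] / c2[logdown]) * dt[logdown]
  auc <- sum(seg)
  imax <- which.max(conc)        # first occurrence tie-break
  cmax <- conc[imax]; tmax <- times[imax]
  lambda_z <- NA_real_
  if (extrapolate) {
    # final descending stretch after Cmax with positive concentrations
    cand <- which(seq_len(n) > imax & conc > 0)
    if (length(cand) >= 3) {
      use <- utils::tail(cand, max(3, min(length(cand), 6)))
      fit <- stats::lm(log(conc[use]) ~ times[use])
      lz <- -unname(stats::coef(fit)[2])
      if (is.finite(lz) && lz > 0) {
        lambda_z <- lz
        auc <- auc + conc[n] / lz
        interval <- c(interval[1], Inf)
      } else stop("terminal phase is not log-linearly declining")
    } else stop("need >= 3 positive descending terminal points to extrapolate")
  }
  structure(list(auc = auc, cmax = cmax, tmax = tmax, interval = interval,
                 lambda_z = lambda_z), class = "pk_metrics")
}

#' @export
print.pk_metrics <- function(x, ...) {
  cat("<pk_metrics> AUC", signif(x$auc, 5), "uM*min | Cmax",
      signif(x$cmax, 5), "uM | Tmax", x$tmax, "min | interval [",
      x$interval[1], ",", x$interval[2], "]\n")
  invisible(x)
}

#' DDI exposure ratios (victim with vs without perpetrator)
#'
#' @param victim_alone,victim_with_perp [compute_metrics()] results on
#'   matching intervals.
#' @return Object of class `ddi_ratios`: `auc_ratio`, `cmax_ratio`.
#' @export
ddi_ratios <- function(victim_alone, victim_with_perp) {
  stopifnot(inherits(victim_alone, "pk_metrics"),
            inherits(victim_with_perp, "pk_metrics"))
  if (!isTRUE(all.equal(victim_alone$interval, victim_with_perp$interval,
                        tolerance = 1e-9)))
    stop("endpoint intervals do not match: [",
         paste(victim_alone$interval, collapse = ", "), "] vs [",
         paste(victim_with_perp$interval, collapse = ", "), "]")
  if (victim_alone$auc <= 0 || victim_alone$cmax <= 0)
    stop("victim-alone exposure is zero; ratios undefined")
  structure(list(auc_ratio = victim_with_perp$auc / victim_alone$auc,
                 cmax_ratio = victim_with_perp$cmax / victim_alone$cmax),
            class = "ddi_ratios")
}

#' @export
print.ddi_ratios <- function(x, ...) {
  cat("<ddi_ratios> AUC_R", signif(x$auc_ratio, 4), "| Cmax_R",
      signif(x$cmax_ratio, 4), "\n")
  invisible(x)
}

#' Predicted/observed ratio with two-fold acceptance flags
#'
#' @param predicted,observed [ddi_ratios()] objects.
#' @return List: `auc` and `cmax` predicted/observed ratios, and
#'   `auc_within_2fold` / `cmax_within_2fold` flags (0.5 <= r <= 2).
#' @export
pred_obs_ratio <- function(predicted, observed) {
  stopifnot(inherits(predicted, "ddi_ratios"), inherits(observed, "ddi_ratios"))
  if (observed$auc_ratio == 0 || observed$cmax_ratio == 0)
    stop("observed ratios must be nonzero")
  r_auc <- predicted$auc_ratio / observed$auc_ratio
  r_cmax <- predicted$cmax_ratio / observed$cmax_ratio
  list(auc = r_auc, cmax = r_cmax,
       auc_within_2fold = r_auc >= 0.5 && r_auc <= 2,
       cmax_within_2fold = r_cmax >= 0.5 && r_cmax <= 2)
}
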