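#' Percent viability from optical densities
#'
#' MTT-style normalization: viability is the treated-well optical density as
#' a percentage of the untreated control.
#'
#' @param od_treated optical density of treated wells (vectorized).
#' @param od_control mean optical density of untreated control wells.
#' @return viability in percent.
#' @export
viability_percent <- function(od_treated, od_control) {
  if (any(od_control <= 0)) stop_validation("control OD must be positive")
  if (any(od_treated < 0)) stop_validation("treated OD must be nonnegative")
  100 * od_treated / od_control
}

fourpl_mean <- function(conc, top, bottom, hill, ic50) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `V(c) = bottom + (top - bottom) / (1 + (c/ic50)^hill)`
#' on the log10-concentration scale, the model behind IC50/CC50 estimation
#' in dose-response software. Initialization is multi-start over a grid of
#' hill slopes of both signs; the midpoint is parameterized as log10(ic50)
#' and bounded within two decades of the observed concentration range, with
#' `bottom` in \[0, 50\] and `top` in \[50, 120\] percent.
#'
#' @param data data frame with columns `concentration` (positive, at least
#'   4 distinct values) and `viability` (percent; replicate rows allowed).
#' @return object of class `fourpl_fit` with the fitted parameters
#'   (`top`, `bottom`, `hill`, `ic50`), residual standard deviation, and the
#'   underlying `nls` fit. Methods: `predict()`, `tidy()`, `glance()`,
#'   [icq()], [autoplot.fourpl_fit()].
#' @export
fit_4pl <- function(data) {
  if (!is.data.frame(data) ||
    !all(c("concentration", "viability") %in% names(data))) {
    stop_validation("`data` must have columns concentration and viability")
  }
  conc <- data$concentration
  v <- data$viability
  if (any(conc <= 0)) stop_validation("concentrations must be positive")
  if (length(unique(conc)) < 4) {
    stop_validation("at least 4 distinct concentrations are required")
  }
  if (sd(v) < sqrt(.Machine$double.eps)) {
    abort("flat response: viability does not vary, 4PL fit is degenerate",
      class = "phytonet_fit_error"
    )
  }
  lc <- log10(conc)
  df <- data.frame(lc = lc, v = v)
  means <- tapply(v, lc, mean)
  top0 <- min(max(means), 120)
  bottom0 <- max(min(means), 0)
  mid <- (top0 + bottom0) / 2
  lic50_0 <- as.numeric(names(means))[which.min(abs(means - mid))]
  lower <- c(top = 50, bottom = 0, hill = -20, lic50 = min(lc) - 2)
  upper <- c(top = 120, bottom = 50, hill = 20, lic50 = max(lc) + 2)
  starts <- expand.grid(hill = c(0.5, 1, 2, 4, -0.5, -1, -2, -4), lic50 = lic50_0)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    start <- list(
      top = min(max(top0, 50), 120),
      bottom = min(max(bottom0, 0), 50),
      hill = starts$hill[i],
      lic50 = starts$lic50[i]
    )
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        v ~ bottom + (top - bottom) / (1 + 10^(hill * (lc - lic50))),
        data = df, start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort("4PL fit failed to converge from any start", class = "phytonet_fit_error")
  }
  fit <- best$fit
  cf <- coef(fit)
  dfres <- length(v) - 4
  sigma <- if (dfres > 0) sqrt(best$rss / dfres) else NA_real_
  structure(
    list(
      top = unname(cf["top"]),
      bottom = unname(cf["bottom"]),
      hill = unname(cf["hill"]),
      ic50 = unname(10^cf["lic50"]),
      log10_ic50 = unname(cf["lic50"]),
      sigma = sigma,
      df_residual = dfres,
      n = length(v),
      rss = best$rss,
      fit = fit,
      data = tibble::tibble(concentration = conc, viability = v)
    ),
    class = "fourpl_fit"
  )
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<fourpl_fit> top = %.2f, bottom = %.2f, hill = %.3f, ic50 = %.4g (n = %d, sigma = %.3g)\n",
    x$top, x$bottom, x$hill, x$ic50, x$n, x$sigma
  ))
  invisible(x)
}

#' @export
predict.fourpl_fit <- function(object, concentration = NULL, ...) {
  concentration <- concentration %||% object$data$concentration
  fourpl_mean(concentration, object$top, object$bottom, object$hill, object$ic50)
}

#' @rdname fit_4pl
#' @param x a `fourpl_fit`.
#' @param ... unused.
#' @export
tidy.fourpl_fit <- function(x, ...) {
  cf <- coef(x$fit)
  se <- tryCatch(sqrt(diag(vcov(x$fit))), error = function(e) rep(NA_real_, 4))
  tcrit <- if (x$df_residual > 0) qt(0.975, x$df_residual) else NA_real_
  est <- unname(cf)
  serr <- unname(se[names(cf)])
  out <- tibble::tibble(
    term = names(cf),
    estimate = est,
    std.error = serr,
    conf.low = est - tcrit * serr,
    conf.high = est + tcrit * serr
  )
  # report the midpoint on the concentration scale as well
  lic <- out[out$term == "lic50", ]
  dplyr::bind_rows(out, tibble::tibble(
    term = "ic50",
    estimate = 10^lic$estimate,
    std.error = log(10) * 10^lic$estimate * lic$std.error,
    conf.low = 10^lic$conf.low,
    conf.high = 10^lic$conf.high
  ))
}

#' @rdname fit_4pl
#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble::tibble(
    top = x$top, bottom = x$bottom, hill = x$hill, ic50 = x$ic50,
    sigma = x$sigma, df.residual = x$df_residual, nobs = x$n
  )
}

#' Inhibitory concentration at an arbitrary inhibition level
#'
#' Solves the fitted 4PL analytically for the concentration at which the
#' response has dropped by `q` percent of the top-to-bottom span (so
#' `q = 50` returns the fitted IC50, `q = 25` the IC25).
#'
#' @param fit a [fit_4pl()] result.
#' @param q inhibition level in percent, strictly between 0 and 100.
#' @return concentration in the units of the fitted data.
#' @export
icq <- function(fit, q) {
  if (!inherits(fit, "fourpl_fit")) stop_validation("`fit` must be a fourpl_fit")
  if (any(q <= 0 | q >= 100)) stop_validation("`q` must lie strictly between 0 and 100")
  target <- fit$top - q / 100 * (fit$top - fit$bottom)
  fit$ic50 * ((fit$top - fit$bottom) / (target - fit$bottom) - 1)^(1 / fit$hill)
}

#' Selectivity index
#'
#' Ratio of the 50% cytotoxic concentration on a normal line to the 50%
#' inhibitory concentration on a cancer line; values above 3 are
#' conventionally taken as meaningful tumor selectivity.
#'
#' @param cc50 CC50 on the normal line (ug/mL, positive).
#' @param ic50 IC50 on the cancer line (ug/mL, positive); vectorized.
#' @return unitless selectivity index (full precision; round with
#'   [round_half_up()] for 2-decimal reporting).
#' @export
selectivity_index <- function(cc50, ic50) {
  if (any(cc50 <= 0) || any(ic50 <= 0)) {
    stop_validation("cc50 and ic50 must be positive")
  }
  cc50 / ic50
}

#' NCI activity and selectivity classification
#'
#' A crude extract is considered active when its IC50 is at most
#' `ic50_max` (30 ug/mL, the NCI screening criterion) and selective when
#' its selectivity index strictly exceeds `si_min` (3).
#'
#' @param ic50 IC50 values (ug/mL).
#' @param si selectivity indices.
#' @param ic50_max activity threshold (inclusive, default 30).
#' @param si_min selectivity threshold (exclusive, default 3).
#' @return tibble with logical columns `active` and `selective`.
#' @export
nci_classify <- function(ic50, si, ic50_max = 30, si_min = 3) {
  tibble::tibble(active = ic50 <= ic50_max, selective = si > si_min)
}

#' Cytotoxicity profile across cell lines
#'
#' Combines CC50 (normal line) and IC50 (cancer lines) values into the
#' standard reporting layout: selectivity index per cancer line plus NCI
#' activity/selectivity flags.
#'
#' @param data data frame with columns `cell_line`, `kind` (`"CC50"` or
#'   `"IC50"`), `value` and optionally `sd`.
#' @return tibble with one row per cancer line: `cell_line`, `ic50`, `sd`,
#'   `cc50`, `si`, `si_2dp`, `active`, `selective`.
#' @export
cytotoxicity_profile <- function(data) {
  if (!is.data.frame(data) || !all(c("cell_line", "kind", "value") %in% names(data))) {
    stop_validation("`data` must have columns cell_line, kind, value")
  }
  cc <- data$value[data$kind == "CC50"]
  if (length(cc) != 1) stop_validation("exactly one CC50 row (normal line) is required")
  cancer <- data[data$kind == "IC50", , drop = FALSE]
  if (nrow(cancer) == 0) stop_validation("at least one IC50 row is required")
  si <- selectivity_index(cc, cancer$value)
  flags <- nci_classify(cancer$value, si)
  tibble::tibble(
    cell_line = cancer$cell_line,
    ic50 = cancer$value,
    sd = if ("sd" %in% names(cancer)) cancer$sd else NA_real_,
    cc50 = cc,
    si = si,
    si_2dp = round_half_up(si, 2),
    active = flags$active,
    selective = flags$selective
  )
}

#' Annexin V / PI quadrant fractions
#'
#' Partitions two-channel fluorescence events into the four apoptosis
#' quadrants by threshold gating on (log-scale) intensities: viable
#' (Annexin-/PI-), early apoptotic (Annexin+/PI-), late apoptotic
#' (Annexin+/PI+), necrotic (Annexin-/PI+). Events exactly on a gate are
#' assigned to the positive side.
#'
#' @param events data frame with numeric columns `annexin` and `pi`
#'   (log10 intensities).
#' @param annexin_gate,pi_gate gating thresholds (same scale as the events).
#' @return one-row tibble with percentages `viable`, `early_apoptotic`,
#'   `late_apoptotic`, `necrotic` (summing to 100) and the event count `n`.
#' @export
quadrant_fractions <- function(events, annexin_gate, pi_gate) {
  if (!is.data.frame(events) || nrow(events) == 0 ||
    !all(c("annexin", "pi") %in% names(events))) {
    stop_validation("`events` must be a nonempty data frame with annexin and pi")
  }
  if (!is.finite(annexin_gate) || !is.finite(pi_gate)) {
    stop_validation("gates must be finite")
  }
  a_pos <- events$annexin >= annexin_gate
  p_pos <- events$pi >= pi_gate
  n <- nrow(events)
  tibble::tibble(
    viable = 100 * sum(!a_pos & !p_pos) / n,
    early_apoptotic = 100 * sum(a_pos & !p_pos) / n,
    late_apoptotic = 100 * sum(a_pos & p_pos) / n,
    necrotic = 100 * sum(!a_pos & p_pos) / n,
    n = n
  )
}

death_components <- function(x) {
  if (is.data.frame(x)) {
    needed <- c("early_apoptotic", "late_apoptotic", "necrotic")
    if (!all(needed %in% names(x)) || nrow(x) != 1) {
      stop_validation("quadrant input needs one row with early_apoptotic, late_apoptotic, necrotic")
    }
    c(x$early_apoptotic, x$late_apoptotic, x$necrotic)
  } else if (is.numeric(x) && length(x) == 3) {
    x
  } else {
    stop_validation("quadrant input must be a one-row tibble or numeric (early, late, necrotic)")
  }
}

#' Total cell-death summary and fold induction
#'
#' Total death is the sum of early apoptotic, late apoptotic and necrotic
#' percentages; the fold induction is the treated total over the control
#' total. The apoptotic-only subtotal (early + late) is reported alongside.
#'
#' @param treated,control quadrant fractions: either a one-row tibble from
#'   [quadrant_fractions()] or a numeric vector
#'   `c(early, late, necrotic)` in percent.
#' @return one-row tibble: `total_treated`, `total_control`, `fold`,
#'   `fold_1dp`, `apoptotic_treated`, `apoptotic_control`,
#'   `fold_defined`.
#' @export
death_summary <- function(treated, control) {
  tr <- death_components(treated)
  ct <- death_components(control)
  if (any(c(tr, ct) < 0)) stop_validation("quadrant percentages must be nonnegative")
  total_tr <- sum(tr)
  total_ct <- sum(ct)
  defined <- total_ct > 0
  fold <- if (defined) total_tr / total_ct else NA_real_
  tibble::tibble(
    total_treated = total_tr,
    total_control = total_ct,
    fold = fold,
    fold_1dp = round_half_up(fold, 1),
    apoptotic_treated = tr[1] + tr[2],
    apoptotic_control = ct[1] + ct[2],
    fold_defined = defined
  )
}

#' Cell-cycle phase fractions from DNA-content values
#'
#' Threshold gating of a DNA-content histogram into sub-G1 (hypodiploid
#' debris/apoptotic), G0/G1, S and G2/M. The sub-G1 fraction is reported as
#' a percentage of all events and excluded from the three-phase
#' normalization, which sums to 100 over gated events.
#'
#' @param dna numeric vector of per-event DNA-content values.
#' @param breaks increasing numeric vector of three boundaries:
#'   sub-G1/G0-G1, G0-G1/S and S/G2-M.
#' @return one-row tibble: `sub_g1` (% of all events), `g0g1`, `s`, `g2m`
#'   (% of gated events), `n`, `n_gated`.
#' @export
cycle_fractions <- function(dna, breaks) {
  if (!is.numeric(dna) || length(dna) == 0) stop_validation("`dna` must be nonempty numeric")
  if (length(breaks) != 3 || any(diff(breaks) <= 0)) {
    stop_validation("`breaks` must be three strictly increasing boundaries")
  }
  n <- length(dna)
  sub <- dna < breaks[1]
  gated <- dna[!sub]
  ng <- length(gated)
  if (ng == 0) {
    return(tibble::tibble(
      sub_g1 = 100, g0g1 = 0, s = 0, g2m = 0, n = n, n_gated = 0L
    ))
  }
  tibble::tibble(
    sub_g1 = 100 * sum(sub) / n,
    g0g1 = 100 * sum(gated < breaks[2]) / ng,
    s = 100 * sum(gated >= breaks[2] & gated < breaks[3]) / ng,
    g2m = 100 * sum(gated >= breaks[3]) / ng,
    n = n,
    n_gated = ng
  )
}

#' Wound-closure metrics from scratch-assay areas
#'
#' Closure at time t is the percentage reduction of the wound area relative
#' to the same arm's baseline: `100 * (A0 - At) / A0`. Two treated-versus-
#' control comparisons are reported because both readings of "reduced
#' closure" occur in practice: the treated closure as a percentage of the
#' control closure, and the percentage-point difference.
#'
#' @param series data frame with columns `time_h`, `arm` (`"treated"` /
#'   `"control"`) and `area` (any consistent area unit; baseline row at
#'   `time_h == 0` required per arm).
#' @return tibble with one row per post-baseline timepoint:
#'   `closure_treated`, `closure_control`, `relative_closure_pct`
#'   (treated as % of control), `reduction_pp` (control minus treated,
#'   percentage points), and `flag_negative` when a wound grew beyond its
#'   baseline.
#' @export
wound_metrics <- function(series) {
  if (!is.data.frame(series) ||
    !all(c("time_h", "arm", "area") %in% names(series))) {
    stop_validation("`series` must have columns time_h, arm, area")
  }
  if (any(series$area < 0)) stop_validation("areas must be nonnegative")
  closure_one <- function(df) {
    a0 <- df$area[df$time_h == 0]
    if (length(a0) != 1 || a0 <= 0) {
      stop_validation("each arm needs one positive baseline area at time_h == 0")
    }
    df <- df[df$time_h > 0, , drop = FALSE]
    tibble::tibble(time_h = df$time_h, closure = 100 * (a0 - df$area) / a0)
  }
  tr <- closure_one(series[series$arm == "treated", , drop = FALSE])
  ct <- closure_one(series[series$arm == "control", , drop = FALSE])
  out <- dplyr::inner_join(
    dplyr::rename(tr, closure_treated = "closure"),
    dplyr::rename(ct, closure_control = "closure"),
    by = "time_h"
  ) |>
    dplyr::mutate(
      relative_closure_pct = 100 * .data$closure_treated / .data$closure_control,
      reduction_pp = .data$closure_control - .data$closure_treated,
      flag_negative = .data$closure_treated < 0 | .data$closure_control < 0
    )
  if (any(out$flag_negative)) {
    warn("negative closure: a wound area exceeded its baseline")
  }
  out
}

#' Welch two-sample t-test
#'
#' Unpaired, two-tailed Student's t-test with Welch's correction
#' (Satterthwaite degrees of freedom) for comparing two replicate groups.
#' When both groups have zero variance, equal means give `p = 1` by
#' convention and distinct means give `p = 0`.
#'
#' @param a,b numeric vectors of replicate values (at least 2 each).
#' @return one-row tibble: `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
two_group_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop_validation("each group needs at least 2 values")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble::tibble(
      statistic = if (equal) 0 else Inf,
      df = NA_real_,
      p_value = if (equal) 1 else 0,
      mean_a = mean(a),
      mean_b = mean(b)
    ))
  }
  tt <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_a = mean(a),
    mean_b = mean(b)
  )
}
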