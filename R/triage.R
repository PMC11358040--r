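#' Boltzmann fit of a DSF melt curve
#'
#' Sigmoid model \eqn{F(T) = B + (P - B) / (1 + e^{(T_m - T)/a})}. The fit
#' window is truncated at the global fluorescence maximum plus 2 degC so the
#' post-peak SYPRO decay does not bias the transition; the fit is invariant to
#' affine rescaling of the fluorescence.
#'
#' @param melt A data.frame with ascending `temperature` (degC, >= 10 points)
#'   and `fluorescence` columns.
#' @return A `tm_fit`: `tm`, `tm_se` (degC), `slope` (a, degC), `baseline`,
#'   `plateau`, `window` (degC range fitted), `r2`, `ok` (FALSE when no
#'   significant sigmoidal rise was found).
#' @export
fit_boltzmann_tm <- function(melt) {
  stopifnot(all(c("temperature", "fluorescence") %in% names(melt)))
  temp <- melt$temperature
  fl <- melt$fluorescence
  if (length(temp) < 10L) stop("melt curve needs >= 10 points")
  if (is.unsorted(temp, strictly = TRUE)) {
    stop("temperatures must be strictly increasing")
  }
  tmax <- temp[which.max(fl)]
  keep <- temp <= tmax + 2
  temp <- temp[keep]
  fl <- fl[keep]
  indeterminate <- function(reason) {
    structure(list(tm = NA_real_, tm_se = NA_real_, slope = NA_real_,
                   baseline = NA_real_, plateau = NA_real_,
                   window = range(temp), r2 = NA_real_, ok = FALSE,
                   reason = reason),
              class = "tm_fit")
  }
  if (length(temp) < 6L) return(indeterminate("too few pre-peak points"))
  b0 <- min(fl)
  p0 <- max(fl)
  if (p0 - b0 <= 0) return(indeterminate("no fluorescence rise"))
  tm0 <- temp[which.min(abs(fl - (b0 + p0) / 2))]
  df <- data.frame(T = temp, F = fl)
  fit <- tryCatch(
    minpack.lm::nlsLM(F ~ B + (P - B) / (1 + exp((Tm - T) / a)), data = df,
                      start = list(B = b0, P = p0, Tm = tm0, a = 2),
                      lower = c(B = -Inf, P = -Inf, Tm = min(temp), a = 1e-3),
                      upper = c(B = Inf, P = Inf, Tm = max(temp), a = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(indeterminate("Boltzmann fit did not converge"))
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 4),
                                                     names(co)))
  span <- co[["P"]] - co[["B"]]
  span_se <- sqrt(sum(se[c("P", "B")]^2, na.rm = TRUE))
  if (!is.finite(span) || span <= 0 ||
      (is.finite(span_se) && span_se > 0 && span < 2 * span_se)) {
    return(indeterminate("no significant sigmoidal rise (P - B ~ 0)"))
  }
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((fl - mean(fl))^2)
  structure(list(tm = co[["Tm"]], tm_se = se[["Tm"]], slope = co[["a"]],
                 baseline = co[["B"]], plateau = co[["P"]],
                 window = range(temp), r2 = r2, ok = TRUE, reason = "ok"),
            class = "tm_fit")
}

#' @export
print.tm_fit <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("<tm_fit> Tm = %.2f +/- %.2g degC (a = %.2f, R2 = %.4f)\n",
                x$tm, x$tm_se, x$slope, x$r2))
  } else {
    cat("<tm_fit> indeterminate:", x$reason, "\n")
  }
  invisible(x)
}

#' Quality-control a DSF melt curve
#'
#' Fails curves showing fluorescent interference or aggregation signatures:
#' initial fluorescence above 50% of the curve maximum (pre-aggregated /
#' interference), no fluorescence maximum before the last 3 points (no
#' transition), or a Boltzmann fit with R-squared below `r2_min`.
#'
#' @param melt data.frame with `temperature`, `fluorescence`.
#' @param r2_min Minimum acceptable post-fit R-squared (default 0.95).
#' @return List `pass` (logical) and `reason`.
#' @export
qc_melt_curve <- function(melt, r2_min = 0.95) {
  fl <- melt$fluorescence
  n <- length(fl)
  if (fl[1L] > 0.5 * max(fl)) {
    return(list(pass = FALSE, reason = "pre-aggregated: initial fluorescence > 50% of maximum"))
  }
  if (which.max(fl) > n - 3L) {
    return(list(pass = FALSE, reason = "no transition: fluorescence maximum in the last 3 points"))
  }
  fit <- fit_boltzmann_tm(melt)
  if (!fit$ok) return(list(pass = FALSE, reason = fit$reason))
  if (fit$r2 < r2_min) {
    return(list(pass = FALSE,
                reason = sprintf("poor Boltzmann fit (R2 = %.3f < %.2f)",
                                 fit$r2, r2_min)))
  }
  list(pass = TRUE, reason = "ok")
}

#' k-sigma threshold hit calls against reference replicates
#'
#' The reference mean and (unrounded, n-1) SD define the cutoff
#' \eqn{k\sigma}; a value is a hit when its deviation from the reference mean
#' exceeds the cutoff in the configured sense. Each hit is labeled
#' `"elevating"` or `"lowering"` by the sign of its deviation.
#'
#' @param values Named numeric vector of measurements to call.
#' @param reference_values Numeric vector (>= 2) of reference replicates.
#' @param k Cutoff multiple of the reference SD (default 3).
#' @param sense `"two-sided"`, `"greater"` or `"less"`.
#' @return List with `calls` (data.frame: label, value, delta, hit, class),
#'   `mu`, `sigma`, `cutoff`, and `summary` counts.
#' @export
threshold_call <- function(values, reference_values, k = 3,
                           sense = c("two-sided", "greater", "less")) {
  sense <- match.arg(sense)
  if (length(reference_values) < 2L) stop("need >= 2 reference values")
  mu <- mean(reference_values)
  sigma <- stats::sd(reference_values)
  cutoff <- k * sigma
  delta <- values - mu
  if (sigma == 0 && any(delta != 0)) {
    warning("reference SD is 0; every deviating value is called a hit")
  }
  hit <- switch(sense,
                "two-sided" = abs(delta) > cutoff,
                "greater" = delta > cutoff,
                "less" = delta < -cutoff)
  cls <- ifelse(!hit, "none", ifelse(delta > 0, "elevating", "lowering"))
  labels <- names(values)
  if (is.null(labels)) labels <- paste0("x", seq_along(values))
  calls <- data.frame(label = labels, value = as.numeric(values),
                      delta = as.numeric(delta), hit = as.logical(hit),
                      class = cls, row.names = NULL)
  list(calls = calls, mu = mu, sigma = sigma, cutoff = cutoff,
       summary = c(hits = sum(hit), elevating = sum(cls == "elevating"),
                   lowering = sum(cls == "lowering"), total = length(values)))
}

#' Time-averaged MST response amplitude
#'
#' Each scan's fluorescence is normalized to its pre-excitation baseline
#' (times before `excitation_start`) times 1000; the amplitude is the mean
#' normalized fluorescence over the averaging window, averaged across the
#' first `n_scans` scans.
#'
#' @param trace_set data.frame with columns `time` (s), `fluorescence`,
#'   `scan` (>= 3 scans).
#' @param window Averaging window in seconds within the excitation phase
#'   (default `c(4, 5)`).
#' @param excitation_start,excitation_end Phase boundaries (s): default 3-s
#'   equilibration then 20-s infrared excitation.
#' @param n_scans Number of consecutive scans averaged (default 3).
#' @return Amplitude in normalized response units (baseline = 1000).
#' @export
mst_amplitude <- function(trace_set, window = c(4, 5), excitation_start = 3,
                          excitation_end = 23, n_scans = 3) {
  stopifnot(all(c("time", "fluorescence", "scan") %in% names(trace_set)))
  if (window[1] < excitation_start || window[2] > excitation_end) {
    stop("averaging window lies outside the excitation phase")
  }
  scans <- sort(unique(trace_set$scan))
  if (length(scans) < n_scans) stop(sprintf("need >= %d scans", n_scans))
  scans <- scans[seq_len(n_scans)]
  per_scan <- vapply(scans, function(s) {
    d <- trace_set[trace_set$scan == s, ]
    base <- mean(d$fluorescence[d$time < excitation_start])
    if (!is.finite(base) || base <= 0) stop("invalid pre-excitation baseline")
    inwin <- d$time >= window[1] & d$time <= window[2]
    if (!any(inwin)) stop("no points inside the averaging window")
    1000 * mean(d$fluorescence[inwin]) / base
  }, numeric(1))
  mean(per_scan)
}

#' One-site binding fit of a titration
#'
#' Model \eqn{R(c) = R_0 + \Delta R \; c / (K_d + c)} fitted by bounded
#' nonlinear least squares. The fit is reported indeterminate (ND) when the
#' response span is not significantly different from zero or the fitted Kd
#' exceeds the top titrated concentration by more than 10-fold.
#'
#' @param concentrations Positive ligand concentrations (>= 6 points spanning
#'   >= 2 orders of magnitude).
#' @param responses Measured responses, same length.
#' @return A `binding_fit`: `kd`, `kd_se` (concentration units), `r0`,
#'   `delta_r`, `determinate`, `reason`.
#' @export
one_site_fit <- function(concentrations, responses) {
  conc <- as.numeric(concentrations)
  resp <- as.numeric(responses)
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (length(conc) < 6L) stop("need >= 6 titration points")
  if (max(conc) / min(conc) < 100) {
    stop("titration must span >= 2 orders of magnitude")
  }
  nd <- function(reason) {
    structure(list(kd = NA_real_, kd_se = NA_real_, r0 = NA_real_,
                   delta_r = NA_real_, determinate = FALSE, reason = reason),
              class = "binding_fit")
  }
  r0_0 <- resp[which.min(conc)]
  dr_0 <- resp[which.max(conc)] - r0_0
  if (dr_0 == 0) dr_0 <- 1e-6
  df <- data.frame(c = conc, R = resp)
  fit <- tryCatch(
    minpack.lm::nlsLM(R ~ R0 + dR * c / (Kd + c), data = df,
                      start = list(R0 = r0_0, dR = dr_0,
                                   Kd = stats::median(conc)),
                      lower = c(R0 = -Inf, dR = -Inf, Kd = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(nd("fit did not converge"))
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 3),
                                                     names(co)))
  if (is.finite(se[["dR"]]) && se[["dR"]] > 0 &&
      abs(co[["dR"]]) < 2 * se[["dR"]]) {
    return(nd("response span not significantly different from zero"))
  }
  if (co[["Kd"]] > 10 * max(conc)) {
    return(nd("Kd exceeds the top concentration by > 10x"))
  }
  structure(list(kd = co[["Kd"]], kd_se = se[["Kd"]], r0 = co[["R0"]],
                 delta_r = co[["dR"]], determinate = TRUE, reason = "ok"),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (x$determinate) {
    cat(sprintf("<binding_fit> Kd = %.4g +/- %.2g (R0 = %.4g, dR = %.4g)\n",
                x$kd, x$kd_se, x$r0, x$delta_r))
  } else {
    cat("<binding_fit> ND:", x$reason, "\n")
  }
  invisible(x)
}
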