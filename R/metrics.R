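#' Guinier fit of the low-q region
#'
#' Fits \eqn{\ln I(q) = \ln I(0) - q^2 R_g^2 / 3} by (sigma-weighted when
#' available) linear regression of \eqn{\ln I} on \eqn{q^2}. The fit window
#' starts at the first positive-intensity point at or after `qmin` and its
#' upper bound is shrunk (or grown) from the high-q side until the fixed point
#' \eqn{q_{max} R_g \le} `qmax_rg_limit` is reached.
#'
#' @param curve A [scattering_curve()].
#' @param qmax_rg_limit Upper bound on \eqn{q_{max} R_g} (default 1.3, the
#'   globular-particle convention).
#' @param qmin Optional lower q bound; default is the first point with
#'   positive intensity.
#' @return A `guinier_fit` object: `rg`, `rg_se` (\eqn{\AA}), `i0`, `i0_se`,
#'   `qmin`, `qmax`, `n`, `r2`, `qmax_rg`, plus the window point indices.
#' @export
guinier_fit <- function(curve, qmax_rg_limit = 1.3, qmin = NULL) {
  stopifnot(inherits(curve, "scattering_curve"))
  q <- curve$q
  I <- curve$intensity
  if (all(I <= 0)) stop("all intensities are non-positive")
  ok <- I > 0
  if (!is.null(qmin)) ok <- ok & q >= qmin
  start <- which(ok)[1L]
  if (is.na(start)) stop("no positive-intensity points at or after qmin")
  cand <- which(ok & seq_along(q) >= start)
  # candidate window must be contiguous from the start point
  if (length(cand)) cand <- cand[cand - cand[1L] == seq_along(cand) - 1L]
  if (length(cand) < 5L) stop("fewer than 5 usable points for Guinier fit")

  fit_window <- function(idx) {
    x <- q[idx]^2
    y <- log(I[idx])
    w <- if (!is.null(curve$sigma)) (I[idx] / curve$sigma[idx])^2 else NULL
    fm <- if (is.null(w)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = w)
    fm
  }

  end <- min(length(cand), 10L)
  seen <- integer(0)
  rg <- NA_real_
  fm <- NULL
  for (iter in 1:100) {
    idx <- cand[1:end]
    fm <- fit_window(idx)
    slope <- stats::coef(fm)[[2L]]
    if (!is.finite(slope) || slope >= 0) {
      # no decay in window: shrink and retry
      if (end <= 5L) stop("no convergent Guinier window with >= 5 points")
      end <- end - 1L
      next
    }
    rg <- sqrt(-3 * slope)
    target <- max(which(q[cand] * rg <= qmax_rg_limit + 1e-6))
    if (!is.finite(target) || target < 5L) {
      stop("no convergent Guinier window with >= 5 points")
    }
    if (target == end) break
    if (target %in% seen) { # cycle: take the smaller (safer) window
      end <- min(end, target)
      idx <- cand[1:end]
      fm <- fit_window(idx)
      rg <- sqrt(-3 * stats::coef(fm)[[2L]])
      break
    }
    seen <- c(seen, end)
    end <- target
  }
  idx <- cand[1:end]
  sm <- suppressWarnings(summary(fm)) # noiseless data fits exactly
  slope <- stats::coef(fm)[[2L]]
  inter <- stats::coef(fm)[[1L]]
  se <- sm$coefficients[, "Std. Error"]
  rg <- sqrt(-3 * slope)
  rg_se <- 3 * se[[2L]] / (2 * rg)
  i0 <- exp(inter)
  i0_se <- i0 * se[[1L]]
  structure(list(
    rg = rg, rg_se = rg_se, i0 = i0, i0_se = i0_se,
    qmin = q[idx[1L]], qmax = q[idx[end]], n = length(idx),
    r2 = sm$r.squared, qmax_rg = q[idx[end]] * rg,
    residuals = stats::residuals(fm), window_idx = idx
  ), class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "<guinier_fit> Rg = %.3f +/- %.3f A, I(0) = %.4g +/- %.2g\n  window q [%.4g, %.4g] (%d pts), qmax*Rg = %.3f, R2 = %.4f\n",
    x$rg, x$rg_se, x$i0, x$i0_se, x$qmin, x$qmax, x$n, x$qmax_rg, x$r2))
  invisible(x)
}

#' Flag aggregation from Guinier-window diagnostics
#'
#' Splits the Guinier window in half and refits each half: the presence of
#' large particles inflates the apparent Rg at the lowest q, so the low-half
#' Rg exceeding the high-half Rg by more than `rel_tol` flags aggregation.
#' Systematic positive curvature of the low-q residuals (mean residual of the
#' lowest quartile above twice the residual SD) is an independent trigger.
#'
#' @param curve The fitted [scattering_curve()].
#' @param fit Its [guinier_fit()].
#' @param rel_tol Relative low-half vs high-half Rg excess that triggers the
#'   flag (default 0.05).
#' @return List with `flag` (TRUE/FALSE/NA for indeterminate), `reason`,
#'   `rg_low`, `rg_high`.
#' @export
aggregation_check <- function(curve, fit, rel_tol = 0.05) {
  stopifnot(inherits(fit, "guinier_fit"))
  idx <- fit$window_idx
  if (length(idx) < 10L) {
    return(list(flag = NA, reason = "window too small to split (< 10 points)",
                rg_low = NA_real_, rg_high = NA_real_))
  }
  half <- floor(length(idx) / 2)
  rg_of <- function(ii) {
    x <- curve$q[ii]^2
    y <- log(curve$intensity[ii])
    sl <- stats::coef(stats::lm(y ~ x))[[2L]]
    if (!is.finite(sl) || sl >= 0) return(NA_real_)
    sqrt(-3 * sl)
  }
  rg_low <- rg_of(idx[1:half])
  rg_high <- rg_of(idx[(half + 1):length(idx)])
  res <- fit$residuals
  nq <- max(1L, floor(length(res) / 4))
  curv <- mean(res[1:nq]) > 2 * stats::sd(res)
  halves <- is.finite(rg_low) && is.finite(rg_high) &&
    (rg_low - rg_high) / rg_high > rel_tol
  flag <- isTRUE(halves) || isTRUE(curv)
  reason <- if (isTRUE(halves)) {
    sprintf("low-half Rg %.2f exceeds high-half Rg %.2f by > %.0f%%",
            rg_low, rg_high, 100 * rel_tol)
  } else if (isTRUE(curv)) {
    "systematic positive low-q residual curvature"
  } else {
    "no aggregation signature"
  }
  list(flag = flag, reason = reason, rg_low = rg_low, rg_high = rg_high)
}

#' Dimensionless (normalized) Kratky transform
#'
#' Returns \eqn{x = qR_g}, \eqn{y = (qR_g)^2 I(q)/I(0)}. For a globular
#' particle obeying the Guinier law the curve peaks at
#' \eqn{x = \sqrt{3}, y = 3/e}.
#'
#' @param curve A [scattering_curve()].
#' @param fit Its [guinier_fit()] supplying Rg and I(0).
#' @return data.frame with columns `x` and `y`.
#' @export
kratky_normalized <- function(curve, fit) {
  stopifnot(inherits(curve, "scattering_curve"), inherits(fit, "guinier_fit"))
  if (!is.finite(fit$i0) || fit$i0 <= 0) stop("I(0) must be positive")
  x <- curve$q * fit$rg
  y <- x^2 * curve$intensity / fit$i0
  data.frame(x = x, y = y)
}

#' Z-factor assay-quality statistic
#'
#' \eqn{Z = 1 - 3(\sigma_p + \sigma_n) / |\mu_p - \mu_n|} with sample (n-1)
#' standard deviations. Values of 0.5-1.0 indicate effective discrimination
#' between the positive and negative control states.
#'
#' @param positive_values,negative_values Numeric vectors of replicate control
#'   measurements (>= 2 each).
#' @param metric Name of the measured quantity (e.g. "Rg", "I0").
#' @return An `assay_quality` object with `z`, group means and SDs.
#' @export
z_factor <- function(positive_values, negative_values, metric = "") {
  if (length(positive_values) < 2L || length(negative_values) < 2L) {
    stop("need at least 2 replicate values per control group")
  }
  mu_p <- mean(positive_values); mu_n <- mean(negative_values)
  if (mu_p == mu_n) stop("Z-factor undefined: control group means are equal")
  sd_p <- stats::sd(positive_values); sd_n <- stats::sd(negative_values)
  z <- 1 - 3 * (sd_p + sd_n) / abs(mu_p - mu_n)
  structure(list(z = z, mu_p = mu_p, mu_n = mu_n, sd_p = sd_p, sd_n = sd_n,
                 metric = metric),
            class = "assay_quality")
}

#' @export
print.assay_quality <- function(x, ...) {
  cat(sprintf("<assay_quality> %s: Z = %.3f (mu %.4g/%.4g, sd %.3g/%.3g)\n",
              x$metric, x$z, x$mu_p, x$mu_n, x$sd_p, x$sd_n))
  invisible(x)
}
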