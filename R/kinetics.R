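#' Fit a single exponential to a time trace
#'
#' Decay model \eqn{V(t) = C + A e^{-kt}}; rise model
#' \eqn{y(t) = C - A e^{-kt}} (both with amplitude \eqn{A \ge 0} and rate
#' \eqn{k \ge 0} s\eqn{^{-1}}). Nonlinear least squares (Levenberg-Marquardt
#' with box bounds) initialized from the trace itself: plateau from the last
#' value, amplitude from the first-minus-last span, and rate from a
#' log-linearization of the plateau-corrected values. A fit is flagged
#' non-transitioning when the amplitude is not significantly positive
#' (\eqn{A < 2\,SE(A)}) or the rate is below 1e-3 s\eqn{^{-1}}.
#'
#' @param trace A [vr_trace()] or data.frame with columns `time` and a value
#'   column (`vr` or the second column).
#' @param direction `"decay"` or `"rise"`.
#' @param weights Optional per-point weights for the residuals (default
#'   unweighted).
#' @return An `exponential_fit`: `k`, `k_se`, `A`, `A_se`, `C`, `C_se`,
#'   `direction`, `sse`, `converged`, `transitioning`, `label`.
#' @export
fit_exponential <- function(trace, direction = c("decay", "rise"),
                            weights = NULL) {
  direction <- match.arg(direction)
  tt <- trace[[1L]]
  y <- if ("vr" %in% names(trace)) trace$vr else trace[[2L]]
  if ("time" %in% names(trace)) tt <- trace$time
  if (length(tt) < 4L) stop("need at least 4 time points")
  if (is.unsorted(tt, strictly = TRUE)) stop("times must be strictly increasing")
  if (!all(is.finite(tt)) || !all(is.finite(y))) stop("non-finite trace values")
  sgn <- if (direction == "decay") 1 else -1
  # work on the decaying form z(t) = sgn*y = sgn*C + A e^{-kt}
  z <- sgn * y
  c0 <- z[length(z)]
  a0 <- max(z[1L] - c0, 1e-8)
  pos <- which(z - c0 > a0 * 0.05)
  k0 <- if (length(pos) >= 2L) {
    sl <- stats::coef(stats::lm(log(z[pos] - c0 + 1e-12) ~ tt[pos]))[[2L]]
    max(-sl, 1e-3)
  } else {
    1 / max(tt)
  }
  df <- data.frame(t = tt, z = z)
  fit <- tryCatch(
    minpack.lm::nlsLM(z ~ C + A * exp(-k * t), data = df,
                      start = list(C = c0, A = a0, k = k0),
                      lower = c(C = -Inf, A = 0, k = 0),
                      weights = if (is.null(weights)) rep(1, nrow(df)) else weights,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate (e.g. perfectly flat) traces: report a plateau-only fit
    co <- c(C = mean(z), A = 0, k = 0)
    se <- c(C = stats::sd(z) / sqrt(length(z)), A = stats::sd(z), k = NA_real_)
    sse <- sum((z - mean(z))^2)
    converged <- FALSE
  } else {
    co <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, 3))
    names(se) <- names(co)
    sse <- sum(stats::residuals(fit)^2)
    converged <- fit$convInfo$isConv %||% TRUE
  }
  # amplitude must be significant and non-degenerate (an exactly flat trace
  # fits with A at the optimizer's floor and zero SE)
  transitioning <- is.finite(se[["A"]]) &&
    co[["A"]] > 1e-6 * max(1, abs(z)) &&
    co[["A"]] >= 2 * se[["A"]] && co[["k"]] >= 1e-3
  structure(list(
    k = co[["k"]], k_se = se[["k"]],
    A = co[["A"]], A_se = se[["A"]],
    C = sgn * co[["C"]], C_se = se[["C"]],
    direction = direction, sse = sse, converged = converged,
    transitioning = isTRUE(transitioning),
    label = attr(trace, "label", exact = TRUE)
  ), class = "exponential_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname fit_exponential
#' @export
fit_exponential_decay <- function(trace, weights = NULL) {
  fit_exponential(trace, direction = "decay", weights = weights)
}

#' Fit a rising exponential and report the time to 95% of the plateau
#'
#' @inheritParams fit_exponential
#' @return An `exponential_fit` with an extra `t95 = 3/k` field (s).
#' @export
fit_exponential_rise <- function(trace, weights = NULL) {
  fit <- fit_exponential(trace, direction = "rise", weights = weights)
  fit$t95 <- if (fit$k > 0) 3 / fit$k else Inf
  fit
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf(
    "<exponential_fit> %s: k = %.4g s^-1 (SE %.2g), A = %.4g, C = %.4g%s\n",
    x$direction, x$k, x$k_se, x$A, x$C,
    if (x$transitioning) "" else "  [non-transitioning]"))
  invisible(x)
}

#' Rank k_VR rate constants and cluster the transitioning compounds
#'
#' Transitioning fits are ranked by descending rate (ties by larger amplitude,
#' then label order). The 1-D k values are clustered by k-means with the
#' elbow-selected cluster number and, for cross-checking, by single-linkage
#' AHC at the same k.
#'
#' @param fits Named list of [fit_exponential_decay()] results (names are
#'   compound labels; unnamed fits fall back to their `label` field).
#' @param kmax Largest candidate cluster number for the elbow scan.
#' @param restarts,seed Passed to [kmeans_cluster()].
#' @return List with `ranking` (data.frame: label, k_vr, k_se, A, C, sse,
#'   rank, cluster, cluster_ahc), `non_transitioning` (labels), `k_selected`,
#'   and `wss_by_k`.
#' @export
rank_and_cluster_kvr <- function(fits, kmax = 6, restarts = 50, seed = 1) {
  labels <- names(fits)
  if (is.null(labels)) {
    labels <- vapply(fits, function(f) f$label %||% "", character(1))
  }
  trans <- vapply(fits, function(f) isTRUE(f$transitioning), logical(1))
  non_trans <- labels[!trans]
  if (!any(trans)) {
    message("no transitioning samples; empty ranking")
    return(list(ranking = data.frame(), non_transitioning = non_trans,
                k_selected = NA_integer_, wss_by_k = numeric(0)))
  }
  if (sum(trans) < 2L) stop("need >= 2 transitioning fits to rank and cluster")
  fsub <- fits[trans]
  lab <- labels[trans]
  kv <- vapply(fsub, function(f) f$k, numeric(1))
  av <- vapply(fsub, function(f) f$A, numeric(1))
  ord <- order(-kv, -av, lab)
  n <- length(kv)
  feats <- matrix(kv, ncol = 1L, dimnames = list(lab, NULL))
  kmax_eff <- min(kmax, n - 1L)
  if (kmax_eff >= 3L) {
    wss <- numeric(kmax_eff)
    for (k in seq_len(kmax_eff)) {
      wss[k] <- if (k == 1L) sum((kv - mean(kv))^2)
      else kmeans_cluster(feats, k, restarts = restarts, seed = seed + k)$wss
    }
    k_sel <- elbow_select_k(wss)
  } else {
    wss <- numeric(0)
    k_sel <- min(2L, n)
  }
  km <- kmeans_cluster(feats, k_sel, restarts = restarts, seed = seed)
  ahc <- single_linkage_cluster(feats, k = k_sel)
  ranking <- data.frame(
    label = lab[ord],
    k_vr = kv[ord],
    k_se = vapply(fsub, function(f) f$k_se, numeric(1))[ord],
    A = av[ord],
    C = vapply(fsub, function(f) f$C, numeric(1))[ord],
    sse = vapply(fsub, function(f) f$sse, numeric(1))[ord],
    rank = seq_len(n),
    cluster = unname(km$cluster[ord]),
    cluster_ahc = unname(ahc$cluster[ord]),
    row.names = NULL
  )
  list(ranking = ranking, non_transitioning = non_trans,
       k_selected = k_sel, wss_by_k = wss)
}
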