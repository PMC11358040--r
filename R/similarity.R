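#' Volatility of ratio (V_R) between two SAXS curves
#'
#' The intensity ratio of the two curves is binned into `nbins` contiguous
#' equal-width q bins across the analysis window; with in-bin mean intensities
#' \eqn{\bar I_a, \bar I_b} the per-bin ratio is
#' \eqn{R_i = \bar I_a / \bar I_b}, and
#' \deqn{V_R = \sum_{i=1}^{m-1} \frac{|R_{i+1} - R_i|}{(R_{i+1} + R_i)/2}}
#' over the non-empty bins. V_R is 0 for identical curve shapes, exactly
#' symmetric in its arguments, and invariant to separate rescaling of either
#' curve.
#'
#' @param curve_a,curve_b [scattering_curve()] objects covering the window.
#'   When their grids differ inside the window, `curve_b` is regridded onto
#'   `curve_a`'s grid.
#' @param window Numeric length-2: q window (default `c(0.015, 0.15)`
#'   \eqn{\AA^{-1}}).
#' @param nbins Number of equal-width q bins (default 25).
#' @return A `vr_result`: `value`, `window`, `nbins`, `m` (non-empty bins),
#'   `labels`.
#' @export
volatility_of_ratio <- function(curve_a, curve_b, window = c(0.015, 0.15),
                                nbins = 25) {
  stopifnot(inherits(curve_a, "scattering_curve"),
            inherits(curve_b, "scattering_curve"))
  if (min(curve_a$q) > window[1] || max(curve_a$q) < window[2] ||
      min(curve_b$q) > window[1] || max(curve_b$q) < window[2]) {
    stop("both curves must cover the q window")
  }
  sel <- curve_a$q >= window[1] & curve_a$q <= window[2]
  qa <- curve_a$q[sel]
  ia <- curve_a$intensity[sel]
  same_grid <- length(curve_b$q) == length(curve_a$q) &&
    all(curve_b$q == curve_a$q)
  ib <- if (same_grid) curve_b$intensity[sel] else regrid(curve_b, qa)$intensity
  if (any(ib <= 0)) {
    stop("reference curve has non-positive intensity inside the window")
  }
  edges <- seq(window[1], window[2], length.out = nbins + 1L)
  bin <- pmin(findInterval(qa, edges, rightmost.closed = TRUE), nbins)
  ma <- vapply(split(ia, bin), mean, numeric(1))
  mb <- vapply(split(ib, bin), mean, numeric(1))
  r <- ma / mb
  m <- length(r)
  if (m < 2L) stop("fewer than 2 non-empty bins in the window")
  value <- sum(abs(diff(r)) / ((r[-1L] + r[-m]) / 2))
  structure(list(value = value, window = window, nbins = nbins, m = m,
                 labels = c(curve_a$meta$label, curve_b$meta$label)),
            class = "vr_result")
}

#' @export
print.vr_result <- function(x, ...) {
  cat(sprintf("<vr_result> V_R = %.4f (window %.3g-%.3g A^-1, %d/%d bins)\n",
              x$value, x$window[1], x$window[2], x$m, x$nbins))
  invisible(x)
}

#' All-pairs SAXS similarity matrix (SSM)
#'
#' Computes V_R for every unordered pair of curves; the diagonal is zero and
#' the matrix symmetric by construction.
#'
#' @param labeled_curves Named list of [scattering_curve()] objects (>= 2).
#' @param window,nbins Passed to [volatility_of_ratio()].
#' @return A `similarity_matrix`: square numeric matrix with label dimnames
#'   plus `window`/`nbins` attributes.
#' @export
similarity_matrix <- function(labeled_curves, window = c(0.015, 0.15),
                              nbins = 25) {
  n <- length(labeled_curves)
  if (n < 2L) stop("need at least 2 curves")
  labels <- names(labeled_curves)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- paste0("curve", seq_len(n))
  }
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      # canonical argument order by label so a permuted input reproduces
      # every entry bit-exactly
      ab <- if (labels[i] <= labels[j]) c(i, j) else c(j, i)
      v <- tryCatch(
        volatility_of_ratio(labeled_curves[[ab[1L]]], labeled_curves[[ab[2L]]],
                            window = window, nbins = nbins)$value,
        error = function(e) stop(sprintf("pair (%s, %s): %s", labels[i],
                                         labels[j], conditionMessage(e))))
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  structure(m, window = window, nbins = nbins, class = c("similarity_matrix",
                                                         "matrix", "array"))
}

#' Time-resolved V_R trace for one frame series
#'
#' One V_R value per frame, against either a fixed reference curve or a
#' time-matched reference series (one reference frame per sample frame).
#'
#' @param series A [frame_series()].
#' @param reference A single [scattering_curve()] (fixed-reference mode) or a
#'   [frame_series()] with matching frame times (time-matched mode).
#' @param window,nbins Passed to [volatility_of_ratio()].
#' @return A `vr_trace`: data.frame with columns `time` and `vr`, plus label
#'   attributes.
#' @export
vr_trace <- function(series, reference, window = c(0.015, 0.15), nbins = 25) {
  stopifnot(inherits(series, "frame_series"))
  if (inherits(reference, "frame_series")) {
    if (length(reference$curves) != length(series$curves)) {
      stop("time-matched reference series length differs from sample series")
    }
    refs <- reference$curves
    ref_label <- reference$label
  } else {
    stopifnot(inherits(reference, "scattering_curve"))
    refs <- rep(list(reference), length(series$curves))
    ref_label <- reference$meta$label
  }
  vr <- mapply(function(cv, rf) {
    volatility_of_ratio(cv, rf, window = window, nbins = nbins)$value
  }, series$curves, refs)
  structure(data.frame(time = series$times, vr = as.numeric(vr)),
            label = series$label, reference = ref_label,
            class = c("vr_trace", "data.frame"))
}

#' Replicate-derived V_R significance envelope for a benchmark
#'
#' Per time point, the mean and sample SD of the replicate traces are taken;
#' the per-time SDs are averaged across the series into a single standard
#' uncertainty \eqn{\bar\sigma}, and the significance threshold is the mean
#' trace offset by \eqn{k \bar\sigma}: `mean - k*sigma_bar` for a benchmark a
#' responsive sample departs from toward similarity (sense `"monomer"`),
#' `mean + k*sigma_bar` for a self-similarity benchmark a sample may enter
#' (sense `"dimer"`).
#'
#' @param replicate_traces List of >= 2 [vr_trace()]s on identical time grids.
#' @param k Threshold multiple of the averaged SD (default 3).
#' @param sense `"monomer"` (threshold below the mean) or `"dimer"`
#'   (threshold above).
#' @param label Benchmark label.
#' @return A `benchmark_envelope`: `times`, `mean`, `sd` (per-time), `sigma_bar`,
#'   `threshold`, `k`, `sense`, `n_replicates`.
#' @export
benchmark_envelope <- function(replicate_traces, k = 3,
                               sense = c("monomer", "dimer"), label = NULL) {
  sense <- match.arg(sense)
  if (length(replicate_traces) < 2L) stop("need >= 2 replicate traces")
  times <- replicate_traces[[1L]]$time
  for (tr in replicate_traces) {
    if (length(tr$time) != length(times) || any(tr$time != times)) {
      stop("replicate traces are not on an identical time grid")
    }
  }
  vmat <- vapply(replicate_traces, function(tr) tr$vr, numeric(length(times)))
  vmat <- matrix(vmat, nrow = length(times))
  mu <- rowMeans(vmat)
  sd_t <- apply(vmat, 1L, stats::sd)
  sigma_bar <- mean(sd_t)
  thr <- if (sense == "monomer") mu - k * sigma_bar else mu + k * sigma_bar
  structure(list(label = label, times = times, mean = mu, sd = sd_t,
                 sigma_bar = sigma_bar, threshold = thr, k = k, sense = sense,
                 n_replicates = ncol(vmat)),
            class = "benchmark_envelope")
}

#' Classify a V_R trace against monomer and dimer envelopes
#'
#' Labels each time point `"monomer-like"` (at or above the monomer
#' significance threshold), `"significant"` (below it), or `"dimer-entered"`
#' (also at or below the dimer self-similarity threshold), and reports first
#' crossing times.
#'
#' @param trace A [vr_trace()].
#' @param monomer_env,dimer_env [benchmark_envelope()]s on the same time grid
#'   (monomer sense and dimer sense respectively).
#' @return List with `labels` (per time point), `first_significant`,
#'   `first_dimer_entered` (times, or `NA` for "none"), `summary`.
#' @export
classify_transition <- function(trace, monomer_env, dimer_env) {
  times <- trace$time
  if (length(monomer_env$times) != length(times) ||
      any(monomer_env$times != times) ||
      length(dimer_env$times) != length(times) ||
      any(dimer_env$times != times)) {
    stop("trace and envelopes are not on an identical time grid")
  }
  labels <- ifelse(trace$vr <= dimer_env$threshold, "dimer-entered",
                   ifelse(trace$vr < monomer_env$threshold, "significant",
                          "monomer-like"))
  first_sig <- times[match(TRUE, labels != "monomer-like")]
  first_dim <- times[match(TRUE, labels == "dimer-entered")]
  summary <- if (!is.na(first_dim)) {
    sprintf("dimer-entered at %.3g s", first_dim)
  } else if (!is.na(first_sig)) {
    sprintf("significant at %.3g s", first_sig)
  } else {
    "none"
  }
  list(labels = labels,
       first_significant = if (is.na(first_sig)) NA_real_ else first_sig,
       first_dimer_entered = if (is.na(first_dim)) NA_real_ else first_dim,
       summary = summary)
}
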