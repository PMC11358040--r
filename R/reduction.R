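#' Average scattering curves on a common grid
#'
#' Pointwise mean intensity over replicate curves. When every input carries a
#' sigma column the uncertainty of the mean is propagated as
#' \eqn{\sqrt{\sum \sigma_i^2} / n}; otherwise sigma is dropped.
#'
#' @param curves List of [scattering_curve()] objects on identical q grids.
#' @return A [scattering_curve()] with the averaged intensities.
#' @export
average_curves <- function(curves) {
  if (length(curves) < 1L) stop("need at least one curve")
  q0 <- curves[[1L]]$q
  for (cv in curves) {
    if (length(cv$q) != length(q0) || any(cv$q != q0)) {
      stop("curves are not on a common q grid")
    }
  }
  n <- length(curves)
  imat <- vapply(curves, function(cv) cv$intensity, numeric(length(q0)))
  imean <- rowMeans(matrix(imat, nrow = length(q0)))
  sigma <- NULL
  if (all(vapply(curves, function(cv) !is.null(cv$sigma), logical(1)))) {
    smat <- vapply(curves, function(cv) cv$sigma, numeric(length(q0)))
    sigma <- sqrt(rowSums(matrix(smat, nrow = length(q0))^2)) / n
  }
  scattering_curve(q0, imean, sigma = sigma, meta = curves[[1L]]$meta)
}

#' Subtract time-matched averaged buffer frames from a sample series
#'
#' For each frame time t, the buffer frames at t are averaged across the
#' supplied buffer series (optionally scaled) and subtracted from the sample
#' frame: \eqn{I_{sub}(q,t) = I_{sample}(q,t) - s \cdot \bar I_{buffer}(q,t)}.
#' Uncertainties combine in quadrature.
#'
#' @param sample_series A [frame_series()].
#' @param buffer_series_list List of one or more buffer [frame_series()] with
#'   the same q grid and frame times.
#' @param scale Buffer scale factor before subtraction (default 1.0: buffers
#'   are assumed compound-matched).
#' @param time_tol Frame-time alignment tolerance in seconds (default 1e-3).
#' @return A [frame_series()] of subtracted curves.
#' @export
subtract_time_matched <- function(sample_series, buffer_series_list,
                                  scale = 1.0, time_tol = 1e-3) {
  stopifnot(inherits(sample_series, "frame_series"))
  if (inherits(buffer_series_list, "frame_series")) {
    buffer_series_list <- list(buffer_series_list)
  }
  if (length(buffer_series_list) < 1L) stop("need at least one buffer series")
  ts <- sample_series$times
  for (bs in buffer_series_list) {
    if (length(bs$times) != length(ts) || any(abs(bs$times - ts) > time_tol)) {
      stop("buffer frame times do not align with sample frame times")
    }
  }
  out <- vector("list", length(ts))
  for (i in seq_along(ts)) {
    sc <- sample_series$curves[[i]]
    bufs <- lapply(buffer_series_list, function(bs) bs$curves[[i]])
    bmean <- average_curves(bufs)
    if (any(bmean$q != sc$q)) stop("buffer and sample q grids differ")
    isub <- sc$intensity - scale * bmean$intensity
    sigma <- NULL
    if (!is.null(sc$sigma) && !is.null(bmean$sigma)) {
      sigma <- sqrt(sc$sigma^2 + (scale * bmean$sigma)^2)
    } else if (!is.null(sc$sigma)) {
      sigma <- sc$sigma
    }
    meta <- sc$meta
    meta$subtracted <- TRUE
    meta$buffer_scale <- scale
    out[[i]] <- scattering_curve(sc$q, isub, sigma = sigma, meta = meta)
  }
  frame_series(out, label = sample_series$label)
}

#' Interpolate a curve onto a target q grid
#'
#' Linear interpolation of intensity (and sigma, when present) in (q, I); no
#' smoothing, so noise statistics are preserved for downstream ratio metrics
#' and fits. Extrapolation beyond the source range is refused.
#'
#' @param curve A [scattering_curve()].
#' @param target_grid Strictly increasing numeric vector inside the source
#'   q range.
#' @return A [scattering_curve()] on `target_grid`.
#' @export
regrid <- function(curve, target_grid) {
  stopifnot(inherits(curve, "scattering_curve"))
  target_grid <- as.numeric(target_grid)
  if (min(target_grid) < min(curve$q) || max(target_grid) > max(curve$q)) {
    stop(sprintf(
      "target grid [%g, %g] extends outside source range [%g, %g]",
      min(target_grid), max(target_grid), min(curve$q), max(curve$q)))
  }
  ii <- stats::approx(curve$q, curve$intensity, xout = target_grid)$y
  sigma <- NULL
  if (!is.null(curve$sigma)) {
    sigma <- stats::approx(curve$q, curve$sigma, xout = target_grid)$y
  }
  scattering_curve(target_grid, ii, sigma = sigma, meta = curve$meta)
}
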