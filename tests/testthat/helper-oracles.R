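# Independent oracles, written as plain arithmetic so they share no code
# paths with the package implementations they check.

# V_R by direct spreadsheet-style evaluation: bin means via explicit loops
vr_oracle <- function(q, ia, ib, window = c(0.015, 0.15), nbins = 25) {
  keep <- q >= window[1] & q <= window[2]
  q <- q[keep]; ia <- ia[keep]; ib <- ib[keep]
  width <- (window[2] - window[1]) / nbins
  ra <- c()
  for (b in seq_len(nbins)) {
    lo <- window[1] + (b - 1) * width
    hi <- window[1] + b * width
    inb <- if (b == nbins) q >= lo & q <= hi else q >= lo & q < hi
    if (!any(inb)) next
    ra <- c(ra, sum(ia[inb]) / sum(inb) / (sum(ib[inb]) / sum(inb)))
  }
  v <- 0
  for (i in seq_len(length(ra) - 1)) {
    v <- v + abs(ra[i + 1] - ra[i]) / ((ra[i + 1] + ra[i]) / 2)
  }
  v
}

# Guinier parameters by zooming grid search minimizing weighted SSE of
# ln I ~ ln i0 - q^2 rg^2 / 3 over the same window as the fit
guinier_grid_oracle <- function(curve, fit) {
  idx <- fit$window_idx
  q2 <- curve$q[idx]^2
  y <- log(curve$intensity[idx])
  w <- if (is.null(curve$sigma)) rep(1, length(idx))
  else (curve$intensity[idx] / curve$sigma[idx])^2
  sse <- function(rg, i0) sum(w * (y - (log(i0) - q2 * rg^2 / 3))^2)
  rg0 <- fit$rg; i00 <- fit$i0
  span <- 0.05
  for (stage in 1:4) {
    rgs <- rg0 * seq(1 - span, 1 + span, length.out = 41)
    i0s <- i00 * seq(1 - span, 1 + span, length.out = 41)
    grid <- expand.grid(rg = rgs, i0 = i0s)
    vals <- mapply(sse, grid$rg, grid$i0)
    best <- grid[which.min(vals), ]
    rg0 <- best$rg; i00 <- best$i0
    span <- span / 10
  }
  list(rg = rg0, i0 = i00)
}

# naive O(n^3) single-linkage agglomeration on a feature matrix
single_linkage_oracle <- function(x, k) {
  n <- nrow(x)
  clusters <- as.list(seq_len(n))
  d <- as.matrix(stats::dist(x))
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        dij <- min(d[clusters[[i]], clusters[[j]]])
        if (dij < best[1]) best <- c(dij, i, j)
      }
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  lab <- integer(n)
  for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
  lab
}

# exhaustive minimal within-cluster SS over all k-partitions (tiny n only)
exhaustive_kmeans_oracle <- function(x, k) {
  n <- nrow(x)
  stopifnot(n <= 12)
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    if (length(unique(assign)) == k) {
      w <- 0
      for (g in unique(assign)) {
        xs <- x[assign == g, , drop = FALSE]
        ctr <- colMeans(xs)
        w <- w + sum(sweep(xs, 2, ctr)^2)
      }
      best <- min(best, w)
    }
    i <- n
    while (i >= 1 && assign[i] == k) { assign[i] <- 1L; i <- i - 1 }
    if (i == 0) break
    assign[i] <- assign[i] + 1L
  }
  best
}

# zooming grid search for C + A exp(-k t) minimizing SSE
exp_grid_oracle <- function(tt, y) {
  sse <- function(k, A, C) sum((y - (C + A * exp(-k * tt)))^2)
  k0 <- 1; A0 <- max(y) - min(y); C0 <- min(y)
  span <- 0.9
  for (stage in 1:5) {
    ks <- k0 * seq(1 - span, 1 + span, length.out = 21)
    As <- A0 * seq(1 - span, 1 + span, length.out = 21)
    Cs <- seq(C0 - span * abs(C0 + 0.1), C0 + span * abs(C0 + 0.1),
              length.out = 21)
    grid <- expand.grid(k = pmax(ks, 1e-6), A = pmax(As, 0), C = Cs)
    vals <- mapply(sse, grid$k, grid$A, grid$C)
    best <- grid[which.min(vals), ]
    k0 <- best$k; A0 <- best$A; C0 <- best$C
    span <- span / 4
  }
  list(k = k0, A = A0, C = C0, sse = sse(k0, A0, C0))
}

# Boltzmann Tm by grid over (Tm, a) with (B, P) solved linearly
boltzmann_grid_oracle <- function(temp, fl) {
  sse_of <- function(tm, a) {
    s <- 1 / (1 + exp((tm - temp) / a))
    fm <- stats::lm(fl ~ s)
    sum(stats::residuals(fm)^2)
  }
  tms <- seq(min(temp) + 2, max(temp) - 2, by = 0.5)
  as <- seq(0.5, 5, by = 0.25)
  grid <- expand.grid(tm = tms, a = as)
  vals <- mapply(sse_of, grid$tm, grid$a)
  best <- grid[which.min(vals), ]
  for (stage in 1:3) {
    tms <- seq(best$tm - 0.5, best$tm + 0.5, length.out = 21)
    as <- seq(max(best$a - 0.25, 0.05), best$a + 0.25, length.out = 21)
    grid <- expand.grid(tm = tms, a = as)
    vals <- mapply(sse_of, grid$tm, grid$a)
    best <- grid[which.min(vals), ]
  }
  best$tm
}

# one-site Kd by log-grid with (R0, dR) solved linearly
one_site_grid_oracle <- function(conc, resp) {
  sse_of <- function(kd) {
    f <- conc / (kd + conc)
    fm <- stats::lm(resp ~ f)
    sum(stats::residuals(fm)^2)
  }
  kds <- 10^seq(log10(min(conc) / 10), log10(max(conc) * 10),
                length.out = 400)
  vals <- vapply(kds, sse_of, numeric(1))
  kd <- kds[which.min(vals)]
  for (stage in 1:3) {
    kds <- kd * 10^seq(-0.05, 0.05, length.out = 41)
    vals <- vapply(kds, sse_of, numeric(1))
    kd <- kds[which.min(vals)]
  }
  kd
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# shared default-plate screen, computed once per test session
.screen_cache <- new.env(parent = emptyenv())
default_screen <- function(seed = 42) {
  key <- paste0("s", seed)
  if (is.null(.screen_cache[[key]])) {
    cfg <- sim_config(seed = seed)
    plate <- simulate_screen_plate(config = cfg)
    .screen_cache[[key]] <- list(plate = plate,
                                 report = run_screen(plate, seed = seed))
  }
  .screen_cache[[key]]
}

# convenience fixture: exact Guinier-law (Gaussian) scattering curve
gaussian_curve <- function(rg = 30, i0 = 100,
                           q = seq(0.005, 0.06, length.out = 40),
                           sigma = NULL) {
  scattering_curve(q, i0 * exp(-q^2 * rg^2 / 3), sigma = sigma)
}
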