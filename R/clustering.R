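#' Coerce clustering input to a labeled feature matrix
#' @noRd
as_feature_matrix <- function(features) {
  if (inherits(features, "similarity_matrix")) {
    features <- unclass(features)
  }
  if (is.data.frame(features)) features <- as.matrix(features)
  if (is.null(dim(features))) {
    features <- matrix(as.numeric(features), ncol = 1L,
                       dimnames = list(names(features), NULL))
  }
  if (is.null(rownames(features))) {
    rownames(features) <- paste0("item", seq_len(nrow(features)))
  }
  if (!all(is.finite(features))) stop("feature values must be finite")
  features
}

#' Single-linkage agglomerative hierarchical clustering
#'
#' Euclidean distances between feature vectors (e.g. SSM rows: each sample's
#' V_R profile against all samples) agglomerated by minimum inter-cluster
#' distance via [stats::hclust()]. Items enter in label order, making merges
#' deterministic under distance ties.
#'
#' @param features Numeric matrix (rows = items) or vector; a
#'   [similarity_matrix()] is clustered by its rows.
#' @param k Number of clusters to cut to, or
#' @param height Dendrogram cut height (one of `k`/`height` required).
#' @return A `cluster_assignment`: `cluster` (named integer vector with
#'   contiguous ids from 1), `method` metadata, and `tree` (the hclust object).
#' @export
single_linkage_cluster <- function(features, k = NULL, height = NULL) {
  x <- as_feature_matrix(features)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 items")
  if (!is.null(k) && k > n) stop("k cannot exceed the number of items")
  tree <- stats::hclust(stats::dist(x, method = "euclidean"),
                        method = "single")
  if (is.null(k) && is.null(height)) stop("supply k or height")
  raw <- if (!is.null(k)) stats::cutree(tree, k = k)
  else stats::cutree(tree, h = height)
  cl <- match(raw, unique(raw)) # contiguous ids in label order
  names(cl) <- rownames(x)
  structure(list(cluster = cl,
                 method = list(algorithm = "single-linkage AHC",
                               k = length(unique(cl)), linkage = "single"),
                 tree = tree),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %s, k = %d\n", x$method$algorithm,
              x$method$k))
  print(x$cluster)
  invisible(x)
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k > 1L) {
    d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        idx <- sample.int(n, 1L)
      } else {
        idx <- sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  centers
}

#' k-means clustering with k-means++ restarts
#'
#' Lloyd iterations from k-means++ initial centers, keeping the best of
#' `restarts` runs by total within-cluster sum of squares. Deterministic for a
#' fixed `seed`; restarts that collapse to an empty cluster are re-seeded.
#'
#' @param features Numeric matrix/vector or [similarity_matrix()].
#' @param k Number of clusters (<= number of items).
#' @param restarts Number of random restarts (default 50).
#' @param seed Integer RNG seed.
#' @return A `cluster_assignment` with `wss` (total within-cluster SS) and the
#'   fitted centers in `method`.
#' @export
kmeans_cluster <- function(features, k, restarts = 50, seed = 1) {
  x <- as_feature_matrix(features)
  n <- nrow(x)
  if (k > n) stop("k cannot exceed the number of items")
  if (k == 1L) {
    cl <- stats::setNames(rep(1L, n), rownames(x))
    return(structure(list(cluster = cl,
                          wss = sum(sweep(x, 2, colMeans(x))^2),
                          method = list(algorithm = "k-means (k = 1)", k = 1L,
                                        seed = seed, restarts = restarts)),
                     class = "cluster_assignment"))
  }
  n_distinct <- nrow(unique(x))
  if (n_distinct <= k) {
    # degenerate: fewer distinct points than clusters; assign by value
    uni <- unique(x)
    cl <- match(apply(x, 1L, paste, collapse = "\r"),
                apply(uni, 1L, paste, collapse = "\r"))
    names(cl) <- rownames(x)
    return(structure(list(cluster = cl, wss = 0,
                          method = list(algorithm = "k-means (degenerate)",
                                        k = n_distinct, seed = seed,
                                        restarts = restarts)),
                     class = "cluster_assignment"))
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    km <- NULL
    for (attempt in 1:10) {
      centers <- kmeanspp_centers(x, k)
      if (anyDuplicated(centers)) next
      km <- tryCatch(
        stats::kmeans(x, centers = centers, iter.max = 100,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(km) && !any(km$size == 0)) break
      km <- NULL
    }
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed for every restart")
  cl <- match(best$cluster, unique(best$cluster))
  names(cl) <- rownames(x)
  structure(list(cluster = cl, wss = best$tot.withinss,
                 method = list(algorithm = "k-means (Lloyd, k-means++ init)",
                               k = k, seed = seed, restarts = restarts,
                               centers = best$centers)),
            class = "cluster_assignment")
}

#' Krzanowski-Lai scan for the optimal k-means cluster number
#'
#' Runs [kmeans_cluster()] for k = 1..kmax and evaluates
#' \eqn{DIFF_k = (k-1)^{2/p} W_{k-1} - k^{2/p} W_k} and
#' \eqn{KL(k) = |DIFF_k / DIFF_{k+1}|} (p = feature dimension); the chosen k
#' maximizes KL over 2..kmax-1, ties resolved toward the smaller k.
#'
#' @param features Numeric matrix/vector or [similarity_matrix()].
#' @param kmax Largest candidate k (>= 3, <= n-1; default 8).
#' @param restarts,seed Passed to [kmeans_cluster()].
#' @return A `cluster_scan` data.frame (`k`, `wss`, `diff`, `kl`) with
#'   attributes `chosen_k`, `rule = "krzanowski-lai"`, `low_confidence`.
#' @export
kl_select_k <- function(features, kmax = 8, restarts = 50, seed = 1) {
  x <- as_feature_matrix(features)
  n <- nrow(x)
  kmax <- min(kmax, n - 1L)
  if (kmax < 3L) stop("kmax must be >= 3 (and <= n - 1)")
  p <- ncol(x)
  wss <- numeric(kmax)
  for (k in seq_len(kmax)) {
    wss[k] <- if (k == 1L) sum(scale(x, scale = FALSE)^2)
    else kmeans_cluster(x, k, restarts = restarts, seed = seed + k)$wss
  }
  ks <- seq_len(kmax)
  diffs <- c(NA_real_,
             (ks[-1] - 1)^(2 / p) * wss[ks[-1] - 1] - ks[-1]^(2 / p) * wss[-1])
  kl <- rep(NA_real_, kmax)
  low_conf <- FALSE
  for (k in 2:(kmax - 1L)) {
    if (is.na(diffs[k + 1L]) || diffs[k + 1L] == 0) {
      warning(sprintf("KL undefined at k = %d (DIFF_{k+1} = 0)", k))
      low_conf <- TRUE
      next
    }
    kl[k] <- abs(diffs[k] / diffs[k + 1L])
  }
  if (all(is.na(kl))) {
    warning("KL index undefined at every candidate k; defaulting to k = 2")
    chosen <- 2L
    low_conf <- TRUE
  } else {
    chosen <- which.max(kl) # ties: which.max takes the first (smallest k)
  }
  structure(data.frame(k = ks, wss = wss, diff = diffs, kl = kl),
            chosen_k = as.integer(chosen), rule = "krzanowski-lai",
            low_confidence = low_conf,
            class = c("cluster_scan", "data.frame"))
}

#' Elbow selection of the k-means cluster number
#'
#' Given total within-cluster sums of squares for k = 1..kmax, picks the
#' interior k maximizing the second difference
#' \eqn{(W_{k-1} - W_k) - (W_k - W_{k+1})}; ties go to the smallest k.
#'
#' @param wss_by_k Numeric vector of W_k for k = 1..kmax (kmax >= 3).
#' @return Chosen k (integer).
#' @export
elbow_select_k <- function(wss_by_k) {
  kmax <- length(wss_by_k)
  if (kmax < 3L) stop("need W_k for at least k = 1..3")
  if (any(diff(wss_by_k) > 0)) {
    warning("W_k is not non-increasing in k; proceeding anyway")
  }
  interior <- 2:(kmax - 1L)
  second_diff <- (wss_by_k[interior - 1L] - wss_by_k[interior]) -
    (wss_by_k[interior] - wss_by_k[interior + 1L])
  as.integer(interior[which.max(second_diff)])
}
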