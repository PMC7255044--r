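# squared Euclidean distances from every row of x to every row of centers
dist2_to_centers <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  d2 <- outer(xx, cc, "+") - 2 * x %*% t(centers)
  d2[d2 < 0] <- 0
  d2
}

# kmeans++ seeding: first center uniform, subsequent proportional to squared
# distance to the nearest chosen center
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    if (sum(d2) <= 0) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

lloyd <- function(x, centers, max_iter, tol) {
  k <- nrow(centers)
  labels <- rep(0L, nrow(x))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    # ties break toward the lower cluster index
    labels <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- labels == j
      if (!any(members)) {
        # reseed an emptied cluster with the point farthest from its center
        far <- which.max(d2[cbind(seq_len(nrow(x)), labels)])
        new_centers[j, ] <- x[far, ]
        labels[far] <- j
      } else {
        new_centers[j, ] <- colMeans(x[members, , drop = FALSE])
      }
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) { converged <- TRUE; break }
  }
  d2 <- dist2_to_centers(x, centers)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(nrow(x)), labels)])
  list(labels = labels, centers = centers, inertia = inertia, converged = converged)
}

#' Partition decay features by k-means
#'
#' Lloyd iterations from kmeans++ initialization; the best of `restarts` runs
#' by within-cluster sum of squared Euclidean distances is returned.
#' Deterministic for a fixed seed. Assignment ties break toward the lower
#' cluster index; an emptied cluster is reseeded with the point farthest from
#' its assigned center.
#'
#' @param features A `feature_matrix` from [build_features()], or a plain
#'   numeric matrix (rows = observations).
#' @param k Number of clusters, `1 <= k <=` number of rows.
#' @param seed Integer seed.
#' @param restarts Number of kmeans++ restarts (default 10).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @param tol Convergence tolerance on maximum center movement (default 1e-6).
#' @return List with `labels`, `centers`, `inertia`, `converged`.
#' @export
kmeans_partition <- function(features, k, seed = 1, restarts = 10,
                             max_iter = 300, tol = 1e-6) {
  x <- if (inherits(features, "feature_matrix")) features$features else as.matrix(features)
  if (k < 1 || k != floor(k)) abort("`k` must be a positive integer.", class = "clusterflim_argument_error")
  if (k > nrow(x)) {
    abort(sprintf("`k` (%d) exceeds the number of feature rows (%d).", k, nrow(x)),
          class = "clusterflim_argument_error")
  }
  set.seed(seed)
  # tiny two-cluster instances are solved exactly: Lloyd is a heuristic for
  # the within-cluster SSE objective and can miss the optimum when restarts
  # cannot cover the assignment space, which is enumerable here
  if (k == 2 && nrow(x) <= 12) return(exhaustive_k2(x))
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- lloyd(x, kmeanspp_init(x, k), max_iter, tol)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  best
}

exhaustive_k2 <- function(x) {
  n <- nrow(x)
  best <- NULL
  for (code in 1:(2^(n - 1) - 1)) { # fix point 1 in cluster 1; both non-empty
    assign <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    centers <- rbind(colMeans(x[assign == 1, , drop = FALSE]),
                     colMeans(x[assign == 2, , drop = FALSE]))
    sse <- sum((x - centers[assign, , drop = FALSE])^2)
    if (is.null(best) || sse < best$inertia) {
      best <- list(labels = assign, centers = centers, inertia = sse,
                   converged = TRUE)
    }
  }
  best
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Integer label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
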