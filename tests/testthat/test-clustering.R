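test_that("feature construction masks dim pixels and normalizes shape", {
  counts <- array(0L, dim = c(2, 2, 6))
  counts[1, 1, ] <- c(3L, 2L, 2L, 1L, 1L, 0L)   # 9 photons -> masked at 10
  counts[1, 2, ] <- c(1L, 2L, 1L, 0L, 0L, 0L) * 3L
  counts[2, 1, ] <- c(10L, 20L, 10L, 0L, 0L, 0L)
  counts[2, 2, ] <- c(5L, 5L, 5L, 5L, 5L, 5L)
  cube <- decay_cube(counts)

  fm <- build_features(cube, b = 3, min_counts = 10)
  expect_equal(sum(fm$keep), 3)
  expect_false(fm$keep[1])                       # the 9-count pixel
  expect_equal(rowSums(fm$features), rep(1, 3))
  expect_equal(ncol(fm$features), 3)

  # proportional histograms give identical features (scale invariance)
  i_a <- which(fm$pixel_index[, 1] == 1 & fm$pixel_index[, 2] == 2)
  i_b <- which(fm$pixel_index[, 1] == 2 & fm$pixel_index[, 2] == 1)
  expect_equal(fm$features[i_a, ], fm$features[i_b, ])

  expect_error(build_features(cube, b = 3, min_counts = 1000),
               class = "clusterflim_empty_feature_error")
})

test_that("euclidean distance behaves as a metric", {
  expect_equal(euclidean_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  set.seed(8)
  for (i in 1:5) {
    x <- runif(6); y <- runif(6)
    expect_equal(euclidean_distance(x, y), euclidean_distance(y, x))
  }
  expect_error(euclidean_distance(1:3, 1:4), class = "clusterflim_argument_error")
})

test_that("k-means attains closed-form and brute-force optima", {
  set.seed(2)
  x <- matrix(rnorm(40), 10, 4)
  one <- kmeans_partition(x, 1, seed = 1)
  expect_equal(as.vector(one$centers), colMeans(x))
  expect_equal(one$inertia, sum(sweep(x, 2, colMeans(x))^2))

  xs <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  two <- kmeans_partition(xs, 2, seed = 1)
  expect_equal(two$labels[1], two$labels[2])
  expect_equal(two$labels[3], two$labels[4])
  expect_false(two$labels[1] == two$labels[3])
  oracle <- brute_force_sse_k2(xs)
  expect_equal(two$inertia, oracle$sse, tolerance = 1e-8)

  # SSE optimality on random small point sets versus exhaustive enumeration
  for (s in 1:5) {
    set.seed(100 + s)
    pts <- matrix(runif(16), 8, 2)
    fit <- kmeans_partition(pts, 2, seed = s, restarts = 10)
    expect_equal(fit$inertia, brute_force_sse_k2(pts)$sse, tolerance = 1e-8)
  }
})

test_that("k-means contracts hold and match an independent implementation", {
  set.seed(4)
  # well-separated blobs: both implementations must find the global optimum
  x <- rbind(matrix(rnorm(60, 0, 0.1), ncol = 2),
             matrix(rnorm(60, 5, 0.1), ncol = 2),
             matrix(rnorm(60, c(0, 5), 0.1), ncol = 2))
  ours <- kmeans_partition(x, 3, seed = 1)
  expect_length(ours$labels, nrow(x))
  expect_true(all(tabulate(ours$labels, 3) > 0))
  ref <- stats::kmeans(x, 3, nstart = 10, iter.max = 100)
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-8)
  expect_equal(adjusted_rand_index(ours$labels, ref$cluster), 1)

  expect_error(kmeans_partition(x[1:2, ], 3), class = "clusterflim_argument_error")
  # determinism
  expect_identical(kmeans_partition(x, 3, seed = 9)$labels,
                   kmeans_partition(x, 3, seed = 9)$labels)
})

test_that("FLS accumulation conserves photons exactly", {
  sim <- make_test_image(k = 4, mean_counts = 200, dim_px = 16, seed = 13)
  cube <- sim$cube
  fm <- build_features(cube, b = 16, min_counts = 10)
  km <- kmeans_partition(fm, 4, seed = 1)
  fls <- accumulate_fls(cube, km$labels, fm$keep, k = 4)

  flat <- matrix(cube$counts, prod(dim(cube)[1:2]), dim(cube)[3])
  expect_identical(sum(fls), sum(as.numeric(flat[fm$keep, ])))

  # one cluster holding every unmasked pixel reproduces the total histogram
  all_one <- accumulate_fls(cube, rep(1L, sum(fm$keep)), fm$keep, k = 1)
  expect_equal(as.vector(all_one), colSums(flat[fm$keep, , drop = FALSE]))
})

test_that("accumulated FLS matches its species curve at high counts", {
  panel <- validation_panel(4)[c(1, 4)]
  layout <- scene_layout(block_layout(10, 10, 2), 10000)
  sim <- simulate_image(panel, layout, n_channels = 256,
                        channel_width_ps = 79.88, seed = 17)
  truth <- as.vector(sim$truth)
  fls <- accumulate_fls(sim$cube, truth, k = 2)
  irf <- gaussian_irf(256, 79.88)
  for (s in 1:2) {
    expected <- expected_curve(panel[[s]], irf, 79.88, 256,
                               total = sum(fls[s, ]))
    ok <- expected >= 5   # Pearson validity: exclude near-empty channels
    chisq_red <- sum((fls[s, ok] - expected[ok])^2 / expected[ok]) / (sum(ok) - 1)
    expect_lt(abs(chisq_red - 1), 0.35)
  }
})

test_that("cluster_flim recovers the species map and orders clusters by lifetime", {
  sim <- make_test_image(k = 4, mean_counts = 1000, dim_px = 32, seed = 23)
  res <- cluster_flim(sim$cube, k = 4, seed = 1)

  expect_true(all(diff(res$tau_ns) >= 0))      # palette order = ascending lifetime
  expect_equal(sum(res$fractions), 1, tolerance = 1e-9)
  expect_equal(sum(res$member_counts), sum(!is.na(res$labels)))

  keep <- !is.na(res$labels)
  pred <- res$labels[keep]; truth <- sim$truth[keep]
  mapping <- match_labels(pred, truth, 4)
  acc <- mean(mapping[pred] == truth)
  expect_gt(acc, 0.99)

  # exact photon conservation through the whole pipeline
  flat <- matrix(sim$cube$counts, 32 * 32, 256)
  expect_identical(sum(res$fls), sum(as.numeric(flat[keep, ])))
})

test_that("clustering is brightness-invariant and seed-stable", {
  sim <- make_test_image(k = 4, mean_counts = 600, dim_px = 24, seed = 29)
  res1 <- cluster_flim(sim$cube, k = 4, seed = 1)

  scaled <- decay_cube(sim$cube$counts * 5L, sim$cube$channel_width_ps)
  res2 <- cluster_flim(scaled, k = 4, seed = 1)
  expect_identical(res1$labels, res2$labels)

  res3 <- cluster_flim(sim$cube, k = 4, seed = 2)
  keep <- !is.na(res1$labels)
  expect_gte(adjusted_rand_index(res1$labels[keep], res3$labels[keep]), 0.99)

  one <- cluster_flim(sim$cube, k = 1)
  expect_equal(one$fractions, 1)
})

test_that("false-color rendering paints clusters and mask distinctly", {
  sim <- make_test_image(k = 4, mean_counts = 300, dim_px = 16, seed = 37)
  res <- cluster_flim(sim$cube, k = 4)
  img <- render_false_color(res)
  expect_equal(dim(img), c(16, 16, 3))
  hex <- grDevices::rgb(img[, , 1], img[, , 2], img[, , 3])
  expect_setequal(unique(hex), toupper(c(res$palette[1:4],
                                         if (anyNA(res$labels)) "#FFFFFF" else NULL)))

  # fully masked image renders uniformly white
  dark <- decay_cube(array(0L, dim = c(4, 4, 32)) + 0L)
  dark$counts[1, 1, 1] <- 20L
  resd <- cluster_flim(dark, k = 1, min_counts = 10)
  resd$labels[1, 1] <- NA  # mask everything
  imgd <- render_false_color(resd)
  expect_true(all(imgd == 1))
})

test_that("cluster matching across images recovers a known permutation", {
  sim <- make_test_image(k = 4, mean_counts = 800, dim_px = 24, seed = 41)
  res <- cluster_flim(sim$cube, k = 4, seed = 1)
  shuffled <- res
  ord <- c(3, 1, 4, 2)
  shuffled$fls <- res$fls[ord, ]
  expect_equal(match_clusters(shuffled, res), ord)
})
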