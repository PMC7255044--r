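# independent oracles used across tests; deliberately naive implementations

# exhaustive k=2 partition search: minimal SSE over all assignments with two
# non-empty clusters
brute_force_sse_k2 <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  best <- Inf
  best_assign <- NULL
  for (code in 1:(2^n - 2)) {
    assign <- as.integer(intToBits(code))[1:n] + 1L
    if (length(unique(assign)) < 2) next
    sse <- 0
    for (g in 1:2) {
      xs <- x[assign == g, , drop = FALSE]
      ctr <- colMeans(xs)
      sse <- sse + sum(sweep(xs, 2, ctr)^2)
    }
    if (sse < best) { best <- sse; best_assign <- assign }
  }
  list(sse = best, assign = best_assign)
}

# exhaustive best one-to-one label mapping by total diagonal count
brute_force_mapping <- function(pred, truth, k) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  tab <- table(factor(pred, 1:k), factor(truth, 1:k))
  best <- NULL; bestv <- -1
  for (p in perms(seq_len(k))) {
    v <- sum(tab[cbind(seq_len(k), p)])
    if (v > bestv) { bestv <- v; best <- p }
  }
  best
}

# two-histogram chi-squared homogeneity test (pooled-bin expected counts)
chisq_two_hist_p <- function(a, b, min_expected = 5) {
  keep <- (a + b) > 0
  a <- a[keep]; b <- b[keep]
  # pool sparse channels so expected counts stay reasonable
  grp <- cumsum(c(1, (cumsum(a + b)[-length(a)] %/% (min_expected * 4)) * 0 + 0))
  tot <- a + b
  pool <- integer(length(a)); g <- 1; acc <- 0
  for (i in seq_along(a)) {
    pool[i] <- g
    acc <- acc + tot[i]
    if (acc >= min_expected * 4) { g <- g + 1; acc <- 0 }
  }
  a <- tapply(a, pool, sum); b <- tapply(b, pool, sum)
  suppressWarnings(stats::chisq.test(rbind(a, b))$p.value)
}

# small simulated image shared by clustering tests (kept modest for speed)
make_test_image <- function(k = 4, mean_counts = 800, dim_px = 32,
                            n_channels = 256, seed = 7) {
  panel <- validation_panel(k)
  layout <- scene_layout(block_layout(dim_px, dim_px, k), mean_counts)
  simulate_image(panel, layout, n_channels = n_channels,
                 channel_width_ps = 19.97 * 1024 / n_channels, seed = seed)
}
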