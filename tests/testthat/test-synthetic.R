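test_that("gaussian IRF is normalized, centred, and has the requested width", {
  irf <- gaussian_irf(1024, 19.97, t0_ps = 1000, fwhm_ps = 100)
  expect_equal(sum(irf$vector), 1, tolerance = 1e-9)

  narrow <- gaussian_irf(256, 50, t0_ps = 1234, fwhm_ps = 1)
  expect_equal(which.max(narrow$vector), floor(1234 / 50) + 1)

  # width oracle: FWHM measured on a 10x-oversampled reconstruction
  fine_dt <- 19.97 / 10
  fine <- gaussian_irf(10240, fine_dt, t0_ps = 5000, fwhm_ps = 100)
  v <- fine$vector
  half <- max(v) / 2
  above <- which(v >= half)
  measured <- (max(above) - min(above) + 1) * fine_dt
  expect_equal(measured, 100, tolerance = 0.02)

  expect_error(gaussian_irf(256, 19.97, fwhm_ps = 0), class = "clusterflim_argument_error")
})

test_that("expected_curve matches the closed-form decay and is linear", {
  # effectively delta IRF at t = 0, single tau = 1 ns, dt = 0.02 ns
  irf <- gaussian_irf(200, 20, t0_ps = 0.5, fwhm_ps = 1e-3)
  mono <- species_def("m", 1, 1)
  curve <- expected_curve(mono, irf, 20, 200, total = 1e6)
  ratios <- curve[-1] / curve[-length(curve)]
  expect_equal(ratios, rep(exp(-0.02), 199), tolerance = 1e-6)

  flat <- expected_curve(mono, irf, 20, 200, total = 0, background = 0.5)
  expect_equal(flat, rep(0.5, 200))

  # biexponential curve is the amplitude-weighted sum of monoexponential
  # curves (window long enough that tail truncation is negligible)
  irf2 <- gaussian_irf(2048, 19.97, t0_ps = 1000, fwhm_ps = 100)
  s1 <- species_def("a", 1, 0.5)
  s2 <- species_def("b", 1, 2.5)
  mix <- species_def("ab", c(0.3, 0.7), c(0.5, 2.5))
  # weight by photon contribution: component photons scale with alpha * tau
  w <- c(0.3 * 0.5, 0.7 * 2.5); w <- w / sum(w)
  combo <- w[1] * expected_curve(s1, irf2, 19.97, 2048, 1000) +
    w[2] * expected_curve(s2, irf2, 19.97, 2048, 1000)
  expect_equal(expected_curve(mix, irf2, 19.97, 2048, 1000), combo, tolerance = 1e-5)
})

test_that("simulate_pixel draws reproducible Poisson counts with the right mean", {
  expect_equal(simulate_pixel(rep(0, 50)), rep(0L, 50) * 0)
  expect_identical(simulate_pixel(rep(2.5, 100), seed = 42),
                   simulate_pixel(rep(2.5, 100), seed = 42))
  expect_error(simulate_pixel(c(1, -1)), class = "clusterflim_argument_error")

  curve <- c(5, 3, 2, 1, 0.5)
  set.seed(99)
  totals <- replicate(10000, sum(rpois(length(curve), curve)))
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - sum(curve)), 3 * se)
})

test_that("simulate_image returns the layout as truth with the right photon budget", {
  panel <- validation_panel(4)
  layout <- scene_layout(block_layout(20, 20, 4), mean_counts = 300,
                         background_rate = 0.05)
  sim <- simulate_image(panel, layout, n_channels = 256,
                        channel_width_ps = 79.88, seed = 21)
  expect_identical(sim$truth, layout$label_map)

  totals <- as.numeric(intensity_image(sim$cube))
  expected_mean <- 300 + 0.05 * 256
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - expected_mean), 4 * se)

  # determinism
  sim2 <- simulate_image(panel, layout, n_channels = 256,
                         channel_width_ps = 79.88, seed = 21)
  expect_identical(sim$cube$counts, sim2$cube$counts)

  bad <- scene_layout(matrix(9L, 4, 4), 100)
  expect_error(simulate_image(panel, bad, n_channels = 64),
               class = "clusterflim_validation_error")
})

test_that("same-species pixels agree within Poisson error at high counts", {
  panel <- validation_panel(4)[2]
  layout <- scene_layout(matrix(1L, 3, 3), mean_counts = 10000)
  sim <- simulate_image(panel, layout, n_channels = 256,
                        channel_width_ps = 79.88, seed = 31)
  flat <- matrix(sim$cube$counts, 9, 256)
  pairs <- utils::combn(9, 2)
  pvals <- apply(pairs, 2, function(ij) chisq_two_hist_p(flat[ij[1], ], flat[ij[2], ]))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("validation panel spans the documented mean-lifetime range", {
  p5 <- validation_panel(5)
  expect_length(p5, 5)
  means5 <- vapply(p5, tau_mean_amplitude, numeric(1))
  expect_equal(min(means5), 0.20, tolerance = 1e-12)
  expect_equal(max(means5), 1.53, tolerance = 1e-12)
  expect_equal(diff(means5), rep((1.53 - 0.20) / 4, 4), tolerance = 1e-12)

  p4 <- validation_panel(4)
  means4 <- vapply(p4, tau_mean_amplitude, numeric(1))
  expect_equal(means4[1], 0.20, tolerance = 1e-12)
  expect_equal(means4[4], 1.53, tolerance = 1e-12)
  expect_equal(diff(means4), rep((1.53 - 0.20) / 3, 3), tolerance = 1e-12)

  for (s in p5) expect_equal(sum(s$amplitudes), 1, tolerance = 1e-9)
  expect_error(validation_panel(3), class = "clusterflim_argument_error")
})
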