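test_that("the four-pool derivatives conserve mass and respect limits", {
  taus <- c(8, 28, 88, 107)
  set.seed(44)
  for (i in 1:5) {
    s <- runif(4); s <- s / sum(s)
    expect_equal(sum(kinetic_rhs(s, taus)), 0, tolerance = 1e-12)
  }
  expect_equal(kinetic_rhs(c(0, 0, 0, 1), taus), rep(0, 4))
  expect_equal(kinetic_rhs(c(0.4, 0.3, 0.2, 0.1), rep(1e12, 4)), rep(0, 4),
               tolerance = 1e-12)
  expect_error(kinetic_rhs(c(1, 0, 0, 0), c(1, -1, 1, 1)),
               class = "clusterflim_argument_error")
})

test_that("trajectories start at y0, stay conservative, and are absorbed in the red pool", {
  taus <- c(8, 28, 88, 107)
  tr <- simulate_kinetics(taus, times = c(0, 15, 45, 90, 180, 270))
  expect_equal(unlist(tr[1, -1]), c(c_pm = 1, y_pm = 0, y_cp = 0, r_cp = 0))
  sums <- rowSums(tr[, -1])
  expect_equal(sums, rep(1, nrow(tr)), tolerance = 1e-10)

  late <- simulate_kinetics(taus, times = 1e5)
  expect_equal(late$r_cp, 1, tolerance = 1e-6)
})

test_that("matrix-exponential and numeric ODE solutions agree to 1e-8", {
  taus <- c(8, 28, 88, 107)
  times <- c(0, 5, 15, 45, 90, 180, 270, 500)
  a <- simulate_kinetics(taus, times = times, method = "expm")
  b <- simulate_kinetics(taus, times = times, method = "ode")
  expect_equal(as.matrix(a[, -1]), as.matrix(b[, -1]), tolerance = 1e-8)
})

test_that("noiseless trajectories return the generating time constants within 1%", {
  taus <- c(8, 28, 88, 107)
  tr <- simulate_kinetics(taus, times = c(15, 45, 90, 180, 270))
  obs <- tibble::tibble(time_min = tr$time_min, cyan = tr$c_pm,
                        yellow = tr$y_pm + tr$y_cp, red = tr$r_cp)
  fit <- fit_kinetics(obs)
  expect_equal(unname(fit$taus), taus, tolerance = 0.01)
  expect_true(fit$converged)
})

test_that("identifiability diagnostics surface the weak back-transition", {
  taus <- c(8, 28, 88, 107)
  times <- c(15, 45, 90, 180, 270)
  tr <- simulate_kinetics(taus, times = times)
  clean <- cbind(tr$c_pm, tr$y_pm + tr$y_cp, tr$r_cp)
  set.seed(66)
  rel_se <- replicate(8, {
    noisy <- pmin(pmax(clean * (1 + rnorm(length(clean), 0, 0.05)), 0), 1)
    obs <- tibble::tibble(time_min = times, cyan = noisy[, 1],
                          yellow = noisy[, 2], red = noisy[, 3])
    fit <- fit_kinetics(obs)
    expect_true(all(fit$taus > 0))
    expect_true(all(is.finite(fit$se)))
    fit$se / fit$taus
  })
  med <- apply(rel_se, 1, median)
  # the back transition is less well determined than the forward binding step
  expect_gt(med[["tau_m1"]], med[["tau1"]])

  flat <- tibble::tibble(time_min = c(15, 45, 90, 180), cyan = 0.5,
                         yellow = 0.3, red = 0.2)
  expect_error(fit_kinetics(flat), class = "clusterflim_fit_error")
  ok <- tibble::tibble(time_min = times, cyan = tr$c_pm,
                       yellow = tr$y_pm + tr$y_cp, red = tr$r_cp)
  expect_error(fit_kinetics(ok[1:3, ]), class = "clusterflim_argument_error")
})

test_that("saturation uptake fits recover exact curves and obey the half-max identity", {
  conc <- c(0.25, 0.5, 1, 2, 5, 10, 25)
  ints <- 100 * conc / (2 + conc)
  fit <- fit_saturation(conc, ints)
  expect_equal(fit$I_max, 100, tolerance = 1e-6)
  expect_equal(fit$K50, 2, tolerance = 1e-6)
  expect_equal(predict(fit, fit$K50), fit$I_max / 2)
  expect_equal(predict(fit, 0), 0)
  expect_error(fit_saturation(conc, rep(5, 7)), class = "clusterflim_fit_error")
})

test_that("Hill displacement fits recover exact curves and the half-max identity", {
  conc <- exp(seq(log(10), log(10000), length.out = 10))
  hill <- function(c, amax, amin, k, n) amax + (amin - amax) * c^n / (k^n + c^n)
  areas <- hill(conc, 1, 0.1, 200, 1.5)
  fit <- fit_displacement_hill(conc, areas)
  expect_equal(fit$A_max, 1, tolerance = 1e-6)
  expect_equal(fit$A_min, 0.1, tolerance = 1e-6)
  expect_equal(fit$K50, 200, tolerance = 1e-4)
  expect_equal(fit$n_hill, 1.5, tolerance = 1e-5)
  expect_equal(predict(fit, fit$K50), (fit$A_max + fit$A_min) / 2, tolerance = 1e-9)

  # hyperbolic data (n = 1) at 1% noise returns a Hill coefficient near 1
  set.seed(10)
  noisy <- hill(conc, 1, 0.1, 300, 1) * (1 + rnorm(10, 0, 0.01))
  fitn <- fit_displacement_hill(conc, noisy)
  expect_lt(abs(fitn$n_hill - 1), 0.05)
})
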