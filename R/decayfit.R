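#' Background level of an accumulated FLS
#'
#' Mean counts per channel over a pre-pulse window, i.e. channels recorded
#' before the IRF rise. Defaults to the first 3% of channels.
#'
#' @param fls Integer decay histogram.
#' @param window Integer channel indices of the pre-pulse window.
#' @return Background counts per channel.
#' @export
estimate_background <- function(fls, window = NULL) {
  if (is.null(window)) window <- seq_len(max(1, floor(0.03 * length(fls))))
  if (length(window) == 0) abort("Empty background window.", class = "clusterflim_argument_error")
  mean(fls[window])
}

#' Amplitude- and component-weighted mean lifetimes
#'
#' Closed-form evaluation of the standard mean-lifetime definitions for a
#' multi-exponential decay `I(t) = sum_i alpha_i exp(-t / tau_i)`:
#' the amplitude-weighted mean `tau_m,a = sum_i alpha_i tau_i`, the
#' fractional (intensity) amplitudes `beta_i = alpha_i tau_i / sum_j alpha_j
#' tau_j`, and the component-weighted mean `tau_m = sum_i beta_i tau_i`.
#' Amplitudes are renormalized to sum 1 internally.
#'
#' @param amplitudes Amplitudes `alpha_i` (non-negative).
#' @param lifetimes Lifetimes `tau_i` in ns (positive).
#' @return List with `tau_m_a`, `betas`, `tau_m`.
#' @examples
#' mean_lifetimes(c(0.5, 0.5), c(1, 3)) # tau_m_a = 2, betas = (0.25, 0.75), tau_m = 2.5
#' @export
mean_lifetimes <- function(amplitudes, lifetimes) {
  if (any(lifetimes <= 0)) abort("All lifetimes must be positive.", class = "clusterflim_argument_error")
  if (any(amplitudes < 0) || sum(amplitudes) <= 0) {
    abort("Amplitudes must be non-negative with positive sum.", class = "clusterflim_argument_error")
  }
  a <- amplitudes / sum(amplitudes)
  betas <- a * lifetimes / sum(a * lifetimes)
  list(tau_m_a = sum(a * lifetimes), betas = betas, tau_m = sum(betas * lifetimes))
}

# unit-area basis curve for a monoexponential lifetime under the IRF
basis_curve <- function(tau_ns, irf, channel_width_ps, n_channels) {
  t_ns <- (seq_len(n_channels) - 0.5) * channel_width_ps / 1000
  d <- exp(-t_ns / tau_ns)
  conv <- convolve(irf$vector, rev(d), type = "open")[seq_len(n_channels)]
  conv[conv < 0] <- 0
  conv / sum(conv)
}

# Poisson negative log-likelihood of mu against counts x (constants dropped)
poisson_nll <- function(x, mu) {
  mu <- pmax(mu, 1e-12)
  sum(mu) - sum(x * log(mu))
}

#' Fit a multi-exponential decay model to an FLS
#'
#' Deconvolution fit of `n` exponential components against an accumulated
#' fluorescence lifetime signature, maximizing the Poisson likelihood of the
#' IRF-convolved model plus background (FLS channels span several decades of
#' counts, so unweighted least squares would be biased in the tail).
#' Components are parameterized by lifetime and component photon count; the
#' decay amplitudes `alpha_i` and the derived mean lifetimes follow in closed
#' form. Multi-start over a decade-spaced lifetime grid; lifetimes are bounded
#' to \[0.01, 20\] ns.
#'
#' @param fls Integer decay histogram (one cluster's accumulated FLS).
#' @param n Number of exponential components (1-4).
#' @param irf An `irf_model` matching the histogram length.
#' @param channel_width_ps Channel width in ps.
#' @param background Background counts/channel; `NULL` (default) estimates it
#'   from the pre-pulse window via [estimate_background()] and keeps it fixed.
#' @param max_starts Cap on the number of multi-start fits.
#' @return A `decay_fit` object; see [tidy.decay_fit()] and
#'   [glance.decay_fit()].
#' @export
fit_multiexp <- function(fls, n, irf, channel_width_ps = 19.97,
                         background = NULL, max_starts = 10) {
  if (!n %in% 1:4) abort("`n` must be in 1..4.", class = "clusterflim_argument_error")
  if (sum(fls) <= 0) abort("FLS has no photons.", class = "clusterflim_argument_error")
  n_channels <- length(fls)
  if (length(irf$vector) != n_channels) {
    abort("IRF length must equal the FLS length.", class = "clusterflim_argument_error")
  }
  if (is.null(background)) {
    # pre-pulse window: channels strictly before the IRF rise
    pre <- which(cumsum(irf$vector) < 1e-5)
    background <- if (length(pre)) estimate_background(fls, pre) else 0
  }
  decay_total <- max(sum(fls) - background * n_channels, 1)

  tau_lo <- 0.01; tau_hi <- 20
  grid <- c(0.05, 0.2, 1, 4, 12)
  tau_starts <- if (n == 1) as.list(grid) else {
    combs <- utils::combn(grid, n, simplify = FALSE)
    combs
  }
  if (length(tau_starts) > max_starts) {
    tau_starts <- tau_starts[round(seq(1, length(tau_starts), length.out = max_starts))]
  }

  nll_fn <- function(theta) {
    taus <- exp(theta[seq_len(n)])
    ps <- exp(theta[n + seq_len(n)])
    mu <- background
    for (i in seq_len(n)) {
      mu <- mu + ps[i] * basis_curve(taus[i], irf, channel_width_ps, n_channels)
    }
    poisson_nll(fls, mu)
  }

  lower <- c(rep(log(tau_lo), n), rep(log(decay_total * 1e-9), n))
  upper <- c(rep(log(tau_hi), n), rep(log(decay_total * 10), n))
  best <- NULL
  for (ts in tau_starts) {
    theta0 <- c(log(ts), rep(log(decay_total / n), n))
    fit <- tryCatch(
      optim(theta0, nll_fn, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    abort("Multi-exponential fit failed to converge from any start.",
          class = "clusterflim_fit_error")
  }
  theta <- best$par
  taus <- exp(theta[seq_len(n)])
  ps <- exp(theta[n + seq_len(n)]) # photons per component = beta weights
  # component photons p_i are proportional to alpha_i * tau_i
  alphas <- (ps / taus) / sum(ps / taus)
  ml <- mean_lifetimes(alphas, taus)
  at_bound <- any(abs(theta[seq_len(n)] - log(tau_lo)) < 1e-6) ||
    any(abs(theta[seq_len(n)] - log(tau_hi)) < 1e-6)

  mu <- background
  for (i in seq_len(n)) mu <- mu + ps[i] * basis_curve(taus[i], irf, channel_width_ps, n_channels)
  dof <- n_channels - 2 * n
  chisq_red <- sum((fls - mu)^2 / pmax(mu, 1)) / dof

  # standard errors: numeric Hessian of the NLL, delta method to natural scale
  se_tau <- se_alpha <- rep(NA_real_, n)
  hess <- tryCatch(optim(theta, nll_fn, method = "L-BFGS-B", lower = lower,
                         upper = upper, hessian = TRUE,
                         control = list(maxit = 1))$hessian,
                   error = function(e) NULL)
  if (!is.null(hess)) {
    cov_theta <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(cov_theta) && all(is.finite(cov_theta))) {
      jac <- numeric_jacobian(function(th) {
        tt <- exp(th[seq_len(n)]); pp <- exp(th[n + seq_len(n)])
        aa <- (pp / tt) / sum(pp / tt)
        c(tt, aa)
      }, theta)
      cov_nat <- jac %*% cov_theta %*% t(jac)
      ses <- sqrt(pmax(diag(cov_nat), 0))
      se_tau <- ses[seq_len(n)]
      se_alpha <- ses[n + seq_len(n)]
    }
  }

  ord <- order(taus)
  structure(
    list(n_components = n, amplitudes = alphas[ord], lifetimes_ns = taus[ord],
         betas = ml$betas[ord], tau_m_a = ml$tau_m_a, tau_m = ml$tau_m,
         background = background, se_lifetimes = se_tau[ord],
         se_amplitudes = se_alpha[ord], chisq_red = chisq_red,
         loglik = -best$value, at_bound = at_bound,
         converged = best$convergence == 0, fitted = mu, data = fls,
         channel_width_ps = channel_width_ps),
    class = "decay_fit"
  )
}

numeric_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  jac <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- xp[j] + eps
    jac[, j] <- (f(xp) - f0) / eps
  }
  jac
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %d component(s): tau_m,a = %.3f ns, tau_m = %.3f ns, red. chi2 = %.3f\n",
              x$n_components, x$tau_m_a, x$tau_m, x$chisq_red))
  print(tidy(x))
  invisible(x)
}

#' Tidy a multi-exponential decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return One row per component: `amplitude` (`alpha_i`), `lifetime_ns`,
#'   `beta` (fractional amplitude), and standard errors.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(
    component = seq_len(x$n_components),
    amplitude = x$amplitudes,
    lifetime_ns = x$lifetimes_ns,
    beta = x$betas,
    se_amplitude = x$se_amplitudes,
    se_lifetime = x$se_lifetimes
  )
}

#' One-row summary of a decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(
    n_components = x$n_components,
    tau_m_a = x$tau_m_a,
    tau_m = x$tau_m,
    background = x$background,
    chisq_red = x$chisq_red,
    loglik = x$loglik,
    converged = x$converged,
    at_bound = x$at_bound
  )
}

#' @export
autoplot.decay_fit <- function(object, ...) {
  n <- length(object$data)
  t_ns <- (seq_len(n) - 0.5) * object$channel_width_ps / 1000
  df <- tibble(time_ns = t_ns, counts = as.numeric(object$data),
               fitted = object$fitted)
  ggplot(df, aes(x = .data$time_ns)) +
    geom_point(aes(y = .data$counts), size = 0.3, alpha = 0.4) +
    geom_line(aes(y = .data$fitted), color = "red") +
    scale_y_log10() +
    labs(x = "time (ns)", y = "counts / channel") +
    theme_minimal()
}

#' Compare component counts by BIC
#'
#' Fits `n = 1..n_max` components and reports the Bayesian information
#' criterion per model, to guide the user's choice of `n`.
#'
#' @param fls Decay histogram.
#' @param irf An `irf_model`.
#' @param channel_width_ps Channel width in ps.
#' @param n_max Largest component count to try (<= 4).
#' @return Tibble with `n`, `bic`, `tau_m_a`, `chisq_red`.
#' @export
scan_components <- function(fls, irf, channel_width_ps = 19.97, n_max = 4) {
  purrr::map_dfr(seq_len(n_max), function(n) {
    fit <- tryCatch(fit_multiexp(fls, n, irf, channel_width_ps), error = function(e) NULL)
    if (is.null(fit)) return(tibble(n = n, bic = NA_real_, tau_m_a = NA_real_, chisq_red = NA_real_))
    tibble(n = n, bic = -2 * fit$loglik + 2 * n * log(length(fls)),
           tau_m_a = fit$tau_m_a, chisq_red = fit$chisq_red)
  })
}
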