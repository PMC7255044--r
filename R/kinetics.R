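#' Four-pool endocytosis transport model
#'
#' First-order kinetic scheme of receptor-mediated nanocarrier uptake:
#' receptor-bound at the plasma membrane (`c_pm`, cyan) reversibly enters
#' caveolae/lipid-raft membrane domains (`y_pm`, yellow), caveolar vesicles
#' detach into the cytoplasm (`y_cp`, yellow), and the cargo accumulates in
#' lysosomes (`r_cp`, red, absorbing):
#'
#' \deqn{c_{pm} \rightleftharpoons y_{pm} \rightarrow y_{cp} \rightarrow r_{cp}}
#'
#' with forward/backward time constants `tau1`/`tau_m1` for the first step
#' and `tau2`, `tau3` for the two irreversible steps (all in minutes). The
#' system is closed: the pool fractions sum to 1 along every trajectory.
#'
#' @param state Numeric vector `(c_pm, y_pm, y_cp, r_cp)`.
#' @param taus Named or positional vector `(tau1, tau_m1, tau2, tau3)` in
#'   minutes, all positive.
#' @return `kinetic_rhs()`: the four time derivatives (summing to zero).
#' @name kinetics_model
NULL

check_taus <- function(taus) {
  if (length(taus) != 4 || any(!is.finite(taus)) || any(taus <= 0)) {
    abort("`taus` must be four positive time constants (tau1, tau_m1, tau2, tau3).",
          class = "clusterflim_argument_error")
  }
}

rate_matrix <- function(taus) {
  t1 <- taus[[1]]; tm1 <- taus[[2]]; t2 <- taus[[3]]; t3 <- taus[[4]]
  matrix(c(
    -1 / t1,        1 / tm1,           0,       0,
     1 / t1, -1 / tm1 - 1 / t2,        0,       0,
          0,          1 / t2,   -1 / t3,        0,
          0,               0,    1 / t3,        0
  ), 4, 4, byrow = TRUE)
}

#' @rdname kinetics_model
#' @export
kinetic_rhs <- function(state, taus) {
  check_taus(taus)
  as.vector(rate_matrix(taus) %*% state)
}

#' Simulate the four-pool transport model
#'
#' Solves the linear ODE system, either in closed form through the matrix
#' exponential of the rate matrix (default, exact) or numerically with
#' `deSolve::ode` (`method = "ode"`, available as an independent check).
#'
#' @inheritParams kinetics_model
#' @param taus Time constants `(tau1, tau_m1, tau2, tau3)` in minutes.
#' @param y0 Initial pool fractions; default all receptor-bound.
#' @param times Sorted non-negative times in minutes.
#' @param method `"expm"` (closed form) or `"ode"` (lsoda).
#' @return Tibble with columns `time_min`, `c_pm`, `y_pm`, `y_cp`, `r_cp`.
#' @export
simulate_kinetics <- function(taus, y0 = c(1, 0, 0, 0), times,
                              method = c("expm", "ode")) {
  method <- match.arg(method)
  check_taus(taus)
  if (is.unsorted(times) || any(times < 0)) {
    abort("`times` must be sorted and non-negative.", class = "clusterflim_argument_error")
  }
  A <- rate_matrix(taus)
  if (method == "expm") {
    states <- t(vapply(times, function(t) {
      as.vector(as.matrix(Matrix::expm(A * t)) %*% y0)
    }, numeric(4)))
  } else {
    rhs <- function(t, y, parms) list(as.vector(A %*% y))
    out <- deSolve::ode(y = y0, times = if (times[1] == 0) times else c(0, times),
                        func = rhs, parms = NULL, rtol = 1e-10, atol = 1e-12)
    states <- unname(out[match(times, out[, 1]), -1, drop = FALSE])
  }
  tibble(time_min = times, c_pm = states[, 1], y_pm = states[, 2],
         y_cp = states[, 3], r_cp = states[, 4])
}

# model prediction of the three observable cluster fractions
# (yellow = membrane + cytoplasmic caveolar pools)
observed_fractions <- function(taus, y0, times) {
  tr <- simulate_kinetics(taus, y0, times)
  cbind(cyan = tr$c_pm, yellow = tr$y_pm + tr$y_cp, red = tr$r_cp)
}

#' Fit the four-pool model to cluster-fraction time series
#'
#' Least-squares fit of the model-predicted cluster fractions (cyan,
#' yellow = membrane + cytoplasmic caveolar pools, red) to observed
#' fractions over the four time constants, starting from `y0 = (1, 0, 0, 0)`
#' (all nanocarrier receptor-bound at the first observation). The fit is
#' multi-start over a deterministic grid of time-constant combinations;
#' standard errors come from the Jacobian at the optimum (the back-transition
#' constant `tau_m1` is typically weakly identified from three observables at
#' few time points - expect a large standard error there).
#'
#' @param data Tibble/data.frame with columns `time_min`, `cyan`, `yellow`,
#'   `red` (fractions in \[0, 1\]).
#' @param y0 Initial pool fractions.
#' @return A `kinetic_fit` with `taus` (tau1, tau_m1, tau2, tau3 in minutes),
#'   `se`, `residual_norm`, `fitted`, `converged`.
#' @export
fit_kinetics <- function(data, y0 = c(1, 0, 0, 0)) {
  req <- c("time_min", "cyan", "yellow", "red")
  if (!all(req %in% names(data))) {
    abort("`data` needs columns time_min, cyan, yellow, red.", class = "clusterflim_argument_error")
  }
  if (nrow(data) < 4) {
    abort("At least 4 time points are required for 4 free parameters.",
          class = "clusterflim_argument_error")
  }
  obs <- as.matrix(data[, c("cyan", "yellow", "red")])
  if (any(obs < -1e-9) || any(obs > 1 + 1e-9)) {
    abort("Observed fractions must lie in [0, 1].", class = "clusterflim_argument_error")
  }
  if (all(apply(obs, 2, function(v) diff(range(v))) < 1e-12)) {
    abort("Observations show no dynamics; the time constants are not identifiable.",
          class = "clusterflim_fit_error")
  }
  times <- data$time_min
  resid_fn <- function(log_taus) {
    as.vector(observed_fractions(exp(log_taus), y0, times) - obs)
  }
  starts <- expand.grid(t1 = c(5, 20), tm1 = c(15, 60),
                        t2 = c(40, 120), t3 = c(60, 180))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log(as.numeric(starts[i, ])), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) abort("Kinetic fit failed from every start.", class = "clusterflim_fit_error")
  log_taus <- best$par
  taus <- exp(log_taus)
  # covariance on the log scale from the residual Jacobian, delta to minutes
  nobs <- length(obs); npar <- 4
  sigma2 <- best$deviance / max(nobs - npar, 1)
  jac <- numeric_jacobian(resid_fn, log_taus)
  se <- rep(NA_real_, 4)
  cov_log <- tryCatch(solve(crossprod(jac)) * sigma2, error = function(e) NULL)
  if (!is.null(cov_log)) se <- taus * sqrt(pmax(diag(cov_log), 0))
  names(taus) <- names(se) <- c("tau1", "tau_m1", "tau2", "tau3")
  fitted <- observed_fractions(taus, y0, times)
  structure(
    list(taus = taus, se = se, y0 = y0,
         residual_norm = sqrt(best$deviance),
         data = as_tibble(data[, req]),
         fitted = as_tibble(cbind(time_min = times, as.data.frame(fitted))),
         converged = best$info %in% 1:4),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit> time constants (min):\n")
  print(round(rbind(estimate = x$taus, se = x$se), 2))
  invisible(x)
}

#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble(term = names(x$taus), estimate = unname(x$taus), std_error = unname(x$se))
}

#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(residual_norm = x$residual_norm, n_times = nrow(x$data),
         converged = x$converged)
}

#' @export
autoplot.kinetic_fit <- function(object, ...) {
  obs <- tidyr::pivot_longer(object$data, -"time_min",
                             names_to = "cluster", values_to = "fraction")
  dense <- simulate_kinetics(object$taus, object$y0,
                             seq(0, max(object$data$time_min), length.out = 200))
  fit <- tibble(time_min = rep(dense$time_min, 3),
                cluster = rep(c("cyan", "yellow", "red"), each = nrow(dense)),
                fraction = c(dense$c_pm, dense$y_pm + dense$y_cp, dense$r_cp))
  cols <- c(cyan = "#00AAAA", yellow = "#B8860B", red = "#CC0000")
  ggplot(obs, aes(x = .data$time_min, y = .data$fraction, color = .data$cluster)) +
    geom_point() +
    geom_line(data = fit) +
    scale_color_manual(values = cols) +
    labs(x = "incubation time (min)", y = "cluster fraction") +
    theme_minimal()
}

#' Saturation (Michaelis-Menten-like) uptake fit
#'
#' Nonlinear least squares of `I = I_max * c / (K50 + c)` to intensity-vs-
#' concentration uptake data; `K50` is the half-maximum uptake concentration.
#'
#' @param concentrations Non-negative concentrations.
#' @param intensities Observed intensities.
#' @return A `saturation_fit` with `I_max`, `K50` and standard errors.
#' @export
fit_saturation <- function(concentrations, intensities) {
  if (length(concentrations) < 3) abort("At least 3 points required.", class = "clusterflim_argument_error")
  if (any(concentrations < 0)) abort("Concentrations must be non-negative.", class = "clusterflim_argument_error")
  if (sd(intensities) == 0) abort("Degenerate (constant) intensities.", class = "clusterflim_fit_error")
  df <- data.frame(conc = concentrations, int = intensities)
  start <- list(I_max = max(intensities),
                K50 = max(median(concentrations[concentrations > 0]), 1e-6))
  fit <- tryCatch(
    minpack.lm::nlsLM(int ~ I_max * conc / (K50 + conc), data = df, start = start,
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort(paste("Saturation fit failed:", conditionMessage(e)),
                              class = "clusterflim_fit_error")
  )
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 2))
  structure(list(I_max = est[["I_max"]], K50 = est[["K50"]],
                 se = setNames(se, c("I_max", "K50")), nls = fit,
                 data = df),
            class = "saturation_fit")
}

#' @export
predict.saturation_fit <- function(object, concentrations, ...) {
  object$I_max * concentrations / (object$K50 + concentrations)
}

#' @method tidy saturation_fit
#' @export
tidy.saturation_fit <- function(x, ...) {
  tibble(term = c("I_max", "K50"), estimate = c(x$I_max, x$K50),
         std_error = unname(x$se))
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("<saturation_fit> I_max = %.4g, K50 = %.4g\n", x$I_max, x$K50))
  invisible(x)
}

#' Hill displacement fit
#'
#' Nonlinear least squares of the modified Hill function
#' `A = A_max + (A_min - A_max) * c^n / (K50^n + c^n)` to occupied-area vs
#' competitor-concentration data; `K50` is the apparent binding affinity and
#' `n` the Hill (cooperativity) coefficient.
#'
#' @param concentrations Competitor concentrations (e.g. nM).
#' @param areas Occupied areas.
#' @param fix_n Optionally fix the Hill coefficient (e.g. `1`); `NULL` fits it.
#' @return A `hill_fit` with `A_max`, `A_min`, `K50`, `n_hill`, `se`.
#' @export
fit_displacement_hill <- function(concentrations, areas, fix_n = NULL) {
  if (length(concentrations) < 4) abort("At least 4 points required.", class = "clusterflim_argument_error")
  if (sd(areas) == 0) abort("Degenerate (constant) areas.", class = "clusterflim_fit_error")
  df <- data.frame(conc = concentrations, area = areas)
  k0 <- exp(mean(log(concentrations[concentrations > 0])))
  fit <- tryCatch({
    if (is.null(fix_n)) {
      minpack.lm::nlsLM(
        area ~ A_max + (A_min - A_max) * conc^n / (K50^n + conc^n), data = df,
        start = list(A_max = max(areas), A_min = min(areas), K50 = k0, n = 1),
        lower = c(-Inf, -Inf, 1e-12, 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 300))
    } else {
      n <- fix_n
      minpack.lm::nlsLM(
        area ~ A_max + (A_min - A_max) * conc^n / (K50^n + conc^n), data = df,
        start = list(A_max = max(areas), A_min = min(areas), K50 = k0),
        lower = c(-Inf, -Inf, 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 300))
    }
  }, error = function(e) abort(paste("Hill fit failed:", conditionMessage(e)),
                               class = "clusterflim_fit_error"))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, length(est)))
  structure(list(A_max = est[["A_max"]], A_min = est[["A_min"]],
                 K50 = est[["K50"]],
                 n_hill = if (is.null(fix_n)) est[["n"]] else fix_n,
                 se = se, nls = fit, data = df),
            class = "hill_fit")
}

#' @export
predict.hill_fit <- function(object, concentrations, ...) {
  with(object, A_max + (A_min - A_max) * concentrations^n_hill /
         (K50^n_hill + concentrations^n_hill))
}

#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, ...) {
  terms <- c("A_max", "A_min", "K50", "n_hill")
  tibble(term = terms,
         estimate = c(x$A_max, x$A_min, x$K50, x$n_hill),
         std_error = c(x$se, rep(NA_real_, 4 - length(x$se)))[1:4])
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> A_max = %.4g, A_min = %.4g, K50 = %.4g, n = %.3g\n",
              x$A_max, x$A_min, x$K50, x$n_hill))
  invisible(x)
}
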