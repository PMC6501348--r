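## Summary statistics of dimer trajectories: mean length with batch-means
## confidence intervals, the centre-of-mass velocity autocorrelation
## function (VACF), Green-Kubo and mean-squared-displacement diffusion
## estimates, and the two-parameter exponential VACF fit.

#' Estimate the centre-of-mass velocity autocorrelation function
#'
#' Time-averaged estimator of
#' \eqn{C_d(\tau) = \frac13 \langle \bar V(t+\tau)\cdot\bar V(t)\rangle}
#' using all overlapping origins after the burn-in; the lag grid is the
#' trajectory sampling interval.
#'
#' @param traj a `"dimer_trajectory"`.
#' @param max_lag largest lag time.
#' @param burn_in initial time span discarded before averaging (default:
#'   first half of the trajectory).
#' @return Object of class `"vacf_estimate"`: list with `lags`, `values`,
#'   `n_samples` (origins per lag) and the sampling interval `dt`.
#' @export
estimate_vacf <- function(traj, max_lag, burn_in = NULL) {
  times <- traj$times
  span <- times[length(times)] - times[1]
  burn_in <- burn_in %||% (span / 2)
  keep <- times >= times[1] + burn_in
  if (sum(keep) < 10L) stopf("trajectory too short after burn-in")
  V <- traj$Vbar[keep, , drop = FALSE]
  n <- nrow(V)
  dt_s <- mean(diff(times[keep]))
  n_lag <- floor(max_lag / dt_s + 1e-9)
  if (n_lag >= n)
    stopf("max_lag = %g exceeds the post-burn-in span %g", max_lag, n * dt_s)
  vals <- numeric(n_lag + 1L)
  ns <- integer(n_lag + 1L)
  for (lag in 0:n_lag) {
    i <- seq_len(n - lag)
    vals[lag + 1L] <- sum(V[i, ] * V[i + lag, ]) / (3 * length(i))
    ns[lag + 1L] <- length(i)
  }
  structure(list(lags = (0:n_lag) * dt_s, values = vals, n_samples = ns,
                 dt = dt_s),
            class = "vacf_estimate")
}

#' @export
print.vacf_estimate <- function(x, ...) {
  cat(sprintf("VACF estimate: %d lags over [0, %g]; C(0) = %.4g\n",
              length(x$lags), max(x$lags), x$values[1]))
  invisible(x)
}

#' Green-Kubo diffusion constant from the VACF
#'
#' Trapezoidal integral of the VACF over `[0, upper]`; for the Langevin
#' dimer the limit is `D / 2`.
#'
#' @param vacf a [estimate_vacf()] result.
#' @param upper integration endpoint (default 1 time unit).
#' @return The diffusion estimate.
#' @export
diffusion_from_vacf <- function(vacf, upper = 1) {
  if (upper > max(vacf$lags) + 1e-12)
    stopf("`upper` = %g exceeds the available lag range %g", upper,
          max(vacf$lags))
  if (upper <= 0) return(0)
  keep <- vacf$lags <= upper + 1e-12
  x <- vacf$lags[keep]
  y <- vacf$values[keep]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Diffusion constant and its standard error by batch means
#'
#' Splits the post-burn-in trajectory into `n_batches` contiguous blocks,
#' computes the Green-Kubo estimate in each, and reports their mean and
#' standard error. Used to attach an uncertainty to [diffusion_from_vacf()].
#'
#' @inheritParams estimate_vacf
#' @param upper VACF integration endpoint.
#' @param n_batches number of blocks (default 10).
#' @return List with `estimate`, `se`, and the per-batch values.
#' @export
diffusion_from_vacf_batched <- function(traj, upper = 1, burn_in = NULL,
                                        n_batches = 10L) {
  times <- traj$times
  span <- times[length(times)] - times[1]
  burn_in <- burn_in %||% (span / 2)
  keep <- which(times >= times[1] + burn_in)
  idx <- split(keep, cut(seq_along(keep), n_batches, labels = FALSE))
  vals <- vapply(idx, function(ii) {
    sub <- structure(list(times = times[ii],
                          Vbar = traj$Vbar[ii, , drop = FALSE]),
                     class = "dimer_trajectory")
    v <- estimate_vacf(sub, max_lag = upper, burn_in = 0)
    diffusion_from_vacf(v, upper = min(upper, max(v$lags)))
  }, numeric(1))
  list(estimate = mean(vals), se = sd(vals) / sqrt(length(vals)),
       batch_values = vals)
}

#' Diffusion constant from the mean-squared displacement
#'
#' Least-squares slope of \eqn{\langle (\bar X(t) - \bar X(t_0))^2 \rangle}
#' against `6 t` over the diffusive regime (lags beyond a few velocity
#' relaxation times). Origins are taken on a decorrelated grid.
#'
#' @inheritParams estimate_vacf
#' @param fit_window lag-time window `c(lo, hi)` used for the slope.
#' @return List with `estimate` and the lag/msd table used for the fit.
#' @export
diffusion_from_msd <- function(traj, burn_in = NULL,
                               fit_window = c(0.5, 2)) {
  times <- traj$times
  span <- times[length(times)] - times[1]
  burn_in <- burn_in %||% (span / 2)
  keep <- times >= times[1] + burn_in
  X <- traj$Xbar[keep, , drop = FALSE]
  n <- nrow(X)
  dt_s <- mean(diff(times[keep]))
  lags <- unique(round(seq(fit_window[1] / dt_s, fit_window[2] / dt_s,
                           length.out = 24L)))
  lags <- lags[lags >= 1 & lags < n]
  if (length(lags) < 3L) stopf("trajectory too short for the MSD window")
  msd <- vapply(lags, function(lag) {
    i <- seq_len(n - lag)
    mean(rowSums((X[i + lag, , drop = FALSE] - X[i, , drop = FALSE])^2))
  }, numeric(1))
  tau <- lags * dt_s
  fit <- lm(msd ~ tau)
  list(estimate = unname(coef(fit)[2] / 6),
       table = data.frame(lag = tau, msd = msd))
}

#' Mean dimer length with a batch-means confidence interval
#'
#' Post-burn-in time average of the separation `R` with a two-sided
#' confidence interval from batch means (contiguous blocks, Student-t
#' quantile), which accounts for the autocorrelation of `R`.
#'
#' @inheritParams estimate_vacf
#' @param level confidence level (default 0.99).
#' @param n_batches number of blocks (default 20).
#' @return List with `L_d`, `ci` (two-sided), `se`, and settings.
#' @export
estimate_mean_length <- function(traj, burn_in = NULL, level = 0.99,
                                 n_batches = 20L) {
  times <- traj$times
  span <- times[length(times)] - times[1]
  burn_in <- burn_in %||% (span / 2)
  keep <- which(times >= times[1] + burn_in)
  if (length(keep) < n_batches)
    stopf("trajectory too short after burn-in for %d batches", n_batches)
  R <- traj$R[keep]
  batches <- vapply(split(R, cut(seq_along(R), n_batches, labels = FALSE)),
                    mean, numeric(1))
  m <- mean(batches)
  se <- sd(batches) / sqrt(n_batches)
  hw <- qt(1 - (1 - level) / 2, df = n_batches - 1L) * se
  list(L_d = m, ci = c(m - hw, m + hw), se = se, level = level,
       n_batches = n_batches, burn_in = burn_in)
}

#' Fit the exponential Langevin form to an estimated VACF
#'
#' Nonlinear least squares fit of \eqn{(D\gamma/2) e^{-\gamma\tau}} to the
#' VACF estimate, recovering both `D` and `gamma` simultaneously. Starting
#' values come from a log-linear regression on the positive part.
#'
#' @param vacf a [estimate_vacf()] result.
#' @param fit_upper largest lag used (default: all lags).
#' @return List with `D_hat`, `gamma_hat` and the `nls` fit object.
#' @export
fit_exponential_vacf <- function(vacf, fit_upper = NULL) {
  keep <- if (is.null(fit_upper)) rep(TRUE, length(vacf$lags))
          else vacf$lags <= fit_upper
  tau <- vacf$lags[keep]
  y <- vacf$values[keep]
  pos <- y > 0
  if (sum(pos) < 4L) stopf("VACF not positive over enough of the fit window")
  init <- coef(lm(log(y[pos]) ~ tau[pos]))
  g0 <- max(-init[2], 1e-8)
  D0 <- 2 * exp(init[1]) / g0
  ## Levenberg-Marquardt: robust to the zero-residual case of exact input
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Dh * gh / 2 * exp(-gh * tau),
                      start = list(Dh = unname(D0), gh = unname(g0)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stopf("exponential VACF fit did not converge: %s (start D = %.3g, gamma = %.3g)",
            conditionMessage(e), D0, g0))
  cf <- coef(fit)
  list(D_hat = unname(cf["Dh"]), gamma_hat = unname(cf["gh"]), fit = fit)
}
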