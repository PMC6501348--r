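## Random-variate machinery for the open-boundary solvent insertion:
## acceptance-rejection sampling of the erfc-tail depth distribution,
## Maxwell-Boltzmann and truncated-Gaussian velocity samplers, and the
## calibrated bath density of the collision heat bath.

#' Acceptance-rejection constants for the erfc-tail sampler
#'
#' The depth of an incoming solvent particle is distributed as
#' \eqn{p(z;\beta) = C_3(\beta)\,\mathrm{erfc}(z+\beta)} on \eqn{z \ge 0}.
#' The sampler draws an exponential proposal with mean \eqn{a_1(\beta)} and
#' accepts with an envelope scaled by \eqn{a_2(\beta)}:
#' \deqn{a_1(\beta) = (\sqrt\pi/2)\,\mathrm{erfc}(\beta) e^{\beta^2}
#'   \;(\beta \ge 0),\quad (\sqrt\pi/2) \;(\beta \le 0),}
#' \deqn{a_2(\beta) = 1/\mathrm{erfc}(\beta) \;(\beta \ge 0),\quad
#'   e^{2\beta/\sqrt\pi} \;(\beta \le 0).}
#' Both branches agree at \eqn{\beta = 0}. For large \eqn{\beta} the product
#' \eqn{\mathrm{erfc}(\beta) e^{\beta^2}} is evaluated through the scaled
#' complementary error function, so neither constant under- or overflows.
#'
#' @param beta dimensionless shift (frame velocity component divided by
#'   \eqn{\sigma_\mu \sqrt 2}).
#' @return Named vector `c(a1 = ..., a2 = ...)`.
#' @examples
#' ar_constants(0)  # a1 = sqrt(pi)/2, a2 = 1
#' @export
ar_constants <- function(beta) {
  check_number(beta, "beta")
  if (beta >= 0) {
    a1 <- sqrt(pi) / 2 * erfcx_up(beta)  # erfc(b) e^{b^2}, stable
    ## 1/erfc(b) = e^{b^2}/erfcx(b); capped at the largest double for
    ## extreme b (the sampler itself always uses the ratio form there)
    la2 <- beta^2 - log(erfcx_up(beta))
    a2 <- exp(min(la2, log(.Machine$double.xmax)))
  } else {
    a1 <- sqrt(pi) / 2
    a2 <- exp(2 * beta / sqrt(pi))
  }
  c(a1 = a1, a2 = a2)
}

#' Normalizing constant of the erfc-tail density
#'
#' \eqn{C_3(\beta) = \sqrt\pi / (e^{-\beta^2} - \sqrt\pi \beta\,
#' \mathrm{erfc}(\beta))}, fixed by
#' \eqn{\int_0^\infty C_3\,\mathrm{erfc}(z+\beta)\,dz = 1}.
#'
#' @inheritParams ar_constants
#' @export
erfc_tail_norm_const <- function(beta) {
  1 / erfc_tail_mass(beta)
}

#' Density of the erfc-tail distribution
#'
#' @param z non-negative evaluation points.
#' @inheritParams ar_constants
#' @export
erfc_tail_density <- function(z, beta) {
  if (any(z < 0)) stopf("`z` must be non-negative")
  if (beta > 6) {
    ## ratio form: erfc(z+b)/mass = erfcx(z+b) e^{-z^2-2bz} / (e^{b^2} mass)
    erfcx_up(z + beta) * exp(-z^2 - 2 * beta * z) /
      erfc_tail_mass_scaled(beta)
  } else {
    erfc(z + beta) / erfc_tail_mass(beta)
  }
}

#' Distribution function of the erfc-tail distribution
#'
#' Closed form used as the reference in goodness-of-fit tests:
#' \eqn{F(z) = 1 - G(z+\beta)/G(\beta)} with
#' \eqn{G(x) = e^{-x^2}/\sqrt\pi - x\,\mathrm{erfc}(x)}.
#'
#' @inheritParams erfc_tail_density
#' @export
erfc_tail_cdf <- function(z, beta) {
  if (any(z < 0)) stopf("`z` must be non-negative")
  if (beta > 6) {
    1 - exp(-z^2 - 2 * beta * z) * erfc_tail_mass_scaled(z + beta) /
      erfc_tail_mass_scaled(beta)
  } else {
    1 - erfc_tail_mass(z + beta) / erfc_tail_mass(beta)
  }
}

#' Sample the erfc-tail distribution by acceptance-rejection
#'
#' Exact sampler for \eqn{p(z;\beta) = C_3(\beta) \mathrm{erfc}(z+\beta)}:
#' draw \eqn{\eta_1, \eta_2 \sim U(0,1)}, set
#' \eqn{\eta_3 = -a_1(\beta)\log\eta_1}, and accept \eqn{\eta_3} when
#' \eqn{\eta_1 \eta_2 < a_2(\beta)\,\mathrm{erfc}(\eta_3 + \beta)}.
#'
#' @param n number of samples.
#' @inheritParams ar_constants
#' @param a1,a2 optional overrides of the proposal constants (e.g. the
#'   tuned pair `a1 = 0.532`, `a2 = 0.814` at `beta = 0`).
#' @return Numeric vector of `n` non-negative samples, with attribute
#'   `"acceptance_rate"` (accepted / proposed).
#' @examples
#' set.seed(1)
#' z <- erfc_tail_sample(1000, beta = 0)
#' attr(z, "acceptance_rate")  # about 2/pi
#' @export
erfc_tail_sample <- function(n, beta, a1 = NULL, a2 = NULL) {
  cc <- ar_constants(beta)
  a1 <- a1 %||% cc[["a1"]]
  a2 <- a2 %||% cc[["a2"]]
  out <- numeric(n)
  need <- n
  filled <- 0L
  proposed <- 0L
  rounds <- 0L
  while (need > 0L) {
    rounds <- rounds + 1L
    if (rounds > 1000L)
      stopf("erfc-tail sampler: acceptance rate implausibly low (internal inconsistency)")
    m <- max(64L, ceiling(need * 1.8))
    eta1 <- runif(m)
    eta2 <- runif(m)
    eta3 <- -a1 * log(eta1)
    acc <- eta1 * eta2 < .erfc_envelope(eta3, beta, a2)
    n_acc <- sum(acc)
    if (n_acc > need) {
      ## only consume proposals up to the `need`-th acceptance, so the
      ## reported acceptance rate stays unbiased
      last <- which(acc)[need]
      acc <- acc[seq_len(last)]
      n_acc <- need
      m <- last
    }
    proposed <- proposed + m
    if (n_acc > 0L) {
      out[(filled + 1L):(filled + n_acc)] <- eta3[seq_len(m)][acc]
      filled <- filled + n_acc
      need <- need - n_acc
    }
  }
  structure(out, acceptance_rate = filled / proposed)
}

## a2 * erfc(z + beta), in a form stable for large positive beta when a2 is
## the default 1/erfc(beta)
.erfc_envelope <- function(z, beta, a2) {
  if (beta > 6) {
    ## a2 erfc(z+b) ~= erfc(z+b)/erfc(b) = erfcx(z+b)/erfcx(b) e^{-z^2-2bz}
    ## (only exact when a2 is the default; custom a2 at such beta is unused)
    erfcx_up(z + beta) / erfcx_up(beta) * exp(-z^2 - 2 * beta * z)
  } else {
    a2 * erfc(z + beta)
  }
}

#' Acceptance probability of the erfc-tail sampler
#'
#' Probability that one proposal of [erfc_tail_sample()] is accepted,
#' \eqn{a_2(\beta) / (a_1(\beta) C_3(\beta))}, valid whenever the envelope
#' \eqn{a_2 \mathrm{erfc}(z+\beta) e^{z/a_1} \le 1} holds for all
#' \eqn{z \ge 0}.
#'
#' @inheritParams ar_constants
#' @param a1,a2 proposal constants; default [ar_constants()].
#' @return Probability in (0, 1].
#' @examples
#' acceptance_probability(0)                      # 2/pi
#' acceptance_probability(0, a1 = 0.532, a2 = 0.814)  # about 0.863
#' @export
acceptance_probability <- function(beta, a1 = NULL, a2 = NULL) {
  cc <- ar_constants(beta)
  a1 <- a1 %||% cc[["a1"]]
  a2 <- a2 %||% cc[["a2"]]
  if (a1 <= 0 || a2 <= 0) stopf("a1 and a2 must be positive")
  p <- a2 / a1 * erfc_tail_mass(beta)
  ## envelope validity: a2 erfc(z + beta) e^{z / a1} <= 1 on z >= 0
  if (beta <= 6) {
    zg <- seq(0, 20 * a1 + 5, length.out = 2000)
    env <- a2 * erfc(zg + beta) * exp(zg / a1)
    if (max(env) > 1 + 1e-9 || p > 1 + 1e-12)
      stopf("envelope violation: a2*erfc(z+beta)*exp(z/a1) exceeds 1 (a1 = %g, a2 = %g, beta = %g)",
            a1, a2, beta)
  }
  min(p, 1)
}

#' Maxwell-Boltzmann velocity sampler
#'
#' Draws isotropic Gaussian velocity vectors with per-component standard
#' deviation `sigma_mu`.
#'
#' @param n number of vectors.
#' @param sigma_mu velocity scale (per-component sd).
#' @return `n x 3` matrix.
#' @export
maxwell_boltzmann_sample <- function(n, sigma_mu) {
  check_number(sigma_mu, "sigma_mu", lower = 0, strict_lower = TRUE)
  matrix(rnorm(3 * n, sd = sigma_mu), ncol = 3)
}

#' One-sided truncated normal sampler
#'
#' Exact draws from N(0, sd^2) conditioned on exceeding `lower`, using plain
#' rejection from the Gaussian when the truncation point is in the bulk and
#' the shifted-exponential acceptance-rejection scheme for far tails.
#'
#' @param n number of draws.
#' @param sd standard deviation.
#' @param lower truncation point (may be `-Inf`).
#' @export
rtnorm_lower <- function(n, sd, lower) {
  if (lower == -Inf) return(rnorm(n, sd = sd))
  a <- lower / sd
  out <- numeric(n)
  if (a <= 0.5) {
    ## bulk: rejection from the untruncated Gaussian
    need <- n; filled <- 0L
    p_keep <- pnorm(a, lower.tail = FALSE)
    while (need > 0L) {
      m <- max(64L, ceiling(need / p_keep * 1.5))
      x <- rnorm(m)
      x <- x[x > a]
      k <- min(length(x), need)
      if (k > 0L) {
        out[(filled + 1L):(filled + k)] <- x[seq_len(k)]
        filled <- filled + k; need <- need - k
      }
    }
  } else {
    ## tail: shifted-exponential proposal with optimal rate
    lam <- (a + sqrt(a^2 + 4)) / 2
    need <- n; filled <- 0L
    while (need > 0L) {
      m <- max(64L, ceiling(need * 1.5))
      x <- a + rexp(m, rate = lam)
      acc <- runif(m) < exp(-(x - lam)^2 / 2)
      x <- x[acc]
      k <- min(length(x), need)
      if (k > 0L) {
        out[(filled + 1L):(filled + k)] <- x[seq_len(k)]
        filled <- filled + k; need <- need - k
      }
    }
  }
  out * sd
}

#' Velocity of an entering solvent particle
#'
#' Samples velocity vectors whose first component is Gaussian conditioned to
#' exceed `threshold` (the particle must be fast enough to reach its sampled
#' depth within one step) while the other two components are unconditioned
#' Gaussians.
#'
#' @param n number of vectors.
#' @param threshold lower bound on the first component.
#' @param sigma_mu per-component standard deviation.
#' @return `n x 3` matrix.
#' @export
truncated_gaussian_velocity_sample <- function(n, threshold, sigma_mu) {
  check_number(sigma_mu, "sigma_mu", lower = 0, strict_lower = TRUE)
  cbind(rtnorm_lower(n, sd = sigma_mu, lower = threshold),
        rnorm(n, sd = sigma_mu), rnorm(n, sd = sigma_mu))
}

#' Short-range (collision) heat bath parameters
#'
#' A gas of point particles of mass `m = M/mu` colliding elastically with
#' the monomers (balls of radius `r0`). The gas density `lambda_mu` and the
#' Maxwell-Boltzmann velocity scale `sigma_mu` are derived from
#' `(r0, mu, gamma, D)` so that a single monomer in the infinite gas
#' converges to Langevin dynamics with friction `gamma` and diffusion `D`:
#' \deqn{\sigma_\mu = \sqrt{(\mu+1) D \gamma}, \qquad
#'   \lambda_\mu = \frac{3}{8 r_0^2}\sqrt{\frac{(\mu+1)\gamma}{2\pi D}}.}
#' The density follows from the free-molecular drag on a sphere with the
#' reduced-mass collision rule,
#' \eqn{\gamma M = (8/3)\sqrt{2\pi}\,\lambda_\mu m_r \sigma_\mu r_0^2} with
#' \eqn{m_r = m\mu/(\mu+1)}; it scales as \eqn{r_0^{-2}\sqrt{\gamma/D}}.
#'
#' @param r0 monomer radius.
#' @param mu mass ratio M/m.
#' @param gamma target friction coefficient.
#' @param D target diffusion coefficient.
#' @param M monomer mass (default 1).
#' @return Object of class `"short_range_bath_params"` with derived fields
#'   `lambda_mu`, `sigma_mu`, `m`, `kBT`.
#' @examples
#' bath <- short_range_bath_params(r0 = 0.08, mu = 1e3, gamma = 10, D = 1)
#' bath$lambda_mu * 0.32^3  # expected particle count in an L = 0.32 frame
#' @export
short_range_bath_params <- function(r0, mu, gamma, D, M = 1) {
  check_number(r0, "r0", lower = 0, strict_lower = TRUE)
  check_number(mu, "mu", lower = 0, strict_lower = TRUE)
  check_number(gamma, "gamma", lower = 0, strict_lower = TRUE)
  check_number(D, "D", lower = 0, strict_lower = TRUE)
  check_number(M, "M", lower = 0, strict_lower = TRUE)
  structure(list(r0 = r0, mu = mu, gamma = gamma, D = D, M = M,
                 m = M / mu,
                 sigma_mu = sqrt((mu + 1) * D * gamma),
                 lambda_mu = 3 / (8 * r0^2) * sqrt((mu + 1) * gamma / (2 * pi * D)),
                 kBT = M * D * gamma),
            class = "short_range_bath_params")
}

#' @export
print.short_range_bath_params <- function(x, ...) {
  cat(sprintf(
    "collision heat bath: r0 = %g, mu = %g -> lambda_mu = %.4g, sigma_mu = %.4g\n",
    x$r0, x$mu, x$lambda_mu, x$sigma_mu))
  invisible(x)
}

#' Number density of the collision heat bath
#'
#' @param bath a [short_range_bath_params()].
#' @return `lambda_mu` (particles per unit volume).
#' @export
bath_density <- function(bath) {
  bath$lambda_mu
}
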