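## Macroscopic dimer model: two monomers of mass M joined by a harmonic
## spring, immersed in an implicit solvent described by Langevin friction
## and noise. All quantities are in dimensionless units.

#' Harmonic spring parameters
#'
#' The dimer potential is \eqn{\Phi(R) = k (R - \ell_0)^2 / 2}, where `R` is
#' the distance between the two monomers.
#'
#' @param k spring constant (energy / length^2); `k = 0` is allowed and
#'   describes a free pair of monomers.
#' @param ell0 rest length of the spring (length), non-negative.
#' @return An object of class `"spring_params"`.
#' @examples
#' sp <- spring_params(k = 1e6, ell0 = 0.32)
#' @export
spring_params <- function(k, ell0) {
  check_number(k, "k", lower = 0)
  check_number(ell0, "ell0", lower = 0)
  structure(list(k = k, ell0 = ell0), class = "spring_params")
}

#' @export
print.spring_params <- function(x, ...) {
  cat(sprintf("harmonic spring: k = %g, rest length = %g\n", x$k, x$ell0))
  invisible(x)
}

#' Langevin (macroscopic solvent) parameters
#'
#' Parameters of the Langevin description of the solvent acting on each
#' monomer: friction `gamma` and diffusion coefficient `D`. The thermal
#' energy follows from the Einstein--Smoluchowski relation
#' \eqn{k_B T = M D \gamma} and is not an independent parameter.
#'
#' @param M monomer mass.
#' @param D diffusion coefficient of a single monomer (length^2 / time).
#' @param gamma friction coefficient (1 / time).
#' @return An object of class `"langevin_params"` with fields `M`, `D`,
#'   `gamma` and the derived `kBT = M * D * gamma`.
#' @examples
#' lp <- langevin_params(M = 1, D = 1, gamma = 10)
#' lp$kBT  # 10
#' @export
langevin_params <- function(M = 1, D = 1, gamma = 10) {
  check_number(M, "M", lower = 0, strict_lower = TRUE)
  check_number(D, "D", lower = 0, strict_lower = TRUE)
  check_number(gamma, "gamma", lower = 0, strict_lower = TRUE)
  structure(list(M = M, D = D, gamma = gamma, kBT = M * D * gamma),
            class = "langevin_params")
}

#' @export
print.langevin_params <- function(x, ...) {
  cat(sprintf("Langevin parameters: M = %g, D = %g, gamma = %g (kBT = %g)\n",
              x$M, x$D, x$gamma, x$kBT))
  invisible(x)
}

#' Dimer state
#'
#' Positions and velocities of both monomers at a given time.
#'
#' @param X1,X2 positions of monomer 1 and 2 (3-vectors).
#' @param V1,V2 velocities (3-vectors), default zero.
#' @param t time.
#' @return An object of class `"dimer_state"`.
#' @export
dimer_state <- function(X1, X2, V1 = c(0, 0, 0), V2 = c(0, 0, 0), t = 0) {
  structure(list(X1 = check_vec3(X1, "X1"), X2 = check_vec3(X2, "X2"),
                 V1 = check_vec3(V1, "V1"), V2 = check_vec3(V2, "V2"),
                 t = check_number(t, "t")),
            class = "dimer_state")
}

#' @export
print.dimer_state <- function(x, ...) {
  cat(sprintf("dimer state at t = %g; separation R = %g\n",
              x$t, dimer_separation(x)))
  invisible(x)
}

#' Monomer separation R = |X2 - X1|
#' @param state a [dimer_state()].
#' @export
dimer_separation <- function(state) {
  sqrt(sum((state$X2 - state$X1)^2))
}

#' Spring force on the two monomers
#'
#' Returns the pair of forces generated by the harmonic dimer potential.
#' The forces are equal and opposite; for `R > ell0` the force on monomer 1
#' points towards monomer 2.
#'
#' @param state a [dimer_state()].
#' @param spring a [spring_params()].
#' @return A list with 3-vectors `F1` and `F2` (`F1 + F2 = 0`).
#' @export
spring_force <- function(state, spring) {
  Rvec <- state$X2 - state$X1
  R <- sqrt(sum(Rvec^2))
  if (R == 0)
    stopf("degenerate separation: R = 0, spring force direction undefined")
  f <- spring$k * (R - spring$ell0)   # = Phi'(R)
  F1 <- f * Rvec / R
  list(F1 = F1, F2 = -F1)
}

#' Closed-form velocity autocorrelation of the dimer centre of mass
#'
#' For the Langevin dimer the centre-of-mass velocity is an
#' Ornstein--Uhlenbeck process and its autocorrelation function is
#' \eqn{C_d(\tau) = (D\gamma/2) e^{-\gamma\tau}}.
#'
#' @param tau lag time(s), non-negative.
#' @param p a [langevin_params()].
#' @export
analytic_vacf <- function(tau, p) {
  if (any(tau < 0)) stopf("`tau` must be non-negative")
  p$D * p$gamma / 2 * exp(-p$gamma * tau)
}

#' Closed-form diffusion constant of the dimer centre of mass
#'
#' Green--Kubo integral of [analytic_vacf()], equal to `D / 2`.
#'
#' @param p a [langevin_params()].
#' @export
analytic_dimer_diffusion <- function(p) {
  p$D / 2
}

## integration window capturing essentially all mass of
## r^2 exp(-Phi(r)/kBT); used for the quadrature normalization below
.density_support <- function(spring, p) {
  if (spring$k == 0) stopf("stationary length density requires k > 0")
  w <- sqrt(p$kBT / spring$k)
  lo <- max(0, spring$ell0 - 40 * w)
  hi <- spring$ell0 + 40 * w + 5 * w * (spring$ell0 == 0)
  c(lo, hi)
}

#' Stationary density of the dimer separation vector
#'
#' Equilibrium density \eqn{\varrho(R)} of the separation vector under the
#' overdamped dimer dynamics,
#' \eqn{\varrho(R) \propto \exp[-\Phi(R)/(M D \gamma)]}, normalized so that
#' the induced radial density \eqn{4\pi R^2 \varrho(R)} integrates to one.
#'
#' @param R separation(s), non-negative.
#' @param spring a [spring_params()] with `k > 0`.
#' @param p a [langevin_params()].
#' @return Density values of the same length as `R`.
#' @seealso [radial_length_density()] for the density of the scalar length.
#' @export
stationary_length_density <- function(R, spring, p) {
  if (any(R < 0)) stopf("`R` must be non-negative")
  su <- .density_support(spring, p)
  z <- integrate(function(r) r^2 * exp(-spring$k * (r - spring$ell0)^2 /
                                         (2 * p$kBT)),
                 su[1], su[2], rel.tol = 1e-10)$value
  exp(-spring$k * (R - spring$ell0)^2 / (2 * p$kBT)) / (4 * pi * z)
}

#' Radial density of the dimer length
#'
#' `4 * pi * R^2 * stationary_length_density(R, ...)`; integrates to 1 over
#' `[0, Inf)`.
#'
#' @inheritParams stationary_length_density
#' @export
radial_length_density <- function(R, spring, p) {
  4 * pi * R^2 * stationary_length_density(R, spring, p)
}

#' First-order mean dimer length
#'
#' Asymptotic mean length of the dimer at equilibrium,
#' \eqn{L_d \approx \ell_0 (1 + 2 M D \gamma / (k \ell_0^2))}, valid to first
#' order in \eqn{\varepsilon = M D \gamma / (k \ell_0^2)}. A warning is
#' issued when \eqn{\varepsilon > 0.1}.
#'
#' @param spring a [spring_params()] with `k > 0` and `ell0 > 0`.
#' @param p a [langevin_params()].
#' @export
analytic_mean_length <- function(spring, p) {
  if (spring$k == 0 || spring$ell0 == 0)
    stopf("analytic mean length requires k > 0 and ell0 > 0")
  eps <- p$kBT / (spring$k * spring$ell0^2)
  if (eps > 0.1)
    warning(sprintf(
      "epsilon = M*D*gamma/(k*ell0^2) = %.3g > 0.1; first-order formula inaccurate",
      eps))
  spring$ell0 * (1 + 2 * eps)
}

#' Effective rest length of a dimer sharing one oscillator heat bath
#'
#' When both monomers couple symmetrically to a single harmonic-oscillator
#' bath, the bath variables cancel from the separation dynamics and leave an
#' extra linear restoring force \eqn{-(\gamma \bar\omega / \pi) R}, which
#' shortens the effective rest length to
#' \eqn{2 k \pi \ell_0 / (2 k \pi + \gamma \bar\omega)}.
#'
#' @param spring a [spring_params()] with `k > 0`.
#' @param gamma friction coefficient of the target Langevin description.
#' @param omega_bar mean oscillator frequency of the bath.
#' @export
effective_rest_length_one_bath <- function(spring, gamma, omega_bar) {
  if (spring$k <= 0) stopf("requires k > 0")
  check_number(gamma, "gamma", lower = 0)
  check_number(omega_bar, "omega_bar", lower = 0)
  2 * spring$k * pi * spring$ell0 / (2 * spring$k * pi + gamma * omega_bar)
}

#' Simulate the macroscopic Langevin dimer
#'
#' Integrates the six-dimensional Langevin system for the two monomers:
#' spring force, friction \eqn{-\gamma V_i} and noise with increment
#' \eqn{\gamma \sqrt{2D}\, dW_i} per velocity component, independent across
#' monomers and components (stationary velocity variance \eqn{D\gamma} per
#' component).
#'
#' @param spring a [spring_params()].
#' @param p a [langevin_params()].
#' @param tmax run length (time units).
#' @param dt integrator step; must satisfy `dt * gamma < 1`.
#' @param seed integer seed (the run seeds R's RNG).
#' @param integrator `"euler_maruyama"` (positions updated first, velocity
#'   kick with the updated spring force, matching the mixed-resolution
#'   update) or `"bbk"` (velocity-Verlet splitting with the friction and
#'   noise folded into the half-kicks).
#' @param state initial [dimer_state()]; default: monomers at rest separated
#'   by `ell0` along x.
#' @param sample_interval spacing of recorded samples (time units).
#' @return A `"dimer_trajectory"` object; see [as.data.frame.dimer_trajectory()].
#' @examples
#' traj <- simulate_langevin_dimer(spring_params(1e6, 0.32),
#'                                 langevin_params(1, 1, 10),
#'                                 tmax = 1, dt = 1e-4, seed = 1)
#' @export
simulate_langevin_dimer <- function(spring, p, tmax, dt, seed,
                                    integrator = c("euler_maruyama", "bbk"),
                                    state = NULL,
                                    sample_interval = 1e-3) {
  integrator <- match.arg(integrator)
  check_number(tmax, "tmax", lower = 0, strict_lower = TRUE)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  if (dt * p$gamma >= 1)
    stopf("unstable step: dt * gamma = %g >= 1", dt * p$gamma)
  if (is.null(state))
    state <- dimer_state(X1 = c(0, 0, 0), X2 = c(spring$ell0, 0, 0))
  n_steps <- round(tmax / dt)
  sample_every <- max(1L, round(sample_interval / dt))
  set.seed(seed)
  res <- cpp_langevin_run(rbind(state$X1, state$X2),
                          rbind(state$V1, state$V2),
                          p$M, p$D, p$gamma, spring$k, spring$ell0,
                          dt, n_steps, sample_every,
                          integrator == "bbk")
  new_trajectory(res$samples, t0 = state$t, model = "langevin",
                 params = list(spring = spring, langevin = p, dt = dt,
                               integrator = integrator),
                 seed = seed,
                 final_state = dimer_state(res$X[1, ], res$X[2, ],
                                           res$V[1, ], res$V[2, ],
                                           state$t + n_steps * dt))
}
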