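## Kac-Zwanzig harmonic-oscillator heat bath: each monomer couples linearly
## to a cloud of oscillators with exponentially distributed frequencies.
## Eliminating the oscillators yields a generalized Langevin equation with
## a Lorentzian friction kernel; the oscillators are simulated explicitly
## with velocity Verlet instead of integrating the kernel.

#' Build a harmonic-oscillator heat bath
#'
#' Oscillator frequencies are i.i.d. Exponential with mean `omega_bar`.
#' Couplings are chosen so that the friction kernel acting on each monomer
#' converges (as the oscillator count grows) to the Lorentzian
#' [friction_kernel()] with total integral `gamma`:
#' \describe{
#'   \item{`two_bath`}{each monomer gets its own `N` oscillators with
#'     \eqn{k_j = m\omega_j^2} and \eqn{\alpha_j^2 = 2\gamma\bar\omega /
#'     (N m \pi \omega_j^2)}.}
#'   \item{`shared`}{one set of `N` oscillators couples to both monomers
#'     with identical constants \eqn{k_j = m\omega_j^2/2},
#'     \eqn{\alpha_j^2 = \gamma\bar\omega/(N\pi k_j)}; the bath then cancels
#'     exactly from the separation dynamics
#'     (see [effective_rest_length_one_bath()]).}
#'   \item{`split`}{one set of `N = N1 + N2` oscillators, the first `N1`
#'     coupled only to monomer 1 and the rest only to monomer 2 (each group
#'     normalized by its own count) --- statistically identical to
#'     `two_bath`.}
#' }
#'
#' @param N oscillators per monomer (`two_bath`), in total (`shared`), or
#'   total with `N1` attached to monomer 1 (`split`).
#' @param omega_bar mean oscillator frequency.
#' @param gamma target friction coefficient.
#' @param m oscillator mass.
#' @param mode `"two_bath"`, `"shared"` or `"split"`.
#' @param N1 size of the first group in `"split"` mode (default `N / 2`).
#' @return Object of class `"oscillator_bath"` with per-oscillator vectors
#'   `omega`, `k1`, `alpha1`, `k2`, `alpha2` (zero coupling encoded as
#'   `k = 0`).
#' @export
build_bath <- function(N, omega_bar, gamma, m,
                       mode = c("two_bath", "shared", "split"), N1 = NULL) {
  mode <- match.arg(mode)
  if (N < 1) stopf("`N` must be >= 1")
  check_number(omega_bar, "omega_bar", lower = 0, strict_lower = TRUE)
  check_number(gamma, "gamma", lower = 0, strict_lower = TRUE)
  check_number(m, "m", lower = 0, strict_lower = TRUE)
  if (mode == "two_bath") {
    omega <- rexp(2 * N, rate = 1 / omega_bar)
    k <- m * omega^2
    alpha2 <- 2 * gamma * omega_bar / (N * m * pi * omega^2)
    k1 <- k * rep(c(1, 0), c(N, N))
    k2 <- k * rep(c(0, 1), c(N, N))
    a1 <- sqrt(alpha2) * rep(c(1, 0), c(N, N))
    a2 <- sqrt(alpha2) * rep(c(0, 1), c(N, N))
  } else if (mode == "shared") {
    omega <- rexp(N, rate = 1 / omega_bar)
    kj <- m * omega^2 / 2
    aj <- sqrt(gamma * omega_bar / (N * pi * kj))
    k1 <- k2 <- kj
    a1 <- a2 <- aj
  } else {
    N1 <- N1 %||% floor(N / 2)
    if (N1 < 1 || N1 >= N) stopf("split mode needs 0 < N1 < N")
    N2 <- N - N1
    omega <- rexp(N, rate = 1 / omega_bar)
    k <- m * omega^2
    grp1 <- rep(c(1, 0), c(N1, N2))
    alpha2 <- 2 * gamma * omega_bar / (m * pi * omega^2) *
      ifelse(grp1 == 1, 1 / N1, 1 / N2)
    k1 <- k * grp1
    k2 <- k * (1 - grp1)
    a1 <- sqrt(alpha2) * grp1
    a2 <- sqrt(alpha2) * (1 - grp1)
  }
  structure(list(omega = omega, k1 = k1, alpha1 = a1, k2 = k2, alpha2 = a2,
                 m = m, omega_bar = omega_bar, gamma = gamma, mode = mode,
                 N = N, N1 = if (mode == "split") N1 else NULL),
            class = "oscillator_bath")
}

#' @export
print.oscillator_bath <- function(x, ...) {
  cat(sprintf(
    "oscillator heat bath (%s): %d oscillators, mean frequency %g, m = %g\n",
    x$mode, length(x$omega), x$omega_bar, x$m))
  invisible(x)
}

#' Lorentzian friction kernel of the oscillator bath
#'
#' Infinite-oscillator limit of the memory kernel,
#' \eqn{\kappa(\tau) = (2\gamma/\pi)\,\bar\omega / (\bar\omega^2\tau^2 + 1)},
#' with \eqn{\kappa(0) = 2\gamma\bar\omega/\pi} and
#' \eqn{\int_0^\infty \kappa\,d\tau = \gamma}.
#'
#' @param tau lag(s), non-negative.
#' @param gamma friction coefficient.
#' @param omega_bar mean oscillator frequency (kernel width is
#'   `1 / omega_bar`).
#' @export
friction_kernel <- function(tau, gamma, omega_bar) {
  if (any(tau < 0)) stopf("`tau` must be non-negative")
  2 * gamma / pi * omega_bar / (omega_bar^2 * tau^2 + 1)
}

#' Finite-bath empirical friction kernel
#'
#' The memory kernel realized by a drawn bath on monomer `i`,
#' \eqn{\kappa_i(\tau) = \sum_j k_{i,j} \alpha_{i,j}^2 \cos(\omega_j \tau)}
#' (for pure monomer couplings \eqn{k_{i,j} = m\omega_j^2} this is the
#' classical \eqn{m \sum_j \alpha_j^2 \omega_j^2 \cos \omega_j\tau}).
#' Converges to [friction_kernel()] as the bath grows.
#'
#' @param tau lag(s).
#' @param bath an [build_bath()] result.
#' @param monomer 1 or 2.
#' @export
empirical_friction_kernel <- function(tau, bath, monomer = 1) {
  kk <- if (monomer == 1) bath$k1 * bath$alpha1^2 else bath$k2 * bath$alpha2^2
  vapply(tau, function(s) sum(kk * cos(bath$omega * s)), numeric(1))
}

#' Oscillator state
#'
#' @param positions,velocities `N x 3` matrices matching the bath size.
#' @param bath the [build_bath()] result the state belongs to.
#' @export
oscillator_state <- function(positions, velocities, bath) {
  positions <- as.matrix(positions); velocities <- as.matrix(velocities)
  if (nrow(positions) != length(bath$omega) ||
      nrow(velocities) != length(bath$omega))
    stopf("oscillator state shape does not match the bath")
  structure(list(positions = positions, velocities = velocities),
            class = "oscillator_state")
}

#' Thermal initialization of the oscillator bath
#'
#' Velocities are Maxwell--Boltzmann, per-component variance
#' \eqn{k_B T / m}; positions are Gaussian about the oscillator's potential
#' minimum (the stiffness-weighted mean of \eqn{\alpha_{1,j} X_1} and
#' \eqn{\alpha_{2,j} X_2}) with per-component variance
#' \eqn{k_B T / (k_{1,j} + k_{2,j})}. The thermal energy is fixed by the
#' Einstein--Smoluchowski relation \eqn{k_B T = M D \gamma}.
#'
#' @param dimer a [dimer_state()].
#' @param bath an oscillator bath.
#' @param kBT thermal energy.
#' @return An [oscillator_state()].
#' @export
initialize_oscillators <- function(dimer, bath, kBT) {
  check_number(kBT, "kBT", lower = 0, strict_lower = TRUE)
  N <- length(bath$omega)
  ktot <- bath$k1 + bath$k2
  centre <- (outer(bath$k1 * bath$alpha1, dimer$X1) +
               outer(bath$k2 * bath$alpha2, dimer$X2)) / ktot
  pos <- centre + matrix(rnorm(3 * N), ncol = 3) * sqrt(kBT / ktot)
  vel <- matrix(rnorm(3 * N, sd = sqrt(kBT / bath$m)), ncol = 3)
  oscillator_state(pos, vel, bath)
}

#' Forces of the coupled dimer-oscillator system
#'
#' Force on monomer `i`: spring force plus
#' \eqn{\sum_j k_{i,j}\alpha_{i,j}(x_j - \alpha_{i,j} X_i)}; acceleration of
#' oscillator `j`:
#' \eqn{[-k_{1,j}(x_j - \alpha_{1,j}X_1) - k_{2,j}(x_j - \alpha_{2,j}X_2)]/m}.
#'
#' @param dimer a [dimer_state()].
#' @param bath an oscillator bath.
#' @param state an [oscillator_state()].
#' @param spring a [spring_params()]; `NULL` omits the spring term.
#' @return List with monomer forces `F1`, `F2` and the `N x 3` matrix
#'   `osc_accel`.
#' @export
bath_forces <- function(dimer, bath, state, spring = NULL) {
  x <- state$positions
  d1 <- x - outer(bath$alpha1, dimer$X1)
  d2 <- x - outer(bath$alpha2, dimer$X2)
  F1 <- colSums(bath$k1 * bath$alpha1 * d1)
  F2 <- colSums(bath$k2 * bath$alpha2 * d2)
  if (!is.null(spring)) {
    fs <- spring_force(dimer, spring)
    F1 <- F1 + fs$F1
    F2 <- F2 + fs$F2
  }
  list(F1 = F1, F2 = F2,
       osc_accel = (-bath$k1 * d1 - bath$k2 * d2) / bath$m)
}

.check_lr_step <- function(bath, dt) {
  om_max <- sqrt(max(bath$k1 + bath$k2) / bath$m)
  if (dt * om_max > 1)
    stopf("stability error: dt * omega_max = %.3g > 1 (stiffest oscillator frequency %.3g); reduce dt",
          dt * om_max, om_max)
  invisible(om_max)
}

#' Default step for oscillator-bath runs
#'
#' `min(1e-3 / omega_bar, 0.1 / omega_max)` where `omega_max` is the largest
#' drawn frequency; the exponential tail is never truncated, the step
#' adapts instead.
#'
#' @param bath an oscillator bath.
#' @export
default_lr_step <- function(bath) {
  om_max <- sqrt(max(bath$k1 + bath$k2) / bath$m)
  min(1e-3 / bath$omega_bar, 0.1 / om_max)
}

#' One velocity-Verlet step of the full deterministic system
#'
#' Synchronized velocity Verlet for both monomers and all oscillators;
#' time-reversible and energy-conserving up to the usual bounded Verlet
#' drift.
#'
#' @param dimer a [dimer_state()].
#' @param bath an oscillator bath.
#' @param state an [oscillator_state()].
#' @param spring a [spring_params()].
#' @param M monomer mass.
#' @param dt step; must satisfy `dt * omega_max <= 1` (error above).
#' @param n_steps number of steps (default 1).
#' @return List with updated `dimer` and `state`.
#' @export
step_verlet_full <- function(dimer, bath, state, spring, M, dt, n_steps = 1L) {
  .check_lr_step(bath, dt)
  res <- cpp_long_range_run(
    X = rbind(dimer$X1, dimer$X2), V = rbind(dimer$V1, dimer$V2),
    osc_pos = state$positions, osc_vel = state$velocities,
    k1 = bath$k1, a1 = bath$alpha1, k2 = bath$k2, a2 = bath$alpha2,
    m = bath$m, M = M, k = spring$k, ell0 = spring$ell0,
    gamma = 0, D = 0, dt = dt, n_steps = as.integer(n_steps),
    sample_every = 0L, monomer2_langevin = FALSE, record_energy = FALSE)
  list(dimer = dimer_state(res$X[1, ], res$X[2, ], res$V[1, ], res$V[2, ],
                           dimer$t + n_steps * dt),
       state = oscillator_state(res$osc_pos, res$osc_vel, bath))
}

#' One step of the mixed-resolution long-range algorithm
#'
#' Monomer 1 and its oscillators evolve by velocity Verlet; monomer 2 by the
#' BBK discretization of the Langevin equation folded into the same
#' half-kick structure (acceleration
#' \eqn{-\Phi'(R)/M\,\hat R - \gamma V_2 + \gamma\sqrt{2D/\Delta t}\,\xi},
#' fresh \eqn{\xi} each step).
#'
#' @inheritParams step_verlet_full
#' @param langevin a [langevin_params()] for monomer 2.
#' @export
step_mixed_long_range <- function(dimer, bath, state, spring, langevin, dt,
                                  n_steps = 1L) {
  .check_lr_step(bath, dt)
  if (any(bath$k2 != 0))
    stopf("mixed resolution requires a bath attached to monomer 1 only (k2 = 0)")
  res <- cpp_long_range_run(
    X = rbind(dimer$X1, dimer$X2), V = rbind(dimer$V1, dimer$V2),
    osc_pos = state$positions, osc_vel = state$velocities,
    k1 = bath$k1, a1 = bath$alpha1, k2 = bath$k2, a2 = bath$alpha2,
    m = bath$m, M = langevin$M, k = spring$k, ell0 = spring$ell0,
    gamma = langevin$gamma, D = langevin$D, dt = dt,
    n_steps = as.integer(n_steps), sample_every = 0L,
    monomer2_langevin = TRUE, record_energy = FALSE)
  list(dimer = dimer_state(res$X[1, ], res$X[2, ], res$V[1, ], res$V[2, ],
                           dimer$t + n_steps * dt),
       state = oscillator_state(res$osc_pos, res$osc_vel, bath))
}

#' Simulate the dimer in the long-range oscillator heat bath
#'
#' Builds the bath, thermalizes the oscillators around the initial monomer
#' positions, and integrates the coupled system. In `"mixed"` mode monomer 2
#' follows BBK Langevin dynamics and the bath (of `N` oscillators) attaches
#' to monomer 1 only; the other modes are fully deterministic MD after the
#' random initialization.
#'
#' @param spring a [spring_params()].
#' @param p a [langevin_params()] (supplies `M`, `gamma`, `D`, and the
#'   thermal energy for initialization).
#' @param N oscillator count (per monomer in `"two_bath"`; total otherwise).
#' @param omega_bar mean oscillator frequency.
#' @param m oscillator mass.
#' @param tmax run length.
#' @param seed integer seed.
#' @param mode `"two_bath"`, `"shared"`, `"split"` or `"mixed"`.
#' @param dt step; default [default_lr_step()].
#' @param N1 first-group size for `"split"`.
#' @param state optional initial [dimer_state()]; default: monomers at rest
#'   separated by `ell0` along x.
#' @param sample_interval spacing of recorded samples.
#' @return A `"dimer_trajectory"`.
#' @export
simulate_long_range <- function(spring, p, N, omega_bar, m, tmax, seed,
                                mode = c("two_bath", "shared", "split",
                                         "mixed"),
                                dt = NULL, N1 = NULL, state = NULL,
                                sample_interval = 1e-3) {
  mode <- match.arg(mode)
  check_number(tmax, "tmax", lower = 0, strict_lower = TRUE)
  if (is.null(state))
    state <- dimer_state(X1 = c(0, 0, 0), X2 = c(spring$ell0, 0, 0))
  set.seed(seed)
  bath <- if (mode == "mixed") {
    b <- build_bath(N, omega_bar, p$gamma, m, mode = "two_bath")
    ## keep only the monomer-1 half
    idx <- seq_len(N)
    structure(list(omega = b$omega[idx], k1 = b$k1[idx],
                   alpha1 = b$alpha1[idx], k2 = numeric(N),
                   alpha2 = numeric(N), m = m, omega_bar = omega_bar,
                   gamma = p$gamma, mode = "mixed", N = N, N1 = NULL),
              class = "oscillator_bath")
  } else build_bath(N, omega_bar, p$gamma, m, mode = mode, N1 = N1)
  osc <- initialize_oscillators(state, bath, p$kBT)
  dt <- dt %||% default_lr_step(bath)
  .check_lr_step(bath, dt)
  n_steps <- round(tmax / dt)
  sample_every <- max(1L, round(sample_interval / dt))
  res <- cpp_long_range_run(
    X = rbind(state$X1, state$X2), V = rbind(state$V1, state$V2),
    osc_pos = osc$positions, osc_vel = osc$velocities,
    k1 = bath$k1, a1 = bath$alpha1, k2 = bath$k2, a2 = bath$alpha2,
    m = bath$m, M = p$M, k = spring$k, ell0 = spring$ell0,
    gamma = p$gamma, D = p$D, dt = dt, n_steps = n_steps,
    sample_every = sample_every,
    monomer2_langevin = (mode == "mixed"), record_energy = FALSE)
  new_trajectory(res$samples, t0 = state$t,
                 model = paste0("long_range_", mode),
                 params = list(spring = spring, langevin = p, N = N,
                               omega_bar = omega_bar, m = m, dt = dt,
                               mode = mode, N1 = N1),
                 seed = seed,
                 final_state = dimer_state(res$X[1, ], res$X[2, ],
                                           res$V[1, ], res$V[2, ],
                                           state$t + n_steps * dt))
}
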