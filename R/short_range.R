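## Collision molecular dynamics of the dimer in a point-particle gas,
## simulated inside a co-moving cubic frame with stochastic boundary
## insertion. The per-step algorithm: free flight; rewind-and-replay of
## monomer-solvent overlaps with elastic momentum exchange; forward-Euler
## spring kick; frame recentring and culling; erfc-tail boundary insertion
## thinned by the edge/corner overcount correction.

#' Solvent particle set
#'
#' @param positions,velocities `N x 3` matrices.
#' @param bath_id `"shared"` (collides with both monomers), `"bath1"` or
#'   `"bath2"` (collides with that monomer only).
#' @return Object of class `"solvent_set"`.
#' @export
solvent_set <- function(positions, velocities,
                        bath_id = c("shared", "bath1", "bath2")) {
  bath_id <- match.arg(bath_id)
  positions <- as.matrix(positions)
  velocities <- as.matrix(velocities)
  if (length(positions) == 0L) positions <- matrix(0, 0, 3)
  if (length(velocities) == 0L) velocities <- matrix(0, 0, 3)
  if (ncol(positions) != 3L || ncol(velocities) != 3L ||
      nrow(positions) != nrow(velocities))
    stopf("positions and velocities must be N x 3 matrices of equal length")
  structure(list(positions = positions, velocities = velocities,
                 bath_id = bath_id),
            class = "solvent_set")
}

#' @export
print.solvent_set <- function(x, ...) {
  cat(sprintf("solvent set (%s): N = %d particles\n",
              x$bath_id, nrow(x$positions)))
  invisible(x)
}

#' Co-moving cubic simulation frame
#'
#' @param centre frame centre (3-vector).
#' @param L side length.
#' @param velocity per-step frame velocity (3-vector), default zero.
#' @export
sim_frame <- function(centre, L, velocity = c(0, 0, 0)) {
  check_number(L, "L", lower = 0, strict_lower = TRUE)
  structure(list(centre = check_vec3(centre, "centre"), L = L,
                 velocity = check_vec3(velocity, "velocity")),
            class = "sim_frame")
}

#' Elastic frictionless collision between a monomer and a point particle
#'
#' Momentum- and energy-conserving exchange of the velocity components along
#' the contact normal, weighted by the mass ratio `mu = M/m`:
#' \deqn{\tilde V^\perp = \frac{\mu-1}{\mu+1} V^\perp + \frac{2}{\mu+1}
#'   v^\perp, \qquad \tilde v^\perp = \frac{1-\mu}{\mu+1} v^\perp +
#'   \frac{2\mu}{\mu+1} V^\perp,} with tangential components unchanged.
#'
#' @param V_mono monomer velocity (3-vector).
#' @param v_solv solvent particle velocity (3-vector).
#' @param n_hat unit contact normal (from monomer centre to contact point).
#' @param mu mass ratio M/m.
#' @return List with post-collision `V_mono` and `v_solv`.
#' @export
elastic_collision <- function(V_mono, v_solv, n_hat, mu) {
  n_hat <- check_vec3(n_hat, "n_hat")
  if (abs(sum(n_hat^2) - 1) > 1e-8)
    stopf("`n_hat` must be a unit vector")
  Vn <- sum(V_mono * n_hat)
  vn <- sum(v_solv * n_hat)
  list(V_mono = V_mono + 2 / (mu + 1) * (vn - Vn) * n_hat,
       v_solv = v_solv + 2 * mu / (mu + 1) * (Vn - vn) * n_hat)
}

#' Rewind a free-flight overlap to the contact time
#'
#' Given pre-step positions/velocities whose free-flight endpoints overlap
#' (separation < `r0` at `t + dt`), solves the quadratic contact condition
#' `|x_rel(t + s)| = r0` for the earliest contact time `s` in `(0, dt)` and
#' returns the rewind time `tau = dt - s` together with the outward unit
#' normal at contact.
#'
#' @param X_mono,V_mono monomer position and velocity at time t.
#' @param x_solv,v_solv solvent position and velocity at time t.
#' @param r0 monomer radius.
#' @param dt step length.
#' @return `NULL` when the pair never touches within the step; otherwise a
#'   list with `tau` (rewind time), `s = dt - tau` (contact time) and
#'   `normal`.
#' @export
resolve_collision <- function(X_mono, V_mono, x_solv, v_solv, r0, dt) {
  d0 <- x_solv - X_mono
  dv <- v_solv - V_mono
  c0 <- sum(d0^2) - r0^2
  if (c0 < 0)
    stopf("integrity error: solvent particle starts the step inside the monomer")
  a <- sum(dv^2)
  b <- 2 * sum(d0 * dv)
  disc <- b^2 - 4 * a * c0
  if (a == 0 || disc <= 0) return(NULL)
  s <- (-b - sqrt(disc)) / (2 * a)   # first root: incoming contact
  if (s <= 0 || s >= dt) return(NULL)
  contact <- d0 + dv * s
  list(tau = dt - s, s = s, normal = contact / sqrt(sum(contact^2)))
}

#' Per-face influx probability of the co-moving frame
#'
#' Expected number of statistically represented gas particles crossing one
#' face of the frame in a step of length `dt` (used as a probability in the
#' small-`dt` regime):
#' \deqn{p_{in} = \lambda_\mu L^2 \Delta t \left( \frac{\sigma_\mu}
#'   {\sqrt{2\pi}} e^{-V^2/2\sigma_\mu^2} - \frac{V}{2}\,
#'   \mathrm{erfc}\!\left(\frac{V}{\sigma_\mu\sqrt2}\right) \right),}
#' where `V` is the frame-velocity component along the inward normal of the
#' face.
#'
#' @param lambda_mu gas number density.
#' @param sigma_mu gas velocity scale.
#' @param L frame side length.
#' @param dt step length.
#' @param Vf_normal frame velocity along the inward normal of the face.
#' @export
influx_probability <- function(lambda_mu, sigma_mu, L, dt, Vf_normal) {
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  v <- Vf_normal
  p <- lambda_mu * L^2 * dt *
    (sigma_mu / sqrt(2 * pi) * exp(-v^2 / (2 * sigma_mu^2)) -
       v / 2 * erfc(v / (sigma_mu * sqrt(2))))
  if (6 * p > 0.1)
    stopf("step-size error: 6 * p_in = %.3g > 0.1; reduce dt (or L)", 6 * p)
  p
}

#' Edge/corner overcount acceptance factor
#'
#' Boundary insertion integrates influx over six half-spaces, which counts
#' edge regions twice and corner regions three times. A proposed particle
#' whose back-propagated pre-step position has `j` coordinates outside the
#' frame is therefore accepted with probability `1/j`.
#'
#' @param y_rel back-propagated pre-step position minus the (pre-step) frame
#'   centre.
#' @param L frame side length.
#' @return `1`, `1/2` or `1/3`.
#' @export
overcount_acceptance <- function(y_rel, L) {
  y_rel <- check_vec3(y_rel, "y_rel")
  j <- sum(abs(y_rel) > L / 2)
  if (j == 0L)
    stopf("integrity error: an entering particle must originate outside the frame")
  1 / j
}

#' Sample position and velocity of an entering solvent particle
#'
#' Draws the lab-frame position and velocity of a particle entering through
#' one face of the co-moving frame during one step. The penetration depth is
#' `sigma_mu * dt * sqrt(2)` times an erfc-tail sample with
#' `beta = Vn / (sigma_mu * sqrt(2))` (`Vn` = frame velocity along the
#' face's inward normal); transverse coordinates are uniform on the face;
#' the velocity component along the inward normal is Gaussian conditioned to
#' carry the particle to its depth within `dt`.
#'
#' @param face integer 1..6: faces in axis order (x-low, x-high, y-low,
#'   y-high, z-low, z-high).
#' @param frame a [sim_frame()] with its post-step centre and per-step
#'   velocity.
#' @param bath a [short_range_bath_params()].
#' @param dt step length.
#' @return List with `position` and `velocity` (lab coordinates) and the
#'   frame-coordinate `depth`.
#' @export
sample_incoming_particle <- function(face, frame, bath, dt) {
  if (!face %in% 1:6) stopf("`face` must be in 1..6")
  axis <- (face + 1L) %/% 2L           # 1, 1, 2, 2, 3, 3
  low <- face %% 2L == 1L
  sgn <- if (low) 1 else -1            # inward normal sign along `axis`
  sigma <- bath$sigma_mu
  Vn <- sgn * frame$velocity[axis]
  beta <- Vn / (sigma * sqrt(2))
  depth <- sigma * dt * sqrt(2) * erfc_tail_sample(1L, beta)[1L]
  vn <- rtnorm_lower(1L, sd = sigma, lower = depth / dt + Vn)
  vt <- rnorm(2L, sd = sigma)
  pos <- frame$centre
  vel <- numeric(3)
  other <- setdiff(1:3, axis)
  pos[axis] <- frame$centre[axis] + sgn * (depth - frame$L / 2)
  pos[other] <- frame$centre[other] - frame$L / 2 + runif(2L) * frame$L
  ## the truncated variable is the lab velocity measured along the inward
  ## normal of the face; map back to the lab axis direction
  vel[axis] <- sgn * vn
  vel[other] <- vt
  list(position = pos, velocity = vel, depth = depth)
}

#' Initialize the solvent in one or two co-moving frames
#'
#' Draws a Poisson(`lambda_mu * L^3`) number of particles uniformly in each
#' frame with Maxwell-Boltzmann velocities, then removes particles
#' overlapping a monomer they can collide with.
#'
#' @param dimer a [dimer_state()].
#' @param frames a single [sim_frame()] (`mode = "one_bath"`) or list of two
#'   frames centred on the monomers (`mode = "two_bath"`); for
#'   `mode = "mixed"` one frame centred on monomer 1.
#' @param bath a [short_range_bath_params()].
#' @param mode `"one_bath"`, `"two_bath"` or `"mixed"`.
#' @return A [solvent_set()] or (for `"two_bath"`) a list of two.
#' @export
initialize_short_range <- function(dimer, frames, bath,
                                   mode = c("one_bath", "two_bath", "mixed")) {
  mode <- match.arg(mode)
  fill <- function(frame, id, monomers) {
    n <- rpois(1L, bath$lambda_mu * frame$L^3)
    pos <- matrix(runif(3 * n, -frame$L / 2, frame$L / 2), ncol = 3,
                  byrow = TRUE) +
      matrix(frame$centre, n, 3, byrow = TRUE)
    keep <- rep(TRUE, n)
    for (Xm in monomers)
      keep <- keep & (rowSums((pos - matrix(Xm, n, 3, byrow = TRUE))^2) >=
                        bath$r0^2)
    solvent_set(pos[keep, , drop = FALSE],
                maxwell_boltzmann_sample(sum(keep), bath$sigma_mu), id)
  }
  switch(mode,
    one_bath = fill(frames, "shared", list(dimer$X1, dimer$X2)),
    mixed = fill(frames, "bath1", list(dimer$X1)),
    two_bath = {
      if (!is.list(frames) || length(frames) != 2L)
        stopf("two_bath mode needs a list of two frames")
      list(fill(frames[[1]], "bath1", list(dimer$X1)),
           fill(frames[[2]], "bath2", list(dimer$X2)))
    })
}

## ---- stepping (single-step wrappers over the compiled engine) ----

sr_mode_code <- c(one_bath = 0L, two_bath = 1L, mixed = 2L,
                  bath_only = 3L, drag = 4L)

#' One iteration of the co-moving-frame collision MD algorithm
#'
#' Advances dimer, solvent and frame by one step `dt`: free flight, overlap
#' rewind and elastic exchange, spring kick, frame recentring (per
#' `frame_anchor`) with culling of departed particles, and boundary
#' insertion thinned by [overcount_acceptance()]. Uses R's global RNG; seed
#' with `set.seed()` before stepping for reproducibility.
#'
#' @param dimer a [dimer_state()].
#' @param solvent a [solvent_set()].
#' @param frame a [sim_frame()] (its `L` is used; the centre is re-anchored).
#' @param spring a [spring_params()].
#' @param bath a [short_range_bath_params()].
#' @param dt step length.
#' @param frame_anchor `"com"`, `"monomer1"` or `"monomer2"`.
#' @return List with updated `dimer`, `solvent`, `frame` and `counters`.
#' @export
step_comoving <- function(dimer, solvent, frame, spring, bath, dt,
                          frame_anchor = c("com", "monomer1", "monomer2")) {
  frame_anchor <- match.arg(frame_anchor)
  res <- cpp_short_range_run(
    mode = sr_mode_code[["one_bath"]],
    X = rbind(dimer$X1, dimer$X2), V = rbind(dimer$V1, dimer$V2),
    sol_pos = list(solvent$positions), sol_vel = list(solvent$velocities),
    r0 = bath$r0, mu = bath$mu, gamma = bath$gamma, D = bath$D,
    M = bath$M, k = spring$k, ell0 = spring$ell0,
    L = frame$L, dt = dt, n_steps = 1L, sample_every = 0L,
    anchor = match(frame_anchor, c("com", "monomer1", "monomer2")) - 1L,
    frame_centre = frame$centre, drag_velocity = c(0, 0, 0),
    record_counts = FALSE, pool_velocities = FALSE)
  list(dimer = dimer_state(res$X[1, ], res$X[2, ], res$V[1, ], res$V[2, ],
                           dimer$t + dt),
       solvent = solvent_set(res$sol_pos[[1]], res$sol_vel[[1]],
                             solvent$bath_id),
       frame = sim_frame(res$frame_centre, frame$L, res$frame_velocity),
       counters = res$counters)
}

#' One iteration of the mixed-resolution (MD / Langevin) algorithm
#'
#' Monomer 1 undergoes collision MD inside a frame anchored on itself;
#' monomer 2 follows an Euler--Maruyama Langevin update with the shared
#' spring force.
#'
#' @inheritParams step_comoving
#' @param langevin a [langevin_params()] for monomer 2.
#' @export
step_mixed_resolution <- function(dimer, solvent, frame, spring, bath,
                                  langevin, dt) {
  if (!identical(solvent$bath_id, "bath1"))
    stopf("mixed resolution requires a bath1 solvent set (collides with monomer 1 only)")
  res <- cpp_short_range_run(
    mode = sr_mode_code[["mixed"]],
    X = rbind(dimer$X1, dimer$X2), V = rbind(dimer$V1, dimer$V2),
    sol_pos = list(solvent$positions), sol_vel = list(solvent$velocities),
    r0 = bath$r0, mu = bath$mu, gamma = langevin$gamma, D = langevin$D,
    M = langevin$M, k = spring$k, ell0 = spring$ell0,
    L = frame$L, dt = dt, n_steps = 1L, sample_every = 0L,
    anchor = 1L, frame_centre = frame$centre, drag_velocity = c(0, 0, 0),
    record_counts = FALSE, pool_velocities = FALSE)
  list(dimer = dimer_state(res$X[1, ], res$X[2, ], res$V[1, ], res$V[2, ],
                           dimer$t + dt),
       solvent = solvent_set(res$sol_pos[[1]], res$sol_vel[[1]], "bath1"),
       frame = sim_frame(res$frame_centre, frame$L, res$frame_velocity),
       counters = res$counters)
}

#' Simulate the dimer in the short-range collision heat bath
#'
#' Full co-moving-frame run in one of three configurations: `"one_bath"`
#' (both monomers share one gas inside a frame anchored at the centre of
#' mass), `"two_bath"` (independent gases in two frames, each anchored on
#' its monomer), or `"mixed"` (monomer 1 by collision MD, monomer 2 by
#' Langevin dynamics).
#'
#' @param spring a [spring_params()].
#' @param bath a [short_range_bath_params()].
#' @param L frame side length (per frame).
#' @param tmax run length.
#' @param dt step length.
#' @param seed integer seed.
#' @param mode `"one_bath"`, `"two_bath"` or `"mixed"`.
#' @param state optional initial [dimer_state()]; default: monomers at rest
#'   separated by `ell0` along x.
#' @param sample_interval spacing of recorded samples.
#' @return A `"dimer_trajectory"` with event counters.
#' @export
simulate_short_range <- function(spring, bath, L, tmax, dt, seed,
                                 mode = c("two_bath", "one_bath", "mixed"),
                                 state = NULL, sample_interval = 1e-3) {
  mode <- match.arg(mode)
  check_number(tmax, "tmax", lower = 0, strict_lower = TRUE)
  if (L <= 2 * bath$r0)
    stopf("frame side L = %g must exceed the monomer diameter %g", L, 2 * bath$r0)
  if (is.null(state))
    state <- dimer_state(X1 = c(0, 0, 0), X2 = c(spring$ell0, 0, 0))
  set.seed(seed)
  frames <- switch(mode,
    one_bath = sim_frame((state$X1 + state$X2) / 2, L),
    mixed = sim_frame(state$X1, L),
    two_bath = list(sim_frame(state$X1, L), sim_frame(state$X2, L)))
  solvent <- initialize_short_range(state, frames, bath, mode)
  if (mode != "two_bath") solvent <- list(solvent)
  n_steps <- round(tmax / dt)
  sample_every <- max(1L, round(sample_interval / dt))
  res <- cpp_short_range_run(
    mode = sr_mode_code[[mode]],
    X = rbind(state$X1, state$X2), V = rbind(state$V1, state$V2),
    sol_pos = lapply(solvent, `[[`, "positions"),
    sol_vel = lapply(solvent, `[[`, "velocities"),
    r0 = bath$r0, mu = bath$mu, gamma = bath$gamma, D = bath$D,
    M = bath$M, k = spring$k, ell0 = spring$ell0,
    L = L, dt = dt, n_steps = n_steps, sample_every = sample_every,
    anchor = if (mode == "one_bath") 0L else 1L,
    frame_centre = if (mode == "one_bath") (state$X1 + state$X2) / 2
                   else state$X1,
    drag_velocity = c(0, 0, 0),
    record_counts = FALSE, pool_velocities = FALSE)
  new_trajectory(res$samples, t0 = state$t,
                 model = paste0("short_range_", mode),
                 params = list(spring = spring, bath = bath, L = L, dt = dt,
                               mode = mode),
                 seed = seed,
                 final_state = dimer_state(res$X[1, ], res$X[2, ],
                                           res$V[1, ], res$V[2, ],
                                           state$t + n_steps * dt),
                 counters = res$counters)
}

#' Evolve an empty (or dragged) co-moving frame of gas
#'
#' Diagnostic run without monomers: the frame translates at a constant
#' velocity while the insertion/culling machinery maintains the gas. Used to
#' verify that the boundary treatment preserves the equilibrium state
#' (Poisson particle counts, Maxwell-Boltzmann velocities).
#'
#' @param bath a [short_range_bath_params()].
#' @param L frame side length.
#' @param tmax,dt run length and step.
#' @param seed integer seed.
#' @param drag_velocity constant frame velocity (3-vector).
#' @param sample_interval spacing of recorded snapshots.
#' @return List with `counts` (N(t) at snapshot times), `velocity_pool`
#'   (solvent velocity components pooled over snapshots), final `solvent`,
#'   and `counters`.
#' @export
simulate_bath_frame <- function(bath, L, tmax, dt, seed,
                                drag_velocity = c(0, 0, 0),
                                sample_interval = NULL) {
  set.seed(seed)
  n <- rpois(1L, bath$lambda_mu * L^3)
  pos <- matrix(runif(3 * n, -L / 2, L / 2), ncol = 3)
  vel <- maxwell_boltzmann_sample(n, bath$sigma_mu)
  n_steps <- round(tmax / dt)
  sample_interval <- sample_interval %||% (tmax / 200)
  sample_every <- max(1L, round(sample_interval / dt))
  res <- cpp_short_range_run(
    mode = sr_mode_code[["bath_only"]],
    X = matrix(0, 2, 3), V = matrix(0, 2, 3),
    sol_pos = list(pos), sol_vel = list(vel),
    r0 = bath$r0, mu = bath$mu, gamma = bath$gamma, D = bath$D,
    M = bath$M, k = 0, ell0 = 0,
    L = L, dt = dt, n_steps = n_steps, sample_every = sample_every,
    anchor = 0L, frame_centre = c(0, 0, 0),
    drag_velocity = check_vec3(drag_velocity, "drag_velocity"),
    record_counts = TRUE, pool_velocities = TRUE)
  list(counts = res$counts,
       velocity_pool = res$velocity_pool,
       solvent = solvent_set(res$sol_pos[[1]], res$sol_vel[[1]], "shared"),
       counters = res$counters)
}

#' Measure the collision drag on a monomer held at constant velocity
#'
#' Diagnostic used to calibrate the bath density: a single monomer moves at
#' constant velocity `V0` through the gas (its velocity is not updated by
#' collisions) and the momentum transferred by collisions is accumulated.
#' The mean force divided by `M |V0|` estimates the realized friction
#' coefficient, which should match `gamma`.
#'
#' @param bath a [short_range_bath_params()].
#' @param L frame side length.
#' @param V0 imposed monomer velocity (3-vector).
#' @param tmax,dt run length and step.
#' @param seed integer seed.
#' @return List with `friction_estimate`, total `impulse` and `counters`.
#' @export
measure_collision_friction <- function(bath, L, V0, tmax, dt, seed) {
  V0 <- check_vec3(V0, "V0")
  set.seed(seed)
  n <- rpois(1L, bath$lambda_mu * L^3)
  pos <- matrix(runif(3 * n, -L / 2, L / 2), ncol = 3)
  keep <- rowSums(pos^2) >= bath$r0^2
  pos <- pos[keep, , drop = FALSE]
  vel <- maxwell_boltzmann_sample(nrow(pos), bath$sigma_mu)
  n_steps <- round(tmax / dt)
  res <- cpp_short_range_run(
    mode = sr_mode_code[["drag"]],
    X = rbind(c(0, 0, 0), c(0, 0, 0)), V = rbind(V0, c(0, 0, 0)),
    sol_pos = list(pos), sol_vel = list(vel),
    r0 = bath$r0, mu = bath$mu, gamma = bath$gamma, D = bath$D,
    M = bath$M, k = 0, ell0 = 0,
    L = L, dt = dt, n_steps = n_steps, sample_every = 0L,
    anchor = 1L, frame_centre = c(0, 0, 0), drag_velocity = c(0, 0, 0),
    record_counts = FALSE, pool_velocities = FALSE)
  Fmean <- res$impulse / (n_steps * dt)
  speed2 <- sum(V0^2)
  list(friction_estimate = -sum(Fmean * V0) / (bath$M * speed2),
       impulse = res$impulse, counters = res$counters)
}
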