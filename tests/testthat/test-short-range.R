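test_that("elastic collision has the right mass-ratio limits", {
  n <- c(1, 0, 0)
  V <- c(3, 1, -2); v <- c(-5, 2, 4)
  ## equal masses: normal components swap
  out <- elastic_collision(V, v, n, mu = 1)
  expect_equal(out$V_mono, c(-5, 1, -2))
  expect_equal(out$v_solv, c(3, 2, 4))
  ## very heavy monomer: solvent reflects about the monomer velocity
  out <- elastic_collision(V, v, n, mu = 1e12)
  expect_equal(out$V_mono, V, tolerance = 1e-10)
  expect_equal(out$v_solv, c(2 * V[1] - v[1], v[2], v[3]), tolerance = 1e-9)
  expect_error(elastic_collision(V, v, c(1, 1, 0), 10), "unit")
})

test_that("collisions conserve momentum and energy to machine precision", {
  set.seed(21)
  mu <- 1e3
  M <- 1; m <- M / mu
  for (i in 1:1e4) {
    V <- rnorm(3, sd = 3); v <- rnorm(3, sd = 100)
    n <- random_unit_vector()
    out <- elastic_collision(V, v, n, mu)
    P0 <- M * V + m * v
    P1 <- M * out$V_mono + m * out$v_solv
    E0 <- M * sum(V^2) + m * sum(v^2)
    E1 <- M * sum(out$V_mono^2) + m * sum(out$v_solv^2)
    expect_lt(max(abs(P1 - P0)), 1e-12 * max(1, max(abs(P0))))
    expect_lt(abs(E1 - E0), 1e-10 * E0)
  }
})

test_that("overlap rewind finds the exact contact time and normal", {
  r0 <- 0.08; dt <- 1e-3
  ## head-on: starts at r0 + d, closes at speed u, contact at s = d / u
  d <- 2e-5; u <- 0.1
  res <- resolve_collision(X_mono = c(0, 0, 0), V_mono = c(0, 0, 0),
                           x_solv = c(r0 + d, 0, 0), v_solv = c(-u, 0, 0),
                           r0 = r0, dt = dt)
  expect_equal(res$tau, dt - d / u, tolerance = 1e-12)
  expect_equal(res$normal, c(1, 0, 0))
  ## tangential grazing never makes contact
  res <- resolve_collision(c(0, 0, 0), c(0, 0, 0),
                           c(r0 * 1.001, 0, 0), c(0, 1, 0), r0, dt)
  expect_null(res)
  ## particle inside at the start of the step is an integrity error
  expect_error(resolve_collision(c(0, 0, 0), c(0, 0, 0),
                                 c(r0 / 2, 0, 0), c(1, 0, 0), r0, dt),
               "integrity")
})

test_that("rewound configurations touch at separation r0", {
  set.seed(22)
  r0 <- 0.08; dt <- 1e-4
  found <- 0
  while (found < 200) {
    X <- rnorm(3, sd = 0.1); V <- rnorm(3, sd = 3)
    dir <- random_unit_vector()
    x <- X + dir * (r0 * (1 + runif(1)))
    v <- rnorm(3, sd = 100)
    ## only configurations whose free flight ends inside the monomer
    if (sum((x + v * dt - X - V * dt)^2) >= r0^2) next
    res <- resolve_collision(X, V, x, v, r0, dt)
    expect_false(is.null(res))
    sep <- sqrt(sum((x + v * res$s - X - V * res$s)^2))
    expect_equal(sep, r0, tolerance = 1e-10)
    ## bisection oracle on the separation function
    f <- function(s) sqrt(sum((x + v * s - X - V * s)^2)) - r0
    s_star <- uniroot(f, c(0, res$s + 1e-12), tol = 1e-14)$root
    expect_equal(res$s, s_star, tolerance = 1e-8)
    found <- found + 1
  }
})

test_that("influx probability has the closed static form and V limits", {
  lam <- 2000; sig <- 100; L <- 0.32; dt <- 1e-7
  expect_equal(influx_probability(lam, sig, L, dt, 0),
               lam * L^2 * dt * sig / sqrt(2 * pi), tolerance = 1e-12)
  vs <- seq(-200, 200, by = 50)
  ps <- vapply(vs, function(v) influx_probability(lam, sig, L, dt, v),
               numeric(1))
  expect_true(all(diff(ps) < 0))     # frame outrunning the gas sees less
  expect_lt(influx_probability(lam, sig, L, dt, 1e4), 1e-12)
  expect_error(influx_probability(lam, sig, L, 1e-3, 0), "step-size")
})

test_that("influx probability matches free-streaming Monte-Carlo counts", {
  ## gas at rest, plane moving at velocity V: count crossings in one step.
  ## 1e6 independent windows are simulated at once as one Poisson cloud.
  set.seed(23)
  lam <- 1; sig <- 1; L <- 0.5; dt <- 0.05
  n_win <- 1e6
  for (V in c(-sig, 0.5 * sig)) {
    p <- influx_probability(lam, sig, L, dt, V)
    W <- (8 * sig + abs(V)) * dt
    Np <- rpois(1, n_win * lam * L^2 * W)
    x0 <- -runif(Np) * W
    vx <- rnorm(Np, sd = sig)
    crossings <- sum(x0 + vx * dt > V * dt)
    expect_lt(abs(crossings - n_win * p), 3 * sqrt(n_win * p))
  }
})

test_that("overcount acceptance thins edge and corner insertions", {
  L <- 1
  expect_equal(overcount_acceptance(c(0.6, 0, 0) * L, L), 1)
  expect_equal(overcount_acceptance(c(0.6, 0.6, 0) * L, L), 1 / 2)
  expect_equal(overcount_acceptance(c(0.6, 0.6, -0.6) * L, L), 1 / 3)
  expect_error(overcount_acceptance(c(0.1, 0.2, 0) * L, L), "integrity")
})

test_that("incoming particles have the stated depth law and reachability", {
  set.seed(24)
  bath <- preset_bath()
  dt <- 1e-6
  fr <- sim_frame(c(0, 0, 0), L = 0.32, velocity = c(0, 0, 0))
  n <- 4000
  draws <- replicate(n, {
    s <- sample_incoming_particle(1L, fr, bath, dt)
    c(s$depth, s$position, s$velocity)
  })
  depth <- draws[1, ]
  scale <- bath$sigma_mu * dt * sqrt(2)
  ks <- suppressWarnings(ks.test(depth / scale,
                                 function(q) erfc_tail_cdf(q, 0)))
  expect_gt(ks$p.value, 0.01)
  ## every particle can reach its depth within dt (Heaviside constraint)
  expect_true(all(draws[5, ] * dt > depth))
  ## transverse coordinates uniform on the face
  expect_gt(suppressWarnings(
    ks.test(draws[3, ], "punif", -0.16, 0.16)$p.value), 0.01)

  ## the opposite face is the mirror image
  draws2 <- replicate(n, {
    s <- sample_incoming_particle(2L, fr, bath, dt)
    c(s$depth, s$position, s$velocity)
  })
  expect_gt(suppressWarnings(ks.test(depth, draws2[1, ])$p.value), 0.01)
  expect_true(all(draws2[5, ] < 0))  # enters moving in the -x direction
})

test_that("solvent initialization culls monomer overlap and reproduces", {
  bath <- preset_bath()
  sp <- preset_spring()
  st <- dimer_state(c(0, 0, 0), c(sp$ell0, 0, 0))
  set.seed(31)
  counts <- replicate(60, {
    s <- initialize_short_range(st, sim_frame(c(0, 0, 0), 0.32), bath,
                                mode = "one_bath")
    nrow(s$positions)
  })
  L <- 0.32
  vol_frac <- 2 * (4 / 3) * pi * bath$r0^3 / L^3
  expected <- bath$lambda_mu * L^3 * (1 - vol_frac)
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected / 60))
  ## two-bath mode returns independently tagged sets
  set.seed(32)
  both <- initialize_short_range(
    st, list(sim_frame(st$X1, 0.32), sim_frame(st$X2, 0.32)), bath,
    mode = "two_bath")
  expect_identical(both[[1]]$bath_id, "bath1")
  expect_identical(both[[2]]$bath_id, "bath2")
  ## determinism
  set.seed(33)
  a <- initialize_short_range(st, sim_frame(c(0, 0, 0), 0.32), bath,
                              "one_bath")
  set.seed(33)
  b <- initialize_short_range(st, sim_frame(c(0, 0, 0), 0.32), bath,
                              "one_bath")
  expect_identical(a$positions, b$positions)
})

test_that("single steps compose to the same trajectory as a full run", {
  sp <- preset_spring()
  bath <- preset_bath()
  tr <- simulate_short_range(sp, bath, L = 0.32, tmax = 2e-4, dt = 1e-6,
                             seed = 77, mode = "mixed",
                             sample_interval = 1e-6)
  ## replay: same seed, same initialization, stepping one step at a time
  set.seed(77)
  st <- dimer_state(c(0, 0, 0), c(sp$ell0, 0, 0))
  fr <- sim_frame(st$X1, 0.32)
  sol <- initialize_short_range(st, fr, bath, mode = "mixed")
  lp <- langevin_params(1, bath$D, bath$gamma)
  for (i in 1:200) {
    out <- step_mixed_resolution(st, sol, fr, sp, bath, lp, dt = 1e-6)
    st <- out$dimer; sol <- out$solvent; fr <- out$frame
  }
  expect_equal(unname((st$X1 + st$X2) / 2), unname(tr$Xbar[200, ]),
               tolerance = 1e-12)
  expect_equal(dimer_separation(st), tr$R[200], tolerance = 1e-12)
})

test_that("with no solvent a step reduces to symplectic-Euler oscillation", {
  sp <- preset_spring(k = 100, ell0 = 0.3)
  bath <- preset_bath()
  st <- dimer_state(c(0, 0, 0), c(0.35, 0, 0))
  sol <- solvent_set(matrix(0, 0, 3), matrix(0, 0, 3), "shared")
  fr <- sim_frame(c(0.175, 0, 0), 0.32)
  dt <- 1e-6
  set.seed(1)
  out <- step_comoving(st, sol, fr, sp, bath, dt)
  ## manual symplectic Euler: drift, then spring kick at the new positions
  X1 <- st$X1 + st$V1 * dt; X2 <- st$X2 + st$V2 * dt
  R <- X2 - X1; Rn <- sqrt(sum(R^2))
  kick <- sp$k * (Rn - sp$ell0) / Rn * R * dt
  expect_equal(out$dimer$X1, X1)
  expect_equal(out$dimer$X2, X2)
  expect_equal(out$dimer$V1, st$V1 + kick, tolerance = 1e-14)
  expect_equal(out$dimer$V2, st$V2 - kick, tolerance = 1e-14)
})

test_that("the co-moving frame maintains gas equilibrium (static and dragged)", {
  ## the strongest joint test of influx, depth/velocity sampling and the
  ## overcount thinning: an empty frame must keep N(t) Poisson and the
  ## velocities Maxwell-Boltzmann
  bath <- preset_bath()
  L <- 0.16
  target_N <- bath$lambda_mu * L^3
  for (vdrag in list(c(0, 0, 0), c(bath$sigma_mu / 100, 0, 0))) {
    res <- simulate_bath_frame(bath, L = L, tmax = 0.5, dt = 5e-6,
                               seed = 41 + round(vdrag[1]),
                               drag_velocity = vdrag,
                               sample_interval = 2.5e-3)
    counts <- res$counts
    expect_lt(abs(mean(counts) - target_N),
              3 * sqrt(target_N / length(counts)))
    ## chi-squared against Poisson(lambda L^3), pooled tails
    brk <- qpois(c(0.05, 0.2, 0.4, 0.6, 0.8, 0.95), target_N)
    cuts <- c(-Inf, unique(brk), Inf)
    obs <- table(cut(counts, cuts))
    pr <- diff(ppois(c(-Inf, unique(brk), Inf), target_N))
    chi <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
    expect_gt(chi$p.value, 0.01)
    ## velocities stay Maxwell-Boltzmann in the lab frame
    vp <- matrix(res$velocity_pool, ncol = 3, byrow = TRUE)
    expect_gt(suppressWarnings(
      ks.test(vp[, 1], "pnorm", 0, bath$sigma_mu)$p.value), 0.01)
    expect_gt(suppressWarnings(
      ks.test(vp[, 3], "pnorm", 0, bath$sigma_mu)$p.value), 0.01)
    ## no integrity guard events
    expect_equal(res$counters$origin_inside_guard, 0)
  }
})

test_that("two-bath dimer simulation reproduces and tracks the Langevin limit", {
  sp <- preset_spring()
  bath <- preset_bath()
  tr <- simulate_short_range(sp, bath, L = 0.32, tmax = 1.5, dt = 1e-6,
                             seed = 51, mode = "two_bath")
  tr2 <- simulate_short_range(sp, bath, L = 0.32, tmax = 1.5, dt = 1e-6,
                              seed = 51, mode = "two_bath")
  expect_identical(tr$R, tr2$R)
  expect_gt(tr$counters$collisions, 1e4)   # ~7.5e3 per monomer per unit time
  len <- estimate_mean_length(tr, burn_in = 0.5)
  pred <- analytic_mean_length(sp, preset_langevin())
  ## desk-scale run: the CI must cover the Langevin prediction
  expect_gt(pred, len$ci[1])
  expect_lt(pred, len$ci[2])
  ## centre-of-mass velocity variance approaches D gamma / 2 per component
  v <- tr$Vbar[tr$times > 0.5, ]
  expect_equal(mean(v^2), bath$D * bath$gamma / 2, tolerance = 0.2)
})

test_that("shared-bath (one-bath) collision runs stay within the frame budget", {
  sp <- preset_spring()
  bath <- preset_bath()
  tr <- simulate_short_range(sp, bath, L = 0.48, tmax = 0.2, dt = 5e-7,
                             seed = 52, mode = "one_bath")
  expect_gt(tr$counters$collisions, 1e3)
  expect_true(all(is.finite(tr$R)))
  expect_gt(min(tr$R), 2 * bath$r0)  # monomers never interpenetrate badly
  expect_error(simulate_short_range(sp, bath, L = 0.1, tmax = 0.1,
                                    dt = 1e-6, seed = 1, mode = "one_bath"),
               "exceed")
})
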