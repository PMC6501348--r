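test_that("bath construction satisfies the exact coupling sum rules", {
  set.seed(61)
  g <- 10; w <- 100; m <- 1e-3
  ## two-bath: m * sum(alpha^2 omega^2) = 2 gamma omega_bar / pi exactly,
  ## independent of the drawn frequencies (= kappa_i(0))
  b <- build_bath(500, w, g, m, mode = "two_bath")
  s1 <- m * sum(b$alpha1^2 * b$omega^2)
  s2 <- m * sum(b$alpha2^2 * b$omega^2)
  expect_equal(s1, 2 * g * w / pi, tolerance = 1e-12)
  expect_equal(s2, 2 * g * w / pi, tolerance = 1e-12)
  ## shared: sum k_j alpha_j^2 = gamma omega_bar / pi exactly
  bs <- build_bath(500, w, g, m, mode = "shared")
  expect_equal(sum(bs$k1 * bs$alpha1^2), g * w / pi, tolerance = 1e-12)
  ## split: groups attach exclusively and normalize per group
  sp <- build_bath(300, w, g, m, mode = "split", N1 = 100)
  expect_true(all(sp$k2[1:100] == 0) && all(sp$k1[101:300] == 0))
  expect_equal(m * sum(sp$alpha1^2 * sp$omega^2 * (sp$k1 > 0)),
               2 * g * w / pi, tolerance = 1e-12)
  ## frequencies are exponential with mean omega_bar
  set.seed(62)
  bb <- build_bath(1e4, w, g, m, mode = "shared")
  expect_lt(abs(mean(bb$omega) - w), 3 * w / sqrt(1e4))
})

test_that("the friction kernel is Lorentzian with total integral gamma", {
  g <- 10; w <- 100
  expect_equal(friction_kernel(0, g, w), 2 * g * w / pi)
  expect_equal(friction_kernel(1 / w, g, w), friction_kernel(0, g, w) / 2)
  quad <- integrate(friction_kernel, 0, Inf, gamma = g, omega_bar = w,
                    rel.tol = 1e-10)$value
  expect_equal(quad, g, tolerance = 1e-6)
})

test_that("drawn baths realize the Lorentzian kernel as N grows", {
  set.seed(63)
  g <- 10; w <- 100
  tau <- seq(0, 0.1, by = 0.002)
  reps <- 6
  emp <- replicate(reps, {
    b <- build_bath(1e4, w, g, 1e-3, mode = "two_bath")
    empirical_friction_kernel(tau, b, monomer = 1)
  })
  m_emp <- rowMeans(emp)
  se <- apply(emp, 1, sd) / sqrt(reps)
  ref <- friction_kernel(tau, g, w)
  expect_true(all(abs(m_emp - ref) < 4 * se + 1e-9))
  ## and the kernel value at 0 is exact by construction
  expect_equal(emp[1, 1], friction_kernel(0, g, w), tolerance = 1e-10)
})

test_that("bath forces match a naive per-oscillator evaluation", {
  set.seed(64)
  b <- build_bath(40, 100, 10, 1e-3, mode = "shared")
  st <- dimer_state(rnorm(3), rnorm(3) + c(2, 0, 0), rnorm(3), rnorm(3))
  osc <- oscillator_state(matrix(rnorm(120), ncol = 3),
                          matrix(rnorm(120), ncol = 3), b)
  f <- bath_forces(st, b, osc)
  F1 <- c(0, 0, 0); acc1 <- matrix(0, 40, 3)
  for (j in 1:40) {
    d1 <- osc$positions[j, ] - b$alpha1[j] * st$X1
    d2 <- osc$positions[j, ] - b$alpha2[j] * st$X2
    F1 <- F1 + b$k1[j] * b$alpha1[j] * d1
    acc1[j, ] <- (-b$k1[j] * d1 - b$k2[j] * d2) / b$m
  }
  expect_equal(f$F1, F1, tolerance = 1e-12)
  expect_equal(f$osc_accel, acc1, tolerance = 1e-12)
  ## oscillators at their minima exert no force on the monomers
  osc0 <- oscillator_state(outer(b$alpha1, st$X1), osc$velocities, b)
  ## (shared bath: both couplings identical, minimum only when X1 = X2;
  ##  use a two-bath for the clean statement)
  b2 <- build_bath(40, 100, 10, 1e-3, mode = "two_bath")
  osc2 <- oscillator_state(
    outer(b2$alpha1, st$X1) * (b2$k1 > 0) +
      outer(b2$alpha2, st$X2) * (b2$k2 > 0),
    matrix(0, 80, 3), b2)
  f2 <- bath_forces(st, b2, osc2)
  expect_equal(f2$F1, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(f2$F2, c(0, 0, 0), tolerance = 1e-10)
})

test_that("thermal initialization satisfies equipartition and the
           fluctuation-dissipation relation", {
  set.seed(65)
  g <- 10; w <- 100; kBT <- 10
  st <- dimer_state(c(0, 0, 0), c(0.32, 0, 0))
  b <- build_bath(2e4, w, g, 1e-3, mode = "two_bath")
  osc <- initialize_oscillators(st, b, kBT)
  ## potential energy per component about the minimum: kBT / 2
  ktot <- b$k1 + b$k2
  centre <- (outer(b$k1 * b$alpha1, st$X1) +
               outer(b$k2 * b$alpha2, st$X2)) / ktot
  pe <- ktot * (osc$positions - centre)^2 / 2
  expect_equal(mean(pe), kBT / 2, tolerance = 3 * sqrt(2) / sqrt(6e4) * 10)
  expect_equal(mean(b$m * osc$velocities^2), kBT, tolerance = 0.05 * kBT)

  ## fluctuation-dissipation: with the monomer pinned, the autocovariance
  ## of the summed bath force equals kBT * kappa(tau) per component
  ## (oscillators evolve freely: x(t) = mean + d cos wt + (v/w) sin wt)
  nrep <- 400
  tau <- c(0, 0.005, 0.01, 0.02)
  N <- 3000
  acc <- matrix(0, nrep, length(tau))
  for (r in 1:nrep) {
    bb <- build_bath(N, w, g, 1e-3, mode = "two_bath")
    keep <- bb$k1 > 0
    om <- bb$omega[keep]; kj <- bb$k1[keep]; aj <- bb$alpha1[keep]
    d <- rnorm(N, sd = sqrt(kBT / kj))       # displacement, x component
    v <- rnorm(N, sd = sqrt(kBT / bb$m))
    F_t <- function(t) sum(kj * aj * (d * cos(om * t) +
                                        (v / om) * sin(om * t)))
    F0 <- F_t(0)
    acc[r, ] <- vapply(tau, function(s) F0 * F_t(s), numeric(1))
  }
  covF <- colMeans(acc)
  se <- apply(acc, 2, sd) / sqrt(nrep)
  ## alpha^2 k = m alpha^2 omega^2: the force autocovariance target
  ref <- kBT * friction_kernel(tau, g, w)
  expect_true(all(abs(covF - ref) < 4 * se))
})

test_that("velocity Verlet traces a single oscillator and conserves energy", {
  ## single oscillator against a pinned (infinitely heavy) monomer
  m <- 1e-3; w0 <- 50; kj <- m * w0^2
  b <- structure(list(omega = w0, k1 = kj, alpha1 = 1, k2 = 0, alpha2 = 0,
                      m = m, omega_bar = w0, gamma = 0, mode = "two_bath",
                      N = 1, N1 = NULL), class = "oscillator_bath")
  st <- dimer_state(c(0, 0, 0), c(10, 0, 0), t = 0)
  amp <- 0.01
  osc <- oscillator_state(matrix(c(amp, 0, 0), 1), matrix(0, 1, 3), b)
  dt <- 1e-4
  out <- step_verlet_full(st, b, osc, spring_params(0, 0), M = 1e15,
                          dt = dt, n_steps = 2000)
  t_end <- 2000 * dt
  expect_equal(out$state$positions[1, 1], amp * cos(w0 * t_end),
               tolerance = amp * (w0 * dt)^2 * 50)

  ## full coupled system conserves energy over many steps
  set.seed(66)
  b2 <- build_bath(64, 100, 10, 1e-3, mode = "two_bath")
  st2 <- dimer_state(c(0, 0, 0), c(0.32, 0, 0))
  osc2 <- initialize_oscillators(st2, b2, kBT = 10)
  dt2 <- default_lr_step(b2)
  res <- cpp_long_range_run(
    X = rbind(st2$X1, st2$X2), V = rbind(st2$V1, st2$V2),
    osc_pos = osc2$positions, osc_vel = osc2$velocities,
    k1 = b2$k1, a1 = b2$alpha1, k2 = b2$k2, a2 = b2$alpha2,
    m = b2$m, M = 1, k = 1e6, ell0 = 0.32, gamma = 0, D = 0,
    dt = dt2, n_steps = 1e4, sample_every = 500,
    monomer2_langevin = FALSE, record_energy = TRUE)
  E <- res$energies
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-4)
})

test_that("the deterministic integrator is time-reversible", {
  set.seed(67)
  b <- build_bath(32, 100, 10, 1e-3, mode = "shared")
  st <- dimer_state(c(0, 0, 0), c(0.32, 0, 0))
  osc <- initialize_oscillators(st, b, kBT = 10)
  sp <- preset_spring()
  dt <- default_lr_step(b)
  fwd <- step_verlet_full(st, b, osc, sp, M = 1, dt = dt, n_steps = 500)
  flip <- fwd$dimer
  flip$V1 <- -flip$V1; flip$V2 <- -flip$V2
  oscf <- oscillator_state(fwd$state$positions, -fwd$state$velocities, b)
  back <- step_verlet_full(flip, b, oscf, sp, M = 1, dt = dt, n_steps = 500)
  expect_equal(back$dimer$X1, st$X1, tolerance = 1e-8)
  expect_equal(back$dimer$X2, st$X2, tolerance = 1e-8)
  expect_equal(back$state$positions, osc$positions, tolerance = 1e-8)
})

test_that("stability guard names an over-stiff oscillator step", {
  set.seed(68)
  b <- build_bath(32, 100, 10, 1e-3, mode = "two_bath")
  st <- dimer_state(c(0, 0, 0), c(0.32, 0, 0))
  osc <- initialize_oscillators(st, b, kBT = 10)
  om_max <- sqrt(max(b$k1 + b$k2) / b$m)
  expect_error(step_verlet_full(st, b, osc, preset_spring(), M = 1,
                                dt = 2 / om_max),
               "stability")
})

test_that("shared-bath runs land on the shortened effective rest length", {
  ## bath variables cancel exactly from the separation dynamics; the mean
  ## length must match 2 k pi ell0 / (2 k pi + gamma omega_bar) closely
  sp <- preset_spring()
  p <- preset_langevin()
  tr <- simulate_long_range(sp, p, N = 400, omega_bar = 100, m = 1e-3,
                            tmax = 3, seed = 71, mode = "shared", dt = 1e-5)
  len <- estimate_mean_length(tr, burn_in = 1)
  pred <- effective_rest_length_one_bath(sp, p$gamma, 100)
  expect_lt(abs(len$L_d - pred), 2e-5)
  expect_lt(len$L_d, sp$ell0)   # shared coupling shortens the dimer
})

test_that("split-coupling one-bath runs behave like two independent baths", {
  sp <- preset_spring()
  p <- preset_langevin()
  tr_split <- simulate_long_range(sp, p, N = 400, omega_bar = 100, m = 1e-3,
                                  tmax = 6, seed = 72, mode = "split",
                                  N1 = 200, dt = 1e-5)
  tr_two <- simulate_long_range(sp, p, N = 200, omega_bar = 100, m = 1e-3,
                                tmax = 6, seed = 73, mode = "two_bath",
                                dt = 1e-5)
  ls <- estimate_mean_length(tr_split, burn_in = 2)
  lt <- estimate_mean_length(tr_two, burn_in = 2)
  pred <- analytic_mean_length(sp, p)
  ## both extend the dimer and cover the Langevin prediction
  expect_gt(pred, ls$ci[1]); expect_lt(pred, ls$ci[2])
  expect_gt(pred, lt$ci[1]); expect_lt(pred, lt$ci[2])
  expect_lt(abs(ls$L_d - lt$L_d), 4 * sqrt(ls$se^2 + lt$se^2))
})

test_that("mixed long-range steps compose and reproduce", {
  set.seed(74)
  sp <- preset_spring()
  p <- preset_langevin()
  a <- simulate_long_range(sp, p, N = 100, omega_bar = 100, m = 1e-3,
                           tmax = 0.01, seed = 75, mode = "mixed",
                           dt = 1e-5, sample_interval = 1e-5)
  b <- simulate_long_range(sp, p, N = 100, omega_bar = 100, m = 1e-3,
                           tmax = 0.01, seed = 75, mode = "mixed",
                           dt = 1e-5, sample_interval = 1e-5)
  expect_identical(a$R, b$R)
  expect_true(all(is.finite(a$R)))
})
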