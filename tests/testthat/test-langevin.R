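test_that("langevin parameters enforce the stability preconditions", {
  expect_error(langevin_params(dt = 0.3, tdamp = 0.25), "smaller than tdamp")
  p <- langevin_params()
  expect_lt(p$dt, p$tdamp)
  # default model/step pair is inside the Verlet window; the stiff-bond
  # combination dt = 0.04 is not
  chk <- check_stability(chain_model("FJC", N = 10, eps_pw = 0), p,
                         warn = FALSE)
  expect_lt(chk$omega_dt, chk$limit)
  expect_warning(
    check_stability(chain_model("FJC", N = 10, eps_pw = 0),
                    langevin_params(dt = 0.04)),
    "unstable")
})

test_that("trajectories are bitwise reproducible for a fixed seed/stream", {
  m <- chain_model("FJC", N = 10, eps_pw = 0.4)
  st <- generate_coil(m, seed = 5)
  st$positions[, 3] <- st$positions[, 3] - min(st$positions[, 3]) + 0.7
  r1 <- run_dynamics(st, m, langevin_params(), 2000, seed = 7, stream = 3)
  r2 <- run_dynamics(st, m, langevin_params(), 2000, seed = 7, stream = 3)
  expect_identical(r1$state$positions, r2$state$positions)
  r3 <- run_dynamics(st, m, langevin_params(), 2000, seed = 7, stream = 4)
  expect_false(identical(r3$state$positions, r1$state$positions))
})

test_that("thermostat recovers the target temperature", {
  kT <- boltzmann_kJmol() * 300
  # free bead: kinetic energy -> (3/2) kBT
  m1 <- chain_model("FJC", N = 1, eps_pw = 0)
  st <- system_state(matrix(c(0, 0, 10), 1, 3))
  r <- run_dynamics(st, m1, langevin_params(), 4e5, seed = 2, stream = 1,
                    wall = FALSE, record = "thermo", record_stride = 10)
  ke <- mean(r$record[-(1:50), "ekin"])
  expect_equal(ke, 1.5 * kT, tolerance = 0.02)

  # harmonic dimer: kinetic and configurational temperature both recover.
  # A small omega*dt (0.27 here) keeps the Verlet positional-variance
  # inflation 1/(1 - (omega dt/2)^2) below the statistical tolerance.
  m2 <- chain_model("FJC", N = 2, eps_pw = 0, kb = 8000)
  st2 <- system_state(matrix(c(0, 0, 10, 0.33, 0, 10), 2, 3, byrow = TRUE))
  pfine <- langevin_params(dt = 0.01)
  r2 <- run_dynamics(st2, m2, pfine, 8e5, seed = 3, stream = 1,
                     wall = FALSE, record = "thermo", record_stride = 25)
  ke2 <- mean(r2$record[-(1:50), "ekin"])
  expect_equal(ke2, 2 * 1.5 * kT, tolerance = 0.02)
  # one stiff radial mode at equipartition: <kb (r-lb)^2> = kBT/2
  ep2 <- mean(r2$record[-(1:50), "epot"])
  expect_equal(ep2, kT / 2, tolerance = 0.06)
})

test_that("free-particle diffusivity matches kBT tdamp / m", {
  p <- langevin_params()
  m1 <- chain_model("FJC", N = 1, eps_pw = 0)
  d <- chain_diffusivity(m1, p, t_total = 1500, n_replicas = 30, seed = 4)
  D1 <- boltzmann_kJmol() * 300 * p$tdamp / 45
  expect_equal(d$D, D1, tolerance = 0.03)
  # the published magnitude: ~1.4e-4 cm^2/s
  expect_equal(d$D * 1e-2, 1.39e-4, tolerance = 0.05)
})

test_that("chain diffusivity follows Rouse 1/N scaling", {
  p <- langevin_params()
  d25 <- chain_diffusivity(chain_model("FJC", N = 25, eps_pw = 0), p,
                           t_total = 1200, n_replicas = 24, seed = 6)
  d50 <- chain_diffusivity(chain_model("FJC", N = 50, eps_pw = 0), p,
                           t_total = 1200, n_replicas = 24, seed = 7)
  expect_equal(d25$D / d50$D, 2,
               tolerance = 4 * (d25$se / d25$D + d50$se / d50$D) + 0.02)
  expect_equal(d50$D, rouse_diffusivity(chain_model("FJC", N = 50,
                                                    eps_pw = 0), p),
               tolerance = 0.05)
})
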