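test_that("chain model presets encode the intended interactions", {
  frc <- chain_model("FRC", N = 10, eps_pw = 0.4)
  expect_true(frc$use_angle && !frc$use_ev && !frc$use_torsionlike)
  expect_equal(frc$kA, 2000)
  expect_equal(frc$thetaA, 111.58)

  full <- chain_model("FRC+EV+T", N = 10, eps_pw = 0.4)
  expect_true(full$use_ev && full$use_angle && full$use_torsionlike)
  alias <- chain_model("FRC+EV+D", N = 10, eps_pw = 0.4)
  expect_equal(unclass(alias), unclass(full))

  expect_error(chain_model("FJC", N = 10, eps_pw = 0.4, ePP = 0.2),
               "use_ev")
  expect_error(chain_model("FRC", N = 10, eps_pw = 0.4, kA = 0),
               "use_angle")
  expect_error(chain_model("XYZ"), "unknown chain model")
})

test_that("switching function matches the rational form and its limits", {
  sw <- switching_params()
  expect_equal(switching_function(0.35, sw), 1)            # x = 0
  expect_equal(switching_function(0.1, sw), 1)             # clamped plateau
  expect_equal(switching_function(1.05, sw), 6 / 14,       # L'Hopital at x=1
               tolerance = 1e-7)
  z <- seq(0.36, 6, by = 0.01)
  expect_equal(switching_function(z, sw), ref_switch(z), tolerance = 1e-12)
  expect_lt(switching_function(5, sw), 1e-4)
  s <- switching_function(seq(0.35, 8, by = 0.005), sw)
  expect_true(all(diff(s) <= 0))          # monotone beyond the onset
  expect_true(all(s > 0 & s <= 1))
  expect_error(switching_params(m_exp = 6, n = 6), "larger than n")
  expect_error(switching_params(m_exp = 4, n = 6), "larger than n")
})

test_that("contact number sums switching weights and has its symmetries", {
  sw <- switching_params()
  N <- 50
  z <- rep(0.35, N)
  expect_equal(contact_number(z, sw), N)
  expect_lt(contact_number(rep(20, N), sw), 1e-5) # deep in basin B
  z1 <- c(0.35 + 0.7, rep(25, 9))
  expect_equal(contact_number(z1, sw), 6 / 14, tolerance = 1e-6)

  pos <- cbind(runif(10), runif(10), runif(10, 0.4, 2))
  st <- system_state(pos)
  shifted <- system_state(sweep(pos, 2, c(3.2, -1.5, 0), "+"))
  relabeled <- system_state(pos[sample(10), ])
  expect_equal(contact_number(st, sw), contact_number(shifted, sw))
  expect_equal(contact_number(st, sw), contact_number(relabeled, sw))
})

test_that("Steele wall potential has the right shape, scaling and force", {
  s <- 0.47
  # far tail is dominated by the z^-3 attraction and vanishes at infinity
  zz <- s * c(50, 100, 200, 400)
  vt <- abs(wall_potential(zz, s, 1))
  expect_true(all(diff(vt) < 0))
  expect_lt(vt[2], 1e-5)
  expect_lt(vt[4], 1e-7)
  z <- c(0.2, 0.4, 0.6, 1.1)
  expect_equal(wall_potential(z, s, 0.6), 0.6 * wall_potential(z, s, 1))
  expect_error(wall_potential(-0.1, s, 1), "positive")

  # minimum from a 1-D minimization oracle; analytic force vanishes there
  zstar <- optimize(wall_potential, c(0.1, 2), sigma_pw = s, eps_pw = 1,
                    tol = 1e-10)
  expect_lt(abs(wall_force(zstar$minimum, s, 1)), 1e-5)
  # numerically refined root of the analytic force agrees
  root <- uniroot(wall_force, c(0.3, 1.5), sigma_pw = s, eps_pw = 1,
                  tol = 1e-13)
  expect_lt(abs(wall_force(root$root, s, 1)), 1e-10)
  expect_equal(zstar$minimum, root$root, tolerance = 1e-6)
  # the potential at z = 2 sigma is small relative to the well depth
  expect_lt(abs(wall_potential(2 * s, s, 1)), 0.15 * abs(zstar$objective))
  # repulsive divergence near the wall
  expect_gt(wall_potential(0.05, s, 1), 1e4)
})

test_that("total potential and forces follow the model terms exactly", {
  # relaxed dimer far from the wall: everything at its minimum
  # (300 nm out, where even the z^-3 wall tail is < 1e-9)
  m2 <- chain_model("FJC", N = 2, eps_pw = 0.6)
  st <- system_state(matrix(c(0, 0, 300, 0.33, 0, 300), 2, 3, byrow = TRUE))
  ef <- chain_energy_forces(st, m2)
  expect_lt(abs(ef$energy), 1e-6)
  expect_lt(max(abs(ef$forces)), 1e-4)

  # bent trimer: pure harmonic angle energy kA (0.1 rad)^2 = 20 kJ/mol
  m3 <- chain_model("FRC", N = 3, eps_pw = 0.6)
  th <- m3$thetaA * pi / 180 + 0.1
  lb <- m3$lb
  pos <- rbind(c(lb, 0, 300), c(0, 0, 300),
               c(lb * cos(th), lb * sin(th), 300))
  ef3 <- chain_energy_forces(system_state(pos), m3)
  expect_equal(ef3$energy, 2000 * 0.1^2, tolerance = 1e-6)

  # overlapping beads with excluded volume
  mev <- chain_model("FJC+EV", N = 3, eps_pw = 0.6)
  bad <- rbind(c(0, 0, 5), c(0.33, 0, 5), c(0, 0, 5))
  expect_error(chain_energy_forces(system_state(bad), mev), "overlap")
})

test_that("forces are the exact negative gradient for every model", {
  set.seed(99)
  for (name in c("FJC", "FRC", "FJC+EV", "FRC+EV", "FRC+EV+T")) {
    model <- chain_model(name, N = 8, eps_pw = 0.5)
    st <- generate_coil(model, seed = 31)
    pos <- st$positions
    pos[, 3] <- pos[, 3] - min(pos[, 3]) + 0.5 # near the wall
    st <- system_state(pos)
    ef <- chain_energy_forces(st, model)
    num <- fd_forces(st, model)
    scale <- max(abs(ef$forces), 1)
    expect_lt(max(abs(num - ef$forces)) / scale, 1e-6)
  }
})

test_that("mean-field wall potential matches quadrature oracle and grows with attraction", {
  expect_equal(mean_field_potential(0.47, 0, 300), 0)

  # dense-trapezoid oracle on [1e-3 sigma, 2 sigma]
  s <- 0.47; e <- 0.6; kT <- boltzmann_kJmol() * 300
  z <- seq(1e-3 * s, 2 * s, length.out = 1e6)
  v <- wall_potential(z, s, e)
  w <- exp(-pmin(v / kT, 700))
  oracle <- -sum(v * w) / sum(w)
  vmf <- mean_field_potential(s, e, 300)
  expect_equal(vmf, oracle, tolerance = 1e-4)
  expect_gt(vmf, 0)

  vals <- vapply(c(0.2, 0.3, 0.4, 0.6, 1.0), mean_field_potential,
                 numeric(1), sigma_pw = s, temperature = 300)
  expect_true(all(diff(vals) > 0))
})
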