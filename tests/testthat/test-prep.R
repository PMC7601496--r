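test_that("generated coils honor bond lengths, angles and excluded volume", {
  m <- chain_model("FJC", N = 50, eps_pw = 0.6)
  st <- generate_coil(m, seed = 1)
  bl <- sqrt(rowSums(diff(st$positions)^2))
  expect_equal(bl, rep(m$lb, 49), tolerance = 1e-9)

  m3 <- chain_model("FRC", N = 3, eps_pw = 0.6)
  st3 <- generate_coil(m3, seed = 2)
  v1 <- st3$positions[1, ] - st3$positions[2, ]
  v2 <- st3$positions[3, ] - st3$positions[2, ]
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(ang, m3$thetaA, tolerance = 1e-6)

  mev <- chain_model("FJC+EV", N = 40, eps_pw = 0.6)
  sev <- generate_coil(mev, seed = 3)
  dmat <- as.matrix(dist(sev$positions))
  nonadj <- abs(row(dmat) - col(dmat)) >= 2
  expect_true(all(dmat[nonadj] >= 0.8 * mev$sPP))
})

test_that("constructed freely jointed coils have ideal-chain statistics", {
  m <- chain_model("FJC", N = 40, eps_pw = 0)
  coils <- lapply(1:500, function(k) generate_coil(m, seed = 1000 + k))
  ree2 <- mean(vapply(coils, function(s) {
    sum((s$positions[40, ] - s$positions[1, ])^2)
  }, numeric(1)))
  rg2 <- radius_of_gyration(coils)$Rg2
  expect_equal(ree2 / rg2, 6, tolerance = 0.1)
  expect_equal(ree2, 39 * m$lb^2, tolerance = 0.1)
})

test_that("pivot sampling reproduces equilibrium coil statistics", {
  # ideal chain: pivot moves are always accepted and the ensemble is
  # exact; Rg^2 = lb^2 (N^2 - 1)/(6 N) for the discrete chain
  m <- chain_model("FJC", N = 40, eps_pw = 0)
  s <- pivot_sample(m, 300, seed = 13, spacing = 3)
  expect_equal(attr(s, "acceptance"), 1)
  rg <- radius_of_gyration(s)
  exact <- 0.33^2 * (40^2 - 1) / (6 * 40)
  expect_lt(abs(rg$Rg2 - exact), 4 * rg$se2)

  # excluded volume: pivot ensemble matches long Langevin dynamics
  mev <- chain_model("FJC+EV", N = 25, eps_pw = 0)
  sev <- pivot_sample(mev, 150, seed = 14)
  expect_lt(attr(sev, "acceptance"), 1) # some moves must now be rejected
  p <- langevin_params()
  md <- equilibrate_and_sample(generate_coil(mev, seed = 15), mev, p, 50,
                               seed = 16)
  expect_equal(radius_of_gyration(sev)$Rg2, radius_of_gyration(md)$Rg2,
               tolerance = 0.1)
})

test_that("equilibration measures tau_ends and spaces samples by 2 tau", {
  m <- chain_model("FJC", N = 16, eps_pw = 0)
  p <- langevin_params()
  st <- generate_coil(m, seed = 4)
  samples <- equilibrate_and_sample(st, m, p, 30, seed = 11, n_tau = 40)
  tau <- attr(samples, "tau_ends")
  expect_gt(tau, 0)
  # two independent estimates agree reasonably (stationarity)
  tau2 <- attr(equilibrate_and_sample(st, m, p, 0, seed = 12, n_tau = 40),
               "tau_ends")
  expect_lt(abs(tau - tau2) / mean(c(tau, tau2)), 0.3)

  # consecutive samples decorrelated to ~ e^-2
  ree <- t(vapply(samples, function(s) {
    s$positions[16, ] - s$positions[1, ]
  }, numeric(3)))
  n <- nrow(ree)
  corr <- mean(rowSums(ree[-n, ] * ree[-1, ])) / mean(rowSums(ree^2))
  se <- 1 / sqrt(n - 1)
  expect_lt(corr, exp(-2) + 3 * se)

  expect_length(equilibrate_and_sample(st, m, p, 0, seed = 13), 0)
})

test_that("adsorption accepts by the contact threshold and rejects without attraction", {
  p <- langevin_params()
  m <- chain_model("FJC", N = 25, eps_pw = 0.3)
  states <- sample_adsorbed(m, p, 5, seed = 21)
  expect_length(states, 5)
  thr <- min(10, 0.1 * 25)
  cc <- vapply(states, contact_number, numeric(1))
  expect_true(all(cc >= thr))

  # essentially no attraction (eps_pw = 0.01 keeps the repulsive core but
  # offers no bound state): no run ever reaches the 90%-adsorbed stop,
  # every run ends by COM drift or the time cap, and whatever transient
  # contacts remain at that point drain away under further relaxation
  m0 <- chain_model("FJC", N = 50, eps_pw = 0.01)
  final_c <- numeric(0)
  for (k in 1:5) {
    coil <- generate_coil(m0, seed = 30 + k)
    res <- adsorb(coil, m0, p, seed = 40, stream = k)
    if (inherits(res, "adsorb_rejection")) {
      expect_true(res$reason %in% c("far", "maxsteps"))
      next
    }
    relax <- run_dynamics(res, m0, p, round(3e4 / p$dt), seed = 41,
                          stream = k, stop_c_lo = 1e-5)
    final_c <- c(final_c, relax$contact)
  }
  # any transiently "accepted" state desorbs: no bound state exists
  expect_true(all(final_c < min(10, 0.1 * 50)))
})

test_that("accepted basin states keep a stationary contact number", {
  p <- langevin_params()
  m <- chain_model("FJC", N = 25, eps_pw = 0.3)
  states <- sample_adsorbed(m, p, 4, seed = 22)
  tau <- attr(states, "tau_ends")
  drift <- vapply(seq_along(states), function(i) {
    r <- run_dynamics(states[[i]], m, p, round(10 * tau / p$dt), seed = 23,
                      stream = i, record = "contact", record_stride = 50)
    cc <- r$record[, "C"]
    half <- length(cc) %/% 2
    mean(cc[(half + 1):length(cc)]) - mean(cc[1:half])
  }, numeric(1))
  # no systematic drift of the mean contact number after further relaxation
  expect_lt(abs(mean(drift)), 0.15 * 25)
})
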