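test_that("interface assignment reproduces the two-step average", {
  # worked example: lambda0 = (10+4)/2 = 7, lambdaA = (7+10)/2 = 8.5
  iface <- assign_interfaces(c(12, 10, 15), c(4, 6, 2))
  expect_equal(iface$lambda_0, 7)
  expect_equal(iface$lambda_A, 8.5)

  # algebraic identity: lambdaA = 3/4 min<C> + 1/4 median(Cmin)
  set.seed(14)
  for (k in 1:20) {
    cm <- runif(11, 5, 20)
    cn <- runif(11, 0, 4)
    iface <- assign_interfaces(cm, cn)
    expect_equal(iface$lambda_A, 0.75 * min(cm) + 0.25 * median(cn))
  }

  # degenerate statistics: all runs identical
  expect_error(assign_interfaces(rep(7, 5), rep(7, 5)), "degenerate")
})

test_that("armed crossing counter implements the re-arming rule", {
  # second dip not re-armed (never rose back above lambda_A)
  r <- count_forward_crossings(c(9, 7.9, 6.9, 7.9, 6.9), 8, 7)
  expect_equal(r$n_crossings, 1)
  # full re-arm between dips
  r <- count_forward_crossings(c(9, 6.9, 9, 6.9), 8, 7)
  expect_equal(r$n_crossings, 2)
  # monotone decrease: exactly one crossing
  r <- count_forward_crossings(seq(50, 0, by = -1), 8, 7)
  expect_equal(r$n_crossings, 1)

  # eligible time excludes basin B and the B -> A transit: of the eight
  # steps, those inside B (index 3->4) and in transit back to lambda_A
  # (4->5, 5->6, 6->7) are discarded; the only countable crossing is the
  # armed drop 9 -> 6.5 after full re-entry into A
  trace <- c(9, 7, 0.5e-5, 0.5e-5, 2, 5, 9, 6.5, 9)
  r <- count_forward_crossings(trace, lambda_A = 8, lambda_0 = 7,
                               lambda_B = 1e-5, dt = 1)
  expect_equal(r$n_crossings, 1)
  expect_equal(r$eligible_time, 4)
})

test_that("C++ crossing harvest replays the R counting rule exactly", {
  m <- fjc25(0.3)
  p <- langevin_params()
  states <- sample_adsorbed(m, p, 2, seed = 31)
  n_steps <- round(400 / p$dt)
  tr <- run_dynamics(states[[1]], m, p, n_steps, seed = 8, stream = 12,
                     record = "contact", record_stride = 1)
  lamA <- 12; lam0 <- 8
  rc <- count_forward_crossings(tr$record[, "C"], lamA, lam0, 1e-5,
                                dt = p$dt)
  cc <- ffsdesorb:::cpp_chain_crossings(
    states[[1]]$positions, states[[1]]$velocities,
    ffsdesorb:::as_cpp_model(m), p$temperature, p$dt, p$tdamp, 8, 12,
    n_steps, lamA, lam0, 1e-5, 100L)
  expect_equal(cc$n_crossings, rc$n_crossings)
  expect_equal(cc$eligible_time, rc$eligible_time, tolerance = 1e-9)
  # harvested snapshots sit just below lambda_0 (first touch)
  if (cc$n_crossings > 0) {
    cs <- vapply(cc$snapshots, function(s) {
      contact_number(s$positions[, 3], m$switching)
    }, numeric(1))
    expect_true(all(cs < lam0))
  }
})

test_that("fixed selection spreads trials evenly; random selection starves", {
  set.seed(3)
  counts <- allocate_trials(300, 1000, "fixed")
  expect_equal(sum(counts), 1000)
  expect_setequal(unique(counts), c(3L, 4L))
  expect_equal(sum(counts == 4L), 100)

  # random selection: expected never-selected fraction (499/500)^1500
  frac <- replicate(200, mean(allocate_trials(500, 1500, "random") == 0))
  expect_equal(mean(frac), (499 / 500)^1500, tolerance = 0.05)
  expect_equal(500 * mean(frac), 25, tolerance = 0.05 * 25)
})

test_that("adaptive placement takes the lower 10th percentile of minima", {
  ctrl <- ffs_control(n_pilot = 100, n_trials = 100, lambda_B = 1e-5)
  snaps <- list(list(c_mean = 50, c_min = 1))
  prop <- mock_propagator(as.list(sample(1:100)))
  r <- place_next_level(prop, snaps, lambda_A = 120, lambda_cur = 110,
                        control = ctrl, seed = 1)
  expect_equal(r$lambda_next, 10) # order-statistic (type 1) percentile

  # >= 10% of pilot trials reach B: the next level is lambda_B itself
  prop2 <- mock_propagator(as.list(c(rep(0, 15), sample(30:114, 85))))
  r2 <- place_next_level(prop2, snaps, lambda_A = 120, lambda_cur = 110,
                         control = ctrl, seed = 1)
  expect_equal(r2$lambda_next, ctrl$lambda_B)
  expect_gte(r2$frac_B, 0.1)

  # identical minima: the percentile is that value; progression guard trips
  prop3 <- mock_propagator(list(42))
  r3 <- place_next_level(prop3, snaps, lambda_A = 120, lambda_cur = 110,
                         control = ctrl, seed = 1)
  expect_equal(r3$lambda_next, 42)
  expect_error(
    place_next_level(prop3, snaps, lambda_A = 120, lambda_cur = 42,
                     control = ctrl, seed = 1),
    "progress")
})

test_that("level runs allocate, record parentage and detect extinction", {
  ctrl <- ffs_control(n_pilot = 10, n_trials = 100, lambda_B = 1e-5)
  snaps <- rep(list(list(c_mean = 9, c_min = 5)), 7)
  # scripted: every 5th trial succeeds
  script <- as.list(rep(c(FALSE, FALSE, FALSE, FALSE, TRUE), 20))
  prop <- mock_propagator(as.list(rep(1, 100)), script)
  lv <- run_level(prop, snaps, lambda_A = 12, lambda_next = 3,
                  control = ctrl, seed = 2)
  expect_equal(sum(lv$alloc), 100)
  expect_true(all(lv$alloc %in% c(14L, 15L)))
  expect_equal(lv$p_hat, sum(lv$successes) / 100)
  expect_equal(length(lv$snapshots), sum(lv$successes))
  expect_equal(length(lv$parents), sum(lv$successes))
  expect_true(all(lv$parents %in% seq_len(7)))
  expect_equal(lv$p_j, lv$successes / lv$alloc)

  prop_fail <- mock_propagator(as.list(rep(1, 10)), list(FALSE))
  expect_error(
    run_level(prop_fail, snaps[1], lambda_A = 12, lambda_next = 3,
              control = ctrl, seed = 2),
    "extinction")
})

test_that("rate assembly multiplies the base rate by level probabilities", {
  # once-per-ns base flux with a 1e-9 conversion probability needs 9
  # levels at 10% advancement
  expect_equal(log(1e-9) / log(0.1), 9)
  r <- assemble_rate(1e-3, rep(0.1, 9))
  expect_equal(r$rate, 1e-12)
  expect_equal(r$tdes, 1e12)

  expect_equal(assemble_rate(2.5e-3, rep(1, 4))$rate, 2.5e-3)
  r1 <- assemble_rate(1e-3, c(0.4, 0.2))
  r2 <- assemble_rate(1e-3, c(0.2, 0.2))
  expect_equal(r2$rate, r1$rate / 2)
  expect_error(assemble_rate(1e-3, c(0.5, 0)), "undefined")
  d <- assemble_rate(1e-2, c(0.5), D = 0.1, Rg = sqrt(10))
  expect_equal(d$dimensionless_tdes, 200 * 0.1 / 10)
})

test_that("a full FFS run is deterministic under its master seed", {
  ctrl <- ffs_control(n_runs = 20, n_pilot = 40, n_trials = 200,
                      trate0 = 400, lambda_B = -0.8)
  a <- double_well_rate(4, langevin_params(), "ffs", control = ctrl,
                        seed = 77)
  b <- double_well_rate(4, langevin_params(), "ffs", control = ctrl,
                        seed = 77)
  expect_identical(a$rate, b$rate)
  expect_identical(a$levels, b$levels)
  expect_identical(a$p_hats, b$p_hats)
  expect_identical(lapply(a$genealogy, `[[`, "parent"),
                   lapply(b$genealogy, `[[`, "parent"))
  c_ <- double_well_rate(4, langevin_params(), "ffs", control = ctrl,
                         seed = 78)
  expect_false(identical(a$rate, c_$rate))
})
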