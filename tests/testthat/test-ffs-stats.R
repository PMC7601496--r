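# genealogy fixture used throughout: level-1 snapshots from 6 founders
# with group sizes {2,1,1,2,5,4} (15 snapshots)
sizes_gen <- function() {
  parents <- rep(1:6, times = c(2, 1, 1, 2, 5, 4))
  make_genealogy(list(parents), n0 = 6)
}

test_that("descendant groups partition snapshots and count intragroup pairs", {
  gen <- sizes_gen()
  g0 <- descendant_groups(gen, 1, 0)
  expect_length(g0, 15)
  expect_equal(attr(g0, "n_pairs"), 0)

  g1 <- descendant_groups(gen, 1, 1)
  expect_equal(sort(lengths(g1)), c(1, 1, 2, 2, 4, 5))
  expect_equal(attr(g1, "n_pairs"), 1 + 0 + 0 + 1 + 10 + 6) # = 18
  expect_setequal(unlist(g1), 1:15)

  # chain genealogy collapsing to a single root
  gen2 <- make_genealogy(list(rep(1L, 4), c(1L, 1L, 2L, 3L, 4L)), n0 = 3)
  gtop <- descendant_groups(gen2, 2, 2)
  expect_length(gtop, 1)
  expect_length(gtop[[1]], 5)
  expect_error(descendant_groups(gen2, 1, 2), "order exceeds level")
})

test_that("ancestry-corrected mean weights each group once", {
  gen <- make_genealogy(list(c(1L, 1L, 2L)), n0 = 2)
  g <- descendant_groups(gen, 1, 1)
  expect_equal(corrected_mean(g, c(1, 0, 0.5)), 0.5)

  gen0 <- sizes_gen()
  p <- runif(15)
  g0 <- descendant_groups(gen0, 1, 0)
  expect_equal(corrected_mean(g0, p), mean(p)) # singletons: flat mean
  g1 <- descendant_groups(gen0, 1, 1)
  expect_equal(corrected_mean(g1, rep(0.3, 15)), 0.3)
})

test_that("intraclass correlation detects intragroup agreement", {
  gen <- make_genealogy(list(c(1L, 1L, 2L, 2L)), n0 = 2)
  g <- descendant_groups(gen, 1, 1)
  expect_gte(intraclass_correlation(g, c(1, 1, 0, 0)), 1 - 1e-9)

  # permutation across groups destroys the correlation on average
  gen2 <- make_genealogy(list(rep(1:10, each = 4)), n0 = 10)
  g2 <- descendant_groups(gen2, 1, 1)
  base <- rep(runif(10), each = 4) + rnorm(40, 0, 0.05)
  set.seed(55)
  rs <- replicate(400, intraclass_correlation(g2, sample(base)))
  expect_lt(abs(mean(rs)), 0.05)
  # and the unshuffled p's are strongly correlated within groups
  expect_gt(intraclass_correlation(g2, base), 0.8)

  # zero variance: defined as 0 with a degeneracy flag
  r0 <- intraclass_correlation(g2, rep(0.4, 40))
  expect_equal(as.numeric(r0), 0)
  expect_true(attr(r0, "degenerate"))

  g0 <- descendant_groups(gen2, 1, 0)
  expect_error(intraclass_correlation(g0, base), "no intragroup pairs")
})

test_that("intraclass correlation recovers a known rho on synthetic groups", {
  set.seed(77)
  for (rho in c(0.2, 0.6)) {
    gen <- make_genealogy(list(rep(1:40, each = 6)), n0 = 40)
    g <- descendant_groups(gen, 1, 1)
    rs <- replicate(60, {
      grp <- rnorm(40, 0, sqrt(rho))
      p <- rep(grp, each = 6) + rnorm(240, 0, sqrt(1 - rho))
      intraclass_correlation(g, p)
    })
    expect_lt(abs(mean(rs) - rho), 0.05)
  }
})

test_that("order selection picks the smallest decorrelated grouping", {
  # siblings perfectly correlated, cousins independent:
  # level 2 with 4 founders -> 8 parents -> 16 snapshots
  gen <- make_genealogy(list(rep(1:4, each = 2), rep(1:8, each = 2)),
                        n0 = 4)
  set.seed(9)
  p_sib <- rep(runif(8), each = 2) # identical within sibling pairs
  expect_equal(select_order(gen, 2, p_sib), 2L)
  p_ind <- runif(16)
  L <- select_order(gen, 2, p_ind)
  expect_lte(L, 2L)
  # fully correlated down to the founders: capped with a flag
  p_found <- rep(c(0, 1, 0.2, 0.8), each = 4)
  Lc <- select_order(gen, 2, p_found)
  expect_equal(as.integer(Lc), 2L)
  expect_true(isTRUE(attr(Lc, "capped")))
  expect_equal(select_order(gen, 0, p_ind[1:4]), 0L)
})

test_that("level SEM follows the group-mean formula and its reductions", {
  gen <- make_genealogy(list(c(1L, 1L, 2L, 2L)), n0 = 2)
  g <- descendant_groups(gen, 1, 1)
  expect_equal(level_sem(g, c(0.3, 0.5, 0.5, 0.7)), 0.1) # means {0.4, 0.6}
  expect_equal(level_sem(g, rep(0.4, 4)), 0)

  # order 0 reduces to the classic SEM
  gen2 <- sizes_gen()
  p <- runif(15)
  g0 <- descendant_groups(gen2, 1, 0)
  expect_equal(level_sem(g0, p), sd(p) / sqrt(15))

  single <- descendant_groups(make_genealogy(list(c(1L, 1L)), n0 = 1), 1, 1)
  expect_true(is.na(level_sem(single, c(0.2, 0.4))))

  # bootstrap-over-groups oracle
  set.seed(31)
  gen3 <- make_genealogy(list(rep(1:12, each = 3)), n0 = 12)
  g3 <- descendant_groups(gen3, 1, 1)
  p3 <- rep(runif(12), each = 3) + rnorm(36, 0, 0.1)
  gm <- vapply(g3, function(gr) mean(p3[gr]), numeric(1))
  boot <- replicate(4000, mean(sample(gm, replace = TRUE)))
  expect_equal(level_sem(g3, p3), sd(boot), tolerance = 0.2)
})

test_that("conservative SEM groups by founders and bounds the corrected one", {
  # all snapshots from distinct founders: equals order-0 SEM
  gen <- make_genealogy(list(1:6), n0 = 6)
  p <- runif(6)
  expect_equal(conservative_sem(gen, 1, p),
               level_sem(descendant_groups(gen, 1, 0), p))

  # two founders, identical p within each: half the absolute difference
  gen2 <- make_genealogy(list(rep(1:2, each = 3), rep(1:6, times = 2)),
                         n0 = 2)
  p2 <- numeric(12)
  founder <- rep(rep(1:2, each = 3), times = 2)
  p2[founder == 1] <- 0.2
  p2[founder == 2] <- 0.8
  expect_equal(conservative_sem(gen2, 2, p2), 0.3)

  # independent p: conservative and corrected agree within sampling error
  set.seed(41)
  gen3 <- make_genealogy(list(rep(1:20, each = 2), rep(1:40, each = 2)),
                         n0 = 20)
  p3 <- runif(80)
  L <- select_order(gen3, 2, p3)
  corr <- level_sem(descendant_groups(gen3, 2, L), p3)
  cons <- conservative_sem(gen3, 2, p3)
  expect_equal(cons, corr, tolerance = 0.5)
})

test_that("rate confidence intervals propagate level errors in log space", {
  fake <- structure(list(rate = 1e-6, n_crossings = 1e12, p_hats = 0.5),
                    class = "ffs_result")
  stats <- data.frame(p_hat = 0.5, sem = 0.05, sem_conservative = 0.08)
  ci <- rate_confidence_interval(fake, stats)
  expect_equal(ci$ci, 1e-6 * exp(c(-1, 1) * 1.96 * 0.1), tolerance = 1e-6)
  expect_equal(ci$ci_conservative, 1e-6 * exp(c(-1, 1) * 1.96 * 0.16),
               tolerance = 1e-6)
  # zero uncertainty collapses to the point estimate
  stats0 <- data.frame(p_hat = 0.5, sem = 0, sem_conservative = 0)
  ci0 <- rate_confidence_interval(fake, stats0)
  expect_equal(ci0$ci, c(1e-6, 1e-6), tolerance = 1e-6)
  # conservative interval contains the corrected one
  expect_lte(ci$ci_conservative[1], ci$ci[1])
  expect_gte(ci$ci_conservative[2], ci$ci[2])
})

test_that("per-level statistics table is coherent on a real run", {
  res <- cached_dw_ffs()
  st <- ffs_level_stats(res)
  expect_equal(nrow(st), length(res$p_hats))
  expect_true(all(st$p_hat > 0 & st$p_hat <= 1))
  expect_true(all(is.na(st$sem) | st$sem >= 0))
  ci <- rate_confidence_interval(res, st)
  expect_lt(ci$ci[1], res$rate)
  expect_gt(ci$ci[2], res$rate)
  expect_lte(ci$ci_conservative[1], ci$ci[1])
})
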