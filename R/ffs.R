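# Forward flux sampling engine.  The engine itself is generic over a
# "propagator" (chain or 1D double well): interface assignment from pilot
# statistics, base-rate measurement with armed crossings and eligible-time
# bookkeeping, adaptive level placement at the 10th percentile of trial
# minima, fixed-selection trial allocation, and genealogy recording.

#' FFS run controls
#'
#' @param n_runs basin-A runs for the base-rate measurement (at least 100
#'   recommended so the interface statistics are stable)
#' @param n_pilot pilot trials used to place each next interface
#' @param n_trials production trials per level (at least 1000 recommended)
#' @param lambda_B terminal (desorbed-basin) contact-number threshold
#' @param target_p target advancing probability per level
#' @param trate0 initial base-rate measurement time per run (ps)
#' @param max_doublings budget of `trate` doublings
#' @param max_trial_time per-trial time cap (ps); trials hitting it count
#'   as failures and are reported
#' @param max_levels safety cap on the number of interfaces
#' @param max_snapshots_per_run cap on stored level-0 crossing snapshots
#' @param selection `"fixed"` (default) or `"random"` trial allocation
#' @return an object of class `ffs_control`
#' @export
ffs_control <- function(n_runs = 100, n_pilot = 100, n_trials = 1000,
                        lambda_B = 1e-5, target_p = 0.1, trate0 = 500,
                        max_doublings = 10, max_trial_time = 2e5,
                        max_levels = 150, max_snapshots_per_run = 100,
                        selection = c("fixed", "random")) {
  stopifnot(n_runs >= 2, n_pilot >= 2, n_trials >= 1, target_p > 0,
            target_p < 1, trate0 > 0)
  structure(list(n_runs = n_runs, n_pilot = n_pilot, n_trials = n_trials,
                 lambda_B = lambda_B, target_p = target_p, trate0 = trate0,
                 max_doublings = max_doublings,
                 max_trial_time = max_trial_time, max_levels = max_levels,
                 max_snapshots_per_run = max_snapshots_per_run,
                 selection = match.arg(selection)),
            class = "ffs_control")
}

# ---------------------------------------------------------------------------
# propagators
# ---------------------------------------------------------------------------

#' Propagator for the polymer desorption problem
#'
#' Bundles the Langevin chain dynamics into the interface the FFS engine
#' works against: short trials with first-touch stopping, fixed-length
#' basin runs with contact statistics, and deterministic replay harvesting
#' armed forward crossings.
#'
#' @param model a [chain_model()]
#' @param params a [langevin_params()]
#' @return an object of class `ffs_propagator`
#' @export
chain_propagator <- function(model, params) {
  check_stability(model, params)
  dt <- params$dt
  structure(list(
    dt = dt,
    describe = sprintf("%s N=%d epsPW=%g", model$name, model$N, model$ePW),
    run_to = function(state, lo, hi, max_steps, seed, stream) {
      r <- run_dynamics(state, model, params, max_steps, seed = seed,
                        stream = stream, wall = TRUE,
                        stop_c_lo = lo, stop_c_hi = hi)
      list(state = r$state, stop = r$stop, min_c = r$min_contact,
           steps = r$steps, time = r$time, contact = r$contact)
    },
    # basin statistics are taken up to the first spontaneous entry into B:
    # once the chain desorbs, the rest of the run is not basin-A data
    run_stats = function(state, n_steps, seed, stream, c_lo) {
      r <- run_dynamics(state, model, params, n_steps, seed = seed,
                        stream = stream, wall = TRUE, stop_c_lo = c_lo)
      list(c_mean = r$mean_contact, c_min = r$min_contact)
    },
    crossings = function(state, n_steps, seed, stream, lamA, lam0, lamB,
                         max_snapshots) {
      r <- cpp_chain_crossings(state$positions, state$velocities,
                               as_cpp_model(model), params$temperature,
                               dt, params$tdamp, seed, stream, n_steps,
                               lamA, lam0, lamB, max_snapshots)
      r$snapshots <- lapply(r$snapshots, function(s) {
        system_state(s$positions, s$velocities)
      })
      r
    },
    contact = function(state) contact_number(state, model$switching)
  ), class = "ffs_propagator")
}

# ---------------------------------------------------------------------------
# interface assignment (pilot-run statistics)
# ---------------------------------------------------------------------------

#' Assign the basin edge and first interface from pilot statistics
#'
#' Given per-run time-averaged contact numbers and per-run minima over a
#' set of basin-A runs, places
#' \deqn{\lambda_0 = \tfrac12\big(\min_i \langle C\rangle_i +
#'   \mathrm{median}_i\, C_{i,\min}\big), \qquad
#'   \lambda_A = \tfrac12(\lambda_0 + \min_i \langle C\rangle_i),}
#' so that \eqn{\lambda_A = \tfrac34 \min_i\langle C\rangle_i +
#' \tfrac14\mathrm{median}_i C_{i,\min}}. The gap between the two
#' prevents correlated vibrations around \eqn{\lambda_0} from being
#' counted as repeated crossings.
#'
#' @param c_mean per-run time-averaged contact numbers
#' @param c_min per-run contact-number minima
#' @return list with `lambda_A` and `lambda_0`
#' @export
assign_interfaces <- function(c_mean, c_min) {
  stopifnot(length(c_mean) == length(c_min), length(c_mean) >= 2)
  lambda_0 <- (min(c_mean) + median(c_min)) / 2
  lambda_A <- (lambda_0 + min(c_mean)) / 2
  if (lambda_A <= lambda_0) {
    stop("assign_interfaces: degenerate statistics (lambda_A <= lambda_0); ",
         "use longer pilot runs")
  }
  list(lambda_A = lambda_A, lambda_0 = lambda_0)
}

#' Count armed forward crossings of lambda0 in a contact-number trace
#'
#' A crossing of `lambda_0` is counted only when the trajectory has first
#' dropped below `lambda_A` (arming); re-arming requires rising above
#' `lambda_A` again. Time spent in basin B (`C < lambda_B`) and in the
#' B-to-A transit (until `C` first re-exceeds `lambda_A`) is excluded from
#' the eligible time, during which no crossings are counted.
#'
#' @param C numeric contact-number trace at uniform time resolution
#' @param lambda_A,lambda_0 interface positions (`lambda_A > lambda_0`)
#' @param lambda_B basin-B threshold (`-Inf` disables the exclusion)
#' @param dt time between trace points (ps)
#' @return list with `n_crossings`, `idx` (trace indices of the counted
#'   crossings), `times`, and `eligible_time`
#' @export
count_forward_crossings <- function(C, lambda_A, lambda_0,
                                    lambda_B = -Inf, dt = 1) {
  stopifnot(lambda_A > lambda_0, length(C) >= 1)
  armed <- C[1] < lambda_A
  mode <- if (C[1] < lambda_B) 1L else 0L
  elig <- 0L
  idx <- integer(0)
  for (k in seq_along(C)[-1]) {
    cc <- C[k]
    if (mode == 0L) {
      elig <- elig + 1L
      if (cc < lambda_B) {
        mode <- 1L
        armed <- FALSE
      } else {
        if (!armed && C[k - 1] >= lambda_A && cc < lambda_A) armed <- TRUE
        if (armed && cc < lambda_0) {
          idx <- c(idx, k)
          armed <- FALSE
        }
      }
    } else if (mode == 1L) {
      if (cc >= lambda_B) mode <- 2L
    } else {
      if (cc < lambda_B) mode <- 1L else if (cc >= lambda_A) {
        mode <- 0L
        armed <- FALSE
      }
    }
  }
  list(n_crossings = length(idx), idx = idx, times = (idx - 1) * dt,
       eligible_time = elig * dt)
}

#' Alternative base-rate estimator (lambda1 crossings with lambda0 history)
#'
#' Cross-check estimator that counts forward crossings of `lambda_1` whose
#' history is traceable to `lambda_0` more recently than the previous
#' `lambda_1` crossing, divided by the pooled eligible time. Reported
#' alongside the default estimator; the two definitions are close but not
#' identical, and the discrepancy is surfaced rather than resolved.
#'
#' @param traces list of contact-number traces (uniform resolution `dt`)
#' @param lambda_A,lambda_0,lambda_1 interface positions
#' @param lambda_B basin threshold for the eligible-time bookkeeping
#' @param dt trace resolution (ps)
#' @return list with `rate`, `n_crossings`, `eligible_time`
#' @export
alt_base_rate <- function(traces, lambda_A, lambda_0, lambda_1,
                          lambda_B = 1e-5, dt = 1) {
  stopifnot(lambda_0 > lambda_1)
  total_n <- 0L
  total_t <- 0
  for (C in traces) {
    seen0 <- FALSE # crossed lambda0 since the last lambda1 crossing?
    mode <- if (C[1] < lambda_B) 1L else 0L
    elig <- 0L
    for (k in seq_along(C)[-1]) {
      cc <- C[k]
      if (mode == 0L) {
        elig <- elig + 1L
        if (cc < lambda_B) {
          mode <- 1L
          seen0 <- FALSE
        } else {
          if (!seen0 && C[k - 1] >= lambda_0 && cc < lambda_0) seen0 <- TRUE
          if (seen0 && cc < lambda_1) {
            total_n <- total_n + 1L
            seen0 <- FALSE
          }
        }
      } else if (mode == 1L) {
        if (cc >= lambda_B) mode <- 2L
      } else {
        if (cc < lambda_B) mode <- 1L else if (cc >= lambda_A) mode <- 0L
      }
    }
    total_t <- total_t + elig * dt
  }
  list(rate = total_n / total_t, n_crossings = total_n,
       eligible_time = total_t)
}

# ---------------------------------------------------------------------------
# base rate
# ---------------------------------------------------------------------------

#' Measure the base rate of A-to-L0 crossings
#'
#' Runs every basin-A state for `trate`, assigns `lambda_A`/`lambda_0`
#' from the runs via [assign_interfaces()], and counts armed forward
#' crossings of `lambda_0`. If any run fails to cross, `trate` is doubled
#' for all runs and the whole procedure repeats. The rate is the pooled
#' crossing count divided by the pooled eligible time; the states at the
#' counted crossings seed level 0 of the splitting run.
#'
#' @param prop an `ffs_propagator`
#' @param states list of basin-A starting states
#' @param control an [ffs_control()]
#' @param seed master seed
#' @return list with `rate`, `lambda_A`, `lambda_0`, `snapshots`,
#'   `snapshot_run` (source run of each snapshot), `counts`, `times`
#'   (crossing times per run), `eligible_time`, `trate`, `n_doublings`
#' @export
measure_base_rate <- function(prop, states, control = ffs_control(),
                              seed = 1) {
  stopifnot(inherits(prop, "ffs_propagator"))
  n <- length(states)
  trate <- control$trate0
  for (round_i in 0:control$max_doublings) {
    n_steps <- round(trate / prop$dt)
    stats <- lapply(seq_len(n), function(i) {
      prop$run_stats(states[[i]], n_steps, seed, stream = round_i * 1e6 + i,
                     c_lo = control$lambda_B)
    })
    # degenerate interface statistics are treated like failed crossings:
    # the runs were too short to characterize the basin, so trate doubles
    iface <- tryCatch(
      assign_interfaces(vapply(stats, `[[`, 0, "c_mean"),
                        vapply(stats, `[[`, 0, "c_min")),
      error = function(e) NULL)
    if (is.null(iface)) {
      trate <- 2 * trate
      next
    }
    # deterministic replay of the identical trajectories, harvesting the
    # crossing snapshots under the freshly assigned interfaces
    cross <- lapply(seq_len(n), function(i) {
      prop$crossings(states[[i]], n_steps, seed, stream = round_i * 1e6 + i,
                     iface$lambda_A, iface$lambda_0, control$lambda_B,
                     control$max_snapshots_per_run)
    })
    counts <- vapply(cross, `[[`, 0, "n_crossings")
    if (all(counts >= 1)) {
      snaps <- list()
      runs <- integer(0)
      for (i in seq_len(n)) {
        s <- cross[[i]]$snapshots
        snaps <- c(snaps, s)
        runs <- c(runs, rep(i, length(s)))
      }
      return(list(rate = sum(counts) /
                    sum(vapply(cross, `[[`, 0, "eligible_time")),
                  lambda_A = iface$lambda_A, lambda_0 = iface$lambda_0,
                  snapshots = snaps, snapshot_run = runs, counts = counts,
                  times = lapply(cross, `[[`, "times"),
                  eligible_time = sum(vapply(cross, `[[`, 0,
                                             "eligible_time")),
                  trate = trate, n_doublings = round_i))
    }
    trate <- 2 * trate
  }
  stop("measure_base_rate: trate ceiling reached (", trate / 2,
       " ps) with runs that never crossed lambda_0")
}

# ---------------------------------------------------------------------------
# levels
# ---------------------------------------------------------------------------

#' Allocate trials to level snapshots
#'
#' Fixed selection gives each snapshot `floor(n_trials/S)` trials and
#' assigns the remainder to distinct snapshots at random, which reduces
#' genetic drift relative to random selection (where some snapshots may
#' receive no trials at all).
#'
#' @param n_snapshots number of snapshots at the level
#' @param n_trials total trials to allocate
#' @param method `"fixed"` or `"random"`
#' @return integer vector of per-snapshot trial counts summing to
#'   `n_trials`
#' @export
allocate_trials <- function(n_snapshots, n_trials,
                            method = c("fixed", "random")) {
  method <- match.arg(method)
  if (method == "fixed") {
    base <- n_trials %/% n_snapshots
    rem <- n_trials - base * n_snapshots
    counts <- rep.int(base, n_snapshots)
    if (rem > 0) {
      pick <- sample.int(n_snapshots, rem)
      counts[pick] <- counts[pick] + 1L
    }
    counts
  } else {
    tabulate(sample.int(n_snapshots, n_trials, replace = TRUE),
             nbins = n_snapshots)
  }
}

#' Place the next interface adaptively
#'
#' Runs `n_pilot` trials from randomly chosen snapshots of the current
#' level (each until the trajectory returns to `lambda_A` or enters B),
#' records each trial's contact-number minimum, and returns the 10th
#' percentile (lower/order-statistic interpolation) of the minima as the
#' next interface, floored at `lambda_B`. Once at least a `target_p`
#' fraction of pilot trials reach B, the returned level is `lambda_B`
#' itself and the splitting run enters its final level.
#'
#' @param prop an `ffs_propagator`
#' @param snapshots list of current-level snapshots
#' @param lambda_A basin edge (trial failure boundary)
#' @param lambda_cur current level (used to detect non-progression)
#' @param control an [ffs_control()]
#' @param seed master seed
#' @param stream_base noise stream offset for the pilot trials
#' @return list with `lambda_next`, `minima`, `frac_B`
#' @export
place_next_level <- function(prop, snapshots, lambda_A, lambda_cur,
                             control = ffs_control(), seed = 1,
                             stream_base = 0) {
  S <- length(snapshots)
  stopifnot(S >= 1)
  max_steps <- round(control$max_trial_time / prop$dt)
  pick <- with_seed(derive_seed(seed, stream_base + 1),
                    sample.int(S, control$n_pilot, replace = TRUE))
  minima <- vapply(seq_len(control$n_pilot), function(t) {
    prop$run_to(snapshots[[pick[t]]], lo = control$lambda_B, hi = lambda_A,
                max_steps, seed, stream = stream_base + t)$min_c
  }, numeric(1))
  lambda_next <- unname(quantile(minima, control$target_p, type = 1))
  if (lambda_next < control$lambda_B) lambda_next <- control$lambda_B
  if (lambda_next >= lambda_cur) {
    stop("place_next_level: pilot minima do not progress below the current ",
         "level (reaction coordinate stuck at ", signif(lambda_cur, 4), ")")
  }
  list(lambda_next = lambda_next, minima = minima,
       frac_B = mean(minima < control$lambda_B))
}

#' Run one splitting level
#'
#' Allocates `n_trials` over the level's snapshots (fixed selection by
#' default) and runs each trial until it either advances below
#' `lambda_next` (success; the state at first touch becomes a snapshot of
#' the next level, with parentage recorded) or returns to `lambda_A`
#' (failure). Trials hitting the time cap are counted as failures and
#' reported in `n_timeout`.
#'
#' @param prop an `ffs_propagator`
#' @param snapshots list of current-level snapshots
#' @param lambda_A basin edge
#' @param lambda_next the next interface
#' @param control an [ffs_control()]
#' @param seed master seed
#' @param stream_base noise stream offset
#' @return list with `p_hat`, `p_j` (per-snapshot advancement
#'   probabilities; NA for snapshots that received no trials), `alloc`,
#'   `snapshots` (next level), `parents`, `n_timeout`
#' @export
run_level <- function(prop, snapshots, lambda_A, lambda_next,
                      control = ffs_control(), seed = 1, stream_base = 0) {
  S <- length(snapshots)
  stopifnot(S >= 1)
  alloc <- with_seed(derive_seed(seed, stream_base + 2),
                     allocate_trials(S, control$n_trials, control$selection))
  max_steps <- round(control$max_trial_time / prop$dt)
  new_snaps <- list()
  parents <- integer(0)
  succ <- integer(S)
  n_timeout <- 0L
  stream <- stream_base
  for (j in seq_len(S)) {
    nj <- alloc[j]
    if (nj == 0) next
    for (t in seq_len(nj)) {
      stream <- stream + 1
      r <- prop$run_to(snapshots[[j]], lo = lambda_next, hi = lambda_A,
                       max_steps, seed, stream = stream)
      if (r$stop == "lo") {
        succ[j] <- succ[j] + 1L
        new_snaps[[length(new_snaps) + 1L]] <- r$state
        parents <- c(parents, j)
      } else if (r$stop == "maxsteps") {
        n_timeout <- n_timeout + 1L
      }
    }
  }
  p_hat <- sum(succ) / control$n_trials
  if (p_hat == 0) {
    stop("run_level: level extinction (no trial advanced to ",
         signif(lambda_next, 4), "); re-place the interface closer")
  }
  p_j <- ifelse(alloc > 0, succ / alloc, NA_real_)
  list(p_hat = p_hat, p_j = p_j, alloc = alloc, successes = succ,
       snapshots = new_snaps, parents = parents, n_timeout = n_timeout)
}

#' Assemble the transition rate from its factors
#'
#' \eqn{r_{A\to B} = r_{A\to\lambda_0}\prod_i \hat p_i}; the desorption
#' time is its reciprocal, optionally nondimensionalized as
#' \eqn{t_{des} D / R_g^2}.
#'
#' @param base_rate rate of A-to-L0 crossings (events/ps)
#' @param p_hats per-level advancement probabilities, final level included
#' @param D free-chain diffusivity (nm^2/ps), optional
#' @param Rg free-chain radius of gyration (nm), optional
#' @return list with `rate` (events/ps), `tdes` (ps) and, when `D` and
#'   `Rg` are supplied, `dimensionless_tdes`
#' @export
assemble_rate <- function(base_rate, p_hats, D = NULL, Rg = NULL) {
  stopifnot(base_rate > 0)
  if (any(p_hats <= 0)) stop("assemble_rate: undefined rate (some p = 0)")
  if (any(p_hats > 1)) stop("assemble_rate: probabilities must be <= 1")
  rate <- base_rate * prod(p_hats)
  out <- list(rate = rate, tdes = 1 / rate)
  if (!is.null(D) && !is.null(Rg)) {
    out$dimensionless_tdes <- dimensionless_tdes(out$tdes, D, Rg)
  }
  out
}

# ---------------------------------------------------------------------------
# orchestrators
# ---------------------------------------------------------------------------

# generic engine: base rate, then adaptive levels until B is reached
ffs_core <- function(prop, states, control, seed) {
  base <- measure_base_rate(prop, states, control, seed)
  genealogy <- list(list(parent = rep(NA_integer_,
                                      length(base$snapshots)),
                         run = base$snapshot_run,
                         states = base$snapshots,
                         trials = NULL, successes = NULL))
  levels <- numeric(0)
  p_hats <- numeric(0)
  p_values <- list()
  timeouts <- integer(0)
  snaps <- base$snapshots
  lambda_cur <- base$lambda_0
  for (i in seq_len(control$max_levels)) {
    placement <- place_next_level(prop, snaps, base$lambda_A, lambda_cur,
                                  control, seed,
                                  stream_base = 2e6 + i * 1e5)
    lv <- run_level(prop, snaps, base$lambda_A, placement$lambda_next,
                    control, seed, stream_base = 3e6 + i * 1e5)
    genealogy[[i]]$trials <- lv$alloc
    genealogy[[i]]$successes <- lv$successes
    genealogy[[i + 1]] <- list(parent = lv$parents, run = NULL,
                               states = lv$snapshots, trials = NULL,
                               successes = NULL)
    levels <- c(levels, placement$lambda_next)
    p_hats <- c(p_hats, lv$p_hat)
    p_values[[i]] <- lv$p_j
    timeouts <- c(timeouts, lv$n_timeout)
    snaps <- lv$snapshots
    lambda_cur <- placement$lambda_next
    if (placement$lambda_next <= control$lambda_B) break
    if (i == control$max_levels) {
      stop("ffs_core: max_levels reached before entering basin B")
    }
  }
  ra <- assemble_rate(base$rate, p_hats)
  structure(list(
    base_rate = base$rate, lambda_A = base$lambda_A,
    lambda_0 = base$lambda_0, levels = levels, p_hats = p_hats,
    p_values = p_values, rate = ra$rate, tdes = ra$tdes,
    n_crossings = sum(base$counts), eligible_time = base$eligible_time,
    crossing_times = base$times, trate = base$trate,
    n_doublings = base$n_doublings, genealogy = genealogy,
    n_timeout = timeouts, control = control, seed = seed,
    system = prop$describe), class = "ffs_result")
}

#' Compute a desorption rate by forward flux sampling
#'
#' End-to-end driver for the polymer problem: samples adsorbed basin-A
#' states, measures the base rate of A-to-L0 crossings, then splits the
#' remaining transition over adaptively placed contact-number interfaces
#' until the desorbed basin (`C < lambda_B`) is reached. Deterministic
#' for a fixed seed.
#'
#' @param model a [chain_model()]
#' @param params a [langevin_params()]
#' @param control an [ffs_control()]
#' @param seed master seed
#' @param states optional pre-sampled basin-A states (skips preparation)
#' @return an `ffs_result` with the rate (events/ps), desorption time
#'   `tdes` (ps), interfaces, per-level probabilities, genealogy and
#'   bookkeeping; see [ffs_level_stats()] and
#'   [rate_confidence_interval()] for uncertainties
#' @export
ffs_rate <- function(model, params, control = ffs_control(), seed = 1,
                     states = NULL) {
  if (is.null(states)) {
    states <- sample_adsorbed(model, params, control$n_runs, seed = seed)
  }
  res <- ffs_core(chain_propagator(model, params), states, control, seed)
  res$model <- model
  res$params <- params
  res
}

#' @export
print.ffs_result <- function(x, ...) {
  cat(sprintf("<ffs_result> %s\n", x$system))
  cat(sprintf("  lambda_A = %.4g, lambda_0 = %.4g, %d levels down to %g\n",
              x$lambda_A, x$lambda_0, length(x$levels), min(x$levels)))
  cat(sprintf("  base rate  %.4g /ps  (%d crossings / %.4g ps eligible)\n",
              x$base_rate, x$n_crossings, x$eligible_time))
  cat(sprintf("  rate A->B  %.4g /ps   tdes = %.4g ps\n", x$rate, x$tdes))
  invisible(x)
}
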