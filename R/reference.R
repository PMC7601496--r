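# Ground-truth estimators: brute-force mean-first-passage desorption and a
# 1D double-well toy that validates the FFS engine against direct
# simulation and the Kramers high-friction prediction.

#' Brute-force mean first-passage time to desorption
#'
#' Evolves each adsorbed starting state with plain Langevin dynamics until
#' the contact number first drops below `lambda_B`, and summarizes the
#' first-passage times assuming exponential waiting times (the mean of
#' `n` exponentials follows a Gamma distribution, giving the confidence
#' interval). Runs that exhaust `max_time` are excluded and flagged.
#'
#' @param states list of adsorbed [system_state()]s (one event per state)
#' @param model a [chain_model()]
#' @param params a [langevin_params()]
#' @param lambda_B desorbed-basin contact threshold
#' @param max_time per-event time budget (ps)
#' @param seed master seed
#' @return list with `tdes` (mean, ps), `ci` (95%), `rate`, `times`,
#'   `n_events`, `n_censored`
#' @export
brute_force_mfpt <- function(states, model, params, lambda_B = 1e-5,
                             max_time = 5e6, seed = params$seed) {
  stopifnot(length(states) >= 1)
  max_steps <- round(max_time / params$dt)
  times <- vapply(seq_along(states), function(i) {
    r <- run_dynamics(states[[i]], model, params, max_steps, seed = seed,
                      stream = 5e6 + i, wall = TRUE, stop_c_lo = lambda_B)
    if (r$stop == "lo") r$time else NA_real_
  }, numeric(1))
  censored <- sum(is.na(times))
  times <- times[!is.na(times)]
  n <- length(times)
  if (n == 0) stop("brute_force_mfpt: no desorption event within max_time")
  m <- mean(times)
  # mean of n exponentials: 2 n m / rate ~ chi^2(2n)
  ci <- c(2 * n * m / qchisq(0.975, 2 * n), 2 * n * m / qchisq(0.025, 2 * n))
  out <- list(tdes = m, ci = ci, rate = 1 / m, times = times, n_events = n,
              n_censored = censored)
  if (censored > 0) {
    warning(censored, " run(s) hit the time budget and were excluded")
    out$partial <- TRUE
  }
  out
}

# ---------------------------------------------------------------------------
# 1D double-well validation system
# ---------------------------------------------------------------------------

#' Propagator for the double-well toy
#'
#' Single Langevin particle in \eqn{V(x) = h (x^2 - 1)^2}; the order
#' parameter is \eqn{-x} so that forward progress (escape from the basin
#' at `x = -1` to the one at `x = +1`) decreases it, matching the
#' contact-number convention. Drives the same FFS engine as the chain.
#'
#' @param h barrier height (kJ/mol)
#' @param mass particle mass (g/mol)
#' @param params a [langevin_params()]
#' @return an `ffs_propagator`
#' @export
dw_propagator <- function(h, mass = 45, params = langevin_params()) {
  dt <- params$dt
  tt <- params$temperature
  td <- params$tdamp
  structure(list(
    dt = dt,
    describe = sprintf("double well h=%g kJ/mol", h),
    run_to = function(state, lo, hi, max_steps, seed, stream) {
      r <- cpp_dw_run(state$x, state$v, h, mass, tt, dt, td, seed, stream,
                      max_steps, lo, hi, 0L)
      list(state = list(x = r$x, v = r$v), stop = r$stop, min_c = r$min_op,
           steps = r$steps, time = r$time, contact = r$op)
    },
    run_stats = function(state, n_steps, seed, stream, c_lo) {
      r <- cpp_dw_run(state$x, state$v, h, mass, tt, dt, td, seed, stream,
                      n_steps, c_lo, NA_real_, 1L)
      list(c_mean = mean(r$record[, "C"]), c_min = min(r$record[, "C"]))
    },
    crossings = function(state, n_steps, seed, stream, lamA, lam0, lamB,
                         max_snapshots) {
      r <- cpp_dw_crossings(state$x, state$v, h, mass, tt, dt, td, seed,
                            stream, n_steps, lamA, lam0, lamB,
                            max_snapshots)
      r$snapshots <- Map(function(x, v) list(x = x, v = v), r$snap_x,
                         r$snap_v)
      r
    },
    contact = function(state) -state$x
  ), class = "ffs_propagator")
}

#' Escape rate of the double-well toy
#'
#' Computes the A-to-B escape rate of the quartic double well either by
#' brute-force first passage (mean of `n_events` exponential waiting
#' times) or by running the full FFS machinery (base rate with armed
#' crossings plus adaptive splitting levels) on the same dynamics — the
#' self-consistency of the two is the engine's primary validation.
#'
#' @param h barrier height in units of kBT (typically 2-8 for affordable
#'   brute force)
#' @param params a [langevin_params()]
#' @param method `"brute"` or `"ffs"`
#' @param n_events brute-force events
#' @param control FFS controls (basin threshold `lambda_B` is interpreted
#'   on the order parameter `-x`)
#' @param mass particle mass (g/mol)
#' @param seed master seed
#' @return for `"brute"`: list with `rate`, `tdes`, `ci`, `times`; for
#'   `"ffs"`: an `ffs_result`
#' @export
double_well_rate <- function(h, params = langevin_params(),
                             method = c("brute", "ffs"), n_events = 30,
                             control = NULL, mass = 45, seed = 1) {
  method <- match.arg(method)
  h_kj <- h * kB * params$temperature
  prop <- dw_propagator(h_kj, mass, params)
  lamB <- -0.8 # committed to the product basin at x = +0.8
  vsd <- sqrt(kB * params$temperature / mass)
  if (method == "brute") {
    max_steps <- 5e9
    times <- vapply(seq_len(n_events), function(i) {
      v0 <- with_seed(derive_seed(seed, i), rnorm(1, 0, vsd))
      r <- cpp_dw_run(-1, v0, h_kj, mass, params$temperature, params$dt,
                      params$tdamp, seed, 7e6 + i, max_steps, lamB,
                      NA_real_, 0L)
      if (r$stop != "lo") stop("double_well_rate: event budget exhausted")
      r$time
    }, numeric(1))
    n <- length(times)
    m <- mean(times)
    ci <- c(2 * n * m / qchisq(0.975, 2 * n),
            2 * n * m / qchisq(0.025, 2 * n))
    list(rate = 1 / m, tdes = m, ci_tdes = ci, times = times)
  } else {
    if (is.null(control)) {
      control <- ffs_control(n_runs = 50, n_pilot = 100, n_trials = 1000,
                             lambda_B = lamB, trate0 = 500,
                             max_trial_time = 1e5)
    }
    control$lambda_B <- lamB
    # basin-A states: independent short runs from the A minimum, accepted
    # only if they remain clearly on the A side (op >= 0.5) so that no
    # starting state sits on the barrier
    states <- lapply(seq_len(control$n_runs), function(i) {
      for (try in 1:50) {
        v0 <- with_seed(derive_seed(seed, 1e4 + 100 * i + try),
                        rnorm(1, 0, vsd))
        r <- cpp_dw_run(-1, v0, h_kj, mass, params$temperature, params$dt,
                        params$tdamp, seed, 8e6 + 100 * i + try,
                        round(50 / params$dt), NA_real_, NA_real_, 0L)
        if (-r$x >= 0.5) return(list(x = r$x, v = r$v))
      }
      stop("double_well_rate: could not prepare a basin-A state")
    })
    ffs_core(prop, states, control, seed)
  }
}

#' Kramers high-friction escape rate for the double well
#'
#' \eqn{r = \frac{\omega_a\,\omega_b}{2\pi\gamma} e^{-\Delta E/k_BT}} with
#' \eqn{\omega_a = \sqrt{8h/m}}, \eqn{\omega_b = \sqrt{4h/m}},
#' \eqn{\gamma = 1/t_{damp}} and barrier \eqn{\Delta E = h}; the
#' overdamped benchmark the simulated rates should approach.
#'
#' @param h barrier height in kBT units
#' @param params a [langevin_params()]
#' @param mass particle mass (g/mol)
#' @return rate in events/ps
#' @export
kramers_rate <- function(h, params = langevin_params(), mass = 45) {
  h_kj <- h * kB * params$temperature
  wa <- sqrt(8 * h_kj / mass)
  wb <- sqrt(4 * h_kj / mass)
  gam <- 1 / params$tdamp
  wa * wb / (2 * pi * gam) * exp(-h)
}
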