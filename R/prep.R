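# Basin-A preparation: equilibrium coils in free space, then adsorption
# onto the wall to produce starting states for rate measurements.

#' Generate a random coil configuration
#'
#' Builds a chain with all bonds at the equilibrium length `lb` and random
#' torsional placement: freely jointed models draw each bond direction
#' uniformly on the sphere, freely rotating models place each bond at the
#' equilibrium bending angle with a uniform azimuth. For excluded-volume
#' models, each bead placement that brings two non-adjacent beads closer than
#' `0.8 * sigma_pp` is rejected and redrawn (with whole-chain restarts if a
#' bead's retry budget is exhausted). Velocities are drawn from the
#' Maxwell-Boltzmann distribution.
#'
#' @param model a [chain_model()]
#' @param seed integer seed (R RNG, restored afterwards)
#' @param temperature temperature for the initial velocities (K)
#' @param max_retry per-bead redraw budget before a chain restart
#' @param max_restart whole-chain restart budget
#' @return a [system_state()] centred at the origin
#' @export
generate_coil <- function(model, seed = 1L, temperature = 300,
                          max_retry = 500L, max_restart = 100L) {
  stopifnot(inherits(model, "chain_model"))
  with_seed(seed, {
    N <- model$N
    lb <- model$lb
    rmin2 <- (0.8 * model$sPP)^2
    beta <- pi - model$thetaA * pi / 180 # angle between successive bonds
    if (N == 1) { # degenerate single-bead "chain"
      st <- system_state(matrix(0, 1, 3), NULL, time = 0)
      st$velocities <- maxwell_velocities(model, temperature)
      return(st)
    }
    for (attempt in seq_len(max_restart)) {
      pos <- matrix(0, N, 3)
      pos[2, ] <- lb * rand_unit()
      ok <- TRUE
      i <- 3L
      while (i <= N) {
        u <- (pos[i - 1, ] - pos[i - 2, ]) / lb
        placed <- FALSE
        for (try in seq_len(max_retry)) {
          b <- if (model$use_angle) rand_cone(u, beta) else rand_unit()
          cand <- pos[i - 1, ] + lb * b
          if (model$use_ev && i > 2) {
            d2 <- colSums((t(pos[seq_len(i - 2), , drop = FALSE]) - cand)^2)
            if (any(d2 < rmin2)) next
          }
          pos[i, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
        i <- i + 1L
      }
      if (ok) {
        pos <- sweep(pos, 2, colMeans(pos))
        st <- system_state(pos, NULL, time = 0)
        st$velocities <- maxwell_velocities(model, temperature)
        return(st)
      }
    }
    stop("generate_coil: retry budget exhausted (chain too dense?)")
  })
}

rand_unit <- function() {
  z <- runif(1, -1, 1)
  phi <- runif(1, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  c(s * cos(phi), s * sin(phi), z)
}

# unit vector at polar angle `beta` from `u`, uniform azimuth
rand_cone <- function(u, beta) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  phi <- runif(1, 0, 2 * pi)
  cos(beta) * u + sin(beta) * (cos(phi) * e1 + sin(phi) * e2)
}

# vector autocorrelation of the rows of `m` (mean assumed 0)
vec_acf <- function(m, max_lag) {
  n <- nrow(m)
  c0 <- mean(rowSums(m * m))
  vapply(0:max_lag, function(l) {
    mean(rowSums(m[seq_len(n - l), , drop = FALSE] *
                   m[(1 + l):n, , drop = FALSE])) / c0
  }, numeric(1))
}

#' Sample equilibrium free coils by pivot Monte Carlo
#'
#' Draws an ensemble of free-space chain configurations with the pivot
#' algorithm: a random bead is chosen, the tail beyond it is rotated by a
#' uniform angle about a uniform random axis through that bead, and the
#' move is accepted by Metropolis on the total (wall-free) potential.
#' Bond lengths are preserved exactly; the bending angle at the pivot and
#' all non-bonded interactions enter the acceptance. For ideal chains
#' every move is accepted and the sampler is exact; for excluded-volume
#' chains global observables decorrelate within a few accepted pivots,
#' making this far cheaper than Rouse-time dynamics for conformational
#' statistics. Not applicable to near-wall (adsorbed) sampling.
#'
#' @param model a [chain_model()]
#' @param n_samples configurations to emit
#' @param seed integer seed
#' @param temperature temperature (K)
#' @param spacing attempted pivots between samples, in units of N
#' @param burn_in initial attempted pivots, in units of N
#' @return list of [system_state()]s with attribute `acceptance` (the
#'   fraction of accepted moves)
#' @export
pivot_sample <- function(model, n_samples, seed = 1L, temperature = 300,
                         spacing = 2, burn_in = 5) {
  stopifnot(model$N >= 3, n_samples >= 1)
  st <- generate_coil(model, seed = seed, temperature = temperature)
  cm <- as_cpp_model(model)
  beta <- 1 / (kB * temperature)
  with_seed(derive_seed(seed, 2), {
    pos <- st$positions
    e_cur <- cpp_energy_forces(pos, cm, FALSE)$energy
    n_acc <- 0L
    n_try <- 0L
    out <- vector("list", n_samples)
    do_attempts <- function(k) {
      for (a in seq_len(k)) {
        j <- sample(2:(model$N - 1), 1)
        tail_idx <- (j + 1):model$N
        axis <- rand_unit()
        th <- runif(1, 0, 2 * pi)
        K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                      axis[2], -axis[1], 0), 3, 3)
        R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
        cand <- pos
        rel <- sweep(pos[tail_idx, , drop = FALSE], 2, pos[j, ])
        cand[tail_idx, ] <- sweep(rel %*% t(R), 2, pos[j, ], "+")
        e_new <- tryCatch(cpp_energy_forces(cand, cm, FALSE)$energy,
                          error = function(e) Inf)
        n_try <<- n_try + 1L
        if (is.finite(e_new) &&
            (e_new <= e_cur || runif(1) < exp(-beta * (e_new - e_cur)))) {
          pos <<- cand
          e_cur <<- e_new
          n_acc <<- n_acc + 1L
        }
      }
    }
    do_attempts(round(burn_in * model$N))
    for (s in seq_len(n_samples)) {
      do_attempts(round(spacing * model$N))
      emit <- system_state(sweep(pos, 2, colMeans(pos)))
      emit$velocities <- maxwell_velocities(model, temperature)
      out[[s]] <- emit
    }
    attr(out, "acceptance") <- n_acc / n_try
    out
  })
}

#' Equilibrate a free chain and emit decorrelated samples
#'
#' Runs wall-free dynamics, measures the end-to-end vector autocorrelation
#' time `tau_ends` (exponential fit over the window where the normalized
#' autocorrelation exceeds 1/e), then continues the trajectory and emits
#' one snapshot every `2 * tau_ends`, i.e. consecutive samples are
#' correlated at about \eqn{e^{-2}}.
#'
#' @param state starting [system_state()] (e.g. from [generate_coil()])
#' @param model a [chain_model()]
#' @param params a [langevin_params()]
#' @param n_samples number of snapshots to emit (0 gives an empty list)
#' @param seed master seed for the noise streams
#' @param n_tau length of the measurement run in units of the analytic
#'   Rouse time estimate
#' @return list of [system_state()]s with attributes `tau_ends` (ps) and
#'   `tau_guess`
#' @export
equilibrate_and_sample <- function(state, model, params, n_samples,
                                   seed = params$seed, n_tau = 30) {
  stopifnot(n_samples >= 0)
  tau_guess <- rouse_time(model, params)
  stride <- max(1L, round(tau_guess / 25 / params$dt))
  n_meas <- max(2000L, round(n_tau * tau_guess / params$dt))
  res <- run_dynamics(state, model, params, n_meas, seed = seed,
                      stream = 90001, wall = FALSE, record = "thermo",
                      record_stride = stride)
  ree <- res$record[, c("eex", "eey", "eez"), drop = FALSE]
  ree <- sweep(ree, 2, colMeans(ree))
  max_lag <- min(nrow(ree) - 2L, 200L)
  ac <- vec_acf(ree, max_lag)
  lags <- (0:max_lag) * stride * params$dt
  win <- which(ac > exp(-1) & ac > 0)
  win <- win[win <= (if (any(ac <= exp(-1))) min(which(ac <= exp(-1))) else max_lag)]
  if (length(win) < 3) {
    stop("equilibrate_and_sample: autocorrelation fit failed (too few points above 1/e)")
  }
  fit <- lm(log(ac[win]) ~ lags[win])
  slope <- coef(fit)[2]
  if (!is.finite(slope) || slope >= 0) {
    stop("equilibrate_and_sample: autocorrelation fit failed (non-decaying)")
  }
  tau_ends <- -1 / slope
  out <- vector("list", n_samples)
  cur <- res$state
  gap_steps <- max(1L, round(2 * tau_ends / params$dt))
  if (n_samples > 0) {
    for (k in seq_len(n_samples)) {
      r <- run_dynamics(cur, model, params, gap_steps, seed = seed,
                        stream = 90001 + k, wall = FALSE)
      cur <- r$state
      out[[k]] <- cur
    }
  }
  attr(out, "tau_ends") <- unname(tau_ends)
  attr(out, "tau_guess") <- tau_guess
  out
}

# analytic Rouse relaxation-time estimate (slowest mode) used to size runs
rouse_time <- function(model, params) {
  zeta <- model$m / params$tdamp
  zeta * model$N^2 * model$lb^2 / (3 * pi^2 * kB * params$temperature)
}

#' Adsorb a free coil onto the wall
#'
#' Translates the coil along z so its lowest bead sits at 0.7 nm, then
#' evolves it with the wall on until the chain centre of mass has moved
#' 12 nm from the wall, 90% of its beads are adsorbed (contact number
#' `C >= 0.9 N`), or `100 N` ps have elapsed. The result is accepted as a
#' basin-A starting state if `C >= min(10, 0.1 N)`; a rejected chain is
#' given one extra pre-initialization period of `100 N` ps before final
#' rejection.
#'
#' @param coil an equilibrium free-space [system_state()]
#' @param model a [chain_model()]
#' @param params a [langevin_params()]
#' @param seed,stream noise stream identifiers
#' @return the adsorbed [system_state()] with attribute `accepted = TRUE`,
#'   or an `adsorb_rejection` (list with the final `contact` and the stop
#'   `reason`)
#' @export
adsorb <- function(coil, model, params, seed = params$seed, stream = 0) {
  stopifnot(inherits(coil, "system_state"))
  N <- model$N
  pos <- coil$positions
  pos[, 3] <- pos[, 3] - min(pos[, 3]) + 0.7
  st <- system_state(pos, coil$velocities, coil$time)
  threshold <- min(10, 0.1 * N)
  n_steps <- round(100 * N / params$dt)
  for (round_i in 1:2) { # second pass is the extra pre-initialization time
    res <- run_dynamics(st, model, params, n_steps, seed = seed,
                        stream = stream * 2 + round_i, wall = TRUE,
                        stop_c_hi = 0.9 * N, stop_z_com = 12)
    st <- res$state
    if (res$contact >= threshold) {
      attr(st, "accepted") <- TRUE
      attr(st, "contact") <- res$contact
      return(st)
    }
    if (res$stop == "far") break # drifted away; extra time will not help
  }
  structure(list(contact = res$contact, reason = res$stop),
            class = "adsorb_rejection")
}

#' Sample a set of adsorbed basin-A states
#'
#' Full basin preparation: one random coil, free-space equilibration with
#' decorrelated sampling every `2 tau_ends`, then adsorption of each
#' sample; repeats until `n` accepted states are collected.
#'
#' @param model a [chain_model()]
#' @param params a [langevin_params()]
#' @param n number of accepted states required
#' @param seed master seed
#' @param max_attempts budget of adsorption attempts
#' @return list of `n` adsorbed [system_state()]s, with attributes
#'   `n_attempts` and `tau_ends`
#' @export
sample_adsorbed <- function(model, params, n, seed = params$seed,
                            max_attempts = 20 * n) {
  check_stability(model, params)
  coil <- generate_coil(model, seed = derive_seed(seed, 17))
  batch <- max(4L, ceiling(1.5 * n))
  samples <- equilibrate_and_sample(coil, model, params, batch, seed = seed)
  tau <- attr(samples, "tau_ends")
  accepted <- list()
  attempts <- 0L
  k <- 0L
  cur_tail <- samples[[length(samples)]]
  gap_steps <- max(1L, round(2 * tau / params$dt))
  while (length(accepted) < n && attempts < max_attempts) {
    k <- k + 1L
    if (k > length(samples)) { # extend the equilibrium trajectory
      r <- run_dynamics(cur_tail, model, params, gap_steps, seed = seed,
                        stream = 95000 + k, wall = FALSE)
      cur_tail <- r$state
      samples[[k]] <- cur_tail
    }
    attempts <- attempts + 1L
    st <- adsorb(samples[[k]], model, params, seed = seed, stream = 100 + k)
    if (isTRUE(attr(st, "accepted"))) accepted[[length(accepted) + 1L]] <- st
  }
  if (length(accepted) < n) {
    stop("sample_adsorbed: only ", length(accepted), "/", n,
         " states accepted in ", attempts,
         " attempts (is the adsorption strength too weak?)")
  }
  attr(accepted, "n_attempts") <- attempts
  attr(accepted, "tau_ends") <- tau
  accepted
}
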