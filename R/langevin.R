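#' Langevin integration parameters
#'
#' The chain evolves under the Langevin equation
#' \eqn{m\ddot x = -\nabla V - (m/t_{damp})\dot x + R} integrated with
#' velocity Verlet and impulsive friction/noise (the friction is evaluated
#' at the half-step velocity, as in molecular dynamics engines). The random
#' force has per-component variance \eqn{2 m k_B T/(t_{damp}\,\Delta t)}
#' per step (fluctuation-dissipation). With this scheme the free-particle
#' diffusivity is exactly \eqn{k_B T\, t_{damp}/m} at any stable time step.
#'
#' The default time step of 0.03 ps keeps the stiffest bond phonon of the
#' default chain models (frequency \eqn{2\sqrt{2 k_b/m}} = 53.3 rad/ps)
#' inside the Verlet stability window \eqn{\omega\,\Delta t <
#' \sqrt{4 - 2\Delta t/t_{damp}}} with a conventional safety margin; see
#' the methods vignette for the analysis. A warning is issued when the
#' requested step violates that window for a given model
#' ([check_stability()]).
#'
#' @param temperature temperature (K)
#' @param dt time step (ps)
#' @param tdamp damping time (ps); must exceed `dt`
#' @param seed default master seed for drivers that accept one
#' @return an object of class `langevin_params`
#' @export
langevin_params <- function(temperature = 300, dt = 0.03, tdamp = 0.25,
                            seed = 1L) {
  stopifnot(temperature > 0, dt > 0, tdamp > 0)
  if (dt >= tdamp) stop("dt must be smaller than tdamp for stability")
  structure(list(temperature = temperature, dt = dt, tdamp = tdamp,
                 seed = seed),
            class = "langevin_params")
}

#' Verlet stability check for a model/time-step pair
#'
#' The stiffest phonon of the discrete chain (zone-edge bond mode) has
#' \eqn{\omega_{max} = 2\sqrt{2 k_b/m}}; with impulsive friction the
#' velocity-Verlet scheme is linearly stable only for
#' \eqn{\omega_{max}\Delta t < \sqrt{4 - 2\,\Delta t/t_{damp}}}.
#'
#' @param model a [chain_model()]
#' @param params a [langevin_params()]
#' @param warn issue a warning when unstable?
#' @return invisibly, a list with `omega_dt` and `limit`
#' @export
check_stability <- function(model, params, warn = TRUE) {
  omega <- 2 * sqrt(2 * model$kb / model$m)
  odt <- omega * params$dt
  lim <- sqrt(4 - 2 * params$dt / params$tdamp)
  if (warn && odt >= lim) {
    warning(sprintf(paste0("time step unstable for this model: omega*dt = ",
                           "%.2f >= limit %.2f; reduce dt"), odt, lim))
  }
  invisible(list(omega_dt = odt, limit = lim))
}

#' Advance a chain with Langevin dynamics
#'
#' Integrates `n_steps` of the thermostatted equation of motion, optionally
#' recording a trace and stopping early at contact-number or
#' centre-of-mass thresholds (first-touch convention: the returned state is
#' the first one satisfying a stop condition). Bitwise reproducible for a
#' fixed `(seed, stream)` pair; distinct streams are statistically
#' independent, which is how cloned snapshots receive fresh noise.
#'
#' @param state a [system_state()]
#' @param model a [chain_model()]
#' @param params a [langevin_params()]
#' @param n_steps maximum number of steps
#' @param seed,stream noise stream identifiers (non-negative integers)
#' @param wall include the wall potential?
#' @param stop_c_lo stop when the contact number drops below this (NA = off)
#' @param stop_c_hi stop when the contact number reaches this (NA = off)
#' @param stop_z_com stop when the COM height reaches this (NA = off)
#' @param record one of `"none"`, `"contact"`, `"thermo"`
#' @param record_stride steps between recorded rows
#' @return list with the advanced `state`, `steps`, `time` advanced,
#'   `stop` reason (`"maxsteps"`, `"lo"`, `"hi"`, `"far"`), `contact`,
#'   `min_contact`, `mean_contact`, and (if requested) a `record` matrix
#' @export
run_dynamics <- function(state, model, params, n_steps, seed = params$seed,
                         stream = 0, wall = TRUE,
                         stop_c_lo = NA, stop_c_hi = NA, stop_z_com = NA,
                         record = c("none", "contact", "thermo"),
                         record_stride = 1L) {
  stopifnot(inherits(state, "system_state"), inherits(model, "chain_model"),
            inherits(params, "langevin_params"), n_steps >= 1)
  record <- match.arg(record)
  rmode <- match(record, c("none", "contact", "thermo")) - 1L
  res <- cpp_chain_run(state$positions, state$velocities,
                       as_cpp_model(model), wall, params$temperature,
                       params$dt, params$tdamp, seed, stream, n_steps,
                       stop_c_lo, stop_c_hi, stop_z_com, rmode,
                       as.integer(record_stride))
  res$state <- system_state(res$positions, res$velocities,
                            time = state$time + res$time)
  res$positions <- NULL
  res$velocities <- NULL
  res
}

#' Closed-form Rouse diffusivity
#'
#' Without hydrodynamic interactions the chain centre of mass feels the
#' summed friction of its `N` beads, so
#' \eqn{D = k_B T\, t_{damp} / (m N)}; `N = 1` gives the free-bead value.
#'
#' @param model a [chain_model()]
#' @param params a [langevin_params()]
#' @return diffusivity in nm^2/ps
#' @export
rouse_diffusivity <- function(model, params) {
  kB * params$temperature * params$tdamp / (model$m * model$N)
}

#' Measure the centre-of-mass diffusivity of a free chain
#'
#' Runs `n_replicas` wall-free trajectories and estimates `D` from the
#' centre-of-mass mean-squared displacement over non-overlapping windows
#' of length `lag`, fitting the diffusive law `MSD = 6 D t` with the
#' exact inertial offset of the integrator removed: for the free COM the
#' discrete scheme gives `MSD(t) = 6 D (t - delta)` once `t >> tdamp`,
#' with `delta = tdamp * 2(1 - eps)/(2 - eps)` and `eps = dt/tdamp`
#' (`delta -> tdamp` in the continuous limit). Ignoring the offset would
#' bias `D` low by `delta/lag`. Because all conservative forces are
#' internal, the COM performs free Langevin motion regardless of chain
#' configuration, so no prior equilibration is required.
#'
#' @param model a [chain_model()]
#' @param params a [langevin_params()]
#' @param t_total trajectory length per replica (ps)
#' @param n_replicas number of independent replicas
#' @param lag MSD window (ps)
#' @param seed master seed
#' @return list with `D` (nm^2/ps), `se` (from replica spread),
#'   `D_um2s` (um^2/s), `n_windows`
#' @export
chain_diffusivity <- function(model, params, t_total = 2500, n_replicas = 40,
                              lag = 25, seed = params$seed) {
  stopifnot(t_total > 6 * lag, lag > params$tdamp)
  stride <- max(1L, round(lag / params$dt))
  lag <- stride * params$dt
  n_steps <- floor(t_total / params$dt)
  eps <- params$dt / params$tdamp
  delta <- params$tdamp * 2 * (1 - eps) / (2 - eps)
  sq <- numeric(0)
  for (r in seq_len(n_replicas)) {
    st <- with_seed(derive_seed(seed, r), {
      coil <- generate_coil(model, seed = derive_seed(seed, 1000 + r))
      coil$velocities <- maxwell_velocities(model, params$temperature)
      coil
    })
    res <- run_dynamics(st, model, params, n_steps, seed = seed, stream = r,
                        wall = FALSE, record = "thermo",
                        record_stride = stride)
    com <- res$record[, c("comx", "comy", "comz"), drop = FALSE]
    d <- diff(com) # independent increments over windows of length `lag`
    sq <- c(sq, rowSums(d^2))
  }
  if (length(sq) < 20) {
    stop("chain_diffusivity: trajectory too short for a stable MSD fit")
  }
  D <- mean(sq) / (6 * (lag - delta))
  se <- sd(sq) / sqrt(length(sq)) / (6 * (lag - delta))
  list(D = D, se = se, D_um2s = D * 1e6, se_um2s = se * 1e6,
       n_windows = length(sq), lag = lag)
}
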