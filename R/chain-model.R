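#' Switching-function parameters for the contact number
#'
#' The contact number uses a rational switching function
#' \deqn{s(z) = \frac{1 - x^n}{1 - x^m}, \qquad x = (z - d_0)/r_0,}
#' clamped to 1 for `z <= d0`. The removable singularity at `x = 1`
#' evaluates to `n/m`. `m_exp` must exceed `n` so that `s` has a plateau
#' near the wall and a rapid cutoff.
#'
#' @param d0 onset distance (nm)
#' @param r0 decay distance (nm)
#' @param n numerator exponent
#' @param m_exp denominator exponent; must be larger than `n`
#' @return an object of class `switching_params`
#' @export
switching_params <- function(d0 = 0.35, r0 = 0.7, n = 6, m_exp = 14) {
  stopifnot(d0 > 0, r0 > 0, n >= 1, m_exp >= 1)
  if (m_exp <= n) {
    stop("m_exp must be larger than n for the switching function to have a plateau")
  }
  structure(list(d0 = d0, r0 = r0, n = as.integer(n),
                 m_exp = as.integer(m_exp)),
            class = "switching_params")
}

preset_table <- list(
  "FJC"      = list(use_ev = FALSE, use_angle = FALSE, use_torsionlike = FALSE),
  "FRC"      = list(use_ev = FALSE, use_angle = TRUE,  use_torsionlike = FALSE),
  "FJC+EV"   = list(use_ev = TRUE,  use_angle = FALSE, use_torsionlike = FALSE),
  "FRC+EV"   = list(use_ev = TRUE,  use_angle = TRUE,  use_torsionlike = FALSE),
  "FRC+EV+T" = list(use_ev = TRUE,  use_angle = TRUE,  use_torsionlike = TRUE)
)

#' Coarse-grained bead-spring chain models
#'
#' Builds one of the named chain models (freely jointed chain `"FJC"`,
#' freely rotating chain `"FRC"`, optionally with excluded volume `"+EV"`
#' and a torsion-like 1-4 distance potential `"+T"`; `"FRC+EV+D"` is an
#' accepted alias for `"FRC+EV+T"`). The shared defaults are
#' `lb = 0.33` nm, `kb = 16000` kJ/mol/nm^2, `sigma_pw = 0.47` nm and a
#' bead mass of 45 g/mol; freely rotating chains add `kA = 2000`
#' kJ/mol/rad^2 at `thetaA = 111.58` degrees; excluded-volume models add a
#' 12-6 Lennard-Jones bead-bead interaction with `sigma_pp = 0.43` nm,
#' `eps_pp = 0.2` kJ/mol (pairs `|i-j| >= 2`, cut at `2.5 sigma_pp` and
#' shifted to zero); the torsion-like model adds `kD = 60` kJ/mol/nm^2 at
#' `rD = 0.6` nm.
#'
#' Bonded terms are harmonic without a factor 1/2:
#' `kb (r - lb)^2`, `kA (theta - thetaA)^2`, `kD (r_{i,i+3} - rD)^2`.
#'
#' @param name preset name (see above)
#' @param N number of beads (`>= 2`)
#' @param eps_pw bead-wall interaction strength (kJ/mol)
#' @param sigma_pw bead-wall length parameter (nm)
#' @param m bead mass (g/mol)
#' @param switching contact-number [switching_params()]
#' @param ... overrides for individual fields (`lb`, `kb`, `kA`, `thetaA`,
#'   `kD`, `rD`, `sPP`, `ePP`)
#' @return an object of class `chain_model`
#' @export
chain_model <- function(name = "FJC", N = 50, eps_pw = 0.6,
                        sigma_pw = 0.47, m = 45,
                        switching = switching_params(), ...) {
  if (identical(name, "FRC+EV+D")) name <- "FRC+EV+T"
  if (!name %in% names(preset_table)) {
    stop("unknown chain model '", name, "'; available: ",
         paste(names(preset_table), collapse = ", "))
  }
  flags <- preset_table[[name]]
  model <- list(
    name = name,
    N = as.integer(N),
    m = m,
    lb = 0.33,
    kb = 16000,
    kA = if (flags$use_angle) 2000 else 0,
    thetaA = 111.58, # degrees; converted to rad for the dynamics core
    kD = if (flags$use_torsionlike) 60 else 0,
    rD = 0.6,
    sPP = 0.43,
    ePP = if (flags$use_ev) 0.2 else 0,
    sPW = sigma_pw,
    ePW = eps_pw,
    use_ev = flags$use_ev,
    use_angle = flags$use_angle,
    use_torsionlike = flags$use_torsionlike,
    switching = switching
  )
  model <- modifyList(model, list(...))
  model <- structure(model, class = "chain_model")
  validate_chain_model(model)
  model
}

validate_chain_model <- function(model) {
  with(model, {
    stopifnot(N >= 1, m > 0, lb > 0, kb >= 0, kA >= 0, kD >= 0,
              rD > 0, sPP > 0, sPW > 0, ePP >= 0, ePW >= 0)
    if (use_ev != (ePP > 0)) stop("use_ev inconsistent with ePP")
    if (use_angle != (kA > 0)) stop("use_angle inconsistent with kA")
    if (use_torsionlike != (kD > 0)) stop("use_torsionlike inconsistent with kD")
  })
  stopifnot(inherits(model$switching, "switching_params"))
  invisible(model)
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("<chain_model> %s, N = %d, eps_PW = %g kJ/mol, sigma_PW = %g nm\n",
              x$name, x$N, x$ePW, x$sPW))
  cat(sprintf("  bonds: kb = %g, lb = %g;  mass %g g/mol\n", x$kb, x$lb, x$m))
  if (x$use_angle) cat(sprintf("  bending: kA = %g at %g deg\n", x$kA, x$thetaA))
  if (x$use_ev) cat(sprintf("  LJ: sigma_PP = %g, eps_PP = %g\n", x$sPP, x$ePP))
  if (x$use_torsionlike) cat(sprintf("  1-4: kD = %g at rD = %g\n", x$kD, x$rD))
  invisible(x)
}

# flat list handed to the C++ core
as_cpp_model <- function(model) {
  list(N = model$N, m = model$m, lb = model$lb, kb = model$kb, kA = model$kA,
       thetaA_rad = model$thetaA * pi / 180, kD = model$kD, rD = model$rD,
       sPP = model$sPP, ePP = model$ePP, sPW = model$sPW, ePW = model$ePW,
       use_ev = model$use_ev, use_angle = model$use_angle,
       use_torsionlike = model$use_torsionlike,
       switching = list(d0 = model$switching$d0, r0 = model$switching$r0,
                        n = model$switching$n, m_exp = model$switching$m_exp))
}

#' Simulation state of a chain
#'
#' Positions and velocities of the `N` beads (nm, nm/ps), with the wall
#' normal along z and the wall at `z = 0`, plus the elapsed time.
#'
#' @param positions N x 3 matrix (nm)
#' @param velocities N x 3 matrix (nm/ps); zeros if omitted
#' @param time elapsed simulation time (ps)
#' @return an object of class `system_state`
#' @export
system_state <- function(positions, velocities = NULL, time = 0) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) >= 1)
  if (is.null(velocities)) {
    velocities <- matrix(0, nrow(positions), 3)
  }
  velocities <- as.matrix(velocities)
  stopifnot(all(dim(velocities) == dim(positions)))
  structure(list(positions = positions, velocities = velocities, time = time),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state> N = %d beads, t = %g ps, z in [%g, %g] nm\n",
              nrow(x$positions), x$time, min(x$positions[, 3]),
              max(x$positions[, 3])))
  invisible(x)
}

#' Maxwell-Boltzmann velocities
#'
#' Draws bead velocities at temperature `temperature` for the bead mass of
#' `model`, using R's RNG (seed it with [set.seed()] or via the `seed`
#' arguments of the higher-level drivers for reproducibility).
#'
#' @param model a [chain_model()]
#' @param temperature temperature (K)
#' @return N x 3 matrix of velocities (nm/ps)
#' @export
maxwell_velocities <- function(model, temperature = 300) {
  sdv <- sqrt(kB * temperature / model$m)
  matrix(rnorm(3 * model$N, 0, sdv), model$N, 3)
}
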