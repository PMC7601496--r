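#' Steele 10-4-3 wall potential
#'
#' Integrated wall potential for a bead at height `z` above a semi-infinite
#' solid,
#' \deqn{V_W(z) = 2\pi\epsilon_{PW}\left[\tfrac{2}{5}(\sigma/z)^{10}
#'   - (\sigma/z)^4 - \frac{\sqrt{2}\,\sigma^3}{3\,(z + 0.61\,\sigma/\sqrt{2})^3}
#'   \right]}
#' (the conventional 10-4-3 form with interlayer spacing
#' \eqn{\Delta = \sigma/\sqrt 2}). Diverges to \eqn{+\infty} as
#' \eqn{z \to 0^+} and vanishes at large `z`; the attractive well makes
#' adsorption metastable.
#'
#' @param z distance from the wall (nm); must be positive
#' @param sigma_pw length parameter (nm)
#' @param eps_pw energy parameter (kJ/mol); the potential is linear in it
#' @return energy in kJ/mol (vectorized over `z`)
#' @seealso [wall_force()] for the analytic `-dV/dz`
#' @export
wall_potential <- function(z, sigma_pw = 0.47, eps_pw = 1) {
  if (any(z <= 0)) stop("wall_potential: z must be positive")
  u <- sigma_pw / z
  delta <- 0.61 * sigma_pw / sqrt(2)
  2 * pi * eps_pw * (0.4 * u^10 - u^4 -
                       sqrt(2) * sigma_pw^3 / (3 * (z + delta)^3))
}

#' @rdname wall_potential
#' @export
wall_force <- function(z, sigma_pw = 0.47, eps_pw = 1) {
  if (any(z <= 0)) stop("wall_force: z must be positive")
  delta <- 0.61 * sigma_pw / sqrt(2)
  dV <- 2 * pi * eps_pw * (-4 * sigma_pw^10 / z^11 + 4 * sigma_pw^4 / z^5 +
                             sqrt(2) * sigma_pw^3 / (z + delta)^4)
  -dV
}

#' Rational switching function
#'
#' Smooth weight in (0, 1] measuring how strongly a bead at height `z`
#' counts as a wall contact; see [switching_params()]. Clamped to 1 for
#' `z <= d0` and monotonically non-increasing beyond; the far tail decays
#' as \eqn{x^{n-m}}.
#'
#' @param z distance(s) from the wall (nm); anything at or below `d0`
#'   (including, for wall-free configurations, negative values) takes the
#'   plateau value 1
#' @param params a [switching_params()]
#' @return numeric vector of weights
#' @export
switching_function <- function(z, params = switching_params()) {
  stopifnot(inherits(params, "switching_params"))
  cpp_switching(as.numeric(z), params$d0, params$r0, params$n, params$m_exp)
}

#' Contact number
#'
#' The reaction coordinate for desorption: the sum of the switching
#' function over all bead heights, \eqn{C = \sum_i s(z_i)}. `C` decreases
#' from about `N` (fully adsorbed) towards 0 as the chain leaves the wall;
#' the desorbed basin B is conventionally `C < 1e-5`.
#'
#' @param state a [system_state()], or a numeric vector of bead heights
#' @param params a [switching_params()]
#' @return the contact number (dimensionless scalar)
#' @export
contact_number <- function(state, params = switching_params()) {
  z <- if (inherits(state, "system_state")) state$positions[, 3] else state
  sum(switching_function(z, params))
}

#' Total potential energy and forces of a chain
#'
#' Evaluates the full model potential (bonds, bending, 1-4 springs,
#' excluded-volume LJ, wall) and its exact negative gradient.
#'
#' @param state a [system_state()]
#' @param model a [chain_model()]
#' @param wall include the bead-wall term?
#' @return list with `energy` (kJ/mol), `forces` (N x 3, kJ/mol/nm) and
#'   `contact` (the contact number of the state)
#' @export
chain_energy_forces <- function(state, model, wall = TRUE) {
  stopifnot(inherits(state, "system_state"), inherits(model, "chain_model"))
  if (nrow(state$positions) != model$N) {
    stop("state and model disagree on the number of beads")
  }
  cpp_energy_forces(state$positions, as_cpp_model(model), wall)
}

#' Mean-field wall potential
#'
#' Boltzmann-weighted average bead-wall interaction over the near-wall
#' layer,
#' \deqn{V_{MF} = -\frac{1}{Z}\int_0^{2\sigma_{PW}} V_W(z)\,
#'   e^{-V_W(z)/k_BT}\,dz, \quad Z = \int_0^{2\sigma_{PW}}
#'   e^{-V_W(z)/k_BT}\,dz,}
#' taken positive for attraction. This is the per-monomer well depth that
#' drives the strong-adsorption scaling
#' \eqn{\ln(t_{des} D/R_g^2) \propto N V_{MF}/k_BT}.
#'
#' @param sigma_pw,eps_pw wall parameters (nm, kJ/mol)
#' @param temperature temperature (K)
#' @return \eqn{V_{MF}} in kJ/mol (0 when `eps_pw = 0`)
#' @export
mean_field_potential <- function(sigma_pw = 0.47, eps_pw = 0.6,
                                 temperature = 300) {
  stopifnot(eps_pw >= 0, temperature > 0)
  if (eps_pw == 0) return(0)
  beta <- 1 / (kB * temperature)
  wgt <- function(z) {
    v <- wall_potential(z, sigma_pw, eps_pw)
    w <- exp(-pmin(beta * v, 700))
    w[!is.finite(v) | beta * v > 700] <- 0 # hard-core region underflows
    w
  }
  num <- function(z) {
    v <- wall_potential(z, sigma_pw, eps_pw)
    out <- v * wgt(z)
    out[!is.finite(out)] <- 0
    out
  }
  hi <- 2 * sigma_pw
  i1 <- tryCatch(
    integrate(num, 0, hi, rel.tol = 1e-10, subdivisions = 500L),
    error = function(e) stop("mean_field_potential: quadrature failed: ",
                             conditionMessage(e))
  )
  iz <- tryCatch(
    integrate(wgt, 0, hi, rel.tol = 1e-10, subdivisions = 500L),
    error = function(e) stop("mean_field_potential: quadrature failed: ",
                             conditionMessage(e))
  )
  -i1$value / iz$value
}
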