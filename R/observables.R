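# Chain observables and scaling analyses: radius of gyration, power-law
# fits, the dimensionless desorption time, the strong-adsorption scaling
# coordinates, and the simulation-to-experiment time conversion.

#' Ensemble radius of gyration
#'
#' \eqn{R_g = \sqrt{\langle \sum_i |r_i - \bar r|^2 / N\rangle}} over an
#' ensemble of states, with a delta-method standard error.
#'
#' @param states list of [system_state()]s (at least 2), or a single state
#'   (returns its instantaneous value with `se = NA`)
#' @return list with `Rg` (nm), `se`, `Rg2`, `se2`, `n`
#' @export
radius_of_gyration <- function(states) {
  if (inherits(states, "system_state")) states <- list(states)
  rg2 <- vapply(states, function(s) {
    p <- s$positions
    mean(rowSums(sweep(p, 2, colMeans(p))^2))
  }, numeric(1))
  m2 <- mean(rg2)
  se2 <- if (length(rg2) >= 2) sd(rg2) / sqrt(length(rg2)) else NA_real_
  rg <- sqrt(m2)
  list(Rg = rg, se = se2 / (2 * rg), Rg2 = m2, se2 = se2, n = length(rg2))
}

#' Fit a power law by log-log least squares
#'
#' @param x,y positive numeric vectors (at least 3 points)
#' @return list with `exponent`, `prefactor`, `stderr` (of the exponent)
#'   and the underlying `fit`
#' @export
fit_power_law <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) {
    stop("fit_power_law: need at least 3 (x, y) pairs")
  }
  if (any(x <= 0) || any(y <= 0)) {
    stop("fit_power_law: x and y must be positive")
  }
  lx <- log(x)
  fit <- lm(log(y) ~ lx)
  sm <- summary(fit)$coefficients
  list(exponent = unname(coef(fit)[2]),
       prefactor = unname(exp(coef(fit)[1])),
       stderr = unname(sm[2, 2]), fit = fit)
}

#' Dimensionless desorption time
#'
#' \eqn{t_{des} D / R_g^2}: the mean desorption time in units of the time
#' the free chain needs to diffuse across its own size. Invariant under
#' consistent changes of units.
#'
#' @param tdes mean desorption time (ps)
#' @param D free-chain diffusivity (nm^2/ps)
#' @param Rg free-chain radius of gyration (nm)
#' @return dimensionless number
#' @export
dimensionless_tdes <- function(tdes, D, Rg) {
  stopifnot(all(tdes > 0), all(D > 0), all(Rg > 0))
  tdes * D / Rg^2
}

#' Strong-adsorption scaling slope
#'
#' In the strong-adsorption (detachment-controlled) regime the
#' dimensionless desorption time should follow
#' \eqn{\ln(t_{des} D/R_g^2) \propto N V_{MF}/k_BT} with slope
#' approaching 1 from below as the monomer-wall attraction grows. Fits
#' the slope in those coordinates.
#'
#' @param N chain lengths (at least 3)
#' @param tdes desorption times (ps)
#' @param D diffusivities (nm^2/ps)
#' @param Rg radii of gyration (nm)
#' @param VMF mean-field potential (kJ/mol), scalar (fixed wall strength)
#' @param temperature temperature (K)
#' @return list with `slope`, `stderr`, `x` (the `N VMF/kBT` coordinates),
#'   `y` (`ln(tdes D/Rg^2)`) and the `fit`
#' @export
strong_scaling_test <- function(N, tdes, D, Rg, VMF, temperature = 300) {
  if (length(N) < 3) stop("strong_scaling_test: need at least 3 chain lengths")
  x <- N * VMF / (kB * temperature)
  y <- log(dimensionless_tdes(tdes, D, Rg))
  fit <- lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(slope = unname(coef(fit)[2]), stderr = unname(sm[2, 2]),
       x = x, y = y, fit = fit)
}

#' Simulation-to-experiment time conversion factor
#'
#' Simulated Rouse chains have \eqn{D_{sim} \propto N^{-1}} while dilute
#' chains in good solvent show \eqn{D_{exp} \propto N^{-0.589}}, so the
#' factor \eqn{D_{sim}/D_{exp}} used to convert simulation times to
#' experimental times scales as \eqn{N^{-0.411}}. It is anchored at
#' `N = 50`, where the measured simulated chain diffusivity is divided by
#' the experimental reference (99 um^2/s for PEO in water).
#'
#' @param N chain length(s) to evaluate at
#' @param D_sim50 simulated chain diffusivity at `N = 50`, in um^2/s
#' @param D_exp_ref experimental reference diffusivity at `N = 50`
#'   (um^2/s)
#' @return the factor(s) \eqn{D_{sim}/D_{exp}} (multiply simulation times
#'   by this to obtain experimental times)
#' @export
time_conversion_factor <- function(N, D_sim50, D_exp_ref = 99) {
  stopifnot(all(N >= 1), D_sim50 > 0, D_exp_ref > 0)
  (D_sim50 / D_exp_ref) * (N / 50)^(-0.411)
}

#' Free-chain ensemble statistics for a set of chain lengths
#'
#' Convenience driver producing, per chain length, the ensemble radius of
#' gyration and the chain diffusivity, for the scaling analyses. Ideal
#' (freely jointed, no excluded volume) coils are sampled by direct
#' construction, which is exact; interacting models are sampled by pivot
#' Monte Carlo ([pivot_sample()]).
#'
#' @param name chain model preset name
#' @param Ns integer vector of chain lengths
#' @param params a [langevin_params()]
#' @param n_samples coils per chain length
#' @param seed master seed
#' @param measure_D also measure D by COM displacement (else the exact
#'   Rouse value)
#' @return data frame with columns `N`, `Rg`, `Rg_se`, `Rg2`, `D`
#'   (nm^2/ps)
#' @export
free_chain_table <- function(name, Ns, params = langevin_params(),
                             n_samples = 100, seed = 1,
                             measure_D = FALSE) {
  rows <- lapply(Ns, function(n) {
    model <- chain_model(name, N = n, eps_pw = 0)
    states <- if (!model$use_ev && !model$use_angle &&
                    !model$use_torsionlike) {
      lapply(seq_len(n_samples), function(k) {
        generate_coil(model, seed = derive_seed(seed, n * 1000 + k))
      })
    } else {
      pivot_sample(model, n_samples, seed = derive_seed(seed, n),
                   temperature = params$temperature)
    }
    rg <- radius_of_gyration(states)
    D <- if (measure_D) {
      chain_diffusivity(model, params, seed = derive_seed(seed, n))$D
    } else {
      rouse_diffusivity(model, params)
    }
    data.frame(N = n, Rg = rg$Rg, Rg_se = rg$se, Rg2 = rg$Rg2, D = D)
  })
  do.call(rbind, rows)
}
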