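# Serialization: XYZ trajectories/snapshot libraries, YAML run
# configuration with validation and filled-in defaults, and JSON manifests.

#' Write states to a (multi-frame) XYZ file
#'
#' One frame per state; the comment line carries the elapsed time and the
#' contact number so frames remain interpretable on their own.
#'
#' @param states a [system_state()] or list of them
#' @param file output path
#' @param switching [switching_params()] used for the comment-line contact
#'   number
#' @param label atom label
#' @export
write_xyz <- function(states, file, switching = switching_params(),
                      label = "C") {
  if (inherits(states, "system_state")) states <- list(states)
  con <- file(file, "w")
  on.exit(close(con))
  for (s in states) {
    n <- nrow(s$positions)
    writeLines(as.character(n), con)
    writeLines(sprintf("time=%.6f contact=%.8g", s$time,
                       contact_number(s, switching)), con)
    writeLines(sprintf("%s %.8f %.8f %.8f", label, s$positions[, 1],
                       s$positions[, 2], s$positions[, 3]), con)
  }
  invisible(file)
}

#' Read a (multi-frame) XYZ file
#'
#' @param file path to an XYZ file written by [write_xyz()] (or any plain
#'   XYZ; times default to 0 when absent)
#' @return list of [system_state()]s (velocities zero)
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    if (is.na(n)) stop("read_xyz: malformed frame header at line ", i)
    cm <- lines[i + 1]
    t <- 0
    m <- regmatches(cm, regexec("time=([0-9eE.+-]+)", cm))[[1]]
    if (length(m) == 2) t <- as.numeric(m[2])
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
    pos <- matrix(as.numeric(parts[, 2:4]), ncol = 3)
    out[[length(out) + 1L]] <- system_state(pos, time = t)
    i <- i + 2L + n
  }
  out
}

config_defaults <- function() {
  list(
    model = list(name = "FJC", n_beads = 50L, eps_pw = 0.6,
                 sigma_pw = 0.47, m = 45),
    langevin = list(temperature = 300, dt = 0.03, tdamp = 0.25),
    switching = list(d0 = 0.35, r0 = 0.7, n_exp = 6L, m_exp = 14L),
    prep = list(n_tau = 30, max_attempts_factor = 20L),
    ffs = list(n_runs = 100L, n_pilot = 100L, n_trials = 1000L,
               lambda_B = 1e-5, target_p = 0.1, trate0 = 500,
               max_doublings = 10L, max_trial_time = 2e5,
               selection = "fixed"),
    seed = NULL,
    output = list(dir = ".", prefix = "run")
  )
}

#' Load and validate a run configuration
#'
#' YAML configuration with sections `model`, `langevin`, `switching`,
#' `prep`, `ffs`, `output` and a mandatory top-level `seed`. Unknown keys
#' are rejected by name; omitted keys take the package defaults
#' (T = 300 K, dt = 0.03 ps, tdamp = 0.25 ps, m = 45 g/mol,
#' lambda_B = 1e-5, 100 pilot runs, 1000 trials per level, switching
#' d0 = 0.35 / r0 = 0.7 / exponents 6 and 14). Note the bead-count and
#' exponent keys are spelled `n_beads` and `n_exp`: a bare `N`/`n` is a
#' boolean in YAML 1.1.
#'
#' @param path YAML file path
#' @return validated configuration of class `ffs_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  raw <- yaml::read_yaml(path)
  as_config(raw)
}

as_config <- function(raw) {
  defaults <- config_defaults()
  bad <- setdiff(names(raw), names(defaults))
  if (length(bad) > 0) {
    stop("load_config: unknown section/key: ", paste(bad, collapse = ", "))
  }
  for (sec in setdiff(names(defaults), "seed")) {
    if (!is.null(raw[[sec]])) {
      unknown <- setdiff(names(raw[[sec]]), names(defaults[[sec]]))
      if (length(unknown) > 0) {
        stop("load_config: unknown key in '", sec, "': ",
             paste(unknown, collapse = ", "))
      }
    }
  }
  cfg <- modifyList(defaults, raw)
  if (is.null(cfg$seed)) {
    stop("load_config: a top-level 'seed' is mandatory (reproducibility)")
  }
  # eager validation through the constructors
  sw <- switching_params(cfg$switching$d0, cfg$switching$r0,
                         cfg$switching$n_exp, cfg$switching$m_exp)
  invisible(chain_model(cfg$model$name, cfg$model$n_beads,
                        cfg$model$eps_pw, cfg$model$sigma_pw, cfg$model$m,
                        switching = sw))
  invisible(do.call(langevin_params, c(cfg$langevin, list(seed = cfg$seed))))
  structure(cfg, class = "ffs_config")
}

#' @rdname load_config
#' @param config an `ffs_config`
#' @param path output path
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "ffs_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Instantiate the model/params/control objects of a configuration
#'
#' @param config an `ffs_config`
#' @return list with `model`, `params`, `control`, `seed`
#' @export
config_objects <- function(config) {
  stopifnot(inherits(config, "ffs_config"))
  sw <- switching_params(config$switching$d0, config$switching$r0,
                         config$switching$n_exp, config$switching$m_exp)
  model <- chain_model(config$model$name, config$model$n_beads,
                       config$model$eps_pw, config$model$sigma_pw,
                       config$model$m, switching = sw)
  params <- do.call(langevin_params,
                    c(config$langevin, list(seed = config$seed)))
  control <- ffs_control(
    n_runs = config$ffs$n_runs, n_pilot = config$ffs$n_pilot,
    n_trials = config$ffs$n_trials, lambda_B = config$ffs$lambda_B,
    target_p = config$ffs$target_p, trate0 = config$ffs$trate0,
    max_doublings = config$ffs$max_doublings,
    max_trial_time = config$ffs$max_trial_time,
    selection = config$ffs$selection)
  list(model = model, params = params, control = control,
       seed = config$seed)
}

#' Write a JSON run manifest for an FFS result
#'
#' Captures everything needed to audit or resume the run: interfaces,
#' per-level probabilities and uncertainties, seeds, and the genealogy in
#' columnar form (level, snapshot id, parent id, trials, successes).
#'
#' @param result an `ffs_result`
#' @param file output path
#' @export
write_manifest <- function(result, file) {
  stopifnot(inherits(result, "ffs_result"))
  stats <- ffs_level_stats(result)
  ci <- rate_confidence_interval(result, stats)
  gen <- do.call(rbind, lapply(seq_along(result$genealogy), function(li) {
    g <- result$genealogy[[li]]
    if (length(g$parent) == 0) return(NULL)
    data.frame(level = li - 1L, id = seq_along(g$parent),
               parent = g$parent,
               trials = if (is.null(g$trials)) NA_integer_ else g$trials,
               successes = if (is.null(g$successes)) NA_integer_ else
                 g$successes)
  }))
  jsonlite::write_json(
    list(system = result$system, seed = result$seed,
         lambda_A = result$lambda_A, lambda_0 = result$lambda_0,
         levels = result$levels, p_hats = result$p_hats,
         base_rate = result$base_rate, rate = result$rate,
         tdes = result$tdes, ci = ci$ci,
         ci_conservative = ci$ci_conservative, level_stats = stats,
         n_timeout = result$n_timeout, trate = result$trate,
         genealogy = gen),
    file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
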