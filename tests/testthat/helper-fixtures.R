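# shared fixtures and independent oracles

# independent R implementation of the rational switching function (the
# oracle; the package's own path lives in the C++ core)
ref_switch <- function(z, d0 = 0.35, r0 = 0.7, n = 6, m = 14) {
  vapply(z, function(zz) {
    if (zz <= d0) return(1)
    x <- (zz - d0) / r0
    if (abs(x - 1) < 1e-12) return(n / m)
    (1 - x^n) / (1 - x^m)
  }, numeric(1))
}

# central-difference gradient of the total potential
fd_forces <- function(state, model, h = 1e-6, wall = TRUE) {
  pos <- state$positions
  g <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) {
    for (d in 1:3) {
      p1 <- pos; p1[i, d] <- p1[i, d] + h
      p2 <- pos; p2[i, d] <- p2[i, d] - h
      e1 <- chain_energy_forces(system_state(p1), model, wall)$energy
      e2 <- chain_energy_forces(system_state(p2), model, wall)$energy
      g[i, d] <- -(e1 - e2) / (2 * h)
    }
  }
  g
}

# hand-built genealogy: `parents` is a list of integer vectors, one per
# level >= 1; trials/successes can be attached per level
make_genealogy <- function(parents, trials = NULL, successes = NULL,
                           n0 = max(parents[[1]])) {
  gen <- list(list(parent = rep(NA_integer_, n0), run = seq_len(n0),
                   states = vector("list", n0), trials = NULL,
                   successes = NULL))
  for (k in seq_along(parents)) {
    gen[[k]]$trials <- if (is.null(trials)) rep(5L, length(gen[[k]]$parent))
      else trials[[k]]
    gen[[k]]$successes <- if (is.null(successes)) NULL else successes[[k]]
    gen[[k + 1]] <- list(parent = parents[[k]], run = NULL,
                         states = vector("list", length(parents[[k]])),
                         trials = NULL, successes = NULL)
  }
  gen
}

# mock propagator whose trials return scripted outcomes; used to test the
# engine logic (allocation, percentile placement, genealogy) in isolation
mock_propagator <- function(minima_script, success_script = NULL) {
  counter <- new.env()
  counter$i <- 0
  structure(list(
    dt = 1,
    describe = "mock",
    run_to = function(state, lo, hi, max_steps, seed, stream) {
      counter$i <- counter$i + 1
      mc <- minima_script[[((counter$i - 1) %% length(minima_script)) + 1]]
      stopped <- if (!is.null(success_script)) {
        if (success_script[[((counter$i - 1) %% length(success_script)) + 1]])
          "lo" else "hi"
      } else if (mc < lo) "lo" else "hi"
      list(state = state, stop = stopped, min_c = mc, steps = 1, time = 1,
           contact = mc)
    },
    run_stats = function(state, n_steps, seed, stream, c_lo) {
      list(c_mean = state$c_mean, c_min = state$c_min)
    },
    crossings = function(...) stop("not scripted"),
    contact = function(state) state$c_mean
  ), class = "ffs_propagator")
}

fjc25 <- function(eps = 0.2) chain_model("FJC", N = 25, eps_pw = eps)

# cached small double-well FFS run shared across test files
cached_dw_ffs <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      ctrl <- ffs_control(n_runs = 30, n_pilot = 50, n_trials = 300,
                          trate0 = 500, lambda_B = -0.8)
      val <<- double_well_rate(4, langevin_params(), method = "ffs",
                               control = ctrl, seed = 1234)
    }
    val
  }
})
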