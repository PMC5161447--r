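#' Random antisymmetric coupling matrix
#'
#' `M = scale * (A - t(A)) / 2` for Gaussian `A`: exactly antisymmetric, so
#' all eigenvalues are purely imaginary and the generated flow is a rotation
#' — every oscillatory mode is equally excitable ("critical tuning"). When
#' `omega_max` is given, `M` is rescaled so its largest eigenfrequency is
#' `omega_max` rad/ms.
#'
#' @param N State dimension (>= 2).
#' @param scale Entry scale before normalization.
#' @param omega_max Optional spectral radius target (rad/ms).
#' @param seed Optional seed.
#' @return N x N antisymmetric matrix.
#' @export
make_antisymmetric_matrix <- function(N, scale = 1, omega_max = NULL,
                                      seed = NULL) {
  if (N < 2) stop("N must be >= 2")
  draw <- function() matrix(stats::rnorm(N * N), N, N)
  A <- if (is.null(seed)) draw() else with_seed(seed, draw())
  M <- scale * (A - t(A)) / 2
  if (!is.null(omega_max)) {
    w <- max(abs(Im(eigen(M, only.values = TRUE)$values)))
    M <- M * (omega_max / w)
  }
  M
}

#' Configuration for the reverberant linear network
#'
#' The model is `dv/dt = alpha*M*v - gamma*v + b*u(t) + noise`, with `M`
#' antisymmetric (purely rotational recurrence), `gamma` a uniform leak,
#' `u(t)` the click impulse train coupled through `b`, and additive white
#' noise. Time is in ms throughout.
#'
#' @param N State dimension.
#' @param alpha Recurrent gain (1/ms).
#' @param gamma Leak rate (1/ms); default gives an effective memory of
#'   ~80 ms.
#' @param noise_scale Noise amplitude (state units per sqrt(ms)).
#' @param M Antisymmetric coupling matrix; default drawn with eigenfrequency
#'   spread up to `omega_max`.
#' @param omega_max Spectral radius of `alpha*M` (rad/ms) for the default
#'   matrix.
#' @param input_coupling Input direction `b`; default a random unit vector.
#' @param input_gain Impulse amplitude per click.
#' @param dt Integration step (ms).
#' @param duration Simulation length (ms).
#' @param threshold Tick threshold on state amplitude.
#' @param v0 Initial state (default zero).
#' @param seed Seed used for defaults and the noise stream.
#' @return An `lds_config`.
#' @export
lds_config <- function(N = 50, alpha = 1, gamma = 1 / 80, noise_scale = 0.005,
                       M = NULL, omega_max = 0.6, input_coupling = NULL,
                       input_gain = 1, dt = 0.1, duration = 3000,
                       threshold = 0.05, v0 = NULL, seed = 1) {
  if (is.null(M))
    M <- make_antisymmetric_matrix(
      N, omega_max = if (alpha > 0) omega_max / alpha else NULL,
      seed = seed)
  N <- nrow(M)
  if (max(abs(M + t(M))) > 1e-12)
    stop("M must be antisymmetric (M + t(M) = 0)")
  if (dt <= 0) stop("dt must be > 0")
  if (alpha < 0 || gamma < 0) stop("alpha and gamma must be >= 0")
  if (is.null(input_coupling)) {
    input_coupling <- with_seed(seed + 1, stats::rnorm(N))
    input_coupling <- input_coupling / sqrt(sum(input_coupling^2))
  }
  if (is.null(v0)) v0 <- numeric(N)
  structure(list(N = N, alpha = alpha, gamma = gamma,
                 noise_scale = noise_scale, M = M,
                 input_coupling = input_coupling, input_gain = input_gain,
                 dt = dt, duration = duration, threshold = threshold,
                 v0 = v0, seed = seed),
            class = "lds_config")
}

#' Simulate the reverberant linear network
#'
#' Default integrator applies the exact matrix-exponential propagator of the
#' linear part at each step (the rotation generated by an antisymmetric `M`
#' is then norm-preserving to machine precision, and the pure leak matches
#' `exp(-gamma*t)` exactly), adding click impulses and noise per step. An
#' explicit Euler-Maruyama scheme is available via `method = "euler"` (a
#' warning is raised when `dt * (alpha*||M|| + gamma) > 0.1`).
#'
#' @param config An `lds_config`.
#' @param click_times Click onset times (ms) driving the input, or a
#'   `click_sequence`.
#' @param seed Noise seed (defaults to `config$seed`).
#' @param method `"exact"` (matrix-exponential propagator) or `"euler"`.
#' @return An `lds_trajectory`: list with `v` (steps x N), `time` (ms).
#' @export
simulate_lds <- function(config, click_times = numeric(0),
                         seed = config$seed, method = c("exact", "euler")) {
  stopifnot(inherits(config, "lds_config"))
  method <- match.arg(method)
  if (inherits(click_times, "click_sequence"))
    click_times <- click_times$click_times
  N <- config$N
  dt <- config$dt
  n_steps <- round(config$duration / dt)
  G <- config$alpha * config$M - config$gamma * diag(N)
  if (method == "exact") {
    P <- expm_real(G * dt)
  } else {
    nrmM <- max(abs(eigen(config$M, only.values = TRUE)$values))
    if (dt * (config$alpha * nrmM + config$gamma) > 0.1)
      warning("dt too large for stable explicit Euler integration")
    P <- diag(N) + G * dt
  }
  kick <- numeric(n_steps)
  idx <- round(click_times / dt) + 1L
  idx <- idx[idx >= 1 & idx <= n_steps]
  kick[idx] <- 1

  v <- matrix(0, n_steps + 1, N)
  v[1, ] <- config$v0
  b <- config$input_coupling * config$input_gain
  run <- function() {
    noisy <- config$noise_scale > 0
    for (t in seq_len(n_steps)) {
      x <- P %*% v[t, ]
      if (kick[t]) x <- x + b
      if (noisy) x <- x + config$noise_scale * sqrt(dt) * stats::rnorm(N)
      v[t + 1, ] <- x
    }
    v
  }
  v <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(v = v, time = seq(0, by = dt, length.out = n_steps + 1),
                 config = config),
            class = "lds_trajectory")
}

# Real matrix exponential via complex eigendecomposition (G is normal here:
# antisymmetric minus a scalar multiple of the identity).
expm_real <- function(G) {
  e <- eigen(G)
  Re(e$vectors %*% diag(exp(e$values), nrow = length(e$values)) %*%
       solve(e$vectors))
}

#' Threshold-crossing tick raster of a network trajectory
#'
#' One tick per upward crossing of the threshold, per state dimension —
#' the model analogue of a spike raster.
#'
#' @param trajectory An `lds_trajectory`.
#' @param threshold Amplitude threshold (defaults to the config's).
#' @return List of crossing-time vectors (ms), one per dimension.
#' @export
tick_raster <- function(trajectory, threshold = NULL) {
  stopifnot(inherits(trajectory, "lds_trajectory"))
  if (is.null(threshold)) threshold <- trajectory$config$threshold
  if (!is.finite(threshold)) stop("threshold must be finite")
  v <- trajectory$v
  tm <- trajectory$time
  lapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    up <- which(x[-length(x)] < threshold & x[-1] >= threshold)
    tm[up + 1]
  })
}

#' Sequence discriminability of the reverberant model
#'
#' Simulates `n_trials` noise realizations of the network per sequence,
#' converts each run's tick raster into spike trains of `N` synthetic
#' "units", and feeds them through the population-trajectory ROC analysis.
#'
#' @param config An `lds_config`.
#' @param sequences Named list of >= 2 `click_sequence`s.
#' @param n_trials Noise realizations per sequence.
#' @param seed Master seed for the noise streams.
#' @param ... Passed to [discriminability_experiment()].
#' @return List: `roc`, `dataset` (the tick-raster `spike_dataset`).
#' @export
model_discriminability <- function(config, sequences, n_trials = 10,
                                   seed = 1, ...) {
  if (length(sequences) < 2) stop("need at least two sequences")
  if (is.null(names(sequences)))
    names(sequences) <- vapply(sequences, function(s) s$seq_id, character(1))
  rows <- list()
  k <- 0
  for (sid in names(sequences)) {
    for (trial in seq_len(n_trials)) {
      k <- k + 1
      tr <- simulate_lds(config, sequences[[sid]],
                         seed = child_seed(seed, k))
      ticks <- tick_raster(tr)
      for (j in seq_along(ticks)) {
        if (length(ticks[[j]]))
          rows[[length(rows) + 1L]] <- data.frame(
            unit_id = sprintf("dim%03d", j), trial = trial,
            stimulus_id = sid, time_ms = ticks[[j]],
            stringsAsFactors = FALSE)
      }
    }
  }
  spikes <- do.call(rbind, rows)
  units <- data.frame(unit_id = sprintf("dim%03d", seq_len(config$N)),
                      area_truth = "model", stringsAsFactors = FALSE)
  dataset <- structure(list(spikes = spikes, units = units,
                            stimuli = sequences, n_trials = n_trials,
                            seed = seed),
                       class = "spike_dataset")
  exp <- discriminability_experiment(dataset, "model", n_units = config$N,
                                     ...)
  list(roc = exp$roc, dataset = dataset)
}
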