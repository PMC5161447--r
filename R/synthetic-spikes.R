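#' Parameters for a click-locked primary-like unit
#'
#' Primary (thalamorecipient) units respond to every click with a short,
#' precisely timed spike whose statistics do not depend on the preceding
#' interval: the response carries the stimulus timing but no sequence context.
#'
#' @param latency_mean Mean response latency after a click (ms).
#' @param latency_jitter_sd SD of the latency jitter (ms).
#' @param p_respond Probability of a spike per click.
#' @param baseline_rate Homogeneous background rate (Hz).
#' @param refractory Absolute refractory period (ms); the later spike of any
#'   closer pair is deleted.
#' @return A `primary_unit_params` object.
#' @export
primary_unit_params <- function(latency_mean = 10, latency_jitter_sd = 1,
                                p_respond = 0.9, baseline_rate = 1,
                                refractory = 1) {
  stopifnot(latency_mean > 0, latency_jitter_sd >= 0,
            p_respond >= 0, p_respond <= 1, baseline_rate >= 0)
  structure(list(latency_mean = latency_mean,
                 latency_jitter_sd = latency_jitter_sd,
                 p_respond = p_respond, baseline_rate = baseline_rate,
                 refractory = refractory),
            class = "primary_unit_params")
}

#' Parameters for an interval-context-tuned secondary-like unit
#'
#' Secondary units respond sparsely and selectively: the probability of a
#' spike after a click depends on the class of the interval preceding it
#' (optionally on the ordered pair of the two preceding classes). Context is
#' read through a fixed absolute-time memory window: when the preceding
#' interval is longer than `context_window` ms the context is lost and the
#' unit falls back to its mean tuning weight, which keeps spike rates similar
#' while destroying selectivity — the mechanism by which twofold time
#' dilation degrades the population code.
#'
#' @param interval_tuning Named numeric vector of weights in [0, 1], names =
#'   base (undilated) interval values in ms.
#' @param pair_tuning Optional named weights for ordered pairs of preceding
#'   interval classes, names like `"14>40"` (earlier>later); when a pair key
#'   is present it overrides the single-interval weight.
#' @param latency_mean,latency_jitter_sd Response latency distribution (ms).
#' @param gain Multiplier on the tuning weight to give spike probability.
#' @param baseline_rate Background rate (Hz).
#' @param context_window Absolute memory span (ms) beyond which the
#'   preceding-interval context is unavailable.
#' @param spike_width_class `"narrow"` or `"broad"` (extracellular waveform
#'   peak-to-peak class).
#' @param n_spikes Spikes emitted per effective response (a small burst).
#' @param burst_spread_ms Span over which burst spikes after the first are
#'   jittered (ms).
#' @param refractory Refractory period (ms).
#' @return A `secondary_unit_params` object.
#' @export
secondary_unit_params <- function(interval_tuning,
                                  pair_tuning = NULL,
                                  latency_mean = 15, latency_jitter_sd = 3,
                                  gain = 1, baseline_rate = 0.5,
                                  context_window = 40,
                                  spike_width_class = c("narrow", "broad"),
                                  n_spikes = 3, burst_spread_ms = 12,
                                  refractory = 1) {
  stopifnot(is.numeric(interval_tuning), length(interval_tuning) >= 1,
            !is.null(names(interval_tuning)))
  if (any(interval_tuning < 0)) stop("tuning weights must be >= 0")
  if (all(interval_tuning == 0)) stop("at least one tuning weight must be > 0")
  structure(list(interval_tuning = interval_tuning,
                 pair_tuning = pair_tuning,
                 latency_mean = latency_mean,
                 latency_jitter_sd = latency_jitter_sd,
                 gain = gain, baseline_rate = baseline_rate,
                 context_window = context_window,
                 spike_width_class = match.arg(spike_width_class),
                 n_spikes = n_spikes, burst_spread_ms = burst_spread_ms,
                 refractory = refractory),
            class = "secondary_unit_params")
}

enforce_refractory <- function(times, refractory) {
  times <- sort(times)
  if (length(times) < 2) return(times)
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

baseline_spikes <- function(rate_hz, duration_ms) {
  if (rate_hz <= 0) return(numeric(0))
  n <- stats::rpois(1, rate_hz * duration_ms / 1000)
  sort(stats::runif(n, 0, duration_ms))
}

# Spike probability per click for a secondary unit (vector over clicks).
secondary_click_probs <- function(seq, params) {
  ct <- seq$click_times
  n <- length(ct)
  dil <- seq$intervals$dilation
  w_mean <- mean(params$interval_tuning)
  probs <- numeric(n)
  base_class <- function(iv_ms) {
    b <- iv_ms / dil
    nm <- names(params$interval_tuning)
    hit <- which(abs(as.numeric(nm) - b) < 1e-6)
    if (length(hit)) nm[hit[1]] else NA_character_
  }
  for (i in seq_len(n)) {
    if (i == 1) { probs[i] <- w_mean; next }           # no context yet
    prev <- ct[i] - ct[i - 1]
    if (prev > params$context_window) { probs[i] <- w_mean; next }
    cls <- base_class(prev)
    w <- if (is.na(cls)) {
      warning("interval ", signif(prev, 4),
              " ms has no tuning class; weight 0", call. = FALSE)
      0
    } else params$interval_tuning[[cls]]
    if (!is.null(params$pair_tuning) && i >= 3) {
      prev2 <- ct[i - 1] - ct[i - 2]
      if (prev2 <= 2 * params$context_window) {
        key <- paste0(base_class(prev2), ">", cls)
        if (key %in% names(params$pair_tuning))
          w <- params$pair_tuning[[key]]
      }
    }
    probs[i] <- w
  }
  pmin(1, pmax(0, params$gain * probs))
}

#' Simulate spike trains for one unit
#'
#' Draws `n_trials` spike trains in response to one click sequence. For each
#' click a spike is emitted with the unit's click-response probability at
#' `click_time + latency + N(0, jitter^2)`; homogeneous-Poisson baseline
#' spikes are superimposed and the refractory period enforced by deleting the
#' later spike of any violating pair.
#'
#' @param seq A `click_sequence`.
#' @param params A `primary_unit_params` or `secondary_unit_params`.
#' @param n_trials Number of trials.
#' @param seed Optional seed (restores the caller's RNG state).
#' @return List of length `n_trials`; each element a sorted numeric vector of
#'   spike times (ms).
#' @export
simulate_unit <- function(seq, params, n_trials, seed = NULL) {
  stopifnot(inherits(seq, "click_sequence"))
  probs <- if (inherits(params, "primary_unit_params")) {
    rep(params$p_respond, length(seq$click_times))
  } else if (inherits(params, "secondary_unit_params")) {
    secondary_click_probs(seq, params)
  } else stop("unknown unit parameter class")

  n_spikes <- params$n_spikes %||% 1
  run <- function() {
    lapply(seq_len(n_trials), function(trial) {
      hit <- stats::runif(length(probs)) < probs
      t_first <- seq$click_times[hit] + params$latency_mean +
        stats::rnorm(sum(hit), 0, params$latency_jitter_sd)
      t_click <- t_first
      if (n_spikes > 1 && length(t_first))
        for (j in seq_len(n_spikes - 1))
          t_click <- c(t_click, t_first +
                         stats::runif(length(t_first), 1,
                                      params$burst_spread_ms))
      t_base <- baseline_spikes(params$baseline_rate, seq$total_duration)
      times <- c(t_click, t_base)
      times <- times[times >= 0]
      enforce_refractory(times, params$refractory)
    })
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Default synthetic recording ensemble
#'
#' Ground-truth-labeled ensemble emulating the study conditions: `n_primary`
#' click-locked units plus `n_secondary` context-tuned units. Each secondary
#' unit carries a sparse, reliable tuning surface over the ten interval
#' classes and (when `context_depth = 2`) over all ordered pairs of
#' preceding interval classes: a random `p_active` fraction of contexts
#' drive the unit strongly (weight near 1) and the rest barely (weight near
#' 0), drawn independently per unit, so the population response after a
#' click is a co-activation pattern specific to the local interval bigram —
#' the structure that makes population vectors sequence-selective. Context
#' is read through a fixed ~40-ms absolute memory (see
#' [secondary_unit_params()]). Half the secondary units are narrow-spiking,
#' half broad.
#'
#' @param n_primary,n_secondary Unit counts (canonical 10 + 10).
#' @param seed Seed for the tuning draw.
#' @param context_depth 1 (preceding interval only) or 2 (ordered pairs).
#' @param tuning_contrast Contrast of the tuning surface in [0, 1]: driving
#'   contexts get weight `0.5 + 0.45 * tuning_contrast`, the rest
#'   `0.5 - 0.47 * tuning_contrast`; 0 gives uniform (untuned) weights, 1
#'   the full 0.95 / 0.03 spread.
#' @param p_active Fraction of contexts that drive a secondary unit.
#' @param intervals Base interval values defining the tuning classes.
#' @param context_window Secondary context memory (ms).
#' @return A `synthetic_ensemble`: list with `units` (data.frame: `unit_id`,
#'   `area_truth`, `spike_width_class`) and `params` (named list).
#' @export
make_ensemble <- function(n_primary = 10, n_secondary = 10, seed = 1,
                          context_depth = 2, tuning_contrast = 1,
                          p_active = 0.4,
                          intervals = canonical_intervals(),
                          context_window = 40) {
  stopifnot(tuning_contrast >= 0, tuning_contrast <= 1,
            context_depth %in% 1:2)
  params <- list()
  units <- data.frame(unit_id = character(0), area_truth = character(0),
                      spike_width_class = character(0),
                      stringsAsFactors = FALSE)
  grade <- function(n) ifelse(stats::runif(n) < p_active,
                              0.5 + 0.45 * tuning_contrast,
                              0.5 - 0.47 * tuning_contrast)
  cls <- as.character(intervals)
  with_seed(seed, {
    for (i in seq_len(n_primary)) {
      id <- sprintf("P%02d", i)
      params[[id]] <- primary_unit_params(
        latency_mean = stats::runif(1, 8, 12),
        latency_jitter_sd = 1, p_respond = 0.9, baseline_rate = 1)
      units[nrow(units) + 1L, ] <- list(id, "primary", "narrow")
    }
    for (i in seq_len(n_secondary)) {
      id <- sprintf("S%02d", i)
      w <- stats::setNames(grade(length(cls)), cls)
      pt <- NULL
      if (context_depth == 2) {
        keys <- as.vector(outer(cls, cls, function(a, b) paste0(a, ">", b)))
        pt <- stats::setNames(grade(length(keys)), keys)
      }
      params[[id]] <- secondary_unit_params(
        interval_tuning = w, pair_tuning = pt,
        latency_mean = stats::runif(1, 12, 20), latency_jitter_sd = 3,
        gain = 1, baseline_rate = 3, context_window = context_window,
        spike_width_class = if (i %% 2 == 0) "broad" else "narrow")
      units[nrow(units) + 1L, ] <- list(id, "secondary",
                                        params[[id]]$spike_width_class)
    }
  })
  if (anyDuplicated(units$unit_id)) stop("duplicate unit ids")
  structure(list(units = units, params = params, seed = seed),
            class = "synthetic_ensemble")
}

#' Simulate a full spike dataset over stimuli
#'
#' Applies every unit generator of an ensemble to every stimulus for
#' `n_trials` trials, with per-(unit, stimulus) child seeds so the dataset is
#' reproducible as a whole.
#'
#' @param stimuli Named list of `click_sequence` objects (names become
#'   stimulus ids; unnamed lists use each sequence's `seq_id`).
#' @param ensemble A `synthetic_ensemble`.
#' @param n_trials Trials per unit per stimulus.
#' @param seed Master seed.
#' @return A `spike_dataset`: list with `spikes` (data.frame: `unit_id`,
#'   `trial`, `stimulus_id`, `time_ms`), `units`, `stimuli`, `n_trials`.
#' @export
simulate_ensemble <- function(stimuli, ensemble, n_trials = 20, seed = 1) {
  stopifnot(inherits(ensemble, "synthetic_ensemble"))
  if (!is.list(stimuli) || inherits(stimuli, "click_sequence"))
    stimuli <- list(stimuli)
  if (is.null(names(stimuli)) || any(names(stimuli) == ""))
    names(stimuli) <- vapply(stimuli, function(s) s$seq_id, character(1))
  if (anyDuplicated(names(stimuli))) stop("duplicate stimulus ids")
  rows <- list()
  k <- 0
  for (uid in ensemble$units$unit_id) {
    for (sid in names(stimuli)) {
      k <- k + 1
      trains <- simulate_unit(stimuli[[sid]], ensemble$params[[uid]],
                              n_trials, seed = child_seed(seed, k))
      for (trial in seq_len(n_trials)) {
        tt <- trains[[trial]]
        if (length(tt))
          rows[[length(rows) + 1L]] <- data.frame(
            unit_id = uid, trial = trial, stimulus_id = sid, time_ms = tt,
            stringsAsFactors = FALSE)
      }
    }
  }
  spikes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit_id = character(0), trial = integer(0),
               stimulus_id = character(0), time_ms = numeric(0))
  rownames(spikes) <- NULL
  structure(list(spikes = spikes, units = ensemble$units,
                 stimuli = stimuli, n_trials = n_trials, seed = seed),
            class = "spike_dataset")
}

#' Extract per-trial spike trains for one unit and stimulus
#' @param dataset A `spike_dataset`.
#' @param unit_id,stimulus_id Selectors.
#' @param trials Trial indices to keep (default all).
#' @return List of spike-time vectors, one per requested trial (empty trials
#'   give `numeric(0)`).
#' @export
get_trains <- function(dataset, unit_id, stimulus_id,
                       trials = seq_len(dataset$n_trials)) {
  sp <- dataset$spikes
  sel <- sp$unit_id == unit_id & sp$stimulus_id == stimulus_id
  lapply(trials, function(tr) sort(sp$time_ms[sel & sp$trial == tr]))
}
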