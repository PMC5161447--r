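#' Construct a biphasic extracellular spike template
#'
#' Difference-of-Gaussians waveform with a dominant negative lobe followed by
#' a positive lobe, the canonical extracellular spike shape. The peak-to-peak
#' width (negative peak to subsequent positive peak) equals `p2p_us` by
#' construction.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param p2p_us Peak-to-peak width in microseconds.
#' @param amp Amplitude of the negative lobe (trace units).
#' @param dur_ms Total template duration in ms.
#' @return Numeric waveform vector; attribute `neg_peak` holds the index of
#'   the negative peak.
#' @export
spike_template <- function(sampling_rate = 25000, p2p_us = 400, amp = 1,
                           dur_ms = 2.4) {
  n <- round(dur_ms / 1000 * sampling_rate)
  t_us <- (seq_len(n) - 1) / sampling_rate * 1e6
  t0 <- 0.35 * dur_ms * 1000               # negative peak position (us)
  s_neg <- p2p_us / 3
  s_pos <- p2p_us / 2
  build <- function(offset) {
    -amp * exp(-(t_us - t0)^2 / (2 * s_neg^2)) +
      0.45 * amp * exp(-(t_us - t0 - offset)^2 / (2 * s_pos^2))
  }
  # lobe overlap pushes the extrema apart; one correction step brings the
  # realized peak-to-peak width back to the nominal value
  w <- build(p2p_us)
  realized <- (which.max(w[which.min(w):n]) - 1) / sampling_rate * 1e6
  w <- build(max(p2p_us / 2, 2 * p2p_us - realized))
  structure(w, neg_peak = which.min(w))
}

#' Simulate a raw extracellular voltage trace with ground truth
#'
#' Linear superposition of per-unit spike templates at the given spike times
#' plus Gaussian white noise. The template's negative peak is placed at each
#' spike time, matching the alignment convention of the sorter.
#'
#' @param spike_times Named list of spike-time vectors (ms), one per unit.
#' @param templates Named list of templates from [spike_template()], same
#'   names as `spike_times`.
#' @param duration_ms Trace duration (ms).
#' @param sampling_rate Sampling rate (Hz).
#' @param noise_sd Noise SD in trace units (> 0).
#' @param seed Optional seed.
#' @return A `voltage_trace`: list with `samples`, `sampling_rate`, and
#'   `truth` (data.frame `unit_id`, `time_ms`).
#' @export
simulate_trace <- function(spike_times, templates, duration_ms,
                           sampling_rate = 25000, noise_sd = 0.05,
                           seed = NULL) {
  stopifnot(is.list(spike_times), is.list(templates),
            setequal(names(spike_times), names(templates)))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n <- ceiling(duration_ms / 1000 * sampling_rate)
  make <- function() {
    x <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    for (uid in names(spike_times)) {
      tpl <- templates[[uid]]
      neg <- attr(tpl, "neg_peak")
      for (t in spike_times[[uid]]) {
        i0 <- round(t / 1000 * sampling_rate) + 1L - (neg - 1L)
        idx <- i0:(i0 + length(tpl) - 1L)
        ok <- idx >= 1L & idx <= n
        x[idx[ok]] <- x[idx[ok]] + tpl[ok]
      }
    }
    x
  }
  samples <- if (is.null(seed)) make() else with_seed(seed, make())
  truth <- do.call(rbind, lapply(names(spike_times), function(uid) {
    if (!length(spike_times[[uid]])) return(NULL)
    data.frame(unit_id = uid, time_ms = sort(spike_times[[uid]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth))
    truth <- data.frame(unit_id = character(0), time_ms = numeric(0))
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 noise_sd = noise_sd, truth = truth),
            class = "voltage_trace")
}
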