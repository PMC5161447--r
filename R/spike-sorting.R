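#' High-pass filter a raw voltage trace
#'
#' Third-order Butterworth high-pass at `cutoff` Hz, applied forward-backward
#' (zero phase) so that spike times are not biased by filter delay.
#'
#' @param samples Voltage samples (or a `voltage_trace`).
#' @param sampling_rate Sampling rate in Hz (> 1 kHz).
#' @param cutoff High-pass cutoff (Hz), canonical 500.
#' @return Filtered samples (numeric vector).
#' @export
highpass_filter <- function(samples, sampling_rate = NULL, cutoff = 500) {
  if (inherits(samples, "voltage_trace")) {
    sampling_rate <- samples$sampling_rate
    samples <- samples$samples
  }
  if (is.null(sampling_rate) || sampling_rate <= 1000)
    stop("sampling_rate must exceed 1 kHz")
  bf <- signal::butter(3, cutoff / (sampling_rate / 2), type = "high")
  as.numeric(signal::filtfilt(bf, samples))
}

# Robust noise SD of a (filtered) trace via the median absolute deviation.
robust_noise_sd <- function(x) stats::mad(x)

#' Detect threshold-crossing spikes and align snippets to the negative peak
#'
#' Events are detected where the trace crosses the positive- or negative-going
#' threshold (defaults: +/- 4 robust noise SDs). Each event window is
#' upsampled to `upsample_rate` by cubic-spline interpolation and realigned so
#' the negative peak sits at the window center; of any two events closer than
#' `refractory_ms`, the smaller-amplitude one is suppressed.
#'
#' @param samples Filtered voltage samples (or a `voltage_trace`, which is
#'   high-pass filtered first).
#' @param sampling_rate Sampling rate in Hz.
#' @param pos_threshold,neg_threshold Detection thresholds; `NULL` uses
#'   +/- `threshold_k` robust noise SDs.
#' @param threshold_k Threshold multiplier for the default thresholds.
#' @param window_ms Snippet window length (ms).
#' @param refractory_ms Event-suppression window (ms).
#' @param upsample_rate Interpolation rate (Hz), canonical 250 kHz.
#' @return List: `waveforms` (events x samples matrix at `upsample_rate`),
#'   `times_ms` (aligned negative-peak times), `sampling_rate`.
#' @export
detect_and_align <- function(samples, sampling_rate = NULL,
                             pos_threshold = NULL, neg_threshold = NULL,
                             threshold_k = 4, window_ms = 2,
                             refractory_ms = 1, upsample_rate = 250000) {
  if (inherits(samples, "voltage_trace")) {
    sampling_rate <- samples$sampling_rate
    samples <- highpass_filter(samples$samples, sampling_rate)
  }
  stopifnot(!is.null(sampling_rate))
  n <- length(samples)
  if (window_ms / 1000 * sampling_rate >= n)
    stop("snippet window longer than trace")
  sd0 <- robust_noise_sd(samples)
  if (is.null(pos_threshold)) pos_threshold <- threshold_k * sd0
  if (is.null(neg_threshold)) neg_threshold <- -threshold_k * sd0
  if (pos_threshold == 0 && neg_threshold == 0)
    stop("thresholds must be nonzero")

  exceed <- which(samples > pos_threshold | samples < neg_threshold)
  empty <- list(waveforms = matrix(numeric(0), 0, 0), times_ms = numeric(0),
                sampling_rate = upsample_rate)
  if (!length(exceed)) return(empty)

  # group contiguous exceedances into events; center = most negative sample
  refr_n <- max(1L, round(refractory_ms / 1000 * sampling_rate))
  gaps <- which(diff(exceed) > refr_n)
  starts <- c(1L, gaps + 1L)
  ends <- c(gaps, length(exceed))
  centers <- amps <- numeric(length(starts))
  for (i in seq_along(starts)) {
    run <- exceed[starts[i]:ends[i]]
    centers[i] <- run[which.min(samples[run])]
    amps[i] <- max(abs(samples[run]))
  }
  # refractory suppression: keep larger-amplitude event of close pairs
  ord <- order(-amps)
  keep <- rep(TRUE, length(centers))
  for (i in ord) {
    if (!keep[i]) next
    close <- which(keep & abs(centers - centers[i]) < refr_n &
                     seq_along(centers) != i)
    keep[close[amps[close] <= amps[i]]] <- FALSE
  }
  centers <- sort(centers[keep])

  half <- round(window_ms / 2 / 1000 * sampling_rate)
  margin <- max(2L, round(half / 2))
  up <- round(upsample_rate / sampling_rate)
  half_f <- half * up
  waves <- list()
  times <- numeric(0)
  for (ctr in centers) {
    lo <- ctr - half - margin
    hi <- ctr + half + margin
    if (lo < 1 || hi > n) next  # too close to trace edge
    seg <- samples[lo:hi]
    t_coarse <- lo:hi
    t_fine <- seq(lo, hi, by = 1 / up)
    fine <- stats::spline(t_coarse, seg, xout = t_fine)$y
    # negative peak near the window center
    ctr_f <- which.min(abs(t_fine - ctr))
    search <- max(1, ctr_f - margin * up):min(length(fine), ctr_f + margin * up)
    pk <- search[which.min(fine[search])]
    if (pk - half_f < 1 || pk + half_f > length(fine)) next
    waves[[length(waves) + 1L]] <- fine[(pk - half_f):(pk + half_f)]
    times <- c(times, (t_fine[pk] - 1) / sampling_rate * 1000)
  }
  if (!length(waves)) return(empty)
  list(waveforms = do.call(rbind, waves), times_ms = times,
       sampling_rate = upsample_rate)
}

# Single-level and multi-level Haar discrete wavelet transform.
haar_dwt <- function(x, levels = 4) {
  n2 <- 2^ceiling(log2(length(x)))
  if (n2 > length(x)) x <- c(x, rep(x[length(x)], n2 - length(x)))
  details <- numeric(0)
  a <- x
  for (l in seq_len(levels)) {
    odd <- a[seq(1, length(a), 2)]
    even <- a[seq(2, length(a), 2)]
    details <- c(details, (odd - even) / sqrt(2))
    a <- (odd + even) / sqrt(2)
    if (length(a) < 2) break
  }
  c(a, details)
}

#' Extract PCA + Haar-wavelet features from aligned snippets
#'
#' Features are the first `n_pc` principal-component scores concatenated with
#' a subset of Haar discrete-wavelet coefficients. Wavelet coefficients are
#' ranked by how strongly their across-snippet distribution deviates from
#' normality (Lilliefors statistic), the standard heuristic for picking
#' cluster-separating coefficients; ties and degenerate coefficients fall
#' back to a variance ranking.
#'
#' @param waveforms Events x samples matrix of aligned snippets.
#' @param n_pc Number of principal components (canonical 3).
#' @param wavelet_levels Haar decomposition depth.
#' @param n_wavelet Number of wavelet coefficients retained.
#' @return Numeric matrix, one row per snippet.
#' @export
extract_features <- function(waveforms, n_pc = 3, wavelet_levels = 4,
                             n_wavelet = 10) {
  if (is.list(waveforms) && !is.null(waveforms$waveforms))
    waveforms <- waveforms$waveforms
  if (nrow(waveforms) < 4) stop("need at least 4 snippets for features")
  if (nrow(waveforms) <= n_pc)
    stop("fewer snippets than requested principal components")
  pc <- stats::prcomp(waveforms, center = TRUE, scale. = FALSE)
  npc <- min(n_pc, ncol(pc$x))
  scores <- pc$x[, seq_len(npc), drop = FALSE]

  wc <- t(apply(waveforms, 1, haar_dwt, levels = wavelet_levels))
  sds <- apply(wc, 2, stats::sd)
  score_col <- function(j) {
    v <- wc[, j]
    if (sds[j] < 1e-12) return(-Inf)
    if (nrow(wc) >= 5) {
      st <- tryCatch(nortest::lillie.test(v)$statistic,
                     error = function(e) NA_real_)
      if (is.finite(st)) return(as.numeric(st))
    }
    stats::var(v)
  }
  rank_score <- vapply(seq_len(ncol(wc)), score_col, numeric(1))
  sel <- order(rank_score, decreasing = TRUE)[seq_len(min(n_wavelet, ncol(wc)))]
  out <- cbind(scores, wc[, sel, drop = FALSE])
  colnames(out) <- c(paste0("PC", seq_len(npc)),
                     paste0("W", seq_along(sel)))
  rownames(out) <- NULL
  out
}

#' Cluster spike features with an EM-fitted Gaussian mixture
#'
#' Fits Gaussian mixtures over `k_range` by EM and selects the number of
#' components by BIC.
#'
#' @param features Snippets x features matrix (finite values).
#' @param k_range Candidate component counts.
#' @param seed Seed for the (deterministic given data) fit.
#' @return List: `labels` (integer per snippet), `k` (selected components),
#'   `model` (the mclust fit).
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_em_gmm <- function(features, k_range = 1:5, seed = 1) {
  if (any(!is.finite(features))) stop("features must be finite")
  fit <- with_seed(seed, suppressWarnings(
    Mclust(features, G = k_range, verbose = FALSE)))
  if (is.null(fit)) stop("mixture fit failed for all k in range")
  list(labels = as.integer(fit$classification), k = fit$G, model = fit)
}

#' Peak-to-peak spike width
#'
#' Time from the negative peak of a mean waveform to the subsequent positive
#' peak, in microseconds; the 250-us boundary splits narrow- from
#' broad-spiking units.
#'
#' @param mean_waveform Mean spike waveform.
#' @param sampling_rate Waveform sampling rate (Hz).
#' @return Width in microseconds.
#' @export
spike_width <- function(mean_waveform, sampling_rate) {
  neg <- which.min(mean_waveform)
  if (neg >= length(mean_waveform))
    stop("no samples after the negative peak; width undefined")
  after <- mean_waveform[(neg + 1):length(mean_waveform)]
  pos <- which.max(after)
  if (after[pos] <= mean_waveform[neg] ||
      all(diff(mean_waveform) <= 0) || all(diff(mean_waveform) >= 0))
    stop("waveform lacks a positive peak after the negative peak")
  pos / sampling_rate * 1e6
}

#' Classify spike width as narrow or broad
#' @param width_us Peak-to-peak width (us).
#' @param boundary_us Class boundary (canonical 250 us).
#' @return `"narrow"` if below the boundary, else `"broad"`.
#' @export
classify_spike_width <- function(width_us, boundary_us = 250) {
  ifelse(width_us < boundary_us, "narrow", "broad")
}

refractory_violation_rate <- function(times_ms, refractory_ms = 1) {
  if (length(times_ms) < 2) return(0)
  mean(diff(sort(times_ms)) < refractory_ms)
}

#' Quality-control a list of sorted units
#'
#' @param units List of `sorted_unit` objects (from [sort_spikes()]).
#' @param snr_min Minimum SNR (peak-to-peak of mean waveform over twice the
#'   noise SD).
#' @param violation_max Maximum refractory-violation fraction.
#' @param refractory_ms Refractory period used for the violation rate.
#' @return List: `retained`, `excluded` (unit lists), `report` (data.frame).
#' @export
qc_units <- function(units, snr_min = 5, violation_max = 0.01,
                     refractory_ms = 1) {
  rows <- lapply(units, function(u) {
    viol <- refractory_violation_rate(u$spike_times_ms, refractory_ms)
    data.frame(unit_id = u$unit_id, n_spikes = length(u$spike_times_ms),
               snr = u$snr, refractory_violation_rate = viol,
               retained = u$snr >= snr_min && viol <= violation_max,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(retained = units[report$retained],
       excluded = units[!report$retained],
       report = report)
}

#' Sort spikes from a raw extracellular trace
#'
#' Full chain: high-pass filter, threshold detection with spline realignment,
#' PCA + wavelet features, EM Gaussian-mixture clustering, per-cluster unit
#' summaries and QC.
#'
#' @param trace A `voltage_trace` (or raw samples via `sampling_rate`).
#' @param sampling_rate Required if `trace` is a bare numeric vector.
#' @param k_range Mixture sizes to consider.
#' @param seed Seed for clustering.
#' @param snr_min,violation_max,refractory_ms QC thresholds.
#' @param ... Passed to [detect_and_align()].
#' @return List: `units` (retained `sorted_unit`s with `spike_times_ms`,
#'   `mean_waveform`, `snr`, `p2p_width_us`), `qc` report, `clustering`.
#' @export
sort_spikes <- function(trace, sampling_rate = NULL, k_range = 1:4, seed = 1,
                        snr_min = 4, violation_max = 0.02,
                        refractory_ms = 1, ...) {
  if (inherits(trace, "voltage_trace")) {
    sampling_rate <- trace$sampling_rate
    raw <- trace$samples
  } else raw <- trace
  stopifnot(!is.null(sampling_rate))
  filt <- highpass_filter(raw, sampling_rate)
  det <- detect_and_align(filt, sampling_rate, ...)
  if (!length(det$times_ms))
    return(list(units = list(), qc = NULL, clustering = NULL))
  feats <- extract_features(det)
  cl <- cluster_em_gmm(feats, k_range = k_range, seed = seed)
  noise_sd <- robust_noise_sd(filt)
  units <- lapply(sort(unique(cl$labels)), function(g) {
    sel <- cl$labels == g
    mw <- colMeans(det$waveforms[sel, , drop = FALSE])
    p2p <- diff(range(mw))
    w_us <- tryCatch(spike_width(mw, det$sampling_rate),
                     error = function(e) NA_real_)
    list(unit_id = sprintf("unit%02d", g),
         spike_times_ms = sort(det$times_ms[sel]),
         mean_waveform = mw, waveform_rate = det$sampling_rate,
         snr = p2p / (2 * noise_sd), p2p_width_us = w_us)
  })
  qc <- qc_units(units, snr_min = snr_min, violation_max = violation_max,
                 refractory_ms = refractory_ms)
  list(units = qc$retained, qc = qc$report, clustering = cl)
}

#' Match recovered spike times against ground truth
#'
#' Greedy one-to-one matching within `tol_ms`; reports recall and precision
#' of spike-time recovery.
#'
#' @param estimated Recovered spike times (ms).
#' @param truth Ground-truth spike times (ms).
#' @param tol_ms Matching tolerance (ms).
#' @return List: `recall`, `precision`, `n_matched`.
#' @export
spike_recovery <- function(estimated, truth, tol_ms = 0.5) {
  est <- sort(estimated)
  tru <- sort(truth)
  used <- rep(FALSE, length(est))
  matched <- 0L
  for (t in tru) {
    d <- abs(est - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol_ms) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  list(recall = if (length(tru)) matched / length(tru) else NA_real_,
       precision = if (length(est)) matched / length(est) else NA_real_,
       n_matched = matched)
}
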