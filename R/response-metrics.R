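#' Compute a peri-stimulus time histogram
#'
#' Trial-summed spike counts per half-open bin `[b*delta, (b+1)*delta)`.
#'
#' @param trains List of per-trial spike-time vectors (ms).
#' @param bin_size Bin width in ms (canonical 5).
#' @param duration Stimulus duration in ms.
#' @param rate If `TRUE`, normalize counts to Hz by `n_trials * bin`.
#' @return A `psth`: list with `values`, `bin_size`, `duration`, `n_trials`.
#' @export
compute_psth <- function(trains, bin_size = 5, duration, rate = FALSE) {
  if (is.numeric(trains)) trains <- list(trains)
  n_bins <- ceiling(duration / bin_size)
  counts <- numeric(n_bins)
  n_clipped <- 0L
  for (tt in trains) {
    out <- tt < 0 | tt >= duration
    n_clipped <- n_clipped + sum(out)
    idx <- floor(tt[!out] / bin_size) + 1L
    if (length(idx)) {
      tab <- tabulate(idx, nbins = n_bins)
      counts <- counts + tab
    }
  }
  if (n_clipped > 0)
    warning(n_clipped, " spikes beyond [0, duration) clipped")
  values <- if (rate) counts / (length(trains) * bin_size / 1000) else counts
  structure(list(values = values, bin_size = bin_size, duration = duration,
                 n_trials = length(trains), rate = rate),
            class = "psth")
}

psth_values <- function(x) if (inherits(x, "psth")) x$values else as.numeric(x)

# Kaiser-window FIR band-pass designed for 1-kHz signals: passband 5-110 Hz,
# 2233 taps, ~5% passband ripple / 40 dB stopband attenuation.
psth_fir <- local({
  cache <- NULL
  function(n_taps = 2233, passband = c(5, 110), fs = 1000) {
    if (is.null(cache)) {
      beta <- 3.3953  # Kaiser beta for 40 dB attenuation
      cache <<- signal::fir1(n_taps - 1, passband / (fs / 2), type = "pass",
                             window = signal::kaiser(n_taps, beta))
    }
    cache
  }
})

#' Band-pass smooth and min-max normalize a PSTH
#'
#' The PSTH (5-ms bins) is upsampled to 1 kHz by sample-and-hold, filtered
#' with a linear-phase Kaiser-window FIR band-pass (5-110 Hz, 2233 taps,
#' 40 dB stopband attenuation; the filter's group delay is removed so the
#' output is zero phase), then min-max normalized to [0, 1]. A constant
#' input cannot be normalized and returns all zeros flagged degenerate.
#'
#' @param psth A `psth` (or numeric vector of bin values).
#' @param bin_size Bin width of `psth` in ms (taken from a `psth` object).
#' @return Numeric vector at 1 kHz in [0, 1]; attribute `degenerate` is
#'   `TRUE` for constant input.
#' @export
smooth_and_normalize_psth <- function(psth, bin_size = 5) {
  if (inherits(psth, "psth")) {
    bin_size <- psth$bin_size
    psth <- psth$values
  }
  x <- rep(as.numeric(psth), each = round(bin_size))  # sample-and-hold, 1 kHz
  b <- psth_fir()
  gd <- (length(b) - 1) / 2
  y_full <- stats::convolve(x, rev(b), type = "open")
  y <- y_full[(gd + 1):(gd + length(x))]
  rng <- range(y)
  if (diff(rng) < 1e-12 || diff(range(psth)) < 1e-12)
    return(structure(numeric(length(x)), degenerate = TRUE))
  structure((y - rng[1]) / diff(rng), degenerate = FALSE)
}

#' Detect peaks of a normalized smoothed PSTH
#'
#' Local maxima are retained when they satisfy all of: peak value > 0.3;
#' peak minus neighboring valley > 0.01; and peak height above the higher of
#' its two neighboring valleys > 0.05. Valleys are the minima between
#' consecutive retained peaks; signal endpoints count as valleys. Peaks
#' failing the valley criteria are merged (the lower peak is dropped)
#' iteratively.
#'
#' @param y Normalized signal in [0, 1] (1-kHz samples from
#'   [smooth_and_normalize_psth()]).
#' @param dt_ms Sample spacing of `y` in ms.
#' @param min_value,min_distance,min_height The three criteria.
#' @return List: `indices` (sample indices), `times_ms`.
#' @export
detect_peaks <- function(y, dt_ms = 1, min_value = 0.3,
                         min_distance = 0.01, min_height = 0.05) {
  n <- length(y)
  if (n < 3) return(list(indices = integer(0), times_ms = numeric(0)))
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  cand <- cand[y[cand] > min_value]
  repeat {
    if (!length(cand)) break
    m <- length(cand)
    # valleys: min between consecutive peaks; endpoints count as valleys
    vall <- numeric(m + 1)
    bounds <- c(1L, cand, n)
    for (i in seq_len(m + 1))
      vall[i] <- min(y[bounds[i]:bounds[i + 1]])
    prom <- y[cand] - pmax(vall[seq_len(m)], vall[seq_len(m) + 1])
    bad <- which(prom <= min_height | prom <= min_distance)
    if (!length(bad)) break
    drop <- bad[which.min(y[cand[bad]])]  # merge: drop the lowest offender
    cand <- cand[-drop]
  }
  list(indices = cand, times_ms = (cand - 1) * dt_ms)
}

#' Intervals between neighboring PSTH peaks
#'
#' @param peak_times_ms Peak times (ms), e.g. from [detect_peaks()], or a
#'   list of such vectors (pooled).
#' @param breaks Histogram break points (ms).
#' @return List: `intervals` (all successive differences), `histogram`
#'   (counts per bin), `breaks`.
#' @export
interpeak_intervals <- function(peak_times_ms, breaks = seq(0, 200, by = 5)) {
  if (!is.list(peak_times_ms)) peak_times_ms <- list(peak_times_ms)
  ivals <- unlist(lapply(peak_times_ms, function(p)
    if (length(p) >= 2) diff(sort(p)) else numeric(0)))
  if (!length(ivals))
    return(list(intervals = numeric(0),
                histogram = integer(length(breaks) - 1), breaks = breaks))
  h <- graphics::hist(ivals[ivals >= min(breaks) & ivals <= max(breaks)],
                      breaks = breaks, plot = FALSE)
  list(intervals = ivals, histogram = h$counts, breaks = breaks)
}

#' Click-triggered latency histogram
#'
#' Histogram of spike latencies relative to the nearest preceding click,
#' origin at click onset.
#'
#' @param trains List of per-trial spike-time vectors (ms).
#' @param click_times Click onsets (ms).
#' @param window Latency window (ms).
#' @param bin Histogram bin (ms).
#' @return List: `latencies`, `histogram` (counts), `breaks`.
#' @export
click_triggered_latency <- function(trains, click_times, window = 20,
                                    bin = 1) {
  if (is.numeric(trains)) trains <- list(trains)
  if (window <= 0) stop("window must be > 0")
  lats <- unlist(lapply(trains, function(tt) {
    if (!length(tt)) return(numeric(0))
    prev <- vapply(tt, function(s) {
      before <- click_times[click_times <= s]
      if (length(before)) s - max(before) else NA_real_
    }, numeric(1))
    prev[!is.na(prev) & prev <= window]
  }))
  breaks <- seq(0, window, by = bin)
  if (!length(lats))
    return(list(latencies = numeric(0),
                histogram = integer(length(breaks) - 1), breaks = breaks))
  h <- graphics::hist(lats, breaks = breaks, plot = FALSE)
  list(latencies = lats, histogram = h$counts, breaks = breaks)
}

#' Mean firing rate
#' @param trains List of per-trial spike-time vectors (ms).
#' @param duration_ms Trial duration (ms).
#' @return Rate in Hz.
#' @export
mean_rate <- function(trains, duration_ms) {
  if (duration_ms <= 0) stop("duration must be > 0")
  if (is.numeric(trains)) trains <- list(trains)
  sum(lengths(trains)) / (length(trains) * duration_ms / 1000)
}

# Max correlation coefficient over lags; b is shifted back by `lag` samples
# relative to a (a leads). Zero-variance input gives 0.
max_lag_cor <- function(a, b, max_lag, two_sided = FALSE) {
  n <- min(length(a), length(b))
  a <- a[seq_len(n)]
  b <- b[seq_len(n)]
  lags <- if (two_sided) -max_lag:max_lag else 0:max_lag
  best <- 0
  for (k in lags) {
    if (k >= 0) {
      aa <- a[(1 + k):n]; bb <- b[1:(n - k)]
    } else {
      aa <- a[1:(n + k)]; bb <- b[(1 - k):n]
    }
    if (length(aa) < 3 || stats::sd(aa) == 0 || stats::sd(bb) == 0) next
    r <- stats::cor(aa, bb)
    if (is.finite(r) && r > best) best <- r
  }
  best
}

#' Similarity score between a unit PSTH and the click stimulus
#'
#' Maximum correlation coefficient, over non-negative response lags up to
#' `max_lag_ms`, between the unit's PSTH and the binarized click vector on
#' the same 5-ms bin grid. Zero-variance input scores 0 by convention.
#'
#' @param psth A `psth` or numeric vector of bin values.
#' @param click_vec Binary click-indicator vector (see [binarize()]).
#' @param bin_size Bin width in ms.
#' @param max_lag_ms Largest response lag considered (ms).
#' @return Score in [-1, 1] (negative correlations floor at 0).
#' @export
similarity_score <- function(psth, click_vec, bin_size = 5, max_lag_ms = 50) {
  v <- psth_values(psth)
  max_lag_cor(v, as.numeric(click_vec),
              max_lag = round(max_lag_ms / bin_size), two_sided = FALSE)
}

#' Classify a unit as primary or secondary from its similarity score
#'
#' Units scoring above 0.5 are primary (click-locked); at or below 0.5,
#' secondary.
#'
#' @param score Similarity score(s).
#' @param threshold Decision boundary (canonical 0.5).
#' @return Character vector `"primary"`/`"secondary"`.
#' @export
classify_area <- function(score, threshold = 0.5) {
  ifelse(score > threshold, "primary", "secondary")
}

#' Classify all units of a spike dataset
#'
#' Concatenates each unit's PSTHs across all stimuli (and the matching
#' binarized click vectors) before scoring, so the classification uses the
#' full recording session.
#'
#' @param dataset A `spike_dataset`.
#' @param bin_size PSTH bin (ms).
#' @param max_lag_ms Response-lag window for the score.
#' @return data.frame: `unit_id`, `score`, `area_label`.
#' @export
classify_units <- function(dataset, bin_size = 5, max_lag_ms = 50) {
  click_cat <- unlist(lapply(dataset$stimuli, binarize, bin_size = bin_size))
  rows <- lapply(dataset$units$unit_id, function(uid) {
    v <- unlist(lapply(names(dataset$stimuli), function(sid) {
      tr <- get_trains(dataset, uid, sid)
      suppressWarnings(compute_psth(
        tr, bin_size = bin_size,
        duration = dataset$stimuli[[sid]]$total_duration))$values
    }))
    s <- max_lag_cor(v, click_cat, max_lag = round(max_lag_ms / bin_size))
    data.frame(unit_id = uid, score = s, area_label = classify_area(s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise response-similarity matrix across units
#'
#' Max-lag correlation between the PSTHs of every unit pair (two-sided lags,
#' since neither unit leads by convention). The diagonal is 1 and the matrix
#' symmetric.
#'
#' @param psth_list Named list of `psth` objects or numeric vectors, one per
#'   unit (same bin grid).
#' @param bin_size Bin width (ms).
#' @param max_lag_ms Lag window (ms).
#' @return List: `matrix` (units x units), and `summary` helper closure-free
#'   data.frame when `groups` given.
#' @param groups Optional named character vector unit -> group label for a
#'   per-group summary of off-diagonal similarities.
#' @export
pairwise_response_similarity <- function(psth_list, bin_size = 5,
                                         max_lag_ms = 50, groups = NULL) {
  if (length(psth_list) < 2) stop("need at least 2 units")
  vals <- lapply(psth_list, psth_values)
  ids <- names(vals)
  if (is.null(ids)) ids <- paste0("u", seq_along(vals))
  m <- length(vals)
  L <- round(max_lag_ms / bin_size)
  sim <- diag(1, m)
  dimnames(sim) <- list(ids, ids)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    r <- max_lag_cor(vals[[i]], vals[[j]], max_lag = L, two_sided = TRUE)
    sim[i, j] <- sim[j, i] <- r
  }
  summary <- NULL
  if (!is.null(groups)) {
    gs <- unique(groups[ids])
    summary <- do.call(rbind, lapply(gs, function(g) {
      members <- ids[groups[ids] == g]
      if (length(members) < 2)
        return(data.frame(group = g, mean_similarity = NA_real_,
                          n_pairs = 0L))
      sub <- sim[members, members]
      off <- sub[upper.tri(sub)]
      data.frame(group = g, mean_similarity = mean(off),
                 n_pairs = length(off), stringsAsFactors = FALSE)
    }))
  }
  list(matrix = sim, summary = summary)
}
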