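test_that("high-pass filter removes DC and slow components, passes spikes", {
  fs <- 25000
  t <- seq(0, 1, by = 1 / fs)
  y_dc <- highpass_filter(rep(2, fs), fs)
  expect_lt(max(abs(y_dc[2000:23000])), 2e-6)
  slow <- sin(2 * pi * 10 * t)
  expect_lt(max(abs(highpass_filter(slow, fs)[2000:23000])), 10^(-40 / 20))
  fast <- sin(2 * pi * 5000 * t)
  y <- highpass_filter(fast, fs)
  expect_gt(max(abs(y[2000:23000])), 10^(-1 / 20))
  expect_error(highpass_filter(slow, 800), "1 kHz")
})

test_that("filtering is linear", {
  fs <- 25000
  set.seed(1)
  x <- rnorm(5000)
  expect_equal(highpass_filter(3 * x, fs), 3 * highpass_filter(x, fs),
               tolerance = 1e-10)
})

test_that("detection recovers noiseless template trains at sample accuracy", {
  fs <- 25000
  tpl <- spike_template(fs, p2p_us = 300, amp = 1)
  truth <- c(20, 55, 90, 132, 170)
  tr <- simulate_trace(list(u = truth), list(u = tpl), 200, fs,
                       noise_sd = 1e-4, seed = 1)
  det <- detect_and_align(tr$samples, fs, pos_threshold = 0.2,
                          neg_threshold = -0.2)
  expect_length(det$times_ms, length(truth))
  expect_lt(max(abs(sort(det$times_ms) - truth)), 1000 / fs)
  # aligned snippets have their negative peak at the window center
  ctr <- (ncol(det$waveforms) + 1) / 2
  for (i in seq_len(nrow(det$waveforms)))
    expect_equal(which.min(det$waveforms[i, ]), ctr)
})

test_that("detection returns nothing on silent traces, errors on bad window", {
  fs <- 25000
  det <- detect_and_align(numeric(5000), fs, pos_threshold = 0.1,
                          neg_threshold = -0.1)
  expect_length(det$times_ms, 0)
  expect_error(detect_and_align(numeric(10), fs), "window")
})

test_that("features align with snippets and separate template populations", {
  fs <- 25000
  tpl1 <- spike_template(fs, p2p_us = 200, amp = 1)
  tpl2 <- spike_template(fs, p2p_us = 550, amp = 0.8)
  set.seed(2)
  waves <- rbind(
    t(replicate(30, tpl1 + rnorm(length(tpl1), 0, 0.02))),
    t(replicate(30, tpl2 + rnorm(length(tpl2), 0, 0.02))))
  f <- extract_features(waves)
  expect_equal(nrow(f), 60)
  expect_equal(ncol(f), 13)  # 3 PCs + 10 wavelet coefficients
  lab <- rep(1:2, each = 30)
  centr <- rbind(colMeans(f[lab == 1, ]), colMeans(f[lab == 2, ]))
  between <- sqrt(sum((centr[1, ] - centr[2, ])^2))
  within <- quantile(c(
    sqrt(rowSums((f[lab == 1, ] - centr[rep(1, 30), ])^2)),
    sqrt(rowSums((f[lab == 2, ] - centr[rep(2, 30), ])^2))), 0.95)
  expect_gt(between, within)
  # identical snippets collapse to zero-variance PC scores
  same <- matrix(rep(tpl1, 6), nrow = 6, byrow = TRUE)
  fs_same <- extract_features(same)
  expect_equal(apply(fs_same[, 1:3], 2, sd), c(PC1 = 0, PC2 = 0, PC3 = 0))
  expect_error(extract_features(waves[1:2, ]), "4 snippets")
})

test_that("EM-GMM clustering separates blobs and is seed-stable", {
  set.seed(3)
  x <- rbind(matrix(rnorm(100, 0), ncol = 2),
             matrix(rnorm(100, 6), ncol = 2))
  cl <- cluster_em_gmm(x, k_range = 1:4, seed = 1)
  expect_equal(cl$k, 2)
  lab <- rep(1:2, each = 50)
  agree <- max(mean(cl$labels == lab), mean(cl$labels == 3 - lab))
  expect_gte(agree, 0.99)
  cl2 <- cluster_em_gmm(x, k_range = 1:4, seed = 1)
  expect_identical(cl$labels, cl2$labels)
  one <- matrix(rnorm(120), ncol = 2)
  expect_equal(cluster_em_gmm(one, k_range = 1:3, seed = 1)$k, 1)
})

test_that("spike width measures negative-to-positive peak separation", {
  fs <- 25000
  tpl <- spike_template(fs, p2p_us = 200)
  # templates are built on the coarse grid: width within one sample period
  expect_equal(spike_width(tpl, fs), 200, tolerance = 1000 / fs * 1000 / 200)
  fine <- stats::spline(seq_along(tpl), tpl, n = length(tpl) * 10)$y
  expect_lt(abs(spike_width(fine, fs * 10) - spike_width(tpl, fs)),
            1e6 / fs)
  expect_gt(spike_width(tpl, fs), 0)
  expect_error(spike_width(seq(1, 0, length.out = 50), fs), "peak")
  expect_equal(classify_spike_width(c(200, 300)), c("narrow", "broad"))
})

test_that("QC retains clean units and conserves counts", {
  mk <- function(id, times, snr) list(unit_id = id, spike_times_ms = times,
                                      snr = snr)
  units <- list(mk("a", c(10, 20, 30), 8),
                mk("b", c(10, 10.2, 30), 8),    # refractory violation
                mk("c", c(10, 25, 50), 2))      # low SNR
  qc <- qc_units(units, snr_min = 5, violation_max = 0.01)
  expect_equal(vapply(qc$retained, `[[`, character(1), "unit_id"), "a")
  expect_equal(length(qc$retained) + length(qc$excluded), 3)
  expect_equal(qc$report$refractory_violation_rate[1], 0)
})

test_that("full sorting chain recovers two units from a clean trace", {
  fs <- 25000
  st <- collision_free_trains(seed = 7)
  tpls <- list(u1 = spike_template(fs, p2p_us = 200, amp = 1),
               u2 = spike_template(fs, p2p_us = 500, amp = 0.9))
  tr <- simulate_trace(st, tpls, 2000, fs, noise_sd = 0.04, seed = 1)
  res <- sort_spikes(tr, k_range = 1:4, seed = 1)
  expect_equal(length(res$units), 2)
  for (u in res$units) {
    rec <- lapply(st, function(tt) spike_recovery(u$spike_times_ms, tt))
    best <- rec[[which.max(vapply(rec, `[[`, numeric(1), "recall"))]]
    expect_gte(best$recall, 0.95)
    expect_gte(best$precision, 0.95)
  }
  widths <- sort(vapply(res$units, `[[`, numeric(1), "p2p_width_us"))
  expect_equal(classify_spike_width(widths), c("narrow", "broad"))
})
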