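test_that("PSTH counts spikes into half-open bins and conserves totals", {
  p <- compute_psth(list(c(3, 7), 12), bin_size = 5, duration = 20)
  expect_equal(p$values, c(1, 1, 1, 0))
  expect_equal(compute_psth(list(numeric(0)), 5, 20)$values, rep(0, 4))
  set.seed(1)
  trains <- replicate(4, sort(runif(30, 0, 100)), simplify = FALSE)
  p2 <- compute_psth(trains, 5, 100)
  expect_equal(sum(p2$values), 120)
  expect_warning(compute_psth(list(c(5, 150)), 5, 100), "clipped")
})

test_that("PSTH band-pass filter has the designed frequency response", {
  b <- clickpop:::psth_fir()
  expect_length(b, 2233)
  H <- function(f) abs(sum(b * exp(-2i * pi * f * (seq_along(b) - 1) / 1000)))
  expect_equal(H(50), 1, tolerance = 0.06)     # passband (5% ripple)
  expect_lt(H(1), 10^(-35 / 20))               # stopband ~40 dB
  expect_lt(H(300), 10^(-35 / 20))
})

test_that("smoothed PSTH is normalized to [0, 1]; constant input flagged", {
  set.seed(2)
  p <- compute_psth(list(sort(runif(200, 0, 3000))), 5, 3000)
  y <- smooth_and_normalize_psth(p)
  expect_equal(range(y), c(0, 1))
  expect_length(y, 3000)
  expect_false(attr(y, "degenerate"))
  y0 <- smooth_and_normalize_psth(rep(2, 600), bin_size = 5)
  expect_true(attr(y0, "degenerate"))
  expect_true(all(y0 == 0))
})

test_that("peak detection applies the three selection criteria", {
  bump <- function(center, height, width = 30, n = 400) {
    x <- pmax(0, height * (1 - abs(seq_len(n) - center) / width))
  }
  one <- bump(200, 1)
  expect_equal(detect_peaks(one)$indices, 200)
  # peak of height 0.2 fails the >0.3 value criterion
  expect_length(detect_peaks(bump(200, 0.2))$indices, 0)
  # two bumps with a deep valley are kept; a shallow valley merges them
  deep <- pmax(bump(120, 1), bump(280, 0.8))    # valley near 0
  expect_equal(detect_peaks(deep)$indices, c(120, 280))
  shallow <- c(seq(0, 1, length.out = 100), seq(1, 0.58, length.out = 90),
               seq(0.58, 0.6, length.out = 20), seq(0.6, 0, length.out = 100))
  pk <- detect_peaks(shallow)
  expect_equal(pk$indices, 100)                 # 0.6 bump merged (0.02 < 0.05)
})

test_that("inter-peak intervals of a primary ensemble track the stimulus timescale", {
  s <- build_sequence(seed = 11, seq_id = "seq1")
  ens <- make_ensemble(n_primary = 6, n_secondary = 0, seed = 4)
  inband <- function(seq, lo, hi, seed) {
    ds <- suppressWarnings(simulate_ensemble(list(s = seq), ens, 15, seed))
    peaks <- lapply(ds$units$unit_id, function(u) {
      p <- suppressWarnings(
        compute_psth(get_trains(ds, u, "s"), 5, seq$total_duration))
      detect_peaks(smooth_and_normalize_psth(p))$times_ms
    })
    iv <- interpeak_intervals(peaks)$intervals
    mean(iv >= lo & iv <= hi)
  }
  expect_gte(inband(s, 10, 40, 21), 0.8)
  expect_gte(inband(dilate(s, 2), 20, 80, 22), 0.8)
  expect_equal(interpeak_intervals(c(0, 11, 25))$intervals, c(11, 14))
  expect_length(interpeak_intervals(c(5))$intervals, 0)
})

test_that("mean rate is spikes per trial-second and scales with click count", {
  trains <- replicate(10, runif(3, 0, 3000), simplify = FALSE)
  expect_equal(mean_rate(trains, 3000), 1)
  expect_equal(mean_rate(list(numeric(0)), 3000), 0)
  s <- build_sequence(seed = 1)
  d <- dilate(s, 2)
  p <- primary_unit_params(p_respond = 0.9, baseline_rate = 0)
  r_fast <- mean_rate(simulate_unit(s, p, 50, seed = 1), 3000)
  r_slow <- mean_rate(simulate_unit(d, p, 50, seed = 2), 3000)
  expect_equal(r_slow / r_fast,
               length(d$click_times) / length(s$click_times),
               tolerance = 0.1)
})

test_that("similarity score is 1 for click-locked, 0 for flat responses", {
  s <- build_sequence(seed = 7)
  v <- binarize(s, 5)
  expect_equal(similarity_score(v, v), 1)
  expect_equal(similarity_score(rep(3, length(v)), v), 0)
  expect_equal(classify_area(c(0.9, 0.5, 0.2)),
               c("primary", "secondary", "secondary"))
})

test_that("similarity classification recovers area truth on an ensemble", {
  ds <- small_dataset(seed = 5)
  cls <- classify_units(ds)
  truth <- ds$units$area_truth[match(cls$unit_id, ds$units$unit_id)]
  expect_gte(mean(cls$area_label == truth), 0.95)
  # score distribution splits at the 0.5 boundary by area
  expect_gt(min(cls$score[truth == "primary"]), 0.5)
})

test_that("pairwise similarity is symmetric, unit-diagonal, higher for primary", {
  ds <- small_dataset(seed = 6)
  psths <- lapply(stats::setNames(ds$units$unit_id, ds$units$unit_id),
                  function(u) suppressWarnings(
                    compute_psth(get_trains(ds, u, "seq1"), 5, 3000)))
  groups <- stats::setNames(ds$units$area_truth, ds$units$unit_id)
  ps <- pairwise_response_similarity(psths, groups = groups)
  expect_equal(ps$matrix, t(ps$matrix))
  expect_equal(unname(diag(ps$matrix)), rep(1, nrow(ps$matrix)))
  pri <- ps$summary$mean_similarity[ps$summary$group == "primary"]
  sec <- ps$summary$mean_similarity[ps$summary$group == "secondary"]
  expect_gt(pri, sec)
  # rank test across pair similarities
  m <- ps$matrix
  ids <- names(groups)
  pri_pairs <- m[groups[ids] == "primary", groups[ids] == "primary"]
  sec_pairs <- m[groups[ids] == "secondary", groups[ids] == "secondary"]
  pv <- stats::wilcox.test(pri_pairs[upper.tri(pri_pairs)],
                           sec_pairs[upper.tri(sec_pairs)],
                           alternative = "greater")$p.value
  expect_lt(pv, 0.01)
})
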