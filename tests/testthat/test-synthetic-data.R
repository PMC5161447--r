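test_that("primary generator hits every click in the deterministic limit", {
  s <- build_sequence(seed = 1)
  p <- primary_unit_params(latency_mean = 10, latency_jitter_sd = 0,
                           p_respond = 1, baseline_rate = 0)
  tr <- simulate_unit(s, p, 3, seed = 1)
  for (tt in tr) expect_equal(tt, s$click_times + 10)
  p0 <- primary_unit_params(p_respond = 0, baseline_rate = 0)
  for (tt in simulate_unit(s, p0, 3, seed = 1)) expect_length(tt, 0)
})

test_that("click-triggered latency histogram peaks at the generator latency", {
  # sparse clicks (50-ms gaps) make every spike attributable to one click
  s <- build_sequence(interval_set(50), repeating = TRUE,
                      block_permutations = list(1L), total_duration = 2000)
  p <- primary_unit_params(latency_mean = 10, latency_jitter_sd = 1,
                           p_respond = 0.9, baseline_rate = 0)
  tr <- simulate_unit(s, p, 50, seed = 2)
  h <- click_triggered_latency(tr, s$click_times, window = 20, bin = 1)
  expect_true(which.max(h$histogram) %in% 10:11)  # mode at ~10 ms
  expect_equal(sd(h$latencies), 1, tolerance = 0.2)
  expect_length(click_triggered_latency(list(numeric(0)),
                                        s$click_times)$latencies, 0)
})

test_that("primary latency distribution is independent of preceding interval", {
  s <- build_sequence(seed = 3)
  p <- primary_unit_params(latency_mean = 10, latency_jitter_sd = 1,
                           p_respond = 1, baseline_rate = 0)
  trains <- simulate_unit(s, p, 10, seed = 4)
  iv <- sequence_intervals(s)
  short_prev <- which(iv <= 20) + 1   # click indices (2..)
  long_prev <- which(iv >= 29) + 1
  lat <- function(idx) unlist(lapply(trains, function(tt)
    unlist(lapply(s$click_times[idx], function(ct) {
      d <- tt - ct
      d[d > 0 & d < 15]
    }))))
  a <- lat(short_prev)
  b <- lat(long_prev)
  expect_gt(stats::ks.test(a, b)$p.value, 0.01)
})

test_that("secondary units respond only after tuned interval classes", {
  s <- build_sequence(block_permutations = list(1:10), repeating = TRUE)
  w <- stats::setNames(rep(0, 10), canonical_intervals())
  w["40"] <- 1
  p <- secondary_unit_params(w, latency_mean = 10, latency_jitter_sd = 0,
                             baseline_rate = 0, n_spikes = 1)
  tr <- simulate_unit(s, p, 5, seed = 1)
  after_40 <- s$click_times[which(sequence_intervals(s) == 40) + 1]
  for (tt in tr)
    expect_true(all(vapply(tt, function(x)
      any(abs(x - 10 - after_40) < 1e-9), logical(1))))
})

test_that("units tuned to disjoint classes have disjoint response supports", {
  s <- build_sequence(block_permutations = list(1:10), repeating = TRUE)
  cls <- as.character(canonical_intervals())
  mk <- function(active) {
    w <- stats::setNames(rep(0, 10), cls)
    w[active] <- 1
    secondary_unit_params(w, latency_mean = 12, latency_jitter_sd = 0,
                          baseline_rate = 0, n_spikes = 1)
  }
  t1 <- simulate_unit(s, mk(c("11", "20")), 20, seed = 1)
  t2 <- simulate_unit(s, mk(c("34", "40")), 20, seed = 2)
  p1 <- compute_psth(t1, 5, 3000)
  p2 <- compute_psth(t2, 5, 3000)
  # beyond the context-free first click, response supports are disjoint
  late <- 5:600
  expect_length(intersect(intersect(which(p1$values > 0), late),
                          intersect(which(p2$values > 0), late)), 0)
})

test_that("uniform secondary tuning is rate-indistinguishable from primary", {
  s <- build_sequence(seed = 2)
  w <- stats::setNames(rep(0.6, 10), canonical_intervals())
  sec <- secondary_unit_params(w, latency_mean = 10, latency_jitter_sd = 1,
                               baseline_rate = 0, n_spikes = 1)
  pri <- primary_unit_params(latency_mean = 10, latency_jitter_sd = 1,
                             p_respond = 0.6, baseline_rate = 0)
  n_sec <- lengths(simulate_unit(s, sec, 200, seed = 5))
  n_pri <- lengths(simulate_unit(s, pri, 200, seed = 6))
  expect_gt(stats::wilcox.test(n_sec, n_pri)$p.value, 0.05)
})

test_that("context beyond the memory window falls back to the mean weight", {
  w <- stats::setNames(rep(0, 10), canonical_intervals())
  w["40"] <- 1  # mean weight 0.1
  p <- secondary_unit_params(w, context_window = 40)
  s_fast <- build_sequence(block_permutations = list(1:10), repeating = TRUE)
  s_slow <- dilate(s_fast, 2)
  probs <- clickpop:::secondary_click_probs(s_slow, p)
  iv <- sequence_intervals(s_slow)
  lost <- which(iv > 40) + 1      # preceding interval beyond the memory
  kept <- which(iv <= 40) + 1
  expect_true(all(probs[lost] == mean(w)))
  expect_true(all(probs[kept] == w[as.character(iv[kept - 1] / 2)]))
})

test_that("ensemble simulation is seed-deterministic and conserves spikes", {
  stim <- canonical_pair()
  ens <- make_ensemble(2, 2, seed = 1)
  d1 <- suppressWarnings(simulate_ensemble(stim, ens, 5, seed = 9))
  d2 <- suppressWarnings(simulate_ensemble(stim, ens, 5, seed = 9))
  expect_identical(d1$spikes, d2$spikes)
  n <- 0
  for (u in d1$units$unit_id) for (sid in names(stim))
    n <- n + sum(lengths(get_trains(d1, u, sid)))
  expect_equal(nrow(d1$spikes), n)
  # spike-time support
  expect_true(all(d1$spikes$time_ms >= 0))
  expect_true(all(d1$spikes$time_ms <= 3000 + 20 + 3 * 3 + 12))
})

test_that("trace simulation superimposes templates exactly when noise-free", {
  fs <- 25000
  tpl <- spike_template(fs, p2p_us = 300)
  tr <- simulate_trace(list(u = c(50, 100)), list(u = tpl), 200, fs,
                       noise_sd = 0, seed = 1)
  neg <- attr(tpl, "neg_peak")
  i0 <- round(50 / 1000 * fs) + 1 - (neg - 1)
  expect_equal(tr$samples[i0:(i0 + length(tpl) - 1)], as.numeric(tpl))
  expect_equal(sum(tr$samples != 0), 2 * sum(tpl != 0))
  empty <- simulate_trace(list(u = numeric(0)), list(u = tpl), 50, fs,
                          noise_sd = 0.1, seed = 1)
  expect_equal(nrow(empty$truth), 0)
  expect_equal(sd(empty$samples), 0.1, tolerance = 0.05)
})

test_that("indifferent agents produce near-zero d-prime", {
  ag <- agent_params(p_interrupt_nonrew = 0.2, p_interrupt_rew = 0.2,
                     p_water_rew = 0.5, p_water_nonrew = 0.5)
  dps <- vapply(1:20, function(sd) {
    log <- simulate_trial_log(ag, 1, 1000, seed = sd)
    lc <- learning_curve(classify_trial_outcomes(log))
    lc$days$d_prime[1]
  }, numeric(1))
  expect_lt(abs(mean(dps)), 0.15)
})

test_that("perfect agents saturate at the correction ceiling", {
  ag <- agent_params(p_interrupt_nonrew = 1, p_interrupt_rew = 0,
                     p_water_rew = 1, p_water_nonrew = 0)
  log <- classify_trial_outcomes(simulate_trial_log(ag, 1, 200, seed = 1))
  r <- clickpop:::behavior_rates(log)
  expect_equal(r$H, 1)
  expect_equal(r$F, 0)
  dp <- dprime(r$H, r$F, r$n_reward, r$n_noreward)
  expect_true(is.finite(dp))
  expect_equal(dp, qnorm(1 - 1 / (2 * r$n_reward)) -
                 qnorm(1 / (2 * r$n_noreward)))
})

test_that("catch trials are tagged at the configured fraction", {
  ag <- agent_params()
  log <- simulate_trial_log(ag, 1, 4000, p_catch = 0.1, seed = 3)
  nonrew <- log[!log$rewarded, ]
  expect_equal(mean(nonrew$catch_type == "reverse"), 0.1, tolerance = 0.03)
  expect_true(all(log$catch_type[log$rewarded] == "none"))
})
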