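test_that("boxcar trajectory smoothing conserves mass and partitions trials", {
  ds <- small_dataset(seed = 1, n_trials = 6)
  # impulse spreading: direct check on the smoother
  imp <- c(numeric(10), 1, numeric(10))
  sm <- clickpop:::boxcar_smooth(imp, 6)
  expect_equal(sum(sm), 1)
  expect_equal(sum(sm > 0), 6)
  expect_equal(clickpop:::boxcar_smooth(imp, 1), imp)
  # odd/even partition counts sum to all-trials counts (unsmoothed rates)
  u <- ds$units$unit_id[1]
  args <- list(ds, u, bin_size = 5, smooth_ms = 5, clip_to_clicks = FALSE)
  t_all <- do.call(build_trajectories, c(args, trial_subset = "all"))
  t_odd <- do.call(build_trajectories, c(args, trial_subset = "odd"))
  t_even <- do.call(build_trajectories, c(args, trial_subset = "even"))
  expect_equal(t_all$seq1 * 6, t_odd$seq1 * 3 + t_even$seq1 * 3)
  expect_error(build_trajectories(ds, "nonexistent"), "not present")
})

test_that("trajectory PCA shares one projection and reports variance", {
  ds <- small_dataset(seed = 2, n_trials = 6)
  tr <- build_trajectories(ds, trial_subset = "all")
  pr <- trajectory_pca(tr, n_components = 3)
  expect_true(all(pr$explained >= 0) && sum(pr$explained) <= 1)
  expect_equal(ncol(pr$projected$seq1), 3)
  # with all components the projection is an isometry
  pr_full <- trajectory_pca(tr, n_components = ncol(tr$seq1))
  d_orig <- dist(tr$seq1[1:20, ])
  d_proj <- dist(pr_full$projected$seq1[1:20, ])
  expect_equal(as.numeric(d_proj), as.numeric(d_orig), tolerance = 1e-8)
})

test_that("distance samples: identical and orthogonal constant trajectories", {
  m1 <- matrix(1, 10, 3)
  z <- matrix(0, 10, 3)
  traj <- list(a = m1, b = z)
  ds0 <- distance_samples(list(a = m1, b = z), list(a = m1, b = z))
  expect_true(all(ds0$same_stim == 0))
  e1 <- matrix(rep(c(1, 0), c(10, 10)), 10, 2)
  e2 <- matrix(rep(c(0, 1), c(10, 10)), 10, 2)
  ds1 <- distance_samples(list(a = e1, b = e2), list(a = e1, b = e2))
  expect_true(all(abs(ds1$cross_stim - sqrt(2)) < 1e-12))
  expect_error(distance_samples(list(a = m1), list(a = m1)), "two stimuli")
})

test_that("optimized nearest-point search equals exhaustive enumeration", {
  set.seed(4)
  mk <- function() matrix(runif(30), 10, 3)
  to <- list(a = mk(), b = mk(), c = mk())
  te <- list(a = mk(), b = mk(), c = mk())
  ds <- distance_samples(to, te, mode = "global")
  brute <- unlist(lapply(names(to), function(s) {
    others <- do.call(rbind, te[setdiff(names(to), s)])
    vapply(seq_len(nrow(to[[s]])), function(i)
      min(vapply(seq_len(nrow(others)), function(j)
        sqrt(sum((to[[s]][i, ] - others[j, ])^2)), numeric(1))),
      numeric(1))
  }))
  expect_equal(ds$cross_stim, brute, tolerance = 1e-12)
})

test_that("phase-space distance behaves like a metric on random vectors", {
  set.seed(5)
  d <- function(a, b) sqrt(sum((a - b)^2))
  for (i in 1:20) {
    x <- runif(8); y <- runif(8); z <- runif(8)
    expect_equal(d(x, y), d(y, x))
    expect_lte(d(x, z), d(x, y) + d(y, z) + 1e-12)
    expect_equal(d(x, x), 0)
  }
})

test_that("ROC matches brute-force concordance and handles edge shapes", {
  set.seed(6)
  same <- runif(20); cross <- runif(20) + 0.3
  r <- roc_curve(list(same_stim = same, cross_stim = cross))
  expect_equal(r$auc, auc_bruteforce(same, cross), tolerance = 1e-12)
  # monotone curve through (0,0) and (1,1)
  ord <- order(r$fpr, r$tpr)
  expect_true(all(diff(r$tpr[ord]) >= 0))
  expect_equal(range(r$fpr), c(0, 1))
  expect_equal(range(r$tpr), c(0, 1))
  # separated distributions give AUC 1; identical give ~0.5
  expect_equal(roc_curve(list(same_stim = runif(30),
                              cross_stim = runif(30) + 2))$auc, 1)
  x <- runif(500)
  expect_equal(roc_curve(list(same_stim = x, cross_stim = x))$auc, 0.5,
               tolerance = 1e-12)
  expect_error(roc_curve(list(same_stim = numeric(0), cross_stim = 1)),
               "non-empty")
})

test_that("AUC is invariant under strictly monotone distance transforms", {
  set.seed(7)
  same <- rexp(40); cross <- rexp(40) * 2
  a1 <- roc_curve(list(same_stim = same, cross_stim = cross))$auc
  a2 <- roc_curve(list(same_stim = log1p(same), cross_stim = log1p(cross)))$auc
  a3 <- roc_curve(list(same_stim = same^3, cross_stim = cross^3))$auc
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})

test_that("secondary populations discriminate sequences; primary do not", {
  ds <- small_dataset(seed = 3)
  es <- discriminability_experiment(ds, "secondary", 10)
  ep <- discriminability_experiment(ds, "primary", 10)
  expect_gt(es$roc$auc, 0.9)
  expect_lt(ep$roc$auc, 0.9)
  e500 <- discriminability_experiment(ds, "secondary", 10, max_time_ms = 500)
  p500 <- discriminability_experiment(ds, "primary", 10, max_time_ms = 500)
  expect_gt(e500$roc$auc, p500$roc$auc)
  expect_error(discriminability_experiment(ds, "secondary", 11), "units")
})

test_that("shuffling stimulus labels destroys discriminability", {
  ds <- small_dataset(seed = 8)
  intact <- discriminability_experiment(ds, "secondary", 10)$roc$auc
  # label destruction: each trial keeps a random stimulus assignment
  sw <- ds
  set.seed(1)
  for (u in sw$units$unit_id) for (tr in seq_len(sw$n_trials)) {
    if (runif(1) < 0.5) {
      sel <- sw$spikes$unit_id == u & sw$spikes$trial == tr
      sw$spikes$stimulus_id[sel] <-
        ifelse(sw$spikes$stimulus_id[sel] == "seq1", "seq2", "seq1")
    }
  }
  shuffled <- discriminability_experiment(sw, "secondary", 10)$roc$auc
  expect_lt(shuffled, 0.6)
  expect_gt(intact - shuffled, 0.3)
})

test_that("timescale dilation reduces secondary discriminability, not rates", {
  stim <- canonical_pair()
  stim_slow <- lapply(stim, dilate, factor = 2)
  ens <- make_ensemble(seed = 9)
  fast <- suppressWarnings(simulate_ensemble(stim, ens, 20, seed = 109))
  slow <- suppressWarnings(simulate_ensemble(stim_slow, ens, 20, seed = 209))
  tc <- timescale_comparison(fast, slow, "secondary", 10)
  expect_gt(tc$auc_drop, 0.2)
  expect_identical(tc$auc_fast, tc$fast$roc$auc)
  rate <- function(d, area) {
    ids <- d$units$unit_id[d$units$area_truth == area]
    mean(vapply(ids, function(u)
      mean(vapply(names(d$stimuli), function(s)
        mean_rate(get_trains(d, u, s), 3000), numeric(1))), numeric(1)))
  }
  sec_drop <- 1 - rate(slow, "secondary") / rate(fast, "secondary")
  pri_drop <- 1 - rate(slow, "primary") / rate(fast, "primary")
  expect_lt(sec_drop, pri_drop)   # secondary rate reduction relatively small
  expect_equal(timescale_comparison(fast, fast, "secondary", 10)$auc_drop, 0)
})

test_that("tuning contrast monotonically increases secondary AUC", {
  contrasts <- c(0, 0.25, 0.5, 0.75, 1)
  aucs <- vapply(contrasts, function(ct) {
    a <- vapply(1:3, function(sd) {
      ds <- small_dataset(seed = sd * 31, tuning_contrast = ct)
      discriminability_experiment(ds, "secondary", 10)$roc$auc
    }, numeric(1))
    mean(a)
  }, numeric(1))
  expect_gt(stats::cor(contrasts, aucs, method = "spearman"), 0.9)
})

test_that("window separation: identical sequences never separate; distinct do", {
  s1 <- build_sequence(seed = 11, seq_id = "seq1")
  s2 <- build_sequence(seed = 22, seq_id = "seq2")
  wa_same <- window_separation_analysis(list(a = s1, b = s1),
                                        T_grid = c(50, 150), n_reps = 5)
  expect_true(all(!wa_same$table$separates))
  expect_true(all(wa_same$table$auc_mean < 0.7))
  wa <- window_separation_analysis(list(seq1 = s1, seq2 = s2),
                                   T_grid = c(5, seq(20, 200, 20)),
                                   n_reps = 5, seed = 3)
  # windows resolving single clicks cannot separate the pair
  expect_false(wa$table$separates[wa$table$T == 5])
  expect_lt(wa$table$auc_min[wa$table$T == 5], 1)
  # discriminability grows with integration timescale
  expect_gt(stats::cor(wa$table$T, wa$table$auc_mean,
                       method = "spearman"), 0.8)
  expect_true(is.finite(wa$minimal_T))
  expect_gt(wa$minimal_T, 5)
  expect_error(window_separation_analysis(list(a = s1), c(10)), "two")
  expect_error(window_separation_analysis(list(a = s1, b = s2),
                                          numeric(0)), "grid")
})
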