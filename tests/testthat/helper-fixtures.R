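# Shared fixtures, generated in code.

canonical_pair <- function() {
  list(seq1 = build_sequence(seed = 11, seq_id = "seq1"),
       seq2 = build_sequence(seed = 22, seq_id = "seq2"))
}

small_dataset <- function(seed = 1, n_trials = 20, stimuli = canonical_pair(),
                          ...) {
  ens <- make_ensemble(seed = seed, ...)
  suppressWarnings(simulate_ensemble(stimuli, ens, n_trials = n_trials,
                                     seed = seed + 100))
}

# Two-unit spike trains with all pooled gaps above `gap` ms, so templates
# never overlap on the simulated trace.
collision_free_trains <- function(n_per_unit = 110, duration_ms = 2000,
                                  gap = 3, seed = 7) {
  set.seed(seed)
  all <- sort(runif(3 * n_per_unit, 10, duration_ms - 10))
  all <- all[c(TRUE, diff(all) > gap)]
  all <- all[seq_len(min(2 * n_per_unit, length(all)))]
  idx <- sample(rep(1:2, length.out = length(all)))
  list(u1 = sort(all[idx == 1]), u2 = sort(all[idx == 2]))
}

# Brute-force AUC by concordant-pair counting (ties count half).
auc_bruteforce <- function(same, cross) {
  conc <- 0
  for (s in same) for (cx in cross)
    conc <- conc + (cx > s) + 0.5 * (cx == s)
  conc / (length(same) * length(cross))
}
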