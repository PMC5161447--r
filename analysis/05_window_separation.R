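#!/usr/bin/env Rscript
# Feed-forward "smoothing unit" analysis: smooth the two training sequences
# with rectangular windows {T, T/2, T/4}, build 3-D phase-plane traces, and
# find the minimal integration timescale T at which the traces separate in
# the same distance-and-ROC analysis used for neural trajectories.

suppressMessages(library(clickpop))
out <- "results/window"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

stim <- list(seq1 = build_sequence(repeating = TRUE, seed = 11,
                                   seq_id = "seq1"),
             seq2 = build_sequence(repeating = FALSE, seed = 22,
                                   seq_id = "seq2"))
wa <- window_separation_analysis(stim, T_grid = seq(10, 200, 10),
                                 n_reps = 20, seed = 3)
write.csv(wa$table, file.path(out, "window_separation.csv"),
          row.names = FALSE)

cat("Separability rises with the integration timescale T:\n")
print(wa$table[wa$table$T %in% c(10, 50, 100, 150, 200),
               c("T", "auc_min", "auc_mean", "separates")],
      row.names = FALSE)
if (is.finite(wa$minimal_T)) {
  cat(sprintf("Minimal T with replicate-minimum AUC >= %.2f: %d ms.\n",
              wa$auc_criterion, wa$minimal_T))
} else {
  cat(sprintf(paste0(
    "No T on the grid reaches the %.2f bar for this reconstructed pair;",
    " the replicate-minimum AUC plateaus at %.2f.\n"),
    wa$auc_criterion, max(wa$table$auc_min)))
}
cat(paste0(
  "The strict AUC = 1 rule never triggers: boxcar traces are click counts",
  " on a lattice and coincide exactly at a fraction of time bins (strict",
  " minimal T: ", format(wa$minimal_T_strict), ").\n"))
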