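#!/usr/bin/env Rscript
# Reverberant linear-network model: dv/dt = alpha*M*v - gamma*v + input +
# noise with antisymmetric M ("critical tuning": all oscillatory modes
# equally excitable). Simulates responses to the two click sequences,
# writes tick rasters, and compares discriminability of the tuned network
# against a memoryless (alpha = 0) control.

suppressMessages(library(clickpop))
out <- "results/model"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

stim <- list(seq1 = build_sequence(repeating = TRUE, seed = 11,
                                   seq_id = "seq1"),
             seq2 = build_sequence(repeating = FALSE, seed = 22,
                                   seq_id = "seq2"))
cfg <- lds_config(N = 50, seed = 5)

for (sid in names(stim)) {
  tr <- simulate_lds(cfg, stim[[sid]], seed = 7)
  ticks <- tick_raster(tr)
  raster <- do.call(rbind, lapply(seq_along(ticks), function(j)
    if (length(ticks[[j]]))
      data.frame(dim = j, time_ms = ticks[[j]]) else NULL))
  write.csv(raster, file.path(out, paste0("ticks_", sid, ".csv")),
            row.names = FALSE)
}

tuned <- suppressWarnings(
  model_discriminability(cfg, stim, n_trials = 6, seed = 9))
memoryless <- suppressWarnings(model_discriminability(
  lds_config(N = 50, alpha = 0, gamma = 1 / 5, seed = 5), stim,
  n_trials = 6, seed = 9))
jsonlite::write_json(list(auc_tuned = tuned$roc$auc,
                          auc_memoryless = memoryless$roc$auc),
                     file.path(out, "model_auc.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf(paste0(
  "Critically tuned network: AUC %.3f; memoryless control (alpha = 0):",
  " %.3f. Rotational recurrence turns interval context into distinct",
  " population states.\n"), tuned$roc$auc, memoryless$roc$auc))
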