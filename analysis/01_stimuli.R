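#!/usr/bin/env Rscript
# Construct the click-sequence stimulus set: a repeating 3-s sequence
# (seq1, the non-rewarded training stimulus), a non-repeating one (seq2,
# the rewarded stimulus), their time-reversed, cyclically permuted and
# twofold-dilated variants. Writes click-time tables, WAV renderings and a
# JSON sidecar under results/stimuli/.

suppressMessages(library(clickpop))
out <- "results/stimuli"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

seq1 <- build_sequence(repeating = TRUE, seed = 11, seq_id = "seq1")
seq2 <- build_sequence(repeating = FALSE, seed = 22, seq_id = "seq2")
variants <- list(
  seq1 = seq1,
  seq2 = seq2,
  seq1_rev = reverse_sequence(seq1),
  seq1_cyc = cyclic_permute(seq1, 37),
  seq1_x2 = dilate(seq1, 2),
  seq2_x2 = dilate(seq2, 2))

rows <- list()
for (nm in names(variants)) {
  s <- variants[[nm]]
  rows[[nm]] <- data.frame(seq_id = nm,
                           click_index = seq_along(s$click_times),
                           time_ms = s$click_times)
  write_wav(render_audio(s, 44100), path = file.path(out, paste0(nm, ".wav")))
}
write.csv(do.call(rbind, rows), file.path(out, "click_times.csv"),
          row.names = FALSE)
jsonlite::write_json(
  lapply(variants, function(s) list(
    seq_id = s$seq_id, repeating = s$repeating,
    n_blocks = length(s$blocks), n_clicks = length(s$click_times),
    dilation = s$intervals$dilation,
    last_click_ms = max(s$click_times))),
  file.path(out, "stimuli.json"), auto_unbox = TRUE, digits = NA)

cat("Canonical interval set sums to", sum(canonical_intervals()), "ms;",
    "seq1 holds", length(seq1$blocks), "repetitions of one block,",
    "last click at", max(seq1$click_times), "ms of",
    seq1$total_duration, "ms.\n")
cat("Twofold dilation gives intervals",
    paste(range(sequence_intervals(variants$seq1_x2)), collapse = "-"),
    "ms and", length(variants$seq1_x2$click_times),
    "clicks after the 3-s truncation.\n")
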