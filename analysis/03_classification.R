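#!/usr/bin/env Rscript
# Classify units as primary or secondary from the similarity between their
# PSTH and the click stimulus; summarize pairwise response similarity,
# click-triggered latencies and PSTH inter-peak timescales. Reads
# results/spikes_fast/ (run 02 first); writes under results/metrics/.

suppressMessages(library(clickpop))
out <- "results/metrics"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
ds <- import_spike_data("results/spikes_fast")
slow <- import_spike_data("results/spikes_slow")

cls <- classify_units(ds)
cls$area_truth <- ds$units$area_truth[match(cls$unit_id, ds$units$unit_id)]
write.csv(cls, file.path(out, "classification.csv"), row.names = FALSE)
acc <- mean(cls$area_label == cls$area_truth)
cat(sprintf("Similarity threshold 0.5 recovers %d/%d area labels (%.0f%%).\n",
            sum(cls$area_label == cls$area_truth), nrow(cls), 100 * acc))

psths <- lapply(stats::setNames(ds$units$unit_id, ds$units$unit_id),
                function(u) suppressWarnings(
                  compute_psth(get_trains(ds, u, "seq1"), 5, 3000)))
groups <- stats::setNames(ds$units$area_truth, ds$units$unit_id)
ps <- pairwise_response_similarity(psths, groups = groups)
write.csv(ps$summary, file.path(out, "pairwise_similarity.csv"),
          row.names = FALSE)
cat(sprintf("Mean pairwise PSTH similarity: primary %.2f, secondary %.2f.\n",
            ps$summary$mean_similarity[ps$summary$group == "primary"],
            ps$summary$mean_similarity[ps$summary$group == "secondary"]))

# click-triggered latency of primary units
pri <- ds$units$unit_id[ds$units$area_truth == "primary"]
lat <- unlist(lapply(pri, function(u)
  click_triggered_latency(get_trains(ds, u, "seq1"),
                          ds$stimuli$seq1$click_times, window = 20)$latencies))
cat(sprintf("Primary click-triggered latency: mode %.0f ms, sd %.1f ms.\n",
            density(lat)$x[which.max(density(lat)$y)], sd(lat)))

# PSTH inter-peak interval histograms at the two stimulus timescales
band <- function(d, sid, lo, hi) {
  peaks <- lapply(pri, function(u) {
    p <- suppressWarnings(compute_psth(get_trains(d, u, sid), 5, 3000))
    detect_peaks(smooth_and_normalize_psth(p))$times_ms
  })
  iv <- interpeak_intervals(peaks)
  write.csv(data.frame(t_lo = head(iv$breaks, -1), count = iv$histogram),
            file.path(out, paste0("interpeak_", sid, ".csv")),
            row.names = FALSE)
  mean(iv$intervals >= lo & iv$intervals <= hi)
}
cat(sprintf("Inter-peak intervals in 10-40 ms band (fast): %.0f%%;",
            100 * band(ds, "seq1", 10, 40)),
    sprintf("in 20-80 ms (dilated): %.0f%%.\n",
            100 * band(slow, "seq1", 20, 80)))
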