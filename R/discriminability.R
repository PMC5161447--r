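# Causal boxcar smoothing of a rate vector; mass-conserving (an impulse is
# spread uniformly over `k` bins).
boxcar_smooth <- function(x, k) {
  if (k <= 1) return(x)
  as.numeric(stats::filter(c(x, numeric(k - 1)), rep(1 / k, k),
                           sides = 1))[k:(length(x) + k - 1)]
}

#' Build population-vector trajectories
#'
#' For each stimulus, stacks the per-unit PSTHs (5-ms bins, chosen trial
#' subset, boxcar-smoothed over `smooth_ms`) into a time-bin x unit matrix —
#' the population vector array whose rows are phase-space points.
#'
#' @param dataset A `spike_dataset`.
#' @param unit_ids Units to include (fixed order shared by all trajectories).
#' @param stimulus_ids Stimuli to include (default all).
#' @param bin_size Bin width (ms), canonical 5.
#' @param smooth_ms Rectangular smoothing window (ms), canonical 30.
#' @param trial_subset `"all"`, `"odd"` or `"even"` numbered trials.
#' @param max_time_ms Optional restriction to bins below this time (e.g. 500
#'   for the first-500-ms analysis).
#' @param clip_to_clicks If `TRUE` (default), trajectories are truncated at
#'   the end of the clicked span (last click plus the smoothing window,
#'   minimized over the compared stimuli): the silent tail of the 3-s
#'   playback carries no sequence information and would only dilute the
#'   distance distributions.
#' @return Named list of matrices (bins x units) with attributes `bin_size`,
#'   `unit_ids`.
#' @export
build_trajectories <- function(dataset, unit_ids = dataset$units$unit_id,
                               stimulus_ids = names(dataset$stimuli),
                               bin_size = 5, smooth_ms = 30,
                               trial_subset = c("all", "odd", "even"),
                               max_time_ms = NULL, clip_to_clicks = TRUE) {
  trial_subset <- match.arg(trial_subset)
  if (clip_to_clicks && !is.null(dataset$stimuli)) {
    span <- min(vapply(dataset$stimuli[stimulus_ids], function(s)
      max(s$click_times), numeric(1))) + smooth_ms
    max_time_ms <- if (is.null(max_time_ms)) span else min(max_time_ms, span)
  }
  trials <- seq_len(dataset$n_trials)
  trials <- switch(trial_subset, all = trials,
                   odd = trials[trials %% 2 == 1],
                   even = trials[trials %% 2 == 0])
  k <- max(1L, round(smooth_ms / bin_size))
  have <- unique(dataset$spikes$unit_id)
  out <- list()
  for (sid in stimulus_ids) {
    dur <- dataset$stimuli[[sid]]$total_duration
    n_bins <- ceiling(dur / bin_size)
    mat <- matrix(0, n_bins, length(unit_ids),
                  dimnames = list(NULL, unit_ids))
    for (uid in unit_ids) {
      if (!uid %in% dataset$units$unit_id)
        stop("unit ", uid, " not present in the dataset")
      tr <- get_trains(dataset, uid, sid, trials = trials)
      # late-click responses beyond the stimulus window are clipped silently
      p <- suppressWarnings(compute_psth(tr, bin_size = bin_size,
                                         duration = dur, rate = TRUE))
      mat[, uid] <- boxcar_smooth(p$values, k)
    }
    if (!is.null(max_time_ms))
      mat <- mat[seq_len(min(n_bins, floor(max_time_ms / bin_size))), ,
                 drop = FALSE]
    out[[sid]] <- mat
  }
  attr(out, "bin_size") <- bin_size
  attr(out, "unit_ids") <- unit_ids
  out
}

#' Project trajectories into principal-component space
#'
#' Fits one PCA on the concatenated trajectories so all stimuli share the
#' projection, then returns each trajectory's first `n_components` scores
#' (optionally re-smoothed for visualization).
#'
#' @param trajectories Output of [build_trajectories()].
#' @param n_components Components to keep.
#' @param vis_smooth_ms Optional rectangular window (ms) applied to the
#'   projected traces for display (canonical 10).
#' @return List: `projected` (named list of bins x components matrices),
#'   `explained` (variance fractions), `pca` (the fit).
#' @export
trajectory_pca <- function(trajectories, n_components = 3,
                           vis_smooth_ms = NULL) {
  big <- do.call(rbind, trajectories)
  nc <- min(n_components, qr(scale(big, scale = FALSE))$rank)
  if (nc < n_components)
    message("rank-deficient trajectories: using ", nc, " components")
  pc <- stats::prcomp(big, center = TRUE, scale. = FALSE)
  bin <- attr(trajectories, "bin_size")
  proj <- lapply(trajectories, function(m) {
    s <- stats::predict(pc, m)[, seq_len(nc), drop = FALSE]
    if (!is.null(vis_smooth_ms)) {
      k <- max(1L, round(vis_smooth_ms / bin))
      s <- apply(s, 2, boxcar_smooth, k = k)
    }
    s
  })
  list(projected = proj,
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(nc)],
       pca = pc)
}

#' Same- and cross-stimulus phase-space distance samples
#'
#' For every stimulus and time bin, the same-stimulus distance is the
#' Euclidean distance between the odd- and even-trial population vectors at
#' that bin (the within-stimulus noise floor). The cross-stimulus distance is
#' the distance from the odd-split vector to the nearest point (over time
#' bins, `mode = "global"`, or at the matched bin, `mode = "matched"`) of any
#' other stimulus's even-split trajectory.
#'
#' @param traj_odd,traj_even Trajectory lists from [build_trajectories()]
#'   with identical unit order and bin grid.
#' @param mode `"global"` nearest-point search (default) or `"matched"`
#'   time-aligned distances.
#' @return A `distance_samples` list: `same_stim`, `cross_stim` (numeric
#'   vectors pooled over stimuli and time bins).
#' @export
distance_samples <- function(traj_odd, traj_even,
                             mode = c("global", "matched")) {
  mode <- match.arg(mode)
  sids <- names(traj_odd)
  if (length(sids) < 2) stop("need at least two stimuli")
  stopifnot(identical(sids, names(traj_even)))
  same <- cross <- numeric(0)
  for (s in sids) {
    A <- traj_odd[[s]]
    B <- traj_even[[s]]
    nb <- min(nrow(A), nrow(B))
    same <- c(same, sqrt(rowSums((A[seq_len(nb), , drop = FALSE] -
                                    B[seq_len(nb), , drop = FALSE])^2)))
    others <- do.call(rbind, traj_even[setdiff(sids, s)])
    if (mode == "global") {
      # min over all points of other-stimulus trajectories
      a2 <- rowSums(A^2)
      b2 <- rowSums(others^2)
      G <- A %*% t(others)
      d2 <- outer(a2, b2, "+") - 2 * G
      cross <- c(cross, sqrt(pmax(0, apply(d2, 1, min))))
    } else {
      for (s2 in setdiff(sids, s)) {
        B2 <- traj_even[[s2]]
        nb2 <- min(nrow(A), nrow(B2))
        cross <- c(cross, sqrt(rowSums((A[seq_len(nb2), , drop = FALSE] -
                                          B2[seq_len(nb2), , drop = FALSE])^2)))
      }
    }
  }
  structure(list(same_stim = same, cross_stim = cross, mode = mode),
            class = "distance_samples")
}

#' ROC curve over phase-space distances
#'
#' Sweeps a decision boundary over the pooled distances: a point is called
#' "different stimulus" when its distance exceeds the threshold, giving
#' TPR = P(cross > theta) and FPR = P(same > theta). AUC by the trapezoid
#' rule; it equals the probability that a random cross-stimulus distance
#' exceeds a random same-stimulus distance (ties counted half).
#'
#' @param ds A `distance_samples` (or list with `same_stim`, `cross_stim`).
#' @return A `roc_curve`: list with `thresholds`, `fpr`, `tpr`, `auc`.
#' @export
roc_curve <- function(ds) {
  same <- ds$same_stim
  cross <- ds$cross_stim
  if (!length(same) || !length(cross))
    stop("both distance classes must be non-empty")
  th <- c(-Inf, sort(unique(c(same, cross))), Inf)
  tpr <- vapply(th, function(t) mean(cross > t), numeric(1))
  fpr <- vapply(th, function(t) mean(same > t), numeric(1))
  # trapezoid over the (fpr, tpr) staircase, swept from high to low threshold
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) +
                                 utils::tail(tpr[ord], -1)) / 2)
  structure(list(thresholds = th, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (%d thresholds)\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' End-to-end population discriminability experiment
#'
#' Selects `n_units` units of one area, builds odd/even-split trajectories
#' over all stimuli of the dataset, pools same- and cross-stimulus distances
#' and returns the ROC.
#'
#' @param dataset A `spike_dataset` with ground-truth or assigned area labels
#'   in `dataset$units$area_truth` (or a column named by `area_column`).
#' @param area `"primary"` or `"secondary"`.
#' @param n_units Number of units used (canonical 10).
#' @param max_time_ms Optional first-window restriction (e.g. 500 ms).
#' @param bin_size,smooth_ms Trajectory parameters.
#' @param mode Distance mode, see [distance_samples()].
#' @param area_column Column of `dataset$units` holding area labels.
#' @return List: `roc`, `distances`, `unit_ids`.
#' @export
discriminability_experiment <- function(dataset, area, n_units = 10,
                                        max_time_ms = NULL, bin_size = 5,
                                        smooth_ms = 30, mode = "global",
                                        area_column = "area_truth") {
  labs <- dataset$units[[area_column]]
  ids <- dataset$units$unit_id[labs == area]
  if (length(ids) < n_units)
    stop("only ", length(ids), " units in area '", area,
         "', need ", n_units)
  ids <- ids[seq_len(n_units)]
  t_odd <- build_trajectories(dataset, ids, bin_size = bin_size,
                              smooth_ms = smooth_ms, trial_subset = "odd",
                              max_time_ms = max_time_ms)
  t_even <- build_trajectories(dataset, ids, bin_size = bin_size,
                               smooth_ms = smooth_ms, trial_subset = "even",
                               max_time_ms = max_time_ms)
  ds <- distance_samples(t_odd, t_even, mode = mode)
  list(roc = roc_curve(ds), distances = ds, unit_ids = ids)
}

#' Compare discriminability across stimulus timescales
#'
#' Runs the same ROC experiment on a fast-sequence dataset and its
#' twofold-dilated counterpart (same units and generator, different stimulus
#' timescale) and reports the AUC change.
#'
#' @param dataset_fast,dataset_slow `spike_dataset`s sharing unit ids.
#' @param area,n_units,... Passed to [discriminability_experiment()].
#' @return List: `auc_fast`, `auc_slow`, `auc_drop`, and both experiment
#'   results.
#' @export
timescale_comparison <- function(dataset_fast, dataset_slow, area,
                                 n_units = 10, ...) {
  if (!setequal(dataset_fast$units$unit_id, dataset_slow$units$unit_id))
    stop("fast and slow datasets must contain the same units")
  ef <- discriminability_experiment(dataset_fast, area, n_units, ...)
  es <- discriminability_experiment(dataset_slow, area, n_units, ...)
  list(auc_fast = ef$roc$auc, auc_slow = es$roc$auc,
       auc_drop = ef$roc$auc - es$roc$auc, fast = ef, slow = es)
}
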