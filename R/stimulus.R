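#' Canonical inter-click interval set
#'
#' The ten inter-click intervals (ms) from which all click-sequence stimuli
#' are built. Their sum is 249 ms, the duration of one permutation block.
#' The intervals span 11-40 ms, the range of inter-peak intervals observed
#' in primary-area population PSTHs during song playback.
#'
#' @return Numeric vector of ten intervals in milliseconds.
#' @export
#' @examples
#' sum(canonical_intervals())  # 249
canonical_intervals <- function() {
  c(11, 14, 16, 20, 23, 26, 29, 34, 36, 40)
}

#' Construct an interval set
#'
#' @param intervals Positive inter-click intervals in ms.
#' @param dilation Positive dilation factor applied uniformly to all intervals.
#' @return An object of class `interval_set`.
#' @export
interval_set <- function(intervals = canonical_intervals(), dilation = 1) {
  stopifnot(is.numeric(intervals), length(intervals) >= 1)
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop("all intervals must be positive and finite")
  if (!is.numeric(dilation) || length(dilation) != 1 || dilation <= 0)
    stop("dilation must be a positive scalar")
  structure(list(intervals = as.numeric(intervals),
                 dilation = as.numeric(dilation)),
            class = "interval_set")
}

#' Effective (dilated) intervals of an interval set
#' @param x An `interval_set`.
#' @return Numeric vector of dilated intervals (ms).
#' @export
effective_intervals <- function(x) {
  stopifnot(inherits(x, "interval_set"))
  x$intervals * x$dilation
}

check_permutation <- function(permutation, n) {
  if (length(permutation) != n || !setequal(permutation, seq_len(n)))
    stop("permutation must be a bijection over 1..", n,
         " (got: ", paste(permutation, collapse = ","), ")")
  as.integer(permutation)
}

#' Build one permutation block of clicks
#'
#' A block places a click at its start and one further click after each
#' interval, in the permuted order. Block duration equals the sum of the
#' (dilated) intervals; the final click sits on the block boundary and is
#' shared with the next block when blocks are concatenated.
#'
#' @param iset An `interval_set`.
#' @param permutation Integer permutation of `seq_along(iset$intervals)`.
#' @return List with `click_times` (ms, starting at 0) and `intervals`
#'   (the permuted, dilated intervals).
#' @export
#' @examples
#' b <- make_block(interval_set(), 1:10)
#' max(b$click_times)  # 249
make_block <- function(iset, permutation) {
  stopifnot(inherits(iset, "interval_set"))
  p <- check_permutation(permutation, length(iset$intervals))
  ivals <- effective_intervals(iset)[p]
  list(click_times = c(0, cumsum(ivals)), intervals = ivals)
}

new_click_sequence <- function(click_times, iset, blocks, repeating,
                               total_duration, seq_id) {
  structure(list(click_times = as.numeric(click_times),
                 intervals = iset,
                 blocks = blocks,
                 repeating = isTRUE(repeating),
                 total_duration = as.numeric(total_duration),
                 seq_id = seq_id),
            class = "click_sequence")
}

#' @export
print.click_sequence <- function(x, ...) {
  cat(sprintf(
    "<click_sequence '%s'> %d clicks, %d blocks (%s), %.0f ms, dilation %g\n",
    x$seq_id, length(x$click_times), length(x$blocks),
    if (x$repeating) "repeating" else "non-repeating",
    x$total_duration, x$intervals$dilation))
  invisible(x)
}

#' Inter-click intervals of a sequence
#' @param seq A `click_sequence`.
#' @return Successive differences of the click times (ms).
#' @export
sequence_intervals <- function(seq) {
  stopifnot(inherits(seq, "click_sequence"))
  diff(seq$click_times)
}

distinct_permutations <- function(n_items, n_perms) {
  # rejection-sample pairwise-distinct permutations
  seen <- character(0)
  out <- vector("list", n_perms)
  i <- 1L
  while (i <= n_perms) {
    p <- sample.int(n_items)
    key <- paste(p, collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[[i]] <- p
      i <- i + 1L
    }
  }
  out
}

#' Build a click sequence from permutation blocks
#'
#' Concatenates complete 249-ms (dilated: longer) permutation blocks until no
#' further complete block fits within `total_duration`; the remaining tail is
#' silent. Repeating sequences reuse a single permutation for every block;
#' non-repeating sequences use pairwise-distinct permutations.
#'
#' @param iset An `interval_set`.
#' @param repeating Logical; repeat one block permutation throughout?
#' @param block_permutations Optional list of integer permutations (one if
#'   `repeating`, else one per block). If `NULL`, permutations are drawn from
#'   the current RNG state (set `seed`).
#' @param total_duration Sequence duration in ms (canonical 3000).
#' @param n_blocks Number of complete blocks; default 11 for the canonical
#'   3-s stimulus (11 pattern repetitions followed by a 261-ms silent tail),
#'   otherwise the largest number of complete blocks that fits.
#' @param seed Optional integer seed for reproducible permutation draws.
#' @param seq_id Label carried through downstream tables.
#' @return A `click_sequence`.
#' @export
#' @examples
#' s <- build_sequence(interval_set(), repeating = TRUE, seed = 1)
#' length(s$blocks)  # 11 complete blocks in 3 s
build_sequence <- function(iset = interval_set(), repeating = TRUE,
                           block_permutations = NULL, total_duration = 3000,
                           n_blocks = NULL, seed = NULL, seq_id = "seq") {
  stopifnot(inherits(iset, "interval_set"))
  n_iv <- length(iset$intervals)
  block_dur <- sum(effective_intervals(iset))
  if (total_duration < block_dur)
    stop("total_duration (", total_duration,
         " ms) shorter than one block (", block_dur, " ms)")
  if (is.null(n_blocks)) {
    # canonical playback: 11 repetitions of the 249-ms pattern in 3 s,
    # leaving a silent tail; otherwise as many complete blocks as fit
    n_blocks <- if (isTRUE(all.equal(block_dur, 249)) &&
                      total_duration == 3000) 11L
    else floor(total_duration / block_dur)
  }
  if (n_blocks * block_dur > total_duration)
    stop("n_blocks = ", n_blocks, " does not fit in total_duration")

  if (is.null(block_permutations)) {
    if (!is.null(seed)) {
      blocks <- with_seed(seed, {
        if (repeating) rep(list(sample.int(n_iv)), n_blocks)
        else distinct_permutations(n_iv, n_blocks)
      })
    } else {
      blocks <- if (repeating) rep(list(sample.int(n_iv)), n_blocks)
                else distinct_permutations(n_iv, n_blocks)
    }
  } else {
    perms <- lapply(block_permutations, check_permutation, n = n_iv)
    if (repeating) {
      if (length(perms) != 1)
        stop("repeating sequences take exactly one block permutation")
      blocks <- rep(perms, n_blocks)
    } else {
      if (length(perms) != n_blocks)
        stop("need ", n_blocks, " block permutations, got ", length(perms))
      blocks <- perms
    }
  }

  stream <- unlist(lapply(blocks, function(p) effective_intervals(iset)[p]))
  click_times <- c(0, cumsum(stream))
  new_click_sequence(click_times, iset, blocks, repeating,
                     total_duration, seq_id)
}

#' Reverse the interval order of a sequence end-to-end
#'
#' @param seq A `click_sequence`.
#' @return A `click_sequence` whose interval stream is the reverse of the
#'   input's; duration and click count are preserved.
#' @export
reverse_sequence <- function(seq) {
  stopifnot(inherits(seq, "click_sequence"))
  blocks <- rev(lapply(seq$blocks, rev))
  stream <- rev(sequence_intervals(seq))
  new_click_sequence(c(0, cumsum(stream)), seq$intervals, blocks,
                     seq$repeating, seq$total_duration,
                     paste0(seq$seq_id, "-rev"))
}

#' Cyclically permute a repeating sequence
#'
#' Rotates the repeating interval stream so that playback starts at the
#' chosen interval of the block pattern (a phase shift of the stimulus);
#' the rotation wraps within the block pattern, leaving the silent tail
#' untouched.
#'
#' @param seq A repeating `click_sequence`.
#' @param start_interval_index 0-based index of the interval at which the
#'   rotated stream begins (`0` returns an identical sequence).
#' @return A `click_sequence`.
#' @export
cyclic_permute <- function(seq, start_interval_index) {
  stopifnot(inherits(seq, "click_sequence"))
  if (!seq$repeating)
    stop("cyclic permutation is defined only for repeating sequences")
  n <- length(seq$blocks[[1]])
  k <- as.integer(start_interval_index)
  if (k < 0 || k >= n * length(seq$blocks))
    stop("start_interval_index out of range [0, ", n * length(seq$blocks) - 1, "]")
  k <- k %% n  # rotating the periodic stream == rotating the block pattern
  p <- seq$blocks[[1]]
  p_rot <- if (k == 0) p else c(p[(k + 1):n], p[1:k])
  build_sequence(seq$intervals, repeating = TRUE,
                 block_permutations = list(p_rot),
                 total_duration = seq$total_duration,
                 seq_id = paste0(seq$seq_id, "-cyc", start_interval_index))
}

#' Dilate a sequence in time
#'
#' Multiplies every inter-click interval by `factor` and truncates the click
#' train at the original total duration (complete clicks only), mirroring the
#' slowed stimuli that were cut at three seconds.
#'
#' @param seq A `click_sequence`.
#' @param factor Positive dilation factor (2 gives 22-80 ms intervals from
#'   the canonical set).
#' @return A `click_sequence` with the dilation recorded in its interval set.
#' @export
dilate <- function(seq, factor) {
  stopifnot(inherits(seq, "click_sequence"))
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("dilation factor must be a positive scalar")
  stream <- sequence_intervals(seq) * factor
  times <- c(0, cumsum(stream))
  keep <- times <= seq$total_duration
  iset2 <- interval_set(seq$intervals$intervals,
                        seq$intervals$dilation * factor)
  new_click_sequence(times[keep], iset2, seq$blocks, seq$repeating,
                     seq$total_duration,
                     if (factor == 1) seq$seq_id
                     else paste0(seq$seq_id, "-x", factor))
}

#' Binarize a click sequence into a bin-indicator vector
#'
#' Half-open bins `[b*delta, (b+1)*delta)`; a bin is 1 iff it contains at
#' least one click onset. This is the "normalized click stimulus" vector that
#' the similarity score correlates PSTHs against.
#'
#' @param seq A `click_sequence`.
#' @param bin_size Bin width in ms (canonical 5).
#' @return Integer 0/1 vector of length `ceiling(total_duration / bin_size)`.
#' @export
binarize <- function(seq, bin_size = 5) {
  stopifnot(inherits(seq, "click_sequence"))
  if (!is.numeric(bin_size) || bin_size <= 0) stop("bin_size must be > 0")
  n_bins <- ceiling(seq$total_duration / bin_size)
  v <- integer(n_bins)
  idx <- floor(seq$click_times / bin_size) + 1L
  idx <- idx[idx >= 1L & idx <= n_bins]
  v[unique(idx)] <- 1L
  v
}
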