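#' Signal-detection sensitivity d-prime
#'
#' `d' = z(H) - z(F)` with the standard normal quantile `z`. Extreme rates
#' are corrected by the 1/(2n) rule (0 -> 1/(2n), 1 -> 1 - 1/(2n)) so d'
#' stays finite on perfect days.
#'
#' @param H Hit rate (proportion of rewarded trials answered correctly).
#' @param F False-alarm rate.
#' @param n_reward,n_noreward Trial counts behind `H` and `F` (> 0).
#' @return d-prime (scalar).
#' @export
#' @examples
#' dprime(0.841345, 0.158655, 100, 100)  # ~2
dprime <- function(H, F, n_reward, n_noreward) {
  if (n_reward <= 0 || n_noreward <= 0) stop("trial counts must be > 0")
  clamp <- function(p, n) pmin(1 - 1 / (2 * n), pmax(1 / (2 * n), p))
  stats::qnorm(clamp(H, n_reward)) - stats::qnorm(clamp(F, n_noreward))
}

#' Classify reset-go trial outcomes
#'
#' Each trial receives exactly one primary outcome:
#' * `interruption` — trial-port access at least 200 ms after stimulus start
#'   and before stimulus end (resets the trial);
#' * `hit` — water-port access within the response window (playback plus
#'   `response_window_s` after stimulus end) on a rewarded trial;
#' * `false_alarm` — water-port access on a non-rewarded trial, or outside
#'   the response window on a rewarded one;
#' * `miss` / `correct_rejection` — otherwise, by reward class.
#' Interruption takes precedence when the trial-port event precedes any
#' water-port event.
#'
#' @param records Trial-log data.frame (see [simulate_trial_log()]): columns
#'   `rewarded`, list-columns `trial_port_times`, `water_port_times` (s from
#'   stimulus onset).
#' @param stimulus_duration_s Stimulus length (s), canonical 3.
#' @param response_window_s Response window after stimulus end (s),
#'   canonical 7.
#' @param interrupt_grace_s Earliest effective trial-port access (s),
#'   canonical 0.2.
#' @return `records` with an added `outcome` column.
#' @export
classify_trial_outcomes <- function(records, stimulus_duration_s = 3,
                                    response_window_s = 7,
                                    interrupt_grace_s = 0.2) {
  out <- character(nrow(records))
  win_end <- stimulus_duration_s + response_window_s
  for (i in seq_len(nrow(records))) {
    tp <- records$trial_port_times[[i]]
    wp <- records$water_port_times[[i]]
    if (any(!is.finite(c(tp, wp))) || any(c(tp, wp) < 0)) {
      out[i] <- NA_character_
      next
    }
    t_int <- tp[tp >= interrupt_grace_s & tp < stimulus_duration_s]
    t_int <- if (length(t_int)) min(t_int) else Inf
    t_wat <- if (length(wp)) min(wp) else Inf
    if (is.finite(t_int) && t_int < t_wat) {
      out[i] <- "interruption"
    } else if (records$rewarded[i]) {
      out[i] <- if (is.finite(t_wat) && t_wat <= win_end) "hit"
      else if (is.finite(t_wat)) "false_alarm"  # outside window
      else "miss"
    } else {
      out[i] <- if (is.finite(t_wat)) "false_alarm" else "correct_rejection"
    }
  }
  bad <- is.na(out)
  if (any(bad)) {
    message(sum(bad), " malformed trials rejected")
    records <- records[!bad, , drop = FALSE]
    out <- out[!bad]
  }
  records$outcome <- out
  records
}

behavior_rates <- function(records) {
  rw <- records[records$rewarded & records$catch_type == "none", ]
  nr <- records[!records$rewarded & records$catch_type == "none", ]
  n_r <- nrow(rw)
  n_n <- nrow(nr)
  H <- if (n_r) mean(rw$outcome == "hit") else NA_real_
  F <- if (n_n) mean(nr$outcome == "false_alarm") else NA_real_
  list(H = H, F = F, n_reward = n_r, n_noreward = n_n)
}

#' Trial-interruption ratio for a stimulus class
#'
#' Fraction of trials of the selected class interrupted before stimulus end,
#' with the across-day standard deviation (catch trials are analyzed through
#' this ratio, not through d').
#'
#' @param records Classified trial log (with `outcome`).
#' @param rewarded Select rewarded (`TRUE`) or non-rewarded (`FALSE`) trials.
#' @param catch_type `"none"`, `"reverse"` or `"cyclic"`.
#' @return List: `ratio`, `sd` (across days), `n`.
#' @export
interruption_ratio <- function(records, rewarded = FALSE,
                               catch_type = "none") {
  sel <- records$rewarded == rewarded & records$catch_type == catch_type
  if (!any(sel)) stop("no trials in the requested class")
  sub <- records[sel, ]
  per_day <- tapply(sub$outcome == "interruption", sub$day, mean)
  list(ratio = mean(sub$outcome == "interruption"),
       sd = stats::sd(per_day), n = nrow(sub))
}

#' Per-day d-prime learning curve
#'
#' Computes daily hit and false-alarm rates from classified outcomes
#' (catch trials excluded) and the day each bird first crosses the learning
#' criterion d' > 1.
#'
#' @param records Classified trial log.
#' @param criterion Learning criterion on d'.
#' @return List: `days` (data.frame `day`, `H`, `F`, `n_reward`,
#'   `n_noreward`, `d_prime`), `criterion_day` (first day above criterion,
#'   `NA` if never).
#' @export
learning_curve <- function(records, criterion = 1) {
  if (!"outcome" %in% names(records))
    records <- classify_trial_outcomes(records)
  days <- sort(unique(records$day))
  rows <- lapply(days, function(d) {
    r <- behavior_rates(records[records$day == d, ])
    dp <- if (r$n_reward > 0 && r$n_noreward > 0)
      dprime(r$H, r$F, r$n_reward, r$n_noreward) else NA_real_
    data.frame(day = d, H = r$H, F = r$F, n_reward = r$n_reward,
               n_noreward = r$n_noreward, d_prime = dp)
  })
  tab <- do.call(rbind, rows)
  cross <- which(tab$d_prime > criterion)
  list(days = tab,
       criterion_day = if (length(cross)) tab$day[min(cross)] else NA_real_)
}

#' Port-access probability map over training
#'
#' Per-day histograms of event times at one port, normalized to a
#' probability distribution per day — the trial-time x training-day map
#' whose asymmetry between rewarded and non-rewarded trials reveals
#' learning.
#'
#' @param records Trial log.
#' @param port `"trial"` or `"water"`.
#' @param rewarded Restrict to rewarded (`TRUE`) / non-rewarded (`FALSE`)
#'   trials; `NULL` for all.
#' @param t_max Map extent (s from stimulus onset).
#' @param bin Time bin (s).
#' @return List: `map` (days x bins matrix; rows sum to 1 or are flagged),
#'   `empty_days` (days with no events), `breaks`.
#' @export
port_access_map <- function(records, port = c("trial", "water"),
                            rewarded = NULL, t_max = 10, bin = 0.25) {
  port <- match.arg(port)
  col <- paste0(port, "_port_times")
  if (!is.null(rewarded)) records <- records[records$rewarded == rewarded, ]
  days <- sort(unique(records$day))
  breaks <- seq(0, t_max, by = bin)
  map <- matrix(0, length(days), length(breaks) - 1,
                dimnames = list(paste0("day", days), NULL))
  empty <- logical(length(days))
  for (i in seq_along(days)) {
    ev <- unlist(records[[col]][records$day == days[i]])
    ev <- ev[ev >= 0 & ev < t_max]
    if (!length(ev)) { empty[i] <- TRUE; next }
    h <- graphics::hist(ev, breaks = breaks, plot = FALSE)
    map[i, ] <- h$counts / sum(h$counts)
  }
  list(map = map, empty_days = days[empty], breaks = breaks)
}
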