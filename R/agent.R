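#' Parameters of a simulated reset-go learner
#'
#' A stochastic agent for the reset-go task. Each probability may be a
#' scalar (stationary agent) or a vector over training days (a learning
#' trajectory). On a non-rewarded trial the agent interrupts playback with
#' probability `p_interrupt_nonrew` (at a uniform time within the
#' interruptable span); on rewarded trials it accesses the water port with
#' probability `p_water_rew`. Catch trials use `p_interrupt_catch`, which
#' defaults to `p_interrupt_nonrew` (an agent that treats the catch pattern
#' like the familiar one); set it lower to model a bird that does not
#' recognize the transformed pattern.
#'
#' @param p_interrupt_nonrew,p_interrupt_rew Per-trial interruption
#'   probabilities by reward class.
#' @param p_water_rew,p_water_nonrew Water-port access probabilities.
#' @param p_interrupt_catch Interruption probability on catch trials
#'   (default: same as non-rewarded).
#' @param interrupt_span Uniform support of interruption times (s), within
#'   the 200-ms-to-stimulus-end rule.
#' @param water_span Uniform support of water-access times (s from onset);
#'   canonical within playback plus the 7-s response window.
#' @return An `agent_params`.
#' @export
agent_params <- function(p_interrupt_nonrew = 0.1, p_interrupt_rew = 0.1,
                         p_water_rew = 0.5, p_water_nonrew = 0.5,
                         p_interrupt_catch = NULL,
                         interrupt_span = c(0.25, 2.9),
                         water_span = c(0.5, 6)) {
  ps <- list(p_interrupt_nonrew = p_interrupt_nonrew,
             p_interrupt_rew = p_interrupt_rew,
             p_water_rew = p_water_rew, p_water_nonrew = p_water_nonrew,
             p_interrupt_catch = p_interrupt_catch %||% p_interrupt_nonrew)
  for (nm in names(ps))
    if (any(ps[[nm]] < 0 | ps[[nm]] > 1))
      stop(nm, " must lie in [0, 1]")
  structure(c(ps, list(interrupt_span = interrupt_span,
                       water_span = water_span)),
            class = "agent_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

day_p <- function(p, day) p[min(day, length(p))]

#' Simulate a reset-go operant trial log
#'
#' Draws per-trial port events from an agent model over a training schedule.
#' A fraction `p_catch` of non-rewarded trials is replaced by catch trials
#' of the given type (canonical 10% reverse-pattern probes).
#'
#' @param params An `agent_params`; vector-valued probabilities index days.
#' @param n_days Training days.
#' @param trials_per_day Trials per day.
#' @param p_reward Fraction of rewarded trials (canonical 0.2 in shaping,
#'   0.5 in balanced testing).
#' @param p_catch Fraction of non-rewarded trials flagged as catch.
#' @param catch_type `"reverse"` or `"cyclic"`.
#' @param stimulus_ids Named ids (`rewarded`, `nonrewarded`).
#' @param seed Seed.
#' @return A trial-log data.frame: `day`, `trial_index`, `stimulus_id`,
#'   `rewarded`, `catch_type`, list-columns `trial_port_times`,
#'   `water_port_times` (s from stimulus onset).
#' @export
simulate_trial_log <- function(params, n_days = 1, trials_per_day = 500,
                               p_reward = 0.5, p_catch = 0,
                               catch_type = c("reverse", "cyclic"),
                               stimulus_ids = c(rewarded = "seq2",
                                                nonrewarded = "seq1"),
                               seed = 1) {
  stopifnot(inherits(params, "agent_params"))
  catch_type <- match.arg(catch_type)
  with_seed(seed, {
    rows <- vector("list", n_days * trials_per_day)
    k <- 0
    for (day in seq_len(n_days)) {
      for (i in seq_len(trials_per_day)) {
        k <- k + 1
        rewarded <- stats::runif(1) < p_reward
        catch <- !rewarded && stats::runif(1) < p_catch
        p_int <- if (catch) day_p(params$p_interrupt_catch, day)
        else if (rewarded) day_p(params$p_interrupt_rew, day)
        else day_p(params$p_interrupt_nonrew, day)
        p_wat <- if (rewarded) day_p(params$p_water_rew, day)
        else day_p(params$p_water_nonrew, day)
        tp <- wp <- numeric(0)
        if (stats::runif(1) < p_int) {
          tp <- stats::runif(1, params$interrupt_span[1],
                             params$interrupt_span[2])
        } else if (stats::runif(1) < p_wat) {
          wp <- stats::runif(1, params$water_span[1], params$water_span[2])
        }
        rows[[k]] <- list(day = day, trial_index = i,
                          stimulus_id = unname(
                            if (rewarded) stimulus_ids[["rewarded"]]
                            else stimulus_ids[["nonrewarded"]]),
                          rewarded = rewarded,
                          catch_type = if (catch) catch_type else "none",
                          trial_port_times = list(tp),
                          water_port_times = list(wp))
      }
    }
    log <- data.frame(day = vapply(rows, `[[`, numeric(1), "day"),
                      trial_index = vapply(rows, `[[`, numeric(1),
                                           "trial_index"),
                      stimulus_id = vapply(rows, `[[`, character(1),
                                           "stimulus_id"),
                      rewarded = vapply(rows, `[[`, logical(1), "rewarded"),
                      catch_type = vapply(rows, `[[`, character(1),
                                          "catch_type"),
                      stringsAsFactors = FALSE)
    log$trial_port_times <- lapply(rows, function(r) r$trial_port_times[[1]])
    log$water_port_times <- lapply(rows, function(r) r$water_port_times[[1]])
    log
  })
}

#' Write / read a trial log as CSV
#'
#' Event-time list-columns are serialized as semicolon-joined strings.
#'
#' @param log Trial-log data.frame.
#' @param path CSV path.
#' @return `path` (write) or the trial log (read).
#' @export
write_trial_log <- function(log, path) {
  out <- log
  out$trial_port_times <- vapply(log$trial_port_times, paste,
                                 character(1), collapse = ";")
  out$water_port_times <- vapply(log$water_port_times, paste,
                                 character(1), collapse = ";")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(trial_port_times = "character",
                                      water_port_times = "character"))
  parse_times <- function(s) lapply(strsplit(s, ";", fixed = TRUE),
                                    function(v) as.numeric(v[nzchar(v)]))
  x$trial_port_times <- parse_times(x$trial_port_times)
  x$water_port_times <- parse_times(x$water_port_times)
  x
}
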