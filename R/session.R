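#' @useDynLib ciglm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aov aggregate coef glm.control glm.fit p.adjust pchisq
#'   pnorm poisson printCoefmat qnorm runif sd setNames t.test dpois fitted
#'   residuals
#' @importFrom utils read.csv write.csv
NULL

#' Behavioral interval labels of the T-maze task
#'
#' The six ordered intervals that tile each trial, from placement of the
#' animal in the start box to its removal from the maze, plus the two
#' composite windows used by the interaction models: \code{ExtendedDelay}
#' (Pickup together with the following Delay, both plausibly part of the
#' mnemonic delay) and \code{Response} (the contiguous Run-Branch-Choice
#' navigation epoch).
#'
#' @format Character vectors.
#' @name interval_labels
NULL

#' @rdname interval_labels
#' @export
INTERVALS <- c("Delay", "Run", "Branch", "Choice", "Reward", "Pickup")

#' @rdname interval_labels
#' @export
COMPOSITES <- list(
  ExtendedDelay = c("Pickup", "Delay"),
  Response      = c("Run", "Branch", "Choice")
)

TRIAL_COLS <- c("trial_index", "condition", "arm", "correct",
                "t_startbox", "t_gate", "t_branch", "t_choice",
                "t_reward", "t_pickup")

#' Construct a T-maze recording session
#'
#' A session holds the behavioral timeline of one testing session (41 trials
#' in a paper-faithful session, one condition per session) and the sorted
#' spike trains recorded during it, on a single session clock in seconds.
#'
#' @param session_id Character identifier.
#' @param condition \code{"baseline"} or \code{"stress"}.
#' @param trials Data frame with columns \code{trial_index}, \code{condition},
#'   \code{arm} (\code{"left"}/\code{"right"}), \code{correct} (logical), and
#'   event times \code{t_startbox}, \code{t_gate}, \code{t_branch},
#'   \code{t_choice}, \code{t_reward} (\code{NA} on incorrect trials),
#'   \code{t_pickup}, all in seconds.
#' @param spikes Named list of numeric vectors: strictly ascending spike times
#'   per unit.
#' @param noise_db White-noise level of the session (dB); informational.
#' @param delay_length_s Imposed delay duration in seconds.
#' @param pickup_tail_s Duration of the final trial's Pickup interval, which
#'   has no following trial to close it (default 5 s).
#' @return An object of class \code{tmaze_session}.
#' @seealso [read_session()], [derive_intervals()], [correct_trials()]
#' @export
tmaze_session <- function(session_id, condition, trials, spikes,
                          noise_db = NA_real_, delay_length_s = NA_real_,
                          pickup_tail_s = 5) {
  x <- structure(list(
    session_id = as.character(session_id),
    condition = match.arg(condition, c("baseline", "stress")),
    noise_db = as.numeric(noise_db),
    delay_length_s = as.numeric(delay_length_s),
    pickup_tail_s = as.numeric(pickup_tail_s),
    trials = trials,
    spikes = spikes
  ), class = "tmaze_session")
  validate_session(x)
  x
}

#' Validate a session against its invariants
#'
#' Checks event ordering within trials (\code{t_startbox < t_gate < t_branch
#' < t_choice < t_pickup}, with \code{t_choice < t_reward < t_pickup} when the
#' reward is present), monotonicity across trials, presence of the reward time
#' exactly on correct trials, and strict ascent of each spike train within the
#' session span.
#'
#' @param x A \code{tmaze_session}.
#' @param file Optional file name used to prefix error messages.
#' @return \code{x}, invisibly; errors describe the violated invariant.
#' @export
validate_session <- function(x, file = NULL) {
  where <- if (is.null(file)) "" else paste0(file, ": ")
  tr <- x$trials
  miss <- setdiff(TRIAL_COLS, names(tr))
  if (length(miss))
    stop(where, "trial table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(tr$condition %in% c("baseline", "stress")))
    stop(where, "unknown condition in trial table (row ",
         which(!tr$condition %in% c("baseline", "stress"))[1], ")")
  if (!all(tr$arm %in% c("left", "right")))
    stop(where, "unknown arm in trial table (row ",
         which(!tr$arm %in% c("left", "right"))[1], ")")
  for (i in seq_len(nrow(tr))) {
    ev <- unlist(tr[i, c("t_startbox", "t_gate", "t_branch", "t_choice",
                         "t_pickup")])
    if (any(diff(ev) <= 0))
      stop(where, "trial table row ", i, ": event times violate ordering ",
           "t_startbox < t_gate < t_branch < t_choice < t_pickup")
    if (isTRUE(tr$correct[i])) {
      if (is.na(tr$t_reward[i]))
        stop(where, "trial table row ", i,
             ": correct trial lacks t_reward")
      if (!(tr$t_choice[i] < tr$t_reward[i] && tr$t_reward[i] < tr$t_pickup[i]))
        stop(where, "trial table row ", i,
             ": t_reward must satisfy t_choice < t_reward < t_pickup")
    }
  }
  if (nrow(tr) > 1 && any(diff(tr$t_startbox) <= 0))
    stop(where, "trial start times must strictly increase across trials")
  if (nrow(tr) > 1 && any(tr$t_startbox[-1] < tr$t_pickup[-nrow(tr)]))
    stop(where, "trials overlap: a trial starts before the previous pickup")
  span <- session_span(x)
  for (u in names(x$spikes)) {
    s <- x$spikes[[u]]
    if (length(s) > 1 && any(diff(s) <= 0))
      stop(where, "spike train for unit ", u, " is not strictly increasing")
    if (length(s) && (min(s) < span[1] || max(s) >= span[2]))
      stop(where, "spike train for unit ", u, " has times outside the ",
           "session span [", span[1], ", ", span[2], ")")
  }
  invisible(x)
}

#' Session span
#'
#' The half-open time window covered by a session: from the first trial's
#' start-box placement to the end of the last Pickup interval.
#'
#' @param x A \code{tmaze_session}.
#' @return Numeric length-2 vector \code{c(start, end)} in seconds.
#' @export
session_span <- function(x) {
  tr <- x$trials
  tail_s <- if (is.na(x$pickup_tail_s)) 5 else x$pickup_tail_s
  c(tr$t_startbox[1], tr$t_pickup[nrow(tr)] + tail_s)
}

#' @export
print.tmaze_session <- function(x, ...) {
  cat("T-maze session", x$session_id, sprintf("(%s)", x$condition), "\n")
  cat("  trials:", nrow(x$trials),
      sprintf("(%d correct)", sum(x$trials$correct)),
      " delay:", x$delay_length_s, "s\n")
  cat("  units:", length(x$spikes), " spikes:",
      sum(lengths(x$spikes)), "\n")
  invisible(x)
}

#' Read a session from plain tabular files
#'
#' @param spike_table CSV with columns \code{unit_id}, \code{time_s}
#'   (ascending within unit).
#' @param trial_table CSV with the trial columns documented in
#'   [tmaze_session()]; \code{t_reward} blank on incorrect trials.
#' @param meta JSON with \code{session_id}, \code{condition}, \code{noise_db},
#'   \code{delay_length_s}, \code{pickup_tail_s}.
#' @return A validated \code{tmaze_session}.
#' @export
read_session <- function(spike_table, trial_table, meta) {
  for (f in c(spike_table, trial_table, meta))
    if (!file.exists(f)) stop("file not found: ", f)
  sp <- read.csv(spike_table, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "time_s") %in% names(sp)))
    stop(spike_table, ": expected columns unit_id, time_s")
  tr <- read.csv(trial_table, stringsAsFactors = FALSE)
  if (!all(TRIAL_COLS %in% names(tr)))
    stop(trial_table, ": lacks columns ",
         paste(setdiff(TRIAL_COLS, names(tr)), collapse = ", "))
  tr <- tr[TRIAL_COLS]
  tr$correct <- as.logical(tr$correct)
  tr$t_reward <- suppressWarnings(as.numeric(tr$t_reward))
  md <- jsonlite::fromJSON(meta)
  spikes <- split(sp$time_s, sp$unit_id)
  spikes <- lapply(spikes, as.numeric)
  x <- structure(list(
    session_id = as.character(md$session_id),
    condition = as.character(md$condition),
    noise_db = as.numeric(md$noise_db),
    delay_length_s = as.numeric(md$delay_length_s),
    pickup_tail_s = as.numeric(md$pickup_tail_s),
    trials = tr, spikes = spikes
  ), class = "tmaze_session")
  if (!x$condition %in% c("baseline", "stress"))
    stop(meta, ": unknown condition '", x$condition, "'")
  validate_session(x, file = trial_table)
  x
}

#' Write a session to plain tabular files
#'
#' Inverse of [read_session()]: writes \code{spikes.csv}, \code{trials.csv}
#' and \code{session.json} under \code{dir}.
#'
#' @param x A \code{tmaze_session}.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_session <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- data.frame(
    unit_id = rep(names(x$spikes), lengths(x$spikes)),
    time_s = unlist(x$spikes, use.names = FALSE)
  )
  write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  write.csv(x$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(session_id = x$session_id, condition = x$condition,
         noise_db = x$noise_db, delay_length_s = x$delay_length_s,
         pickup_tail_s = x$pickup_tail_s),
    file.path(dir, "session.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Derive the labeled behavioral intervals of one trial
#'
#' Maps the scored event times onto the six half-open intervals that tile a
#' trial: Delay \code{[t_startbox, t_gate)}, Run \code{[t_gate, t_branch)},
#' Branch \code{[t_branch, t_choice)}, Choice, Reward and Pickup. On correct
#' trials Choice ends at \code{t_reward} and Reward runs to \code{t_pickup};
#' incorrect trials have no Reward interval and Choice extends to
#' \code{t_pickup}. The Pickup interval ends at \code{pickup_end}, normally
#' the next trial's \code{t_startbox}.
#'
#' @param trial One-row data frame (or list) with the trial event fields.
#' @param pickup_end End of the Pickup interval, seconds.
#' @return Data frame with columns \code{trial_index}, \code{label},
#'   \code{start}, \code{end}.
#' @export
derive_intervals <- function(trial, pickup_end = trial$t_pickup + 5) {
  if (isTRUE(trial$correct) && is.na(trial$t_reward))
    stop("correct trial ", trial$trial_index, " lacks t_reward")
  if (isTRUE(trial$correct)) {
    starts <- c(trial$t_startbox, trial$t_gate, trial$t_branch,
                trial$t_choice, trial$t_reward, trial$t_pickup)
    labs <- INTERVALS
  } else {
    starts <- c(trial$t_startbox, trial$t_gate, trial$t_branch,
                trial$t_choice, trial$t_pickup)
    labs <- INTERVALS[-5]
  }
  ends <- c(starts[-1], pickup_end)
  if (any(ends <= starts)) stop("trial ", trial$trial_index,
                                ": non-positive interval duration")
  data.frame(trial_index = trial$trial_index, label = labs,
             start = starts, end = ends, stringsAsFactors = FALSE)
}

#' Derive the labeled intervals of every trial in a session
#'
#' Each trial's Pickup interval is closed by the following trial's start-box
#' time; the final trial uses the session's \code{pickup_tail_s}. The result
#' tiles the session span with no gaps or overlaps.
#'
#' @param x A \code{tmaze_session}.
#' @return Data frame as in [derive_intervals()], all trials concatenated.
#' @export
session_intervals <- function(x) {
  tr <- x$trials
  n <- nrow(tr)
  ends <- c(tr$t_startbox[-1], session_span(x)[2])
  out <- lapply(seq_len(n), function(i)
    derive_intervals(tr[i, ], pickup_end = ends[i]))
  do.call(rbind, out)
}

#' Restrict a session to analyzed (correct) trials
#'
#' Analyses of spiking activity are limited to correctly executed trials, and
#' the first trial of each session (always rewarded by task design) is never
#' analyzed.
#'
#' @param x A \code{tmaze_session}.
#' @param drop_first Drop trial 1 (default \code{TRUE}).
#' @return The session with its trial table filtered; spike trains are kept
#'   untouched so history covariates can still be computed over continuous
#'   session time.
#' @export
correct_trials <- function(x, drop_first = TRUE) {
  keep <- x$trials$correct
  if (drop_first) keep <- keep & x$trials$trial_index != 1L
  x$trials <- x$trials[keep, , drop = FALSE]
  rownames(x$trials) <- NULL
  x
}

#' Classify a unit from its extracellular waveform width
#'
#' Peak-to-peak (P-P) waveform duration separates putative pyramidal
#' wide-spike (WS) cells from narrow-spike (NS) cells: P-P above 200 us is
#' WS; 100-200 us is NS; anything narrower is rejected. Only WS units enter
#' the conditional-intensity analyses.
#'
#' @param pp_duration_us Peak-to-peak duration in microseconds.
#' @return \code{"WS"}, \code{"NS"} or \code{"rejected"} (vectorized).
#' @export
classify_unit <- function(pp_duration_us) {
  if (any(!is.finite(pp_duration_us)) || any(pp_duration_us <= 0))
    stop("pp_duration_us must be positive and finite")
  ifelse(pp_duration_us > 200, "WS",
         ifelse(pp_duration_us >= 100, "NS", "rejected"))
}

#' Indicator of a composite behavioral window
#'
#' Evaluates, at query times, the 0/1 indicator of the union of the
#' constituent intervals of a composite label: \code{ExtendedDelay} is
#' Pickup together with Delay; \code{Response} is Run, Branch and Choice.
#'
#' @param intervals Interval table from [session_intervals()].
#' @param label \code{"ExtendedDelay"} or \code{"Response"}.
#' @param at Numeric query times (seconds).
#' @return Numeric 0/1 vector, one entry per query time.
#' @export
composite_mask <- function(intervals, label, at) {
  if (!label %in% names(COMPOSITES))
    stop("'", label, "' is not a composite label; expected one of ",
         paste(names(COMPOSITES), collapse = ", "))
  parts <- intervals[intervals$label %in% COMPOSITES[[label]], , drop = FALSE]
  out <- numeric(length(at))
  for (i in seq_len(nrow(parts)))
    out[at >= parts$start[i] & at < parts$end[i]] <- 1
  out
}
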