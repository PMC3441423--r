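#' Ground-truth parameters of the generative conditional intensity
#'
#' The generator draws spikes from the same log-linear conditional intensity
#' the fitting side estimates: log expected count per observation bin equals
#' \code{mu + beta*S + B[interval] + sum_k a_k * N_k}, where \code{S} is the
#' stress indicator, \code{B} are interval effects relative to the Delay
#' reference, and \code{N_k} is the spike count in the k-th lagged history
#' window of width \code{history_bin}. The history log-gains are \code{alpha}
#' under baseline and \code{eta} under stress.
#'
#' Defaults emulate a sparsely firing wide-spike prefrontal unit whose
#' history gains decay from 1.5 to 1.05 across the 2.5 s history span and are
#' uniformly suppressed by 10\% under stress. The background rate (0.12 Hz)
#' is deliberately low: with gains of this magnitude the self-exciting
#' process sits close to criticality, and larger backgrounds produce
#' run-away intensities (see the methods vignette).
#'
#' @param mu Log mean count per observation bin (default \code{log(0.03)},
#'   i.e. 0.12 Hz at 250 ms bins).
#' @param beta Stress log rate-ratio.
#' @param B Named numeric vector of interval log rate-ratios over
#'   \code{INTERVALS}; the Delay entry is the reference and must be 0.
#' @param alpha,eta Numeric vectors of history log-gains (baseline, stress);
#'   equal length defines the autoregressive order.
#' @param history_bin Width of one history lag, seconds.
#' @param history_scope \code{"global"} (history acts everywhere) or a
#'   composite label (\code{"ExtendedDelay"}/\code{"Response"}): history gains
#'   then apply only inside that window and are zero elsewhere, the
#'   generative counterpart of the interaction models.
#' @return A \code{truth_params} list.
#' @export
truth_params <- function(mu = log(0.03),
                         beta = log(1.1),
                         B = c(Delay = 0, Run = 0.1, Branch = 0.1,
                               Choice = 0.1, Reward = 0.1, Pickup = 0.05),
                         alpha = log(seq(1.5, 1.05, length.out = 10)),
                         eta = log(0.9 * seq(1.5, 1.05, length.out = 10)),
                         history_bin = 0.25,
                         history_scope = "global") {
  if (length(alpha) != length(eta))
    stop("alpha and eta must have the same length (the history order)")
  if (history_bin <= 0) stop("history_bin must be positive")
  if (!setequal(names(B), INTERVALS))
    stop("B must be named over the six interval labels")
  if (B[["Delay"]] != 0)
    stop("Delay is the reference interval; B['Delay'] must be 0")
  if (!history_scope %in% c("global", names(COMPOSITES)))
    stop("history_scope must be 'global' or a composite label")
  structure(list(mu = mu, beta = beta, B = B[INTERVALS],
                 alpha = alpha, eta = eta,
                 order = length(alpha), history_bin = history_bin,
                 history_scope = history_scope),
            class = "truth_params")
}

#' Configuration of the synthetic-session generator
#'
#' Describes the behavioral structure of a simulated testing day: number of
#' trials per session (41, the first of which is rewarded by design and not
#' analyzed), the imposed delay, the stochastic durations of the remaining
#' behavioral intervals, and the per-trial error rate.
#'
#' @param n_trials Trials per session.
#' @param delay_length_s Imposed delay, seconds (task range 10-40 s).
#' @param durations Named list of \code{c(mean, jitter)} pairs (seconds) for
#'   Run, Branch, Choice, Reward and Pickup; realized durations are uniform
#'   on mean +/- jitter. Delay is exact.
#' @param error_rate Probability a trial (after the first) is an incorrect
#'   repeat of the previous arm.
#' @param sim_resolution Fine simulation step, seconds (default 5 ms, the
#'   PETH bin width).
#' @param seed Integer seed; one seed governs a whole cohort, with fixed
#'   per-unit offsets.
#' @param n_units Number of simulated units (one baseline + one stress
#'   session each).
#' @param truth A [truth_params()] object, or a list of one per unit.
#' @return A \code{generator_config} list.
#' @export
generator_config <- function(n_trials = 41,
                             delay_length_s = 10,
                             durations = list(Run = c(2, 0.4),
                                              Branch = c(1.5, 0.3),
                                              Choice = c(2.5, 0.5),
                                              Reward = c(4, 0.8),
                                              Pickup = c(8, 1.6)),
                             error_rate = 0,
                             sim_resolution = 0.005,
                             seed = 1L,
                             n_units = 1L,
                             truth = truth_params()) {
  stopifnot(n_trials >= 1, delay_length_s > 0, error_rate >= 0,
            error_rate <= 1, sim_resolution > 0, n_units >= 1)
  if (any(vapply(durations, function(d) d[1] - d[2] <= 0, TRUE)))
    stop("interval durations must stay positive under jitter")
  tr <- if (inherits(truth, "truth_params")) list(truth) else truth
  for (t in tr) {
    if (!inherits(t, "truth_params")) stop("truth must be truth_params")
    if (sim_resolution > t$history_bin)
      stop("sim_resolution must not exceed the history bin")
  }
  structure(list(n_trials = as.integer(n_trials),
                 delay_length_s = delay_length_s, durations = durations,
                 error_rate = error_rate, sim_resolution = sim_resolution,
                 seed = as.integer(seed), n_units = as.integer(n_units),
                 truth = truth),
            class = "generator_config")
}

#' Draw the behavioral timeline of one session
#'
#' Trials alternate T-maze arms; with probability \code{error_rate} a trial
#' is an incorrect repeat of the previously visited arm (no reward, no
#' Reward interval). The first trial is always rewarded. Event times are
#' strictly ordered and the Delay interval has exactly the configured
#' length. Uses the current RNG state.
#'
#' @param cfg A [generator_config()].
#' @param condition Session condition label for the trial table.
#' @return Trial-event data frame suitable for [tmaze_session()].
#' @export
make_trial_plan <- function(cfg, condition = "baseline") {
  n <- cfg$n_trials
  draw <- function(nm) {
    d <- cfg$durations[[nm]]
    runif(1, d[1] - d[2], d[1] + d[2])
  }
  arm <- character(n); correct <- logical(n)
  arm[1] <- sample(c("left", "right"), 1); correct[1] <- TRUE
  for (i in seq_len(n)[-1]) {
    correct[i] <- runif(1) >= cfg$error_rate
    arm[i] <- if (correct[i]) setdiff(c("left", "right"), arm[i - 1]) else
      arm[i - 1]
  }
  t0 <- 0
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    t_sb <- t0
    t_gate <- t_sb + cfg$delay_length_s
    t_branch <- t_gate + draw("Run")
    t_choice <- t_branch + draw("Branch")
    if (correct[i]) {
      t_reward <- t_choice + draw("Choice")
      t_pickup <- t_reward + draw("Reward")
    } else {
      t_reward <- NA_real_
      t_pickup <- t_choice + draw("Choice") + draw("Reward")
    }
    t0 <- t_pickup + draw("Pickup")
    rows[[i]] <- data.frame(trial_index = i, condition = condition,
                            arm = arm[i], correct = correct[i],
                            t_startbox = t_sb, t_gate = t_gate,
                            t_branch = t_branch, t_choice = t_choice,
                            t_reward = t_reward, t_pickup = t_pickup,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate one spike train from the generative conditional intensity
#'
#' Discrete-time Bernoulli thinning on a fine grid: at each step the
#' intensity is \code{exp(mu + beta*S + B[interval] + sum_k a_k N_k) /
#' obs_bin}, with the lagged counts \code{N_k} maintained online over
#' continuous session time (crossing trial and interval boundaries), and a
#' spike drawn with probability intensity times step width. Errors if that
#' probability reaches 1, which signals a run-away self-exciting intensity.
#'
#' @param plan Trial-event data frame from [make_trial_plan()].
#' @param truth A [truth_params()].
#' @param condition \code{"baseline"} or \code{"stress"}.
#' @param pickup_tail_s Tail closing the last Pickup interval, seconds.
#' @param sim_resolution Fine step, seconds.
#' @param obs_bin Observation bin the intensity is referenced to, seconds.
#' @return Numeric vector of spike times (session clock, seconds).
#' @export
simulate_spike_train <- function(plan, truth, condition = "baseline",
                                 pickup_tail_s = 5, sim_resolution = 0.005,
                                 obs_bin = 0.25) {
  condition <- match.arg(condition, c("baseline", "stress"))
  dt <- sim_resolution
  t0 <- plan$t_startbox[1]
  t_end <- plan$t_pickup[nrow(plan)] + pickup_tail_s
  n_steps <- as.integer(floor((t_end - t0) / dt))  # last partial step unused
  step_t <- t0 + (seq_len(n_steps) - 1) * dt
  ivs <- do.call(rbind, lapply(seq_len(nrow(plan)), function(i)
    derive_intervals(plan[i, ],
                     pickup_end = if (i < nrow(plan)) plan$t_startbox[i + 1]
                                  else t_end)))
  lab <- ivs$label[findInterval(step_t, ivs$start)]
  base <- truth$mu + (condition == "stress") * truth$beta +
    unname(truth$B[lab])
  a <- if (condition == "stress") truth$eta else truth$alpha
  if (truth$history_scope == "global") {
    grp <- rep(1L, n_steps)
    co <- matrix(a, ncol = 1)
  } else {
    inside <- composite_mask(ivs, truth$history_scope, step_t)
    grp <- ifelse(inside > 0, 1L, 2L)
    co <- cbind(a, rep(0, truth$order))
  }
  t0 + thinning_sim(base, grp, co, dt, obs_bin, truth$history_bin)
}

#' Simulate a baseline session for one unit
#'
#' Convenience wrapper drawing a trial plan and a spike train and packaging
#' them as a [tmaze_session()].
#'
#' @param cfg A [generator_config()].
#' @param truth A [truth_params()].
#' @param condition Session condition.
#' @param session_id,unit_id Identifiers for the returned session.
#' @return A \code{tmaze_session} with one spike train.
#' @export
simulate_session <- function(cfg, truth = cfg$truth[[1]],
                             condition = "baseline",
                             session_id = paste0("sim-", condition),
                             unit_id = "u1") {
  if (inherits(cfg$truth, "truth_params") && missing(truth))
    truth <- cfg$truth
  plan <- make_trial_plan(cfg, condition)
  spk <- simulate_spike_train(plan, truth, condition,
                              pickup_tail_s = 5,
                              sim_resolution = cfg$sim_resolution)
  tmaze_session(session_id, condition, plan,
                spikes = setNames(list(spk), unit_id),
                noise_db = if (condition == "stress") 93 else 60,
                delay_length_s = cfg$delay_length_s,
                pickup_tail_s = 5)
}

#' Simulate a cohort of units, one baseline and one stress session each
#'
#' Each unit gets an independent baseline and stress session drawn from the
#' shared trial-structure distributions and its own ground-truth parameters.
#' Reproducibility: the cohort seed plus a fixed per-unit offset seeds each
#' unit's substream, so the same configuration and seed give byte-identical
#' cohorts. If a unit's simulation trips the run-away intensity guard (rare
#' at the default parameters), that unit is redrawn from a deterministically
#' bumped substream, up to five times, and the retry is recorded.
#'
#' @param cfg A [generator_config()]; \code{cfg$truth} may be a single
#'   [truth_params()] (shared) or a list of one per unit.
#' @return List with one element per unit: \code{baseline} and \code{stress}
#'   sessions, the unit's \code{truth}, and \code{retries}. The truth list is
#'   also attached as attribute \code{"truth"} for recovery tests.
#' @export
simulate_cohort <- function(cfg) {
  truths <- if (inherits(cfg$truth, "truth_params"))
    rep(list(cfg$truth), cfg$n_units) else cfg$truth
  if (length(truths) != cfg$n_units)
    stop("need one truth_params per unit")
  out <- vector("list", cfg$n_units)
  for (u in seq_len(cfg$n_units)) {
    uid <- sprintf("u%02d", u)
    sess <- list()
    retries <- 0L
    for (cond in c("baseline", "stress")) {
      off <- if (cond == "stress") 1L else 0L
      for (attempt in 0:5) {
        set.seed(cfg$seed + 101L * u + off + 13L * attempt)
        s <- try(simulate_session(cfg, truths[[u]], cond,
                                  session_id = sprintf("%s-%s", uid, cond),
                                  unit_id = uid), silent = TRUE)
        if (!inherits(s, "try-error")) break
        retries <- retries + 1L
        if (attempt == 5)
          stop("unit ", uid, " (", cond, "): simulation failed after ",
               "5 retries: ", attr(s, "condition")$message)
      }
      sess[[cond]] <- s
    }
    if (retries > 0)
      warning("unit ", uid, ": ", retries,
              " run-away simulation(s) redrawn from a bumped substream")
    out[[u]] <- list(baseline = sess$baseline, stress = sess$stress,
                     truth = truths[[u]], retries = retries)
  }
  attr(out, "truth") <- truths
  attr(out, "config") <- cfg
  out
}

#' Write a simulated cohort to disk in the session file formats
#'
#' One directory per unit and session (\code{<unit>/<condition>/} holding
#' \code{spikes.csv}, \code{trials.csv}, \code{session.json}), plus
#' \code{truth.json} recording every unit's generative parameters for
#' parameter-recovery checks.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truths <- lapply(cohort, function(u) unclass(u$truth))
  names(truths) <- vapply(cohort, function(u) u$baseline$session_id, "")
  jsonlite::write_json(truths, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  for (u in cohort) {
    uid <- names(u$baseline$spikes)[1]
    write_session(u$baseline, file.path(dir, uid, "baseline"))
    write_session(u$stress, file.path(dir, uid, "stress"))
  }
  invisible(dir)
}
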