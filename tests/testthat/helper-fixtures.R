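# Fixtures built in code: a hand-written two-trial session with known
# event times, and small simulated cohorts.

# Trial rows at fixed times. Trial 1: events 0,10,12,13,14,20 (correct).
# Trial 2 starts at 26: events 26,36,38,39,(40),41 — correctness settable.
make_tiny_trials <- function(correct2 = TRUE) {
  data.frame(
    trial_index = 1:2,
    condition = "baseline",
    arm = c("left", "right"),
    correct = c(TRUE, correct2),
    t_startbox = c(0, 26),
    t_gate = c(10, 36),
    t_branch = c(12, 38),
    t_choice = c(13, 39),
    t_reward = c(14, if (correct2) 40 else NA),
    t_pickup = c(20, 41),
    stringsAsFactors = FALSE
  )
}

make_tiny_session <- function(spikes = c(1.0, 11.5, 30.2), correct2 = TRUE,
                              condition = "baseline") {
  tr <- make_tiny_trials(correct2)
  tr$condition <- condition
  tmaze_session("tiny", condition, tr,
                spikes = list(u1 = spikes),
                noise_db = if (condition == "stress") 93 else 60,
                delay_length_s = 10, pickup_tail_s = 5)
}

# A session whose span and bins are trivial to reason about:
# one trial tiling [0, t_end) with given event times.
make_span_session <- function(spikes, events = c(0, 0.2, 0.3, 0.4, 0.5, 0.55),
                              tail = 0.2, condition = "baseline") {
  tr <- data.frame(trial_index = 1L, condition = condition, arm = "left",
                   correct = TRUE,
                   t_startbox = events[1], t_gate = events[2],
                   t_branch = events[3], t_choice = events[4],
                   t_reward = events[5], t_pickup = events[6],
                   stringsAsFactors = FALSE)
  tmaze_session("span", condition, tr, spikes = list(u1 = spikes),
                delay_length_s = events[2] - events[1], pickup_tail_s = tail)
}

# Homogeneous Poisson spikes over [0, t_end) at `rate` Hz (base R draw).
poisson_train <- function(rate, t_end) {
  n <- stats::rpois(1, rate * t_end)
  sort(stats::runif(n, 0, t_end))
}

# Small simulated baseline/stress pair with package defaults.
sim_pair <- function(seed = 42, n_trials = 15, truth = truth_params()) {
  cfg <- generator_config(n_trials = n_trials, seed = seed, truth = truth)
  set.seed(seed)
  b <- simulate_session(cfg, truth, "baseline")
  s <- simulate_session(cfg, truth, "stress")
  list(baseline = b, stress = s)
}

# Simulate a cohort and fit one model per unit.
fit_cohort <- function(seed, n_units, n_trials = 41, truth = truth_params(),
                       model = "1a") {
  cfg <- generator_config(n_trials = n_trials, seed = seed,
                          n_units = n_units, truth = truth)
  cohort <- simulate_cohort(cfg)
  fits <- lapply(cohort, function(u)
    ciglm(list(u$baseline, u$stress), model = model))
  list(cohort = cohort, fits = fits, truth = truth)
}

# Named generative coefficient vector in model-1a design order.
truth_coef_1a <- function(truth) {
  c(mu = truth$mu, stress = truth$beta,
    setNames(unname(truth$B[c("Run", "Branch", "Choice", "Reward", "Pickup")]),
             paste0("B_", c("Run", "Branch", "Choice", "Reward", "Pickup"))),
    setNames(truth$alpha, paste0("alpha_", seq_along(truth$alpha))),
    setNames(truth$eta, paste0("eta_", seq_along(truth$eta))))
}
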