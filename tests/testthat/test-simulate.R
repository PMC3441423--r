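test_that("trial plans are deterministic, ordered, and honor the error rate", {
  cfg <- generator_config(n_trials = 10, seed = 2, error_rate = 0)
  set.seed(2); p1 <- make_trial_plan(cfg)
  set.seed(2); p2 <- make_trial_plan(cfg)
  expect_identical(p1, p2)
  expect_true(all(p1$correct))
  # correct trials alternate arms
  expect_true(all(p1$arm[-1] != p1$arm[-10]))
  # event ordering and exact delay
  expect_equal(p1$t_gate - p1$t_startbox, rep(10, 10))
  expect_true(all(diff(p1$t_startbox) > 0))
  cfg_err <- generator_config(n_trials = 10, seed = 3, error_rate = 1)
  set.seed(3); pe <- make_trial_plan(cfg_err)
  expect_true(all(!pe$correct[-1]))  # trial 1 always rewarded
  expect_true(all(pe$arm[-1] == pe$arm[-10]))  # errors repeat the arm
})

test_that("with no modulation the generator is homogeneous Poisson", {
  # 0.5 Hz for 100 s: count ~ Poisson(50); check the central 99% interval
  truth <- truth_params(mu = log(0.125), beta = 0,
                        B = setNames(rep(0, 6), INTERVALS),
                        alpha = rep(0, 10), eta = rep(0, 10))
  plan <- data.frame(trial_index = 1, condition = "baseline", arm = "left",
                     correct = TRUE, t_startbox = 0, t_gate = 50,
                     t_branch = 60, t_choice = 70, t_reward = 80,
                     t_pickup = 90, stringsAsFactors = FALSE)
  set.seed(1)
  spk <- simulate_spike_train(plan, truth, pickup_tail_s = 10)
  expect_gte(length(spk), qpois(0.005, 50))
  expect_lte(length(spk), qpois(0.995, 50))
  # inter-spike intervals look exponential (time-rescaling at the truth)
  pass <- vapply(1:20, function(i) {
    set.seed(100 + i)
    s <- simulate_spike_train(plan, truth, pickup_tail_s = 10)
    suppressWarnings(   # 5 ms grid induces occasional ties
      stats::ks.test(diff(s), "pexp", rate = 0.5)$p.value) > 0.05
  }, TRUE)
  expect_gte(sum(pass), 16)  # ~95% of seeds at the 95% level
})

test_that("a lag-1 gain of 2 doubles the post-spike discharge rate", {
  truth <- truth_params(mu = log(0.025), beta = 0,
                        B = setNames(rep(0, 6), INTERVALS),
                        alpha = c(log(2), rep(0, 9)),
                        eta = c(log(2), rep(0, 9)))
  plan <- data.frame(trial_index = 1, condition = "baseline", arm = "left",
                     correct = TRUE, t_startbox = 0, t_gate = 5000,
                     t_branch = 6000, t_choice = 7000, t_reward = 8000,
                     t_pickup = 9000, stringsAsFactors = FALSE)
  set.seed(9)
  spk <- simulate_spike_train(plan, truth, pickup_tail_s = 1000)
  edges <- seq(0, 10000, by = 0.25)
  cnt <- tabulate(findInterval(spk, edges), nbins = length(edges) - 1)
  prev <- cnt[-length(cnt)]
  cur <- cnt[-1]
  r_after <- mean(cur[prev == 1])
  r_quiet <- mean(cur[prev == 0])
  ratio <- r_after / r_quiet
  # MC tolerance: ~1000 post-spike bins at these rates
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("a stress rate-ratio of 1.27 is recovered from session rates", {
  g <- setNames(rep(0, 6), INTERVALS)
  truth <- truth_params(mu = log(0.15), beta = log(1.27), B = g,
                        alpha = rep(0, 10), eta = rep(0, 10))
  cfg <- generator_config(n_trials = 30, seed = 21, truth = truth)
  set.seed(21)
  b <- simulate_session(cfg, truth, "baseline")
  s <- simulate_session(cfg, truth, "stress")
  dur <- function(x) diff(session_span(x))
  ratio <- (length(s$spikes$u1) / dur(s)) / (length(b$spikes$u1) / dur(b))
  se <- ratio * sqrt(1 / length(s$spikes$u1) + 1 / length(b$spikes$u1))
  expect_lt(abs(ratio - 1.27), 3 * se)
})

test_that("mean count per bin converges to exp(mu)", {
  truth <- truth_params(mu = log(0.1), beta = 0,
                        B = setNames(rep(0, 6), INTERVALS),
                        alpha = rep(0, 10), eta = rep(0, 10))
  plan <- data.frame(trial_index = 1, condition = "baseline", arm = "left",
                     correct = TRUE, t_startbox = 0, t_gate = 2000,
                     t_branch = 2100, t_choice = 2200, t_reward = 2300,
                     t_pickup = 2400, stringsAsFactors = FALSE)
  set.seed(4)
  spk <- simulate_spike_train(plan, truth, pickup_tail_s = 100)
  n_bins <- 1e4
  m <- length(spk) / n_bins
  se <- sqrt(0.1 / n_bins)
  expect_lt(abs(m - 0.1), 3 * se)
})

test_that("run-away intensities stop with an instructive error", {
  truth <- truth_params(mu = log(60), beta = 0,
                        B = setNames(rep(0, 6), INTERVALS),
                        alpha = rep(0, 10), eta = rep(0, 10))
  plan <- make_tiny_trials()
  expect_error(simulate_spike_train(plan, truth), "sim_resolution")
})

test_that("cohorts are reproducible from config plus seed", {
  cfg <- generator_config(n_trials = 8, seed = 77, n_units = 2)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1[[1]]$baseline$spikes, c2[[1]]$baseline$spikes)
  expect_identical(c1[[2]]$stress$trials, c2[[2]]$stress$trials)
  # units differ from one another
  expect_false(identical(c1[[1]]$baseline$spikes[[1]],
                         c1[[2]]$baseline$spikes[[1]]))
})

test_that("interval-scoped history only modulates inside its window", {
  # gains active only in ExtendedDelay: post-spike doubling inside,
  # none outside
  truth <- truth_params(mu = log(0.03), beta = 0,
                        B = setNames(rep(0, 6), INTERVALS),
                        alpha = c(log(1.8), rep(0, 9)),
                        eta = c(log(1.8), rep(0, 9)),
                        history_scope = "ExtendedDelay")
  cfg <- generator_config(n_trials = 40, seed = 31, delay_length_s = 20,
                          truth = truth)
  set.seed(31)
  b <- simulate_session(cfg, truth, "baseline")
  cs <- bin_session(b)
  H <- history_matrix(cs, K = 1)
  iv <- as.character(cs$interval)
  prev <- H[, 1]
  in_ed <- iv %in% c("Delay", "Pickup")
  r_in <- mean(cs$count[in_ed & prev >= 1]) / mean(cs$count[in_ed & prev == 0])
  r_out <- mean(cs$count[!in_ed & prev >= 1]) /
    mean(cs$count[!in_ed & prev == 0])
  expect_gt(r_in, 1.3)
  expect_gt(r_in, r_out)
  expect_lt(abs(r_out - 1), 1.2)  # very wide MC band: ~50 post-spike
                                  # bins outside the window at these rates
})
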