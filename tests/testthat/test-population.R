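make_gain_profile <- function(unit, condition, gains, lags = (1:10) * 0.25) {
  data.frame(lag_s = lags, gain = gains, lo = gains * 0.9, hi = gains * 1.1,
             condition = condition, model_id = "1a", unit = unit)
}

test_that("gain aggregation gives exact means and SEMs", {
  p1 <- make_gain_profile("u1", "baseline", c(1.2, rep(1, 9)))
  p2 <- make_gain_profile("u2", "baseline", c(1.4, rep(1, 9)))
  agg <- aggregate_gains(list(p1, p2))
  row <- agg$summary[agg$summary$lag_s == 0.25, ]
  expect_equal(row$mean, 1.3)
  expect_equal(row$sem, 0.1)
  expect_equal(row$n, 2)
  bad <- make_gain_profile("u3", "baseline", rep(1, 5), lags = (1:5) * 0.25)
  expect_error(aggregate_gains(list(p1, bad)), "mismatched")
  expect_error(aggregate_gains(list(p1)), "2 units")
})

test_that("decay fit recovers noiseless parameters and the flat limit", {
  lags <- (1:10) * 0.25
  g <- 1.1 + 0.5 * exp(-(lags - 0.25) / 0.5)
  d <- decay_fit(lags, g)
  expect_equal(d$a, 1.1, tolerance = 1e-6)
  expect_equal(d$b, 0.5, tolerance = 1e-6)
  expect_equal(d$tau_s, 0.5, tolerance = 1e-6)
  flat <- decay_fit(lags, rep(1.07, 10))
  expect_lt(abs(flat$b), 1e-6)
  expect_equal(flat$a, 1.07, tolerance = 1e-6)
  expect_error(decay_fit((1:3) * 0.25, c(1, 1, 1)), "4 lags")
})

test_that("decay fit tracks noisy cohort-mean gains", {
  set.seed(71)
  lags <- (1:10) * 0.25
  truth <- c(a = 1.05, b = 0.45, tau = 0.6)
  ok <- 0
  for (r in 1:20) {
    g <- truth["a"] + truth["b"] * exp(-(lags - 0.25) / truth["tau"]) +
      rnorm(10, 0, 0.02)
    d <- decay_fit(lags, g)
    if (abs(d$a - truth["a"]) < 0.15 && abs(d$b - truth["b"]) < 0.25 &&
        abs(d$tau_s - truth["tau"]) < 0.6) ok <- ok + 1
  }
  expect_gte(ok, 16)
})

test_that("rmANOVA detects nothing when conditions are identical", {
  set.seed(72)
  units <- paste0("u", 1:8)
  profs <- list()
  for (u in units) {
    g <- 1 + abs(rnorm(10, 0.1, 0.05))
    profs[[paste0(u, "b")]] <- make_gain_profile(u, "baseline", g)
    profs[[paste0(u, "s")]] <- make_gain_profile(u, "stress", g)
  }
  res <- gains_rm_anova(aggregate_gains(profs))
  expect_equal(res$anova$condition$F, 0)
  expect_equal(res$anova$condition$p, 1)
  expect_equal(nrow(res$lsd), 10L)
  expect_equal(nrow(res$vs_one), 20L)
})

test_that("rmANOVA rejects unbalanced tables with a repair hint", {
  p1 <- make_gain_profile("u1", "baseline", rep(1.1, 10))
  p2 <- make_gain_profile("u1", "stress", rep(1.0, 10))
  p3 <- make_gain_profile("u2", "baseline", rep(1.2, 10))
  expect_error(gains_rm_anova(aggregate_gains(list(p1, p2, p3))),
               "unbalanced")
})

test_that("uniform gain suppression shows up as a condition main effect", {
  set.seed(73)
  units <- paste0("u", 1:15)
  profs <- list()
  for (u in units) {
    base <- 1.25 + rnorm(10, 0, 0.05)
    profs[[paste0(u, "b")]] <- make_gain_profile(u, "baseline", base)
    profs[[paste0(u, "s")]] <- make_gain_profile(u, "stress",
                                                 0.9 * base + rnorm(10, 0, 0.05))
  }
  res <- gains_rm_anova(aggregate_gains(profs))
  expect_lt(res$anova$condition$p, 0.01)
  # gains well above 1 are detected by the FDR-corrected tests
  expect_true(any(res$vs_one$rejected))
})

test_that("one-proportion chi-square matches analytic and exact oracles", {
  ct <- prop_chi2(30, 100, 0.05)
  expect_equal(ct$chi2, (30 - 5)^2 / (100 * 0.05 * 0.95))
  pt <- suppressWarnings(stats::prop.test(30, 100, 0.05, correct = FALSE))
  expect_equal(ct$chi2, unname(pt$statistic))
  expect_equal(ct$p, pt$p.value)
  bt <- stats::binom.test(30, 100, 0.05)
  expect_lt(ct$p, 1e-10)
  expect_lt(bt$p.value, 1e-10)
  expect_equal(prop_chi2(5, 100, 0.05)$chi2, 0)
})

test_that("delay-related flagging is calibrated on stationary cohorts", {
  set.seed(74)
  sessions <- lapply(1:10, function(i) {
    cfg <- generator_config(n_trials = 10, seed = 74 + i)
    set.seed(74 + i)
    plan <- make_trial_plan(cfg)
    span_end <- plan$t_pickup[10] + 5
    spikes <- poisson_train(1, span_end)
    tmaze_session(paste0("s", i), "baseline", plan, list(u1 = spikes),
                  delay_length_s = 10)
  })
  set.seed(75)
  res <- delay_related_fraction(sessions, n_shift = 199)
  expect_lte(res$n_flagged, 2)       # ~5% false positives expected
  expect_equal(res$n_units, 10)
  # a strongly delay-tuned unit is flagged
  cfg <- generator_config(n_trials = 12, seed = 99)
  set.seed(99)
  plan <- make_trial_plan(cfg)
  spikes <- sort(unlist(lapply(plan$t_startbox, function(on)
    runif(20, on, on + 10))))
  tuned <- tmaze_session("t", "baseline", plan, list(u1 = spikes),
                         delay_length_s = 10)
  set.seed(76)
  res2 <- delay_related_fraction(list(tuned), n_shift = 199)
  expect_equal(res2$n_flagged, 1)
})

test_that("the pipeline writes a complete, reproducible bundle", {
  cfg <- generator_config(n_trials = 20, seed = 81, n_units = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_pipeline(cfg, out_dir = d1)
  r2 <- run_pipeline(cfg, out_dir = d2)
  for (f in c("fits.json", "cohort_gains.csv", "report.json", "run.log"))
    expect_true(file.exists(file.path(d1, f)))
  expect_true(jsonlite::validate(readLines(file.path(d1, "fits.json"))))
  # byte-identical reruns from the same config + seed
  for (f in c("fits.json", "cohort_gains.csv", "report.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_equal(length(r1$fits), 2L)
})
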