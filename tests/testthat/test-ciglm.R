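test_that("bin_session discretizes counts over half-open bins", {
  s <- make_span_session(spikes = c(0.1, 0.2, 0.6))
  cs <- bin_session(s, bin_width = 0.25)
  expect_equal(cs$count, c(2L, 0L, 1L))
  expect_equal(cs$time, c(0, 0.25, 0.5))
  s0 <- make_span_session(spikes = numeric(0))
  expect_equal(bin_session(s0, bin_width = 0.25)$count, c(0L, 0L, 0L))
})

test_that("binning conserves the spike count on simulated sessions", {
  pair <- sim_pair(seed = 8, n_trials = 10)
  for (s in pair) {
    cs <- bin_session(s)
    expect_identical(sum(cs$count), length(s$spikes[[1]]))
  }
})

test_that("history columns are lagged window counts over session time", {
  # counts per 250 ms bin: 2, 0, 1, 3
  s <- make_span_session(spikes = c(0.1, 0.15, 0.6, 0.8, 0.85, 0.9),
                         events = c(0, 0.3, 0.5, 0.6, 0.7, 0.8), tail = 0.2)
  cs <- bin_session(s, bin_width = 0.25)
  expect_equal(cs$count, c(2L, 0L, 1L, 3L))
  H <- history_matrix(cs, K = 2)
  expect_equal(unname(H[4, ]), c(1L, 0L))
  expect_equal(unname(H[3, ]), c(0L, 2L))
  expect_equal(attr(H, "complete"), c(FALSE, FALSE, TRUE, TRUE))
  expect_error(history_matrix(cs, K = 2, delta = 0.3), "multiple")
})

test_that("design matrices have the coding-rule column counts", {
  pair <- sim_pair(seed = 12, n_trials = 12)
  cs <- lapply(pair, bin_session)
  expect_equal(ncol(build_design(cs, model_spec("h0"))$X), 1L)
  expect_equal(ncol(build_design(cs, model_spec("inhom"))$X), 6L)
  expect_equal(ncol(build_design(cs, model_spec("1b"))$X), 22L)
  # 1a: mu + stress + 5 interval dummies + 10 alpha + 10 eta
  expect_equal(ncol(build_design(cs, model_spec("1a"))$X), 27L)
  # model 2: mu + 10 gamma + stress + window dummy + 10 alpha + 10 eta
  d2 <- build_design(cs, model_spec("2"))
  expect_equal(ncol(d2$X), 33L)
  expect_true("D_ExtendedDelay" %in% colnames(d2$X))
  d3 <- build_design(cs, model_spec("3"))
  expect_true("D_Response" %in% colnames(d3$X))
  # single-condition input drops the structurally zero split columns
  db <- build_design(cs[[1]], model_spec("1b"))
  expect_false(any(grepl("^eta", colnames(db$X))))
  expect_true(all(c("eta_1", "stress") %in% attr(db$X, "dropped")))
})

test_that("intercept-only ML equals log mean count exactly", {
  set.seed(33)
  y <- rpois(400, 0.7)
  cs <- structure(
    data.frame(time = (seq_along(y) - 1) * 0.25, count = y,
               interval = factor("Delay", levels = INTERVALS),
               trial = 2L, in_scope = TRUE),
    class = c("count_series", "data.frame"),
    bin_width = 0.25, condition = "baseline", session_id = "x", unit = "u1")
  f <- ciglm(cs, model = "h0")
  expect_equal(unname(coef(f)), log(mean(f$y)), tolerance = 1e-8)
  # IRLS fixed point: fitted total equals observed total
  expect_equal(sum(fitted(f)), sum(f$y), tolerance = 1e-6)
})

test_that("IRLS matches the exhaustive likelihood lattice search", {
  found <- 0; tried <- 0
  for (seed in 1:40) {
    if (found >= 5) break
    p <- 2 + seed %% 2
    dd <- random_tiny_design(p, n = 40, seed = 1000 + seed)
    fit <- suppressWarnings(glm.fit(dd$X, dd$y, family = poisson()))
    if (max(abs(fit$coefficients)) > 0.8) next   # keep truth interior
    tried <- tried + 1
    arg <- grid_argmax_loglik(dd$X, dd$y)
    expect_lt(max(abs(fit$coefficients - arg)), 0.0100001)
    found <- found + 1
  }
  expect_gte(found, 5)
})

test_that("condition-split history columns do not leak across conditions", {
  pair <- sim_pair(seed = 19, n_trials = 30)
  cs <- lapply(pair, bin_session)
  joint <- ciglm(cs, model = "1b")
  base_only <- ciglm(cs[[1]], model = "1b")
  a_joint <- coef(joint)[grep("^alpha", names(coef(joint)))]
  a_base <- coef(base_only)[grep("^alpha", names(coef(base_only)))]
  expect_equal(unname(a_joint), unname(a_base), tolerance = 1e-6)
  expect_equal(unname(coef(joint)["mu"]), unname(coef(base_only)["mu"]),
               tolerance = 1e-6)
})

test_that("gains are invariant to the session time origin", {
  pair <- sim_pair(seed = 23, n_trials = 30)
  shift <- function(s, by) {
    s$trials[c("t_startbox", "t_gate", "t_branch", "t_choice",
               "t_reward", "t_pickup")] <-
      s$trials[c("t_startbox", "t_gate", "t_branch", "t_choice",
                 "t_reward", "t_pickup")] + by
    s$spikes <- lapply(s$spikes, `+`, by)
    s
  }
  f1 <- ciglm(list(pair$baseline, pair$stress), model = "1a")
  f2 <- ciglm(list(shift(pair$baseline, 500), shift(pair$stress, 500)),
              model = "1a")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("gain profiles exponentiate coefficients with Wald intervals", {
  pair <- sim_pair(seed = 29, n_trials = 12)
  f <- ciglm(list(pair$baseline, pair$stress), model = "1b")
  g <- gains(f, "alpha")
  cf <- coef(f)[paste0("alpha_", 1:10)]
  se <- sqrt(diag(vcov(f))[paste0("alpha_", 1:10)])
  expect_equal(g$gain, unname(exp(cf)))
  expect_equal(g$lo, unname(exp(cf - qnorm(0.975) * se)))
  expect_equal(g$lag_s, (1:10) * 0.25)
  expect_true(all(g$lo <= g$gain & g$gain <= g$hi))
  base_only <- ciglm(pair$baseline, model = "1b")
  expect_error(gains(base_only, "eta"), "no eta")
  # a zero coefficient maps to gain exactly 1
  f$coefficients["alpha_1"] <- 0
  expect_equal(gains(f, "alpha")$gain[1], 1)
})

test_that("deviance test compares nested fits and rejects non-nested", {
  pair <- sim_pair(seed = 31, n_trials = 12)
  cs <- lapply(pair, bin_session)
  f1a <- ciglm(cs, model = "1a")
  f1b <- ciglm(cs, model = "1b")
  same <- deviance_test(f1a, f1a)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  dt <- deviance_test(f1a, f1b)
  expect_equal(dt$df, 5L)
  expect_gte(dt$chi2, 0)
  f2 <- ciglm(cs, model = "2")
  f3 <- ciglm(cs, model = "3")
  expect_error(deviance_test(f2, f3), "not nested")
  a <- anova(f1b, f1a)
  expect_equal(a$chi2[2], dt$chi2)
})

test_that("separation is flagged and excluded from aggregation", {
  # a unit that never fires during stress: eta columns all zero counts but
  # the stress main effect separates
  pair <- sim_pair(seed = 37, n_trials = 10)
  pair$stress$spikes[[1]] <- c(100.0, 100.1, 100.2)  # one burst, then silence
  f <- ciglm(list(pair$baseline, pair$stress), model = "1b")
  expect_true(f$flagged || f$converged)  # fit returns rather than errors
  fits <- list(ciglm(list(pair$baseline, pair$stress), model = "1b"),
               ciglm(list(sim_pair(seed = 38, n_trials = 10)$baseline,
                          sim_pair(seed = 38, n_trials = 10)$stress),
                     model = "1b"))
  fits[[1]]$flagged <- TRUE
  cg <- cohort_gains(c(fits, fits[2]))
  expect_equal(attr(cg, "n_excluded"), 1L)
})

test_that("Benjamini-Hochberg step-up matches its defining thresholds", {
  r <- bh_fdr(c(0.001, 0.01, 0.02, 0.9), q = 0.05)
  expect_identical(r$rejected, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(bh_fdr(rep(1, 6))$rejected, rep(FALSE, 6))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # FDR control under the global null (all uniforms)
  set.seed(91)
  any_rej <- replicate(200, any(bh_fdr(runif(50))$rejected))
  expect_lte(mean(any_rej), 0.1)  # FWER = FDR <= q under the null
})
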