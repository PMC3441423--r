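#' Aggregate per-unit gain profiles across a cohort
#'
#' Stacks per-unit [gains()] tables and computes the cohort mean and SEM of
#' the gain at every condition x lag cell. Degenerate (flagged) fits must be
#' excluded before aggregation; [cohort_gains()] does this when starting
#' from fits.
#'
#' @param profiles List of data frames as returned by [gains()], one or two
#'   (alpha and eta) per unit, each tagged with a \code{unit} column or
#'   named by unit.
#' @return List with \code{per_unit} (stacked long table) and \code{summary}
#'   (mean, SEM, n per condition x lag).
#' @export
aggregate_gains <- function(profiles) {
  if (is.null(names(profiles)))
    names(profiles) <- paste0("u", seq_along(profiles))
  long <- do.call(rbind, lapply(names(profiles), function(nm) {
    p <- profiles[[nm]]
    if (is.null(p$unit)) p$unit <- nm
    p
  }))
  if (length(unique(long$unit)) < 2)
    stop("need at least 2 units to aggregate")
  lag_sets <- tapply(long$lag_s, interaction(long$unit, long$condition),
                     function(v) paste(sort(v), collapse = ","))
  if (length(unique(stats::na.omit(as.vector(lag_sets)))) > 1)
    stop("units have mismatched history lags")
  agg <- aggregate(gain ~ condition + lag_s, data = long, FUN = function(v)
    c(mean = mean(v), sem = sd(v) / sqrt(length(v)), n = length(v)))
  out <- data.frame(condition = agg$condition, lag_s = agg$lag_s,
                    mean = agg$gain[, "mean"], sem = agg$gain[, "sem"],
                    n = agg$gain[, "n"])
  list(per_unit = long, summary = out[order(out$condition, out$lag_s), ])
}

#' Gains of every non-degenerate fit in a cohort
#'
#' @param fits List of [ciglm()] fits (models with history terms).
#' @param which Character subset of \code{c("alpha", "eta")}.
#' @return [aggregate_gains()] result; attribute \code{"n_excluded"} counts
#'   degenerate or non-converged fits left out.
#' @export
cohort_gains <- function(fits, which = c("alpha", "eta")) {
  ok <- vapply(fits, function(f) !f$flagged, TRUE)
  profiles <- list()
  for (i in which(ok)) {
    for (w in which) {
      g <- gains(fits[[i]], w)
      g$unit <- paste0("u", i)
      profiles[[paste0("u", i, "_", w)]] <- g
    }
  }
  out <- aggregate_gains(profiles)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Exponential decay fit of cohort-mean gains over history lag
#'
#' Nonlinear least squares of \code{g(x) = a + b * exp(-(x - delta)/tau)}
#' where \code{delta} is the first lag, so \code{a + b} is the gain at the
#' most recent history bin and \code{a} the asymptote deep in the past.
#' Multi-start over time constants \code{tau} in \{0.25, 0.5, 1, 2\} s
#' guards against local minima.
#'
#' @param lag_s Lag times, seconds (at least 4).
#' @param gain Mean gain per lag.
#' @return List with \code{a}, \code{b}, \code{tau_s}, \code{fitted},
#'   \code{residuals}, \code{rss} and the underlying \code{nls} object.
#' @export
decay_fit <- function(lag_s, gain) {
  if (length(lag_s) < 4) stop("need at least 4 lags for a decay fit")
  delta <- min(lag_s)
  best <- NULL
  for (tau0 in c(0.25, 0.5, 1, 2)) {
    f <- tryCatch(
      minpack.lm::nlsLM(gain ~ a + b * exp(-(lag_s - delta) / tau),
                        start = list(a = min(gain), b = max(gain) - min(gain),
                                     tau = tau0),
                        lower = c(-Inf, -Inf, 1e-4),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) {
      rss <- sum(residuals(f)^2)
      if (is.null(best) || rss < best$rss - 1e-12)
        best <- list(fit = f, rss = rss)
    }
  }
  # degenerate flat limit: the exponential term carries no information and
  # the gradient is singular; fall back to the constant model with b = 0
  const_rss <- sum((gain - mean(gain))^2)
  if (is.null(best) && !all(is.finite(gain)))
    stop("decay fit failed to converge from all starts")
  if (is.null(best) || const_rss <= best$rss + 1e-12) {
    if (is.null(best) && const_rss > 1e-8 * sum(gain^2))
      stop("decay fit failed to converge from all starts")
    return(list(a = mean(gain), b = 0, tau_s = Inf,
                fitted = rep(mean(gain), length(gain)),
                residuals = gain - mean(gain), rss = const_rss, nls = NULL))
  }
  cf <- coef(best$fit)
  list(a = unname(cf["a"]), b = unname(cf["b"]), tau_s = unname(cf["tau"]),
       fitted = fitted(best$fit), residuals = residuals(best$fit),
       rss = best$rss, nls = best$fit)
}

#' Two-way repeated-measures ANOVA on SHPD gains
#'
#' Condition (baseline/stress) by history-lag ANOVA with unit as the
#' repeated-measures subject, on the gain scale. Also reports LSD post-hoc
#' comparisons (unadjusted paired t between conditions at each lag) and
#' FDR-corrected one-sample t tests of each condition x lag cell against a
#' gain of 1 (no history modulation).
#'
#' @param cohort Result of [aggregate_gains()]/[cohort_gains()], or the
#'   long per-unit table itself.
#' @param q FDR level for the tests against 1.
#' @return List with \code{anova} (F, df, p per effect), \code{lsd}
#'   (per-lag condition contrast), \code{vs_one} (per-cell test vs 1).
#' @export
gains_rm_anova <- function(cohort, q = 0.05) {
  long <- if (is.data.frame(cohort)) cohort else cohort$per_unit
  long$unit <- factor(long$unit)
  long$condition <- factor(long$condition)
  long$lag <- factor(long$lag_s)
  counts <- table(long$unit, long$condition, long$lag)
  if (any(counts != 1))
    stop("unbalanced unit x condition x lag table; every unit needs one ",
         "gain per cell (drop incomplete units or refit)")
  a <- aov(gain ~ condition * lag + Error(unit / (condition * lag)),
           data = long)
  s <- summary(a)
  pull <- function(stratum, term) {
    tb <- s[[stratum]][[1]]
    i <- trimws(rownames(tb)) == term
    ri <- trimws(rownames(tb)) == "Residuals"
    out <- list(F = tb[i, "F value"],
                df = c(tb[i, "Df"], if (any(ri)) tb[ri, "Df"] else NA),
                p = tb[i, "Pr(>F)"])
    if (is.finite(tb[i, "Sum Sq"]) &&
        tb[i, "Sum Sq"] <= 1e-10 * (sum(tb[, "Sum Sq"]) + 1)) {
      out$F <- 0; out$p <- 1   # effect sum of squares (numerically) zero
    }
    out
  }
  an <- list(condition = pull("Error: unit:condition", "condition"),
             lag = pull("Error: unit:lag", "lag"),
             interaction = pull("Error: unit:condition:lag",
                                "condition:lag"))
  lags <- sort(unique(long$lag_s))
  lsd <- do.call(rbind, lapply(lags, function(l) {
    w <- long[long$lag_s == l, ]
    w <- w[order(w$unit, w$condition), ]
    b <- w$gain[w$condition == "baseline"][order(w$unit[w$condition == "baseline"])]
    st <- w$gain[w$condition == "stress"][order(w$unit[w$condition == "stress"])]
    h <- t.test(b, st, paired = TRUE)
    data.frame(lag_s = l, diff = mean(b - st), t = unname(h$statistic),
               p = h$p.value)
  }))
  cells <- expand.grid(condition = levels(long$condition), lag_s = lags,
                       stringsAsFactors = FALSE)
  vs <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    v <- long$gain[long$condition == cells$condition[i] &
                     long$lag_s == cells$lag_s[i]]
    h <- t.test(v, mu = 1)
    data.frame(condition = cells$condition[i], lag_s = cells$lag_s[i],
               mean = mean(v), t = unname(h$statistic), p = h$p.value)
  }))
  fdr <- bh_fdr(vs$p, q)
  vs$p_adj <- fdr$adjusted
  vs$rejected <- fdr$rejected
  list(anova = an, lsd = lsd, vs_one = vs)
}

#' Fraction of units with delay-related spiking
#'
#' The criterion for "delay-related" is an explicit configurable stand-in:
#' a unit counts as delay-related when its baseline delay-interval rate
#' exceeds its whole-trial rate with p below \code{alpha} under a
#' within-trial circular-shift permutation test. The observed fraction is
#' compared with a null fraction by a one-proportion chi-square test.
#'
#' @param sessions List of baseline \code{tmaze_session}s, one unit each.
#' @param n_shift Permutations per unit.
#' @param alpha Per-unit significance level.
#' @param null_fraction Null proportion for the chi-square test.
#' @return List with \code{fraction}, \code{n_units}, \code{n_flagged},
#'   \code{chi2}, \code{p}, and the per-unit permutation p values.
#' @export
delay_related_fraction <- function(sessions, n_shift = 1000, alpha = 0.05,
                                   null_fraction = 0.05) {
  if (!length(sessions)) stop("no units supplied")
  pvals <- vapply(sessions, function(s) {
    xa <- correct_trials(s)
    if (nrow(xa$trials) == 0) return(NA_real_)
    ivs <- session_intervals(s)
    ivs <- ivs[ivs$trial_index %in% xa$trials$trial_index, ]
    spk <- s$spikes[[1]]
    tr_idx <- sort(unique(ivs$trial_index))
    delay_count <- function(sp) {
      d <- ivs[ivs$label == "Delay", ]
      sum(vapply(seq_len(nrow(d)), function(i)
        sum(sp >= d$start[i] & sp < d$end[i]), 0L))
    }
    obs <- delay_count(spk)
    perm <- vapply(seq_len(n_shift), function(j) {
      sp <- spk
      for (ti in tr_idx) {
        w <- ivs[ivs$trial_index == ti, ]
        t0 <- min(w$start); t1 <- max(w$end)
        inside <- sp >= t0 & sp < t1
        if (any(inside))
          sp[inside] <- t0 + (sp[inside] - t0 + runif(1) * (t1 - t0)) %% (t1 - t0)
      }
      delay_count(sp)
    }, 0L)
    (1 + sum(perm >= obs)) / (n_shift + 1)
  }, 0)
  flagged <- pvals < alpha
  n <- sum(!is.na(flagged))
  x <- sum(flagged, na.rm = TRUE)
  ct <- prop_chi2(x, n, null_fraction)
  list(fraction = x / n, n_units = n, n_flagged = x, chi2 = ct$chi2,
       p = ct$p, pvalues = pvals)
}

#' One-proportion chi-square test
#'
#' Goodness-of-fit chi-square (df 1, no continuity correction) of an
#' observed count against a null proportion.
#'
#' @param x Observed successes.
#' @param n Trials.
#' @param p0 Null proportion.
#' @return List with \code{chi2} and the upper-tail \code{p}.
#' @export
prop_chi2 <- function(x, n, p0) {
  stopifnot(n > 0, x >= 0, x <= n, p0 > 0, p0 < 1)
  chi2 <- (x - n * p0)^2 / (n * p0 * (1 - p0))
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

#' Run the full analysis pipeline on a simulated or loaded cohort
#'
#' Simulates (or loads) a cohort, restricts to analyzed trials, bins each
#' unit, fits the requested conditional-intensity models, runs
#' time-rescaling goodness-of-fit on the primary model, aggregates gains,
#' and computes the population statistics. Writes the full bundle of
#' outputs (fits, gains, GOF, cohort summaries, report, run log) as
#' CSV/JSON under \code{out_dir} when given.
#'
#' @param config A [generator_config()] for simulation, or a directory
#'   written by [write_cohort()].
#' @param out_dir Optional output directory.
#' @param models Model ids to fit per unit.
#' @param gof_model Model whose fit is checked by time rescaling.
#' @return List with \code{fits} (per unit per model), \code{gof},
#'   \code{gains} (cohort aggregation for 1a), \code{rm_anova},
#'   \code{decay}, \code{exclusions}, \code{seed}.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         models = c("1b", "1a"), gof_model = "1a") {
  if (is.character(config)) {
    dirs <- list.dirs(config, recursive = FALSE)
    dirs <- dirs[file.exists(file.path(dirs, "baseline", "session.json"))]
    cohort <- lapply(dirs, function(d) list(
      baseline = read_session(file.path(d, "baseline", "spikes.csv"),
                              file.path(d, "baseline", "trials.csv"),
                              file.path(d, "baseline", "session.json")),
      stress = read_session(file.path(d, "stress", "spikes.csv"),
                            file.path(d, "stress", "trials.csv"),
                            file.path(d, "stress", "session.json")),
      retries = 0L))
    seed <- NA_integer_
  } else {
    cohort <- simulate_cohort(config)
    seed <- config$seed
  }
  fits <- list(); gof <- list()
  for (u in seq_along(cohort)) {
    pair <- list(cohort[[u]]$baseline, cohort[[u]]$stress)
    uid <- names(pair[[1]]$spikes)[1]
    fits[[uid]] <- lapply(setNames(models, models), function(m)
      ciglm(pair, model = m))
    if (gof_model %in% models) {
      f <- fits[[uid]][[gof_model]]
      if (f$converged) {
        z <- time_rescale(f, lapply(pair, function(s) s$spikes[[1]]))
        gof[[uid]] <- if (length(z) >= 2) ks_summary(z) else NULL
      }
    }
  }
  main <- if ("1a" %in% models) "1a" else models[length(models)]
  cg <- tryCatch(cohort_gains(lapply(fits, `[[`, main)),
                 error = function(e) e$message)
  if (is.character(cg)) {
    rma <- dec <- "skipped: too few usable fits"
    nexcl <- sum(vapply(fits, function(m) m[[main]]$flagged, TRUE))
  } else {
    rma <- tryCatch(gains_rm_anova(cg), error = function(e) e$message)
    base_mean <- cg$summary[cg$summary$condition == "baseline", ]
    dec <- tryCatch(decay_fit(base_mean$lag_s, base_mean$mean),
                    error = function(e) e$message)
    nexcl <- attr(cg, "n_excluded")
  }
  out <- list(fits = fits, gof = gof,
              gains = if (is.character(cg)) NULL else cg,
              rm_anova = rma, decay = dec,
              exclusions = nexcl,
              retries = vapply(cohort, function(u) u$retries, 0L),
              seed = seed)
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

# Serialize a pipeline result as CSV/JSON files.
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fits_json <- lapply(res$fits, function(mods) lapply(mods, function(f)
    list(model_id = f$model$model_id,
         coefficients = as.list(round(f$coefficients, 10)),
         se = as.list(round(sqrt(diag(f$vcov)), 10)),
         loglik = f$loglik, deviance = f$deviance,
         converged = f$converged, flagged = f$flagged)))
  jsonlite::write_json(fits_json, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(res$gains))
    write.csv(res$gains$per_unit, file.path(out_dir, "cohort_gains.csv"),
              row.names = FALSE)
  if (length(res$gof)) {
    gtab <- data.frame(unit = names(res$gof),
                       n = vapply(res$gof, `[[`, 0, "n"),
                       D = vapply(res$gof, `[[`, 0, "D"),
                       band = vapply(res$gof, `[[`, 0, "band"),
                       pass = vapply(res$gof, `[[`, TRUE, "pass"))
    write.csv(gtab, file.path(out_dir, "gof.csv"), row.names = FALSE)
  }
  report <- list(
    seed = res$seed,
    exclusions = res$exclusions,
    retries = sum(res$retries),
    rm_anova = if (is.list(res$rm_anova)) res$rm_anova$anova else res$rm_anova,
    decay = if (is.list(res$decay))
      res$decay[c("a", "b", "tau_s", "rss")] else res$decay)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(sprintf("seed: %s", res$seed),
               sprintf("units: %d", length(res$fits)),
               sprintf("degenerate fits excluded: %d", res$exclusions),
               sprintf("runaway retries: %d", sum(res$retries))),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}
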