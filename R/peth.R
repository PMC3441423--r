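#' Peri-event time histogram aligned to an interval onset
#'
#' Trial-by-trial spike counts in fine bins (default 5 ms) aligned to the
#' onset of one behavioral interval across the analyzed (correct, not
#' first) trials of a session. The per-bin value is spiking probability:
#' count divided by the number of trials, which normalizes sessions with
#' different trial counts.
#'
#' @param x A \code{tmaze_session}.
#' @param label Interval whose onset is time 0.
#' @param unit Unit id (default first).
#' @param window \code{c(lo, hi)} seconds around the onset.
#' @param bin_width PETH bin width, seconds.
#' @return A \code{peth} list: \code{edges}, \code{prob}, \code{n_trials},
#'   \code{label}, \code{bin_width}.
#' @export
compute_peth <- function(x, label, unit = names(x$spikes)[1],
                         window = c(0, 2), bin_width = 0.005) {
  stopifnot(label %in% INTERVALS, window[2] > window[1])
  xa <- correct_trials(x)
  if (nrow(xa$trials) == 0) stop("no analyzed trials in session")
  ivs <- session_intervals(x)
  ivs <- ivs[ivs$label == label & ivs$trial_index %in% xa$trials$trial_index, ]
  if (nrow(ivs) == 0) stop("no '", label, "' intervals among analyzed trials")
  spk <- x$spikes[[unit]]
  edges <- seq(window[1], window[2], by = bin_width)
  n_bins <- length(edges) - 1
  counts <- numeric(n_bins)
  for (on in ivs$start) {
    rel <- spk - on
    rel <- rel[rel >= window[1] & rel < edges[n_bins + 1]]
    counts <- counts + tabulate(findInterval(rel, edges), nbins = n_bins)
  }
  structure(list(edges = edges, prob = counts / nrow(ivs),
                 n_trials = nrow(ivs), label = label,
                 bin_width = bin_width),
            class = "peth")
}

#' @export
print.peth <- function(x, ...) {
  cat("PETH aligned to", x$label, "onset:", x$n_trials, "trials,",
      length(x$prob), "bins of", x$bin_width * 1000, "ms\n")
  invisible(x)
}

#' Temporally normalized firing-rate profile of one interval type
#'
#' Behavioral intervals of one type vary in duration across trials, so raw
#' PETHs cannot be averaged over the full interval. Each analyzed trial's
#' interval is resampled onto a fixed number of equal sub-bins; the rate in
#' a sub-bin is its spike count over its duration, averaged across trials.
#' A stationary train gives a flat profile whatever the duration mix.
#'
#' @param x A \code{tmaze_session}.
#' @param label Interval type.
#' @param unit Unit id.
#' @param n_norm_bins Number of normalized sub-bins (default 20).
#' @return Numeric vector of length \code{n_norm_bins}: mean rate (Hz) per
#'   normalized bin, with attribute \code{"n_trials"}.
#' @export
normalized_peth <- function(x, label, unit = names(x$spikes)[1],
                            n_norm_bins = 20) {
  stopifnot(label %in% INTERVALS, n_norm_bins >= 1)
  xa <- correct_trials(x)
  ivs <- session_intervals(x)
  ivs <- ivs[ivs$label == label & ivs$trial_index %in% xa$trials$trial_index, ]
  if (nrow(ivs) == 0) stop("no '", label, "' intervals among analyzed trials")
  if (any(ivs$end <= ivs$start)) stop("zero-duration interval")
  spk <- x$spikes[[unit]]
  rates <- matrix(0, nrow(ivs), n_norm_bins)
  for (i in seq_len(nrow(ivs))) {
    dur <- ivs$end[i] - ivs$start[i]
    sub <- dur / n_norm_bins
    rel <- spk[spk >= ivs$start[i] & spk < ivs$end[i]] - ivs$start[i]
    cnt <- tabulate(pmin(floor(rel / sub) + 1, n_norm_bins), nbins = n_norm_bins)
    rates[i, ] <- cnt / sub
  }
  structure(colMeans(rates), n_trials = nrow(ivs))
}

#' Stress discharge rate as percent of baseline
#'
#' @param stress_rate,baseline_rate Rates in Hz.
#' @return \code{100 * stress_rate / baseline_rate}; \code{NA} (flagged
#'   undefined, to be excluded from statistics) when the baseline rate is 0.
#' @export
percent_of_baseline <- function(stress_rate, baseline_rate) {
  ifelse(baseline_rate > 0, 100 * stress_rate / baseline_rate, NA_real_)
}

#' Mean firing rate per behavioral interval
#'
#' Total spikes over total duration for each interval type, across the
#' analyzed trials of a session, optionally split by chosen arm.
#'
#' @param x A \code{tmaze_session}.
#' @param unit Unit id.
#' @param by_arm Split by T-maze arm choice.
#' @return Data frame with \code{interval}, (optionally \code{arm}),
#'   \code{rate_hz}, \code{duration_s}, \code{n_spikes}.
#' @export
interval_rates <- function(x, unit = names(x$spikes)[1], by_arm = FALSE) {
  xa <- correct_trials(x)
  if (nrow(xa$trials) == 0) stop("no analyzed trials in session")
  ivs <- session_intervals(x)
  ivs <- ivs[ivs$trial_index %in% xa$trials$trial_index, ]
  ivs$arm <- xa$trials$arm[match(ivs$trial_index, xa$trials$trial_index)]
  spk <- x$spikes[[unit]]
  ivs$n <- vapply(seq_len(nrow(ivs)), function(i)
    sum(spk >= ivs$start[i] & spk < ivs$end[i]), 0L)
  ivs$dur <- ivs$end - ivs$start
  keys <- if (by_arm) list(interval = ivs$label, arm = ivs$arm)
          else list(interval = ivs$label)
  agg <- aggregate(cbind(n, dur) ~ ., data = cbind(as.data.frame(keys),
                                                   n = ivs$n, dur = ivs$dur),
                   FUN = sum)
  agg$rate_hz <- agg$n / agg$dur
  names(agg)[names(agg) == "n"] <- "n_spikes"
  names(agg)[names(agg) == "dur"] <- "duration_s"
  agg$interval <- factor(agg$interval, levels = INTERVALS)
  agg[order(agg$interval), , drop = FALSE]
}

#' Interval rate table for a baseline/stress session pair
#'
#' Per interval, the stress rate as percent of the baseline rate, matched on
#' T-maze arm choice: per-arm percents are computed and averaged over the
#' arms represented in both sessions, falling back to the pooled rates when
#' no arm is shared.
#'
#' @param baseline,stress \code{tmaze_session}s of one unit's testing day.
#' @param unit Unit id.
#' @return Data frame with \code{interval}, \code{baseline_hz},
#'   \code{stress_hz}, \code{percent_of_baseline}.
#' @export
interval_rate_table <- function(baseline, stress,
                                unit = names(baseline$spikes)[1]) {
  rb <- interval_rates(baseline, unit, by_arm = TRUE)
  rs <- interval_rates(stress, unit, by_arm = TRUE)
  pb <- interval_rates(baseline, unit)
  ps <- interval_rates(stress, unit)
  out <- data.frame(interval = pb$interval,
                    baseline_hz = pb$rate_hz,
                    stress_hz = ps$rate_hz[match(pb$interval, ps$interval)])
  out$percent_of_baseline <- NA_real_
  for (i in seq_len(nrow(out))) {
    iv <- out$interval[i]
    arms <- intersect(rb$arm[rb$interval == iv & rb$rate_hz > 0],
                      rs$arm[rs$interval == iv])
    if (length(arms)) {
      pcts <- vapply(arms, function(a)
        percent_of_baseline(rs$rate_hz[rs$interval == iv & rs$arm == a],
                            rb$rate_hz[rb$interval == iv & rb$arm == a]),
        0)
      out$percent_of_baseline[i] <- mean(pcts)
    } else {
      out$percent_of_baseline[i] <-
        percent_of_baseline(out$stress_hz[i], out$baseline_hz[i])
    }
  }
  out
}

#' Cohort statistics on percent-of-baseline interval rates
#'
#' One-way ANOVA of percent-of-baseline values across behavioral intervals,
#' plus per-interval one-sample t tests against 100 (no stress effect) with
#' Benjamini-Hochberg correction. Undefined percents (zero baseline rate)
#' are excluded.
#'
#' @param tab Data frame with columns \code{unit}, \code{interval},
#'   \code{percent} (one row per unit x interval).
#' @param q FDR level for the one-sample tests.
#' @return List with \code{anova} (\code{F}, \code{df}, \code{p}) and
#'   \code{tests} (per-interval mean, t, raw and adjusted p, rejection).
#' @export
rate_stats <- function(tab, q = 0.05) {
  tab <- tab[is.finite(tab$percent), , drop = FALSE]
  if (length(unique(tab$unit)) < 2)
    stop("need at least 2 units for cohort rate statistics")
  tab$interval <- factor(tab$interval)
  fit <- aov(percent ~ interval, data = tab)
  s <- summary(fit)[[1]]
  ii <- trimws(rownames(s)) == "interval"
  ri <- trimws(rownames(s)) == "Residuals"
  an <- list(F = s[ii, "F value"], df = c(s[ii, "Df"], s[ri, "Df"]),
             p = s[ii, "Pr(>F)"])
  if (is.finite(s[ii, "Sum Sq"]) &&
      s[ii, "Sum Sq"] <= 1e-10 * (sum(s[, "Sum Sq"]) + 1)) {
    an$F <- 0; an$p <- 1   # no between-interval variation at all
  }
  lv <- levels(tab$interval)
  tt <- lapply(lv, function(l) {
    v <- tab$percent[tab$interval == l]
    if (length(v) < 2 || sd(v) == 0)
      return(data.frame(interval = l, mean = mean(v), t = NA, p = 1))
    h <- t.test(v, mu = 100)
    data.frame(interval = l, mean = mean(v),
               t = unname(h$statistic), p = h$p.value)
  })
  tests <- do.call(rbind, tt)
  fdr <- bh_fdr(tests$p, q)
  tests$p_adj <- fdr$adjusted
  tests$rejected <- fdr$rejected
  list(anova = an, tests = tests)
}
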