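#' Fit a conditional-intensity GLM to binned spike counts
#'
#' The central fitting function. Discretized spike counts are modeled as
#' Poisson with log mean \code{mu + beta*S(t) + B[interval(t)] + history
#' terms}, i.e. the log conditional intensity of the point process is linear
#' in the covariates, and the lagged own-spike counts act as a K-th order
#' autoregressive process (the spike-history-predicted discharge, SHPD).
#' Coefficients are maximum-likelihood via iteratively reweighted least
#' squares; the coefficient covariance is the inverse observed information
#' at the optimum.
#'
#' Fits with any coefficient magnitude above 15 (a rate-ratio beyond 3e6)
#' are flagged as degenerate (separation) and are excluded from population
#' aggregation.
#'
#' @param x A \code{tmaze_session}, \code{count_series}, or a list of either
#'   (typically the baseline and stress sessions of one unit, fitted
#'   jointly).
#' @param model Model id: \code{"1a"}, \code{"1b"}, \code{"2"}, \code{"3"},
#'   \code{"h0"} or \code{"inhom"} (see [model_spec()]).
#' @param unit Unit id when \code{x} contains sessions with several units.
#' @param obs_bin Observation bin width, seconds.
#' @param order,history_bin,reference_interval Passed to [model_spec()].
#' @param epsilon,maxit IRLS convergence tolerance (relative change in
#'   log-likelihood / deviance) and iteration cap.
#' @return An object of class \code{ciglm}: coefficients, covariance,
#'   log-likelihood, deviance, convergence and degeneracy flags, the design
#'   and bookkeeping needed by [time_rescale()] and the methods
#'   \code{print}, \code{summary}, \code{coef}, \code{vcov}, \code{logLik},
#'   \code{predict}, \code{residuals}, \code{fitted}, \code{anova} and
#'   \code{plot}.
#' @examples
#' cfg <- generator_config(n_trials = 8, seed = 7)
#' set.seed(7)
#' s <- simulate_session(cfg)
#' fit <- ciglm(s, model = "1b")
#' coef(fit)[1:3]
#' gains(fit, "alpha")
#' @export
ciglm <- function(x, model = "1a", unit = NULL, obs_bin = 0.25,
                  order = 10, history_bin = 0.25,
                  reference_interval = "Delay",
                  epsilon = 1e-8, maxit = 100) {
  if (inherits(x, "tmaze_session") || inherits(x, "count_series"))
    x <- list(x)
  cs <- lapply(x, function(el) {
    if (inherits(el, "tmaze_session"))
      bin_session(el, unit = if (is.null(unit)) names(el$spikes)[1] else unit,
                  bin_width = obs_bin)
    else el
  })
  spec <- model_spec(model, order = order, history_bin = history_bin,
                     reference_interval = reference_interval)
  d <- build_design(cs, spec)
  fit_design(d, cs, epsilon = epsilon, maxit = maxit)
}

# Poisson ML on a prepared design; shared by ciglm() and the pipeline.
fit_design <- function(d, cs, epsilon = 1e-8, maxit = 100) {
  X <- d$X; y <- d$y
  if (length(y) != nrow(X)) stop("rows of design and counts differ")
  if (any(y < 0) || any(y != round(y))) stop("counts must be nonnegative integers")
  f <- suppressWarnings(
    glm.fit(X, y, family = poisson(),
            control = glm.control(epsilon = epsilon, maxit = maxit)))
  beta <- f$coefficients
  mu_hat <- f$fitted.values
  W <- sqrt(mu_hat)
  info <- crossprod(X * W)
  V <- tryCatch(chol2inv(chol(info)), error = function(e) {
    warning("singular information matrix; covariance via pseudo-inverse")
    svd_i <- svd(info)
    pos <- svd_i$d > max(svd_i$d) * 1e-12
    svd_i$v[, pos] %*% (t(svd_i$u[, pos]) / svd_i$d[pos])
  })
  dimnames(V) <- list(colnames(X), colnames(X))
  ll <- sum(dpois(y, mu_hat, log = TRUE))
  flagged <- !f$converged || any(abs(beta) > 15)
  structure(list(
    coefficients = beta, vcov = V, loglik = ll, deviance = f$deviance,
    converged = f$converged, flagged = flagged, iter = f$iter,
    n_bins = length(y), fitted = mu_hat, y = y,
    model = d$spec, columns = colnames(X),
    dropped = attr(X, "dropped"),
    meta = d$meta, series = cs
  ), class = "ciglm")
}

#' @export
print.ciglm <- function(x, ...) {
  cat("Conditional-intensity GLM (model ", x$model$model_id, ")\n", sep = "")
  cat("  bins:", x$n_bins, " spikes:", sum(x$y),
      " columns:", length(x$coefficients), "\n")
  cat("  deviance:", format(x$deviance, digits = 6),
      " logLik:", format(x$loglik, digits = 6), "\n")
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  if (x$flagged) cat("  flagged degenerate (separation guard)\n")
  invisible(x)
}

#' @export
summary.ciglm <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  out <- list(model = object$model, coefficients = tab,
              deviance = object$deviance, loglik = object$loglik,
              n_bins = object$n_bins, converged = object$converged,
              flagged = object$flagged)
  class(out) <- "summary.ciglm"
  out
}

#' @export
print.summary.ciglm <- function(x, ...) {
  cat("Conditional-intensity GLM (model ", x$model$model_id, "), ",
      x$n_bins, " bins\n", sep = "")
  printCoefmat(x$coefficients, digits = 4)
  cat("deviance:", format(x$deviance, digits = 6),
      "  logLik:", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' @export
coef.ciglm <- function(object, ...) object$coefficients

#' @export
vcov.ciglm <- function(object, ...) object$vcov

#' @export
logLik.ciglm <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_bins, class = "logLik")
}

#' @export
deviance.ciglm <- function(object, ...) object$deviance

#' @export
fitted.ciglm <- function(object, ...) object$fitted

#' Predicted conditional intensity
#'
#' @param object A [ciglm()] fit.
#' @param type \code{"count"} for expected counts per observation bin,
#'   \code{"rate"} for Hz.
#' @param ... Unused.
#' @return Numeric vector over the fitted (in-scope) bins, in design order.
#' @export
predict.ciglm <- function(object, type = c("count", "rate"), ...) {
  type <- match.arg(type)
  bw <- attr(object$series[[1]], "bin_width")
  if (type == "count") object$fitted else object$fitted / bw
}

#' @export
residuals.ciglm <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  y <- object$y; mu <- object$fitted
  if (type == "pearson") (y - mu) / sqrt(mu)
  else sign(y - mu) * sqrt(2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu)))
}

#' Spike-history gain profile (rate-ratios per lag)
#'
#' The spiking gain at lag k is the exponentiated history coefficient: the
#' fold-change in predicted discharge per spike observed k history bins in
#' the past, given everything else in the model. Wald confidence intervals
#' are formed on the log scale and exponentiated.
#'
#' @param object A [ciglm()] fit from a model with history terms.
#' @param which \code{"alpha"} (baseline) or \code{"eta"} (stress); models
#'   2/3 interpret these as the interaction gains in the target window.
#' @param level Confidence level (default 0.95).
#' @return Data frame with \code{lag_s}, \code{gain}, \code{lo}, \code{hi},
#'   \code{condition}, \code{model_id}.
#' @export
gains <- function(object, which = c("alpha", "eta"), level = 0.95) {
  which <- match.arg(which)
  nm <- grep(paste0("^", which, "_"), object$columns, value = TRUE)
  if (!length(nm))
    stop("model ", object$model$model_id, " has no ", which, " columns",
         if (!is.null(object$dropped) &&
             any(grepl(paste0("^", which, "_"), object$dropped)))
           " (dropped: single-condition input)" else "")
  k <- as.integer(sub(".*_", "", nm))
  est <- object$coefficients[nm]
  se <- sqrt(diag(object$vcov)[nm])
  zc <- qnorm(1 - (1 - level) / 2)
  data.frame(lag_s = k * object$model$history_bin,
             gain = exp(est), lo = exp(est - zc * se),
             hi = exp(est + zc * se),
             condition = if (which == "alpha") "baseline" else "stress",
             model_id = object$model$model_id,
             row.names = NULL)
}

#' @rdname gains
#' @export
gain_profile <- gains

#' Plot the spiking-gain profile of a fit
#'
#' Baseline and stress gain curves against history lag, with Wald bands and
#' the no-modulation line at 1.
#'
#' @param x A [ciglm()] fit with history terms.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ciglm <- function(x, ...) {
  ga <- gains(x, "alpha")
  ge <- tryCatch(gains(x, "eta"), error = function(e) NULL)
  ylim <- range(ga$lo, ga$hi, if (!is.null(ge)) c(ge$lo, ge$hi), 1)
  graphics::plot(ga$lag_s, ga$gain, type = "b", pch = 16, ylim = ylim,
                 xlab = "history lag (s)", ylab = "spiking gain (rate-ratio)",
                 ...)
  graphics::arrows(ga$lag_s, ga$lo, ga$lag_s, ga$hi, angle = 90, code = 3,
                   length = 0.03)
  if (!is.null(ge)) {
    graphics::lines(ge$lag_s, ge$gain, type = "b", pch = 1, col = 2)
    graphics::arrows(ge$lag_s, ge$lo, ge$lag_s, ge$hi, angle = 90, code = 3,
                     length = 0.03, col = 2)
    graphics::legend("topright", c("baseline", "stress"), pch = c(16, 1),
                     col = c(1, 2), bty = "n")
  }
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Deviance (likelihood-ratio) test between nested fits
#'
#' The deviance difference between a reduced and a full model is chi-square
#' with degrees of freedom equal to the number of extra columns, under the
#' reduced model. Errors for non-nested inputs, since non-nested
#' conditional-intensity models cannot be compared this way.
#'
#' @param full,reduced [ciglm()] fits on the same observation rows;
#'   \code{reduced}'s columns must be a subset of \code{full}'s.
#' @return List with \code{chi2}, \code{df}, \code{p}.
#' @export
deviance_test <- function(full, reduced) {
  if (full$n_bins != reduced$n_bins)
    stop("fits use different observation rows; cannot compare")
  if (!all(reduced$columns %in% full$columns))
    stop("models are not nested (reduced columns ",
         paste(setdiff(reduced$columns, full$columns), collapse = ", "),
         " absent from full); non-nested models cannot be compared ",
         "by the deviance test")
  chi2 <- reduced$deviance - full$deviance
  df <- length(full$columns) - length(reduced$columns)
  p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' @export
anova.ciglm <- function(object, ...) {
  others <- list(...)
  if (!length(others) || !inherits(others[[1]], "ciglm"))
    stop("supply two ciglm fits: anova(reduced, full)")
  full <- others[[1]]
  dt <- deviance_test(full, object)
  out <- data.frame(
    df = c(length(object$columns), length(full$columns)),
    deviance = c(object$deviance, full$deviance),
    chi2 = c(NA, dt$chi2), p = c(NA, dt$p),
    row.names = paste("model", c(object$model$model_id,
                                 full$model$model_id)))
  class(out) <- c("anova", "data.frame")
  out
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up FDR correction at level \code{q}; a thin wrapper over
#' \code{p.adjust(..., method = "BH")} returning both the rejection flags
#' and the adjusted p values.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List with \code{rejected} (logical) and \code{adjusted}.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p values must lie in [0, 1]")
  adj <- p.adjust(pvalues, method = "BH")
  list(rejected = adj <= q, adjusted = adj)
}
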