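#' Discretize a session's spike train into a labeled count series
#'
#' Bins one unit's spikes into contiguous half-open bins spanning the
#' session, and labels every bin with its behavioral interval, trial,
#' condition indicator and analysis scope. Bins are assigned labels by their
#' start time. A bin is in scope when it starts inside an analyzed trial
#' (correct, excluding trial 1); out-of-scope bins still carry counts so
#' history covariates can be computed over continuous session time.
#'
#' @param x A \code{tmaze_session}.
#' @param unit Unit id; defaults to the first unit in the session.
#' @param bin_width Observation bin width in seconds (default 250 ms, equal
#'   to the history lag width so counts and lags share one grid).
#' @return A \code{count_series}: data frame with columns \code{time} (bin
#'   start), \code{count}, \code{interval}, \code{trial}, \code{in_scope},
#'   and attributes \code{bin_width}, \code{condition}, \code{session_id},
#'   \code{unit}.
#' @export
bin_session <- function(x, unit = names(x$spikes)[1], bin_width = 0.25) {
  stopifnot(inherits(x, "tmaze_session"), bin_width > 0)
  if (!unit %in% names(x$spikes)) stop("unknown unit '", unit, "'")
  spk <- x$spikes[[unit]]
  span <- session_span(x)
  n_bins <- as.integer(ceiling((span[2] - span[1]) / bin_width - 1e-9))
  edges <- span[1] + (0:n_bins) * bin_width
  if (length(spk) && (min(spk) < span[1] || max(spk) >= edges[n_bins + 1]))
    stop("spikes outside the session span")
  counts <- tabulate(findInterval(spk, edges), nbins = n_bins)
  starts <- edges[-(n_bins + 1)]
  ivs <- session_intervals(x)
  idx <- findInterval(starts, ivs$start)
  lab <- ivs$label[idx]
  trial <- ivs$trial_index[idx]
  analyzed <- correct_trials(x)$trials$trial_index
  out <- data.frame(time = starts, count = counts,
                    interval = factor(lab, levels = INTERVALS),
                    trial = trial,
                    in_scope = trial %in% analyzed,
                    stringsAsFactors = FALSE)
  structure(out, class = c("count_series", "data.frame"),
            bin_width = bin_width, condition = x$condition,
            session_id = x$session_id, unit = unit)
}

#' Lagged spike-count history covariates
#'
#' Column \code{k} at a bin starting at time \code{t} holds the total spike
#' count in the window \code{[t - k*delta, t - (k-1)*delta)}. Lags run over
#' continuous session time, crossing trial and interval boundaries. Bins
#' whose full history span precedes the start of the series are marked
#' incomplete (attribute \code{"complete"}) and are dropped from the fitting
#' scope downstream.
#'
#' @param cs A [bin_session()] count series.
#' @param K History order (number of lags).
#' @param delta History lag width, seconds; must be an integer multiple of
#'   the observation bin width.
#' @return Integer matrix with \code{K} columns named \code{lag1..lagK} and
#'   attribute \code{"complete"}.
#' @export
history_matrix <- function(cs, K = 10, delta = attr(cs, "bin_width")) {
  bw <- attr(cs, "bin_width")
  m <- delta / bw
  if (abs(m - round(m)) > 1e-9)
    stop("delta must be an integer multiple of the bin width")
  m <- as.integer(round(m))
  n <- nrow(cs)
  counts <- cs$count
  cum <- c(0L, cumsum(counts))   # cum[i+1] = spikes in bins 1..i
  H <- matrix(0L, n, K, dimnames = list(NULL, paste0("lag", seq_len(K))))
  i <- seq_len(n)
  for (k in seq_len(K)) {
    hi <- pmax(i - (k - 1L) * m - 1L, 0L)  # last bin of window k
    lo <- pmax(i - k * m - 1L, 0L)         # bin before window k
    H[, k] <- cum[hi + 1L] - cum[lo + 1L]
  }
  attr(H, "complete") <- i > K * m
  H
}

#' Specification of a conditional-intensity model
#'
#' The model family: \code{h0} (homogeneous Poisson, intercept only),
#' \code{inhom} (intercept + behavioral-interval effects), \code{1b}
#' (intercept + stress + condition-split history), \code{1a} (1b +
#' behavioral intervals), and the interaction models \code{2} and \code{3}
#' (intercept + global history + stress + one composite-window effect +
#' condition-split history-by-window interactions, with the window being the
#' extended delay for model 2 and the Run-Branch-Choice response for
#' model 3).
#'
#' @param model_id One of \code{"h0"}, \code{"inhom"}, \code{"1a"},
#'   \code{"1b"}, \code{"2"}, \code{"3"}.
#' @param order History order K (default 10; the history span is
#'   \code{K * history_bin}).
#' @param history_bin History lag width, seconds.
#' @param reference_interval Reference level for interval coding (its effect
#'   is absorbed into the intercept); default Delay.
#' @return A \code{ciglm_spec} list (fields include \code{target}, the
#'   composite window of models 2/3).
#' @export
model_spec <- function(model_id = c("1a", "1b", "2", "3", "h0", "inhom"),
                       order = 10, history_bin = 0.25,
                       reference_interval = "Delay") {
  model_id <- match.arg(model_id)
  stopifnot(order >= 1, history_bin > 0,
            reference_interval %in% INTERVALS)
  target <- switch(model_id, "2" = "ExtendedDelay", "3" = "Response", NULL)
  structure(list(model_id = model_id, order = as.integer(order),
                 history_bin = history_bin,
                 reference_interval = reference_interval,
                 target = target),
            class = "ciglm_spec")
}

#' Build the design matrix of a conditional-intensity model
#'
#' Assembles the named covariate columns for the requested model over the
#' in-scope bins of one or more count series (typically the baseline and
#' stress sessions of one unit, fitted jointly). Interval effects use
#' reference coding against the chosen reference interval. Condition-split
#' history columns (\code{alpha_k} baseline, \code{eta_k} stress) are
#' history times the condition indicator; when the input contains a single
#' condition the structurally zero off-condition columns are dropped.
#'
#' @param cs A \code{count_series} or list of them.
#' @param spec A [model_spec()].
#' @return List with design matrix \code{X} (rows = in-scope bins with
#'   complete history), response \code{y}, and per-row bookkeeping
#'   (\code{series}, \code{time}, \code{interval}, \code{stress}).
#' @export
build_design <- function(cs, spec = model_spec("1a")) {
  if (inherits(cs, "count_series")) cs <- list(cs)
  K <- spec$order
  parts <- lapply(seq_along(cs), function(si) {
    s <- cs[[si]]
    H <- history_matrix(s, K = K, delta = spec$history_bin)
    keep <- s$in_scope & attr(H, "complete")
    data.frame(series = si, time = s$time, count = s$count,
               interval = s$interval,
               stress = as.numeric(attr(s, "condition") == "stress"),
               keep = keep)
  })
  Hs <- lapply(seq_along(cs), function(si)
    history_matrix(cs[[si]], K = K, delta = spec$history_bin))
  meta <- do.call(rbind, parts)
  H <- do.call(rbind, Hs)
  keep <- meta$keep
  meta <- meta[keep, , drop = FALSE]
  H <- H[keep, , drop = FALSE]
  y <- meta$count
  S <- meta$stress
  n <- nrow(meta)
  iv_dummies <- function() {
    lv <- setdiff(INTERVALS, spec$reference_interval)
    D <- sapply(lv, function(l) as.numeric(meta$interval == l))
    colnames(D) <- paste0("B_", lv)
    D
  }
  hist_split <- function() {
    A <- H * (1 - S); E <- H * S
    colnames(A) <- paste0("alpha_", seq_len(K))
    colnames(E) <- paste0("eta_", seq_len(K))
    cbind(A, E)
  }
  X <- switch(spec$model_id,
    h0 = matrix(1, n, 1, dimnames = list(NULL, "mu")),
    inhom = cbind(mu = 1, iv_dummies()),
    "1b" = cbind(mu = 1, stress = S, hist_split()),
    "1a" = cbind(mu = 1, stress = S, iv_dummies(), hist_split()),
    "2" = , "3" = {
      G <- H; colnames(G) <- paste0("gamma_", seq_len(K))
      D <- as.numeric(meta$interval %in% COMPOSITES[[spec$target]])
      A <- H * D * (1 - S); E <- H * D * S
      colnames(A) <- paste0("alpha_", seq_len(K))
      colnames(E) <- paste0("eta_", seq_len(K))
      cbind(mu = 1, G, stress = S,
            setNames(data.frame(D), paste0("D_", spec$target)), A, E)
    })
  X <- as.matrix(X)
  zero <- apply(X == 0, 2, all)
  if (any(zero)) {
    dropped <- colnames(X)[zero]
    one_cond <- length(unique(S)) == 1
    if (!one_cond)
      stop("structurally zero columns in design: ",
           paste(dropped, collapse = ", "))
    X <- X[, !zero, drop = FALSE]
    attr(X, "dropped") <- dropped
  }
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("design is rank deficient; offending columns: ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]],
               collapse = ", "))
  list(X = X, y = y, spec = spec,
       meta = meta[c("series", "time", "interval", "stress")])
}
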