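#' Cumulative intensity of a fitted model
#'
#' The fitted conditional intensity is piecewise constant within observation
#' bins (expected count / bin width); its integral is therefore piecewise
#' linear and nondecreasing. Returned per fitted series, over the in-scope
#' bins the model was estimated on.
#'
#' @param object A converged [ciglm()] fit.
#' @return List with one element per series: \code{time} (bin starts),
#'   \code{increment} (expected counts per bin) and \code{Lambda} (cumulative
#'   intensity at bin ends, in expected-count units).
#' @export
cumulative_intensity <- function(object) {
  bw <- attr(object$series[[1]], "bin_width")
  out <- list()
  for (si in unique(object$meta$series)) {
    rows <- object$meta$series == si
    inc <- object$fitted[rows]
    out[[si]] <- list(time = object$meta$time[rows], increment = inc,
                      Lambda = cumsum(inc), bin_width = bw)
  }
  out
}

#' Time-rescale spikes through a fitted conditional intensity
#'
#' Under a correct model, transforming spike times by the cumulative
#' intensity turns the train into a unit-rate Poisson process; the
#' transformed inter-spike intervals \code{tau_j = Lambda(t_j) -
#' Lambda(t_(j-1))} then give \code{z_j = 1 - exp(-tau_j)} uniform on
#' \[0, 1\]. Rescaling runs over the in-scope bins of each fitted series
#' (the first in-scope spike of each series seeds the recursion and yields
#' no z value); spikes keep their recorded times, with exact ties spread
#' uniformly across their bin.
#'
#' @param object A converged [ciglm()] fit.
#' @param spikes Numeric vector of spike times, or a list of one vector per
#'   fitted series (session clock). Defaults to the spike train of the unit
#'   the fit was built from, when sessions were supplied to [ciglm()].
#' @return Numeric vector of z values in \[0, 1\] (class
#'   \code{rescaled_sample}).
#' @export
time_rescale <- function(object, spikes = NULL) {
  if (!object$converged) stop("fit did not converge; rescaling undefined")
  bw <- attr(object$series[[1]], "bin_width")
  if (is.null(spikes))
    stop("supply spike times (the count series does not retain them)")
  if (!is.list(spikes)) spikes <- list(spikes)
  n_series <- length(unique(object$meta$series))
  if (length(spikes) == 1 && n_series > 1)
    stop("supply one spike vector per fitted series")
  z_all <- numeric(0)
  for (si in seq_len(n_series)) {
    rows <- which(object$meta$series == si)
    tt <- object$meta$time[rows]
    inc <- object$fitted[rows]
    cumL <- c(0, cumsum(inc))
    sp <- sort(spikes[[si]])
    b <- findInterval(sp, tt)
    keep <- b >= 1 & (sp - tt[pmax(b, 1)]) < bw
    sp <- sp[keep]; b <- b[keep]
    if (length(sp) < 2) next
    frac <- (sp - tt[b]) / bw
    if (anyDuplicated(sp)) {          # exact ties: spread across the bin
      for (bb in unique(b[duplicated(sp)])) {
        ii <- which(b == bb)
        frac[ii] <- (seq_along(ii) - 0.5) / length(ii)
      }
    }
    L <- cumL[b] + inc[b] * frac
    tau <- diff(L)
    z_all <- c(z_all, 1 - exp(-tau))
  }
  structure(z_all, class = "rescaled_sample")
}

#' Kolmogorov-Smirnov summary of a rescaled sample
#'
#' Orders the rescaled z values, compares them with the uniform quantiles
#' \code{(j - 0.5)/n}, and reports the maximal deviation D against the
#' standard K-S equivalency band (half-width \code{1.36/sqrt(n)} at 95\%,
#' \code{1.63/sqrt(n)} at 99\%). A model fits when the empirical quantiles
#' stay within the band.
#'
#' @param z A [time_rescale()] result (values in \[0, 1\]).
#' @param level 0.95 or 0.99.
#' @return List with \code{D}, \code{band}, \code{pass}, \code{n} and the
#'   quantile pairs (\code{uniform}, \code{empirical}) for plotting.
#' @export
ks_summary <- function(z, level = 0.95) {
  n <- length(z)
  if (n < 2) stop("need at least 2 rescaled spikes")
  if (any(z < 0 | z > 1)) stop("z values must lie in [0, 1]")
  const <- if (level >= 0.99) 1.63 else 1.36
  zs <- sort(unclass(z))
  b <- (seq_len(n) - 0.5) / n
  D <- max(abs(zs - b))
  band <- const / sqrt(n)
  list(D = D, band = band, pass = D <= band, n = n,
       uniform = b, empirical = zs)
}

#' K-S plot of a rescaled spike train
#'
#' Empirical against uniform quantiles with the 95\% equivalency band; a
#' well-fit model tracks the diagonal within the dotted bounds.
#'
#' @param x A [time_rescale()] result.
#' @param level Band level.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rescaled_sample <- function(x, level = 0.95, ...) {
  ks <- ks_summary(x, level)
  graphics::plot(ks$uniform, ks$empirical, type = "l",
                 xlab = "uniform quantiles", ylab = "empirical quantiles",
                 ...)
  graphics::abline(0, 1)
  graphics::abline(ks$band, 1, lty = 3)
  graphics::abline(-ks$band, 1, lty = 3)
  invisible(ks)
}
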