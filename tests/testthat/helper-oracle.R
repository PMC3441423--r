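# Independent brute-force oracle: exhaustive Poisson log-likelihood search
# on a coefficient lattice. Never calls the package's fitting path.
#
# ll(b) = sum_i [ y_i * x_i'b - exp(x_i'b) ]   (up to the constant -log(y!))

grid_argmax_loglik <- function(X, y, lo = -1, hi = 1, step = 0.01) {
  p <- ncol(X)
  g <- seq(lo, hi, by = step)
  xty <- drop(crossprod(X, y))
  if (p == 1) {
    ll <- xty * g - colSums(exp(outer(X[, 1], g)))
    return(g[which.max(ll)])
  }
  E <- lapply(seq_len(p), function(j) exp(outer(X[, j], g)))
  if (p == 2) {
    lin <- outer(xty[1] * g, xty[2] * g, "+")
    S <- crossprod(E[[1]], E[[2]])
    ll <- lin - S
    idx <- arrayInd(which.max(ll), dim(ll))
    return(g[idx])
  }
  if (p == 3) {
    best <- -Inf; arg <- NULL
    lin12 <- outer(xty[1] * g, xty[2] * g, "+")
    for (k in seq_along(g)) {
      S <- crossprod(E[[1]] * E[[3]][, k], E[[2]])
      ll <- lin12 + xty[3] * g[k] - S
      m <- which.max(ll)
      if (ll[m] > best) {
        best <- ll[m]
        idx <- arrayInd(m, dim(ll))
        arg <- c(g[idx], g[k])
      }
    }
    return(arg)
  }
  stop("oracle supports up to 3 columns")
}

# Random tiny Poisson design with interior truth; returns X, y.
random_tiny_design <- function(p, n, seed) {
  set.seed(seed)
  X <- cbind(1, matrix(sample(0:2, n * (p - 1), replace = TRUE,
                              prob = c(0.6, 0.3, 0.1)), n))
  b <- runif(p, -0.5, 0.5)
  y <- rpois(n, exp(drop(X %*% b)))
  list(X = X, y = y, b = b)
}
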