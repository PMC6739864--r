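# Independent oracles used across the suite.  These deliberately avoid the
# package's analytic/vectorised code paths: the Gabor oracle rasterises the
# truncated filter and the grating on a fine pixel grid; the posterior
# oracle evaluates the generative model by plain per-hypothesis loops with
# numerically differentiated rate densities.

# pixel-grid quadrature of the Gabor-grating inner product, same uDC/uAC
# calibration as the analytic response (truncation 4*width, step lambda/40)
quadrature_response <- function(fl, st, uDC = -60, uAC = 12) {
  d <- fl$width
  h <- min(fl$spatial_period, st$spatial_period) / 40
  g <- seq(-4 * d, 4 * d, by = h)
  X <- outer(g, rep(1, length(g))) + fl$x
  Y <- outer(rep(1, length(g)), g) + fl$y
  th <- fl$orientation * pi / 180
  vth <- st$orientation * pi / 180
  kx <- sin(th) / fl$spatial_period; ky <- -cos(th) / fl$spatial_period
  sx <- sin(vth) / st$spatial_period; sy <- -cos(vth) / st$spatial_period
  w <- exp(-((X - fl$x)^2 + (Y - fl$y)^2) / (2 * d^2))
  filt <- w * cos(2 * pi * (kx * (X - fl$x) + ky * (Y - fl$y)) -
                    fl$phase * pi / 180)
  stim <- st$contrast * cos(2 * pi * (sx * X + sy * Y) - st$phase * pi / 180)
  uDC + uAC / (pi * d^2) * sum(filt * stim) * h^2
}

# brute-force posterior over classes: loops over every hypothesis, computes
# each neuron's rate likelihood from first principles (numerical derivative
# of the rate CDF for r > 0), no log-sum-exp tricks beyond plain sums
posterior_oracle <- function(rates, means, class, sigma, nl) {
  H <- nrow(means); K <- max(class)
  lik_r <- function(r, g) {
    if (r == 0) return(pnorm((nl$threshold - g) / sigma))
    cdf <- function(rr) pnorm((nl$threshold + (rr / nl$prefactor)^(1 / nl$exponent) - g) / sigma)
    eps <- 1e-6 * max(r, 1)
    lo <- max(r - eps, r / 2)
    (cdf(r + eps) - cdf(lo)) / (r + eps - lo)
  }
  post <- matrix(0, nrow(rates), K)
  for (m in seq_len(nrow(rates))) {
    for (h in seq_len(H)) {
      p <- 1
      for (nn in seq_len(ncol(rates))) p <- p * lik_r(rates[m, nn], means[h, nn])
      post[m, class[h]] <- post[m, class[h]] + p
    }
  }
  post / rowSums(post)
}

# small default fixture population shared by several files
tiny_pop <- function(N = 24, seed = 301) {
  set.seed(seed)
  make_population(N = N)
}
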