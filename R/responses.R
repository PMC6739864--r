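#' Membrane-potential noise model
#'
#' Additive Gaussian noise applied to mean membrane potentials.  Noise is
#' drawn independently in 20 ms time bins (one draw per stimulus row); the
#' covariance is \eqn{\Sigma_{ii} = \sigma^2} on the diagonal and
#' \eqn{\Sigma_{ij} = \rho\sigma^2} uniformly off the diagonal.
#'
#' @param sigma noise standard deviation per cell, mV.  May be a vector of
#'   per-cell values for heterogeneous populations (in which case `rho` must
#'   be 0).
#' @param rho uniform pairwise noise correlation, in `[0, 1)`.
#' @param bin_width width of the iid sampling bin, seconds.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(sigma = 3, rho = 0, bin_width = 0.02) {
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  if (rho < 0 || rho >= 1) {
    stop("rho must be in [0, 1) for a positive semi-definite covariance",
         call. = FALSE)
  }
  if (rho > 0 && length(sigma) > 1L) {
    stop("correlated noise requires a common sigma", call. = FALSE)
  }
  structure(list(sigma = sigma, rho = rho, bin_width = bin_width),
            class = "noise_model")
}

#' Sample stochastic membrane potentials
#'
#' Adds one multivariate-Gaussian noise draw (one 20 ms bin) to each row of a
#' matrix of mean membrane potentials.  Uniform correlations are sampled
#' exactly via a shared standard-normal component:
#' \eqn{u = \mu + \sigma(\sqrt{\rho}\, z_0 + \sqrt{1-\rho}\, z_i)}.
#'
#' @param means M x N matrix of mean membrane potentials, mV.
#' @param noise a [noise_model()].
#' @return M x N matrix of membrane potentials, mV.  Reproducible under
#'   `set.seed()`.
#' @export
sample_membrane_potentials <- function(means, noise = noise_model()) {
  M <- nrow(means); N <- ncol(means)
  if (all(noise$sigma == 0)) return(means)
  z <- matrix(stats::rnorm(M * N), M, N)
  if (noise$rho > 0) {
    shared <- stats::rnorm(M)
    z <- sqrt(noise$rho) * shared + sqrt(1 - noise$rho) * z
  }
  if (length(noise$sigma) > 1L) {
    if (length(noise$sigma) != N) {
      stop("length(sigma) must equal the number of neurons", call. = FALSE)
    }
    z <- sweep(z, 2L, noise$sigma, `*`)
  } else {
    z <- z * noise$sigma
  }
  means + z
}

#' Threshold-power-law firing rate nonlinearity
#'
#' The map from membrane potential to instantaneous firing rate,
#' \eqn{r(u) = \Phi \lfloor u - u_{th} \rfloor_+^{\kappa}}, where
#' \eqn{\lfloor\cdot\rfloor_+} denotes rectification.
#'
#' @param threshold firing threshold \eqn{u_{th}}, mV.
#' @param exponent power-law exponent \eqn{\kappa \ge 1}.
#' @param prefactor scale \eqn{\Phi} in Hz/mV^kappa; its value does not
#'   affect decoding results.
#' @return An object of class `"frnl"`.
#' @export
frnl <- function(threshold, exponent = 1, prefactor = 16.7) {
  if (any(exponent < 1)) stop("exponent must be >= 1", call. = FALSE)
  stop_if_not_positive(prefactor, "prefactor")
  structure(list(threshold = threshold, exponent = exponent,
                 prefactor = prefactor),
            class = "frnl")
}

#' Apply the firing rate nonlinearity
#'
#' @param u membrane potentials (vector or matrix), mV.
#' @param nl an [frnl()] object.  For a matrix `u`, `threshold` and
#'   `exponent` may be per-neuron (per-column) vectors, as in heterogeneous
#'   populations.
#' @return Firing rates in Hz, same shape as `u`.
#' @examples
#' apply_frnl(c(-50, -44), frnl(threshold = -45, exponent = 1))
#' @export
apply_frnl <- function(u, nl) {
  per_cell <- length(nl$threshold) > 1L || length(nl$exponent) > 1L
  if (per_cell && is.matrix(u)) {
    r <- pmax(sweep(u, 2L, rep_len(nl$threshold, ncol(u))), 0)
    kap <- rep_len(nl$exponent, ncol(u))
    if (any(kap != 1)) {
      r <- sweep(r, 2L, kap, `^`)
    }
  } else {
    r <- pmax(u - nl$threshold, 0)
    if (any(nl$exponent != 1)) r <- r^nl$exponent
  }
  nl$prefactor * r
}

#' Population activity sparseness
#'
#' Fraction of exactly-zero entries across all (stimulus, neuron) pairs of a
#' firing-rate matrix: 0 when every response is superthreshold, 1 when all
#' are silenced, and non-decreasing in the firing threshold.
#'
#' @param rates matrix (or vector) of firing rates, Hz; must be non-negative.
#' @return A fraction in `[0, 1]`.
#' @export
sparseness <- function(rates) {
  if (length(rates) == 0L) stop("empty rate matrix", call. = FALSE)
  if (any(rates < 0)) stop("firing rates must be >= 0", call. = FALSE)
  mean(rates == 0)
}
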