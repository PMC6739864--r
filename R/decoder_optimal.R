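#' Generative model for optimal Bayesian decoding
#'
#' Packages everything the ideal observer knows about the response process:
#' the noise-free mean membrane potential of every neuron for every stimulus
#' hypothesis on a discrete grid, the Gaussian membrane-potential noise, the
#' firing rate nonlinearity, and uniform priors over the hypothesis grid.
#' Membrane potentials are Gaussian around the filter response
#' (\eqn{p(u_n|\vartheta,\phi) = N(u_n; g_n(\vartheta,\phi), \sigma^2)});
#' the firing-rate likelihood mixes a point mass at zero rate,
#' \eqn{p^0_n(\vartheta,\phi) = \Pr(u_n \le u_{th})}, with the
#' change-of-variables density \eqn{\rho_n(r_n|\vartheta,\phi) =
#' p(u_n|\vartheta,\phi)\,(dr/du)^{-1}} for \eqn{r_n > 0}.
#'
#' @param pop a [make_population()] object.
#' @param noise a [noise_model()]; only the marginal standard deviation is
#'   used (the ideal observer here assumes independent noise).
#' @param stimuli a [gratings()] table: the hypothesis grid, typically the
#'   same orientation-within-class x phase grid used to build stimulus banks.
#' @param class integer class label in `1..K` for each hypothesis row.
#' @param nl an [frnl()] object, or `NULL` to supply one per call to
#'   [optimal_posterior()] (as in threshold sweeps).
#' @return An object of class `"generative_model"`.
#' @export
generative_model <- function(pop, noise, stimuli, class, nl = NULL) {
  stimuli <- as_gratings(stimuli)
  class <- as.integer(class)
  if (length(class) != nrow(stimuli)) {
    stop("one class label per hypothesis row required", call. = FALSE)
  }
  structure(
    list(means = population_means(pop, stimuli), stimuli = stimuli,
         class = class, K = max(class), sigma = noise$sigma, nl = nl),
    class = "generative_model"
  )
}

#' Posterior over stimulus classes from the optimal Bayesian decoder
#'
#' Computes, for each response row, the posterior probability of each class
#' by marginalising the per-neuron firing-rate likelihood over the hypothesis
#' grid (nuisance phase bins and within-class orientation bins):
#' \eqn{p(\vartheta_k|r) \propto \sum_j \prod_n p(r_n|\vartheta_k,\phi_j)\,
#' p(\vartheta_k) p(\phi_j)}.  All accumulation is in the log domain with
#' log-sum-exp, so products over hundreds of neurons never underflow.
#'
#' @param rates M x N matrix of firing rates, Hz (or membrane potentials if
#'   `nl$threshold` lies below every sampled potential, in which case the
#'   likelihood reduces to the Gaussian membrane-potential model).
#' @param model a [generative_model()].
#' @param nl an [frnl()]; defaults to the one stored in the model.  Exponents
#'   below 1 are rejected (the change of variables needs an invertible
#'   one-sided derivative at threshold; for `exponent = 1` the derivative is
#'   the prefactor).
#' @return M x K matrix of class posteriors; rows sum to 1.
#' @export
optimal_posterior <- function(rates, model, nl = model$nl) {
  if (is.null(nl)) stop("an frnl must be supplied", call. = FALSE)
  if (any(nl$exponent < 1)) {
    stop("exponent must be >= 1 for an invertible rate density", call. = FALSE)
  }
  rates <- as.matrix(rates)
  M <- nrow(rates); N <- ncol(rates)
  K <- model$K
  if (N == 0L) {
    return(matrix(1 / K, max(M, 1L), K))
  }
  if (N != ncol(model$means)) {
    stop("rate columns do not match the model population", call. = FALSE)
  }
  if (any(rates < 0)) stop("firing rates must be >= 0", call. = FALSE)

  G <- model$means                       # H x N
  sig <- rep_len(model$sigma, N)
  w <- 1 / (2 * sig^2)

  logp0 <- stats::pnorm((nl$threshold - G) / rep(sig, each = nrow(G)),
                        log.p = TRUE)

  mask <- rates > 0
  u <- nl$threshold + (rates / nl$prefactor)^(1 / nl$exponent)
  u[!mask] <- 0

  mu <- mask * u
  t1 <- (mu * u) %*% w                               # M x 1
  t2 <- sweep(mu, 2L, w, `*`) %*% t(G)               # M x H
  t3 <- sweep(mask + 0, 2L, w, `*`) %*% t(G * G)     # M x H
  loglik <- -(as.vector(t1) - 2 * t2 + t3) + (1 - mask) %*% t(logp0)

  # uniform priors over the hypothesis grid: constant, absorbed by
  # normalisation.  Sum hypotheses within each class in the log domain.
  mx <- apply(loglik, 1L, max)
  e <- exp(loglik - mx)
  cmat <- matrix(0, nrow(G), K)
  cmat[cbind(seq_len(nrow(G)), model$class)] <- 1
  post <- e %*% cmat
  post / rowSums(post)
}

#' Posterior under information-limiting correlations
#'
#' Information-limiting correlations are modelled as stochastic jitter of the
#' encoded orientation itself: the presented orientation \eqn{\vartheta} is
#' drawn from a (wrapped) normal around the true orientation \eqn{\Theta}
#' with circular SD `sd_theta` degrees.  The posterior over the true
#' orientation marginalises the jittered orientations:
#' \eqn{p(\Theta|r) = \sum_\vartheta p(\vartheta|r) p(\vartheta|\Theta)},
#' renormalised.  As `sd_theta` approaches 0 this reduces to
#' [optimal_posterior()]; as it grows the posterior flattens to uniform.
#'
#' @inheritParams optimal_posterior
#' @param sd_theta orientation jitter SD, degrees; must be positive.
#' @return M x K matrix of class posteriors over the true orientation.
#' @export
ilc_posterior <- function(rates, model, sd_theta, nl = model$nl) {
  stop_if_not_positive(sd_theta, "sd_theta")
  # fine posterior over distinct grid orientations (marginal over phase)
  ori <- model$stimuli$orientation
  lev <- sort(unique(ori))
  fine_model <- model
  fine_model$class <- match(ori, lev)
  fine_model$K <- length(lev)
  q <- optimal_posterior(rates, fine_model, nl = nl)

  # wrapped-normal mixing kernel on the 180-degree orientation circle
  d <- outer(lev, lev, `-`)
  kern <- 0
  for (s in -2:2) kern <- kern + stats::dnorm(d + 180 * s, 0, sd_theta)
  p_theta <- q %*% kern

  # aggregate true-orientation grid points into the model's classes
  cls <- model$class[match(lev, ori)]
  cmat <- matrix(0, length(lev), model$K)
  cmat[cbind(seq_along(lev), cls)] <- 1
  post <- p_theta %*% cmat
  post / rowSums(post)
}
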