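#' Equal-probability-mass class partition
#'
#' Partitions a stimulus-parameter distribution into `K` classes of equal
#' probability mass.  Class edges are the `k/K` quantiles and class centers
#' the mid-mass quantiles `(k - 0.5)/K`.
#'
#' @param qfun quantile function of the parameter distribution (e.g.
#'   `function(p) qlnorm(p, 0.95, 0.55)` for the natural spatial-period
#'   distribution).
#' @param K number of classes.
#' @return List with `edges` (K - 1 interior boundaries) and `centers`
#'   (length K).
#' @export
equal_mass_classes <- function(qfun, K) {
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  edges <- qfun(seq_len(K - 1) / K)
  if (any(!is.finite(edges)) || any(diff(edges) <= 0) && K > 2) {
    stop("degenerate distribution: class edges are not increasing",
         call. = FALSE)
  }
  list(edges = edges, centers = qfun((seq_len(K) - 0.5) / K))
}

#' Decode a nuisance feature (spatial period or contrast)
#'
#' Measures the threshold dependence of linear decodability when the decoded
#' variable is not orientation but the spatial period or the contrast of the
#' grating.  Classes are `K` equal-probability-mass partitions of the
#' target's natural distribution; within-class values are placed on the
#' distorted grid so every class holds the same number of grid stimuli.
#' All other stimulus parameters -- including orientation -- are variable
#' nuisances.  The encoding population should carry period-diverse filters
#' (periods sampled from the stimulus period distribution) so the feature is
#' represented; see the `filter_periods` helper logic in the example.
#'
#' @param target `"spatial_period"` or `"contrast"`.
#' @param pop a [make_population()] object, typically built with `lambda`
#'   drawn from the stimulus period distribution.
#' @param noise a [noise_model()].
#' @param K decoded classes.
#' @param Mwithin within-class bins of the target feature.
#' @param Mori orientation nuisance grid points.
#' @param Mphi phase nuisance grid points.
#' @param Mrep,Mrep_test noise repetitions.
#' @param thresholds threshold grid, mV.
#' @param period_meanlog,period_sdlog,contrast_shape1,contrast_shape2
#'   natural-distribution parameters.
#' @param decoder_opts passed to [train_linear_decoder()].
#' @return A `"sweep_result"` (linear decoder only).
#' @export
decode_nuisance <- function(target = c("spatial_period", "contrast"),
                            pop, noise = noise_model(), K = 4, Mwithin = 5,
                            Mori = 20, Mphi = 20, Mrep = 2, Mrep_test = 4,
                            thresholds = NULL,
                            period_meanlog = 0.95, period_sdlog = 0.55,
                            contrast_shape1 = 2.4, contrast_shape2 = 3.6,
                            decoder_opts = list()) {
  target <- match.arg(target)
  stop_if_not_positive(period_sdlog, "period_sdlog")
  stop_if_not_positive(contrast_shape1, "contrast_shape1")
  qfun <- if (target == "spatial_period") {
    function(p) stats::qlnorm(p, period_meanlog, period_sdlog)
  } else {
    function(p) stats::qbeta(p, contrast_shape1, contrast_shape2)
  }
  # distorted grid over the target: equal counts per equal-mass class
  tv <- qfun((seq_len(K * Mwithin) - 0.5) / (K * Mwithin))
  tlab <- ceiling(seq_along(tv) / Mwithin)

  grid <- expand.grid(ti = seq_along(tv),
                      orientation = 180 * (seq_len(Mori) - 0.5) / Mori,
                      phase = 360 * (seq_len(Mphi) - 0.5) / Mphi,
                      KEEP.OUT.ATTRS = FALSE)
  S <- nrow(grid)
  other <- if (target == "spatial_period") {
    distorted_grid(function(p) stats::qbeta(p, contrast_shape1,
                                            contrast_shape2), S)
  } else {
    distorted_grid(function(p) stats::qlnorm(p, period_meanlog,
                                             period_sdlog), S)
  }
  stimuli <- if (target == "spatial_period") {
    gratings(grid$orientation, grid$phase, tv[grid$ti], other)
  } else {
    gratings(grid$orientation, grid$phase, other, tv[grid$ti])
  }
  stimuli$label <- tlab[grid$ti]

  means <- population_means(pop, stimuli)
  draw <- function(mrep) {
    idx <- rep(seq_len(S), times = mrep)
    list(u = sample_membrane_potentials(means[idx, , drop = FALSE], noise),
         labels = stimuli$label[idx], stim = idx)
  }
  bank <- structure(
    list(stimuli = stimuli, means = means, train = draw(Mrep),
         test = draw(Mrep_test), K = K, spec = NULL),
    class = "stimulus_bank"
  )
  threshold_sweep(pop, noise, bank, thresholds, which = "linear",
                  decoder_opts = decoder_opts)
}
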