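#' Specification of a labelled stimulus bank
#'
#' Describes the stimulus set used to train and test decoders.  Orientation
#' is discretised into `K` decoded classes with `Mtheta` within-class bins
#' (the grid of `K * Mtheta` orientations covers `[0, 180)` uniformly,
#' zero-anchored like the population's preferred orientations, so the first
#' orientation of each class lies at the class's lower edge).  Phase has
#' `Mphi` grid values.  Each grid stimulus is
#' repeated `Mrep` times in the training bank and `Mrep_test` times in the
#' test bank with independent membrane-potential noise, so the training bank
#' holds `M = K * Mtheta * Mphi * Mrep` rows.  Nuisance parameters are either
#' fixed (phase 180 degrees, spatial period 3 degrees, contrast 0.5) or
#' variable; variable phase is the uniform grid, while variable spatial
#' period (lognormal, `meanlog = 0.95`, `sdlog = 0.55`) and contrast (beta,
#' `shape1 = 2.4`, `shape2 = 3.6` -- distributions matched to natural image
#' statistics) are drawn by a distorted grid: equally spaced probability
#' levels mapped through the inverse CDF and assigned to grid nodes by a
#' random permutation.
#'
#' @param K number of orientation classes.
#' @param Mtheta within-class orientation bins.
#' @param Mphi phase bins (all equal to `phase_value` when phase is fixed).
#' @param Mrep,Mrep_test noise repetitions per grid stimulus for the
#'   training and test banks.
#' @param phase,spatial_period,contrast `"fixed"` or `"variable"`.
#' @param ilc_sd information-limiting-correlation width, degrees: when
#'   positive, each presented orientation is jittered around its grid value
#'   by a (wrapped) normal with this SD while the class label stays that of
#'   the grid value, emulating noise correlations aligned with the
#'   orientation signal itself.
#' @param phase_value,period_value,contrast_value values used when fixed.
#' @param period_meanlog,period_sdlog lognormal parameters of the variable
#'   spatial-period distribution.
#' @param contrast_shape1,contrast_shape2 beta parameters of the variable
#'   contrast distribution.
#' @return An object of class `"bank_spec"`.
#' @export
bank_spec <- function(K = 10, Mtheta = 10, Mphi = 50, Mrep = 20,
                      Mrep_test = 50,
                      phase = c("variable", "fixed"),
                      spatial_period = c("fixed", "variable"),
                      contrast = c("fixed", "variable"),
                      phase_value = 180, period_value = 3,
                      contrast_value = 0.5,
                      period_meanlog = 0.95, period_sdlog = 0.55,
                      contrast_shape1 = 2.4, contrast_shape2 = 3.6,
                      ilc_sd = 0) {
  phase <- match.arg(phase)
  spatial_period <- match.arg(spatial_period)
  contrast <- match.arg(contrast)
  if (spatial_period == "variable") {
    stop_if_not_positive(period_sdlog, "period_sdlog")
  }
  if (contrast == "variable") {
    stop_if_not_positive(contrast_shape1, "contrast_shape1")
    stop_if_not_positive(contrast_shape2, "contrast_shape2")
  }
  stop_if_not_positive(period_value, "period_value")
  out <- as.list(environment())
  structure(out, class = "bank_spec")
}

#' @export
print.bank_spec <- function(x, ...) {
  v <- function(mode) if (mode == "variable") "variable" else "fixed"
  cat(sprintf(
    "<bank_spec> K=%d Mtheta=%d Mphi=%d Mrep=%d/%d (M=%d train rows)\n",
    x$K, x$Mtheta, x$Mphi, x$Mrep, x$Mrep_test,
    x$K * x$Mtheta * x$Mphi * x$Mrep))
  cat(sprintf("  phase %s, spatial period %s, contrast %s\n",
              v(x$phase), v(x$spatial_period), v(x$contrast)))
  invisible(x)
}

# distorted-grid draw: equally spaced probability mass mapped through the
# inverse CDF, randomly assigned to grid nodes
distorted_grid <- function(qfun, n) {
  qfun((seq_len(n) - 0.5) / n)[sample.int(n)]
}

#' Build train/test membrane-potential banks
#'
#' Realises a [bank_spec()] against a population: constructs the stimulus
#' grid with class labels, computes noise-free mean responses once, and adds
#' independent membrane-potential noise draws for the training and test
#' repetitions.  Training and test banks share the stimulus grid but never a
#' noise draw.
#'
#' @param pop a [make_population()] object.
#' @param spec a [bank_spec()].
#' @param noise a [noise_model()].
#' @return An object of class `"stimulus_bank"`: list with `stimuli` (grid
#'   data frame including `label`), `means` (grid x neurons matrix), `train`
#'   and `test` (each with membrane-potential matrix `u`, `labels`, and
#'   `stim` row indices into the grid), and `K`.
#' @export
build_bank <- function(pop, spec, noise = noise_model()) {
  S_theta <- spec$K * spec$Mtheta
  # zero-anchored uniform grids, the same convention as the preferred
  # orientations of the encoding population: the first orientation of each
  # class sits at the class's lower edge
  theta <- 180 * (seq_len(S_theta) - 1) / S_theta
  label <- rep(ceiling(seq_len(S_theta) / spec$Mtheta), times = spec$Mphi)
  phi <- if (spec$phase == "variable") {
    360 * (seq_len(spec$Mphi) - 1) / spec$Mphi
  } else {
    rep(spec$phase_value, spec$Mphi)
  }
  grid <- expand.grid(orientation = theta, phase = phi,
                      KEEP.OUT.ATTRS = FALSE)
  S <- nrow(grid)

  lam <- if (spec$spatial_period == "variable") {
    distorted_grid(function(p) stats::qlnorm(p, spec$period_meanlog,
                                             spec$period_sdlog), S)
  } else {
    spec$period_value
  }
  con <- if (spec$contrast == "variable") {
    distorted_grid(function(p) stats::qbeta(p, spec$contrast_shape1,
                                            spec$contrast_shape2), S)
  } else {
    spec$contrast_value
  }
  ori <- grid$orientation
  if (spec$ilc_sd > 0) {
    ori <- ori + stats::rnorm(S, 0, spec$ilc_sd)
  }
  stimuli <- gratings(ori, grid$phase, lam, con)
  stimuli$label <- label

  means <- population_means(pop, stimuli)
  draw <- function(mrep) {
    idx <- rep(seq_len(S), times = mrep)
    list(u = sample_membrane_potentials(means[idx, , drop = FALSE], noise),
         labels = stimuli$label[idx], stim = idx)
  }
  structure(
    list(stimuli = stimuli, means = means, train = draw(spec$Mrep),
         test = draw(spec$Mrep_test), K = spec$K, spec = spec),
    class = "stimulus_bank"
  )
}

#' @export
print.stimulus_bank <- function(x, ...) {
  cat(sprintf(
    "<stimulus_bank> %d grid stimuli, K=%d classes, %d train / %d test rows, %d neurons\n",
    nrow(x$stimuli), x$K, nrow(x$train$u), nrow(x$test$u), ncol(x$means)))
  invisible(x)
}
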