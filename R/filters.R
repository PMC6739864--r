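#' Circular Gabor receptive-field filters
#'
#' Constructs a table of circular Gabor filters.  Each filter is described by
#' six parameters: the coordinates of its center measured from the line of
#' sight (`x`, `y`, degrees of visual angle), the spatial period of its plane
#' wave component (`spatial_period`, degrees), the preferred orientation of
#' the sinusoidal component (`orientation`, degrees in `[0, 180)`), the phase
#' offset of the sinusoidal component relative to the filter center (`phase`,
#' degrees in `[0, 360)`), and the standard deviation of the circular
#' Gaussian envelope (`width`, degrees).
#'
#' @param x,y filter center coordinates, degrees of visual angle.
#' @param spatial_period spatial period of the plane-wave component, degrees;
#'   must be positive.
#' @param orientation preferred orientation, degrees; wrapped into
#'   `[0, 180)`.
#' @param phase phase offset relative to the filter center, degrees; wrapped
#'   into `[0, 360)`.
#' @param width envelope standard deviation, degrees; must be positive.
#'
#' @return A data frame with class `"gabor_filters"`, one row per filter.
#' @examples
#' gabor_filters(x = 0, y = 0, orientation = 45)
#' @export
gabor_filters <- function(x = 0, y = 0, spatial_period = 3, orientation = 0,
                          phase = 0, width = 2) {
  stop_if_not_positive(spatial_period, "spatial_period")
  stop_if_not_positive(width, "width")
  out <- data.frame(
    x = x, y = y,
    spatial_period = spatial_period,
    orientation = wrap_angle(orientation, 180),
    phase = wrap_angle(phase, 360),
    width = width
  )
  class(out) <- c("gabor_filters", "data.frame")
  out
}

#' Noise-free membrane-potential response of Gabor filters to gratings
#'
#' Computes the analytic mean membrane potential of circular Gabor filters
#' (infinite Gaussian envelope) responding to full-field sine-wave gratings.
#' The filter inner product has a closed form: writing \eqn{k} and \eqn{k_s}
#' for the filter and stimulus wave vectors (magnitudes \eqn{1/\lambda},
#' \eqn{1/\lambda_s}, directions set by the preferred and stimulus
#' orientations), the calibrated response is
#' \deqn{u = u_{DC} + c\, u_{AC} [\cos(\psi_s + \varphi - \phi) E_- +
#'       \cos(\psi_s - \varphi - \phi) E_+],}
#' with \eqn{E_\mp = \exp(-2\pi^2\delta^2 |k \mp k_s|^2)} and
#' \eqn{\psi_s = 2\pi(\sin\vartheta\, x - \cos\vartheta\, y)/\lambda_s} the
#' location phase of the stimulus at the filter center.  The scaling is such
#' that the phase-averaged response equals `uDC` and the modulation amplitude
#' at the preferred orientation, matched spatial period and 100% contrast
#' equals `uAC` (up to the vanishing \eqn{E_+} correction).  The AC component
#' scales linearly with contrast.  Filter and stimulus spatial periods may
#' differ; the expression above is the exact Gaussian integral for that case
#' and is validated against a pixel-grid quadrature oracle in the test suite.
#'
#' @param filters a [gabor_filters()] table (N filters).
#' @param stimuli a [gratings()] table (S stimuli).
#' @param uDC mean (phase-averaged) membrane potential, mV.
#' @param uAC modulation amplitude at preferred orientation and full
#'   contrast, mV.
#'
#' @return An S x N matrix of mean membrane potentials in mV.
#' @examples
#' f <- gabor_filters(orientation = 0, phase = 0)
#' s <- gratings(orientation = 0, phase = 0, contrast = 1, spatial_period = 3)
#' mean_response(f, s, uDC = -60, uAC = 12)  # ~ -48 mV
#' @export
mean_response <- function(filters, stimuli, uDC = -60, uAC = 12) {
  stimuli <- as_gratings(stimuli)
  stop_if_not_positive(filters$spatial_period, "spatial_period")
  stop_if_not_positive(filters$width, "width")

  th  <- deg2rad(filters$orientation)      # N
  phi <- deg2rad(filters$phase)            # N
  vth <- deg2rad(stimuli$orientation)      # S
  vph <- deg2rad(stimuli$phase)            # S
  lam  <- filters$spatial_period           # N
  lams <- stimuli$spatial_period           # S
  S <- nrow(stimuli); N <- nrow(filters)

  # S x N pairwise terms
  cosd <- cos(outer(-vth, th, `+`))                       # cos(theta - vartheta)
  inv2 <- outer(1 / lams^2, 1 / lam^2, `+`)
  cross <- 2 * cosd * outer(1 / lams, 1 / lam)
  d2 <- rep(filters$width^2, each = S)
  em <- exp(-2 * pi^2 * d2 * (inv2 - cross))
  ep <- exp(-2 * pi^2 * d2 * (inv2 + cross))

  psi <- 2 * pi * (outer(sin(vth) / lams, filters$x) -
                   outer(cos(vth) / lams, filters$y))
  pr <- rep(phi, each = S)                 # filter phase, S x N layout
  pc <- rep(vph, times = N)                # stimulus phase
  ac <- cos(psi + pr - pc) * em + cos(psi - pr - pc) * ep
  uDC + stimuli$contrast * uAC * ac
}

#' Model populations of visual neurons
#'
#' Builds a population of `N` model neurons of one of three kinds:
#' \describe{
#'   \item{`"v1"`}{simple cells with circular Gabor receptive fields.
#'     Preferred orientations evenly cover `[0, 180)`
#'     (\eqn{\theta_n = 180(n-1)/N}); filter phases evenly cover `[0, 360)`
#'     with a randomly permuted assignment so that phase and orientation are
#'     uncorrelated; centers are uniform over a disk of radius `R`.}
#'   \item{`"retina"`}{pixel-like point samplers at the same `N` locations:
#'     each neuron reads the grating value at its center, affinely calibrated
#'     so its noise-free response variance over a reference stimulus ensemble
#'     matches that of the corresponding V1 neuron.}
#'   \item{`"lgn"`}{center-surround neurons modelled as a balanced
#'     (equal-volume) difference of Gaussians with center and surround
#'     standard deviations `center_width` and `surround_width`, calibrated
#'     like the retina population.}
#' }
#'
#' @param N number of neurons.
#' @param kind one of `"v1"`, `"retina"`, `"lgn"`.
#' @param uDC,uAC baseline and modulation amplitude of V1 membrane
#'   potentials, mV.
#' @param lambda spatial period of the Gabor plane-wave component, degrees.
#'   May be a length-`N` vector for a period-diverse population (used when
#'   decoding spatial period).
#' @param delta envelope standard deviation of the Gabor filters, degrees.
#' @param R radius of the disk over which receptive-field centers are drawn,
#'   degrees (use 1.5 for the hypercolumn variant whose receptive fields share
#'   one retinotopic location within a 3-degree circle).
#' @param center_width,surround_width LGN difference-of-Gaussians standard
#'   deviations, degrees.
#' @param calibration_stimuli optional [gratings()] table over which
#'   retina/LGN responses are variance-matched to V1; defaults to a 24 x 24
#'   orientation/phase grid at full contrast and spatial period `lambda`.
#'
#' @return An object of class `"neural_population"`: a list with the filter
#'   table, response calibration, and the generating parameters.
#' @examples
#' pop <- make_population(N = 50)
#' pop
#' @export
make_population <- function(N = 500, kind = c("v1", "retina", "lgn"),
                            uDC = -60, uAC = 12, lambda = 3, delta = 2,
                            R = 90, center_width = 1.5, surround_width = 4,
                            calibration_stimuli = NULL) {
  kind <- match.arg(kind)
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  stop_if_not_positive(R, "R")

  theta <- 180 * (seq_len(N) - 1) / N
  phase <- wrap_angle(sample(360 * (seq_len(N) - 1) / N), 360)
  r <- R * sqrt(stats::runif(N))
  ang <- stats::runif(N, 0, 2 * pi)
  filters <- gabor_filters(
    x = r * cos(ang), y = r * sin(ang),
    spatial_period = lambda, orientation = theta, phase = phase,
    width = delta
  )

  pop <- structure(
    list(kind = kind, N = N, filters = filters, uDC = uDC, uAC = uAC,
         gain = NULL,
         params = list(lambda = lambda, delta = delta, R = R,
                       center_width = center_width,
                       surround_width = surround_width)),
    class = "neural_population"
  )

  if (kind != "v1") {
    if (is.null(calibration_stimuli)) {
      g <- expand.grid(orientation = 180 * (0:23) / 24,
                       phase = 360 * (0:23) / 24)
      calibration_stimuli <- gratings(g$orientation, g$phase,
                                      spatial_period = lambda[1L],
                                      contrast = 1)
    }
    v1_var <- apply(mean_response(filters, calibration_stimuli, 0, uAC),
                    2L, stats::var)
    pop$gain <- rep(1, N)
    raw_var <- apply(point_like_means(pop, calibration_stimuli, ac_only = TRUE),
                     2L, stats::var)
    pop$gain <- sqrt(v1_var / raw_var)
  }
  pop
}

# AC component of retina (pixel) and LGN (balanced DoG) responses, S x N.
# Retina: grating value at the filter center.  LGN: equal-volume DoG whose
# grating sensitivity is exp(-2 pi^2 dc^2/ls^2) - exp(-2 pi^2 ds^2/ls^2).
point_like_means <- function(pop, stimuli, ac_only = FALSE) {
  stimuli <- as_gratings(stimuli)
  vth <- deg2rad(stimuli$orientation)
  lams <- stimuli$spatial_period
  psi <- 2 * pi * (outer(sin(vth) / lams, pop$filters$x) -
                   outer(cos(vth) / lams, pop$filters$y))
  ac <- cos(psi - deg2rad(stimuli$phase))
  if (pop$kind == "lgn") {
    w <- exp(-2 * pi^2 * pop$params$center_width^2 / lams^2) -
         exp(-2 * pi^2 * pop$params$surround_width^2 / lams^2)
    ac <- ac * w
  }
  ac <- ac * stimuli$contrast
  ac <- sweep(ac, 2L, pop$gain, `*`)
  if (ac_only) ac else pop$uDC + ac
}

#' Noise-free population mean responses
#'
#' Mean membrane potentials of every neuron in a population for every
#' stimulus in a grating table, before noise is added.
#'
#' @param pop a [make_population()] object.
#' @param stimuli a [gratings()] table.
#' @return An S x N matrix of mean membrane potentials, mV.
#' @export
population_means <- function(pop, stimuli) {
  if (!inherits(pop, "neural_population")) {
    stop("'pop' must be a neural_population", call. = FALSE)
  }
  if (pop$kind == "v1") {
    mean_response(pop$filters, stimuli, pop$uDC, pop$uAC)
  } else {
    point_like_means(pop, stimuli)
  }
}

#' @export
print.neural_population <- function(x, ...) {
  cat(sprintf("<neural_population> kind=%s N=%d uDC=%g mV uAC=%g mV\n",
              x$kind, x$N, x$uDC, x$uAC))
  cat(sprintf("  lambda=%s deg, delta=%g deg, centers within R=%g deg\n",
              paste(format(unique(x$params$lambda)[1:min(3, length(unique(x$params$lambda)))],
                           digits = 3), collapse = ","),
              x$params$delta, x$params$R))
  invisible(x)
}
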