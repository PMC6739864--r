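#' Dependence of the optimal threshold on model parameters
#'
#' Reruns the phase-nuisance threshold sweep while varying one model
#' parameter (`uAC`, `sigma`, `N`, `K`, `rho`, or `kappa`) and records, for
#' each value, the noise-to-signal ratio, the normalised optimal threshold
#' `(uth_opt - uDC)/uAC`, and the peak linear fraction correct.  In the
#' model, jointly rescaling signal and noise leaves the normalised optimum
#' invariant, and the relation between noise-to-signal ratio and normalised
#' optimum collapses across `N`, `K` and `rho`; only the FRNL exponent
#' reshapes it.
#'
#' @param parameter which parameter to vary.
#' @param values values it takes.
#' @param N,K,uDC,uAC,sigma,rho,kappa base model parameters (Table defaults:
#'   a 500-cell Gabor population, 10 classes, -60/12 mV, 3 mV noise,
#'   uncorrelated, linear FRNL); the swept parameter's base value is
#'   ignored.
#' @param Mtheta,Mphi,Mrep,Mrep_test bank sizes (reduced from the asymptotic
#'   bank by default to keep scans tractable).
#' @param thresholds threshold grid; defaults to 1 mV spacing over the MP
#'   range of each model.
#' @param decoder_opts passed to [train_linear_decoder()].
#' @return A data frame with one row per value: `parameter`, `value`,
#'   `noise_to_signal`, `normalised_optimum`, `optimal_threshold`,
#'   `peak_fc`.
#' @export
parameter_scan <- function(parameter = c("uAC", "sigma", "N", "K", "rho",
                                         "kappa"),
                           values, N = 500, K = 10, uDC = -60, uAC = 12,
                           sigma = 3, rho = 0, kappa = 1,
                           Mtheta = 5, Mphi = 25, Mrep = 2, Mrep_test = 4,
                           thresholds = NULL, decoder_opts = list()) {
  parameter <- match.arg(parameter)
  rows <- lapply(values, function(v) {
    a <- list(N = N, K = K, uDC = uDC, uAC = uAC, sigma = sigma, rho = rho,
              kappa = kappa)
    a[[parameter]] <- v
    pop <- make_population(N = a$N, uDC = a$uDC, uAC = a$uAC)
    nm <- noise_model(sigma = a$sigma, rho = a$rho)
    bank <- build_bank(pop, bank_spec(K = a$K, Mtheta = Mtheta, Mphi = Mphi,
                                      Mrep = Mrep, Mrep_test = Mrep_test),
                       nm)
    sw <- threshold_sweep(pop, nm, bank,
                          thresholds %||% default_threshold_grid(pop, nm),
                          which = "linear", exponent = a$kappa,
                          decoder_opts = decoder_opts)
    data.frame(parameter = parameter, value = v,
               noise_to_signal = a$sigma / a$uAC,
               normalised_optimum = sw$normalised_optimum,
               optimal_threshold = sw$optimal_threshold,
               peak_fc = max(sw$table$fc_linear))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Robust-performance regimes of the firing threshold
#'
#' For each noise-to-signal ratio, computes the interval of normalised
#' thresholds `(uth - uDC)/uAC` that retains at least `level` (default 90%)
#' of peak performance for every FRNL exponent in `kappas`.  Two criteria
#' are supported: `"ru"` keeps >= `level` of the peak linear decoding
#' fraction correct (a bounded interval), and `"infomax"` keeps >= `level`
#' of the maximal total information (optimal-decoder mutual information);
#' since total information is non-increasing in the threshold, the infomax
#' regime always extends to infinitely low thresholds and only its upper
#' edge is informative.
#'
#' @param ratios noise-to-signal ratios `sigma/uAC` at which to compute the
#'   regime (e.g. the ratios of recorded cells).
#' @param criterion `"ru"` or `"infomax"`.
#' @param level retained fraction of peak performance.
#' @param kappas FRNL exponents whose admissible sets are intersected.
#' @param z_grid grid of normalised thresholds.
#' @param N,K,uDC,uAC population and task parameters of the homogeneous
#'   model populations (the normalised regime collapses across `N` and `K`,
#'   so reduced populations give the same intervals).
#' @param Mtheta,Mphi,Mrep,Mrep_test bank sizes.
#' @param n_eval_optimal test rows used for the optimal decoder (infomax).
#' @param decoder_opts passed to [train_linear_decoder()].
#' @return An object of class `"robust_regime"`: list with `criterion`,
#'   `level`, `kappas`, and `table` (per ratio: `ratio`, `lo`, `hi`).  Band
#'   edges are placed where the performance curve crosses the criterion by
#'   linear interpolation between grid points (snapping to the outermost
#'   admissible grid point would systematically narrow the band); an empty
#'   intersection is recorded as `NA` edges, never an error.
#' @export
robust_regime <- function(ratios, criterion = c("ru", "infomax"),
                          level = 0.9, kappas = c(1, 1.25, 1.5, 1.75, 2),
                          z_grid = seq(-1.5, 1.5, by = 1 / 6),
                          N = 100, K = 10, uDC = -60, uAC = 12,
                          Mtheta = 5, Mphi = 24, Mrep = 2, Mrep_test = 4,
                          n_eval_optimal = 600, decoder_opts = list()) {
  criterion <- match.arg(criterion)
  if (any(kappas < 1) || any(kappas > 2)) {
    stop("kappas must lie within [1, 2]", call. = FALSE)
  }
  z_grid <- sort(z_grid)

  # continuous band edges of one performance curve: expand from the argmax
  # while the score stays above the cut, then place the edge where linear
  # interpolation crosses the cut (grid snapping would systematically
  # narrow the band)
  band <- function(z, s, cut) {
    i <- which.max(s)
    a <- i
    while (a > 1L && s[a - 1L] >= cut) a <- a - 1L
    b <- i
    while (b < length(s) && s[b + 1L] >= cut) b <- b + 1L
    lo <- if (a == 1L) -Inf else {
      z[a] - (z[a] - z[a - 1L]) * (s[a] - cut) / (s[a] - s[a - 1L])
    }
    hi <- if (b == length(s)) Inf else {
      z[b] + (z[b + 1L] - z[b]) * (s[b] - cut) / (s[b] - s[b + 1L])
    }
    c(lo, hi)
  }

  rows <- lapply(ratios, function(rt) {
    pop <- make_population(N = N, uDC = uDC, uAC = uAC)
    nm <- noise_model(sigma = rt * uAC)
    bank <- build_bank(pop, bank_spec(K = K, Mtheta = Mtheta, Mphi = Mphi,
                                      Mrep = Mrep, Mrep_test = Mrep_test),
                       nm)
    lo <- -Inf
    hi <- Inf
    for (kap in kappas) {
      sw <- threshold_sweep(pop, nm, bank, thresholds = uDC + z_grid * uAC,
                            which = if (criterion == "ru") "linear" else "optimal",
                            exponent = kap, n_eval_optimal = n_eval_optimal,
                            decoder_opts = decoder_opts)
      score <- if (criterion == "ru") sw$table$fc_linear else sw$table$mi_bits
      bd <- band(z_grid, score, level * max(score))
      lo <- max(lo, bd[1L])
      hi <- min(hi, bd[2L])
    }
    # total information can only decrease with the threshold, so the
    # infomax band always extends to infinitely low thresholds
    if (criterion == "infomax") lo <- -Inf
    if (lo > hi) {
      data.frame(ratio = rt, lo = NA_real_, hi = NA_real_)
    } else {
      data.frame(ratio = rt, lo = lo, hi = hi)
    }
  })
  structure(list(criterion = criterion, level = level, kappas = kappas,
                 table = do.call(rbind, rows)),
            class = "robust_regime")
}

#' @export
print.robust_regime <- function(x, ...) {
  cat(sprintf("<robust_regime> criterion=%s level=%.0f%% kappas=%s\n",
              x$criterion, 100 * x$level,
              paste(x$kappas, collapse = ",")))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Test membership of normalised thresholds in a robust regime
#'
#' @param regime a [robust_regime()].
#' @param ratio noise-to-signal ratio(s) of the queried cells; regime edges
#'   are linearly interpolated between computed ratios (constant beyond the
#'   computed range).
#' @param z normalised threshold(s) `(uth - uDC)/uAC`.
#' @return Logical vector: inside the regime or not.
#' @export
in_regime <- function(regime, ratio, z) {
  tab <- regime$table
  # clamp infinite edges to finite sentinels so interpolation stays defined
  interp <- function(y) {
    y <- pmin(pmax(y, -1e30), 1e30)
    if (nrow(tab) == 1L) return(rep(y[1L], length(ratio)))
    stats::approx(tab$ratio, y, xout = ratio, rule = 2)$y
  }
  lo <- interp(tab$lo)
  hi <- interp(tab$hi)
  !is.na(lo) & !is.na(hi) & z >= lo & z <= hi
}

#' Heterogeneous-population threshold perturbation experiment
#'
#' Builds a population in which FRNL exponent and noise SD vary across cells
#' over a grid of parameter combinations (default 5 x 5), with a block of
#' cells per combination.  Each cell's firing threshold is set to the value
#' that is optimal for a homogeneous population with that cell's parameters
#' (thresholds are optimised locally, not jointly).  The threshold vector is
#' then perturbed at a series of Euclidean distances and the linear decoding
#' performance (decoder retrained per perturbation) is recorded against the
#' distance, together with the unperturbed reference and a quadratic fit.
#'
#' @param kappas,sigmas parameter values combined into the grid.
#' @param n_per_combo cells per parameter combination.
#' @param radii Euclidean perturbation distances, mV.
#' @param n_draws random perturbation directions per radius.
#' @param K,uDC,uAC task and response parameters.
#' @param hom_N population size of the homogeneous models used to find each
#'   combination's optimal threshold.
#' @param z_grid normalised threshold grid for the homogeneous
#'   optimisation.
#' @param Mtheta,Mphi,Mrep,Mrep_test bank sizes.
#' @param decoder_opts passed to [train_linear_decoder()].
#' @return An object of class `"hetero_result"`: list with `samples`
#'   (data frame of `distance`, `fc`), `reference_fc`, `optima` (per-combo
#'   thresholds), and `quadratic` (coefficients of `fc ~ distance +
#'   distance^2`).
#' @export
heterogeneous_experiment <- function(kappas = c(1, 1.2, 1.4, 1.6, 1.8),
                                     sigmas = c(2, 2.5, 3, 3.5, 4),
                                     n_per_combo = 20,
                                     radii = c(1, 2, 4, 8, 16, 32),
                                     n_draws = 2, K = 10, uDC = -60,
                                     uAC = 12, hom_N = 100,
                                     z_grid = seq(-0.5, 1, by = 0.25),
                                     Mtheta = 5, Mphi = 20, Mrep = 2,
                                     Mrep_test = 4, decoder_opts = list()) {
  combos <- expand.grid(kappa = kappas, sigma = sigmas,
                        KEEP.OUT.ATTRS = FALSE)
  combos$uth_opt <- vapply(seq_len(nrow(combos)), function(i) {
    pop <- make_population(N = hom_N, uDC = uDC, uAC = uAC)
    nm <- noise_model(sigma = combos$sigma[i])
    bank <- build_bank(pop, bank_spec(K = K, Mtheta = Mtheta, Mphi = Mphi,
                                      Mrep = Mrep, Mrep_test = Mrep_test),
                       nm)
    threshold_sweep(pop, nm, bank, thresholds = uDC + z_grid * uAC,
                    which = "linear", exponent = combos$kappa[i],
                    decoder_opts = decoder_opts)$optimal_threshold
  }, numeric(1))

  N <- nrow(combos) * n_per_combo
  pop <- make_population(N = N, uDC = uDC, uAC = uAC)
  cell_combo <- rep(seq_len(nrow(combos)), each = n_per_combo)
  sig <- combos$sigma[cell_combo]
  kap <- combos$kappa[cell_combo]
  uth0 <- combos$uth_opt[cell_combo]
  nm <- noise_model(sigma = sig)
  bank <- build_bank(pop, bank_spec(K = K, Mtheta = Mtheta, Mphi = Mphi,
                                    Mrep = Mrep, Mrep_test = Mrep_test), nm)

  eval_at <- function(uth) {
    nl <- frnl(uth, kap)
    dec <- do.call(train_linear_decoder,
                   c(list(x = apply_frnl(bank$train$u, nl),
                          labels = bank$train$labels, K = K), decoder_opts))
    pred <- decode_linear(dec, apply_frnl(bank$test$u, nl))
    mean(pred$labels == bank$test$labels)
  }

  reference_fc <- eval_at(uth0)
  samples <- do.call(rbind, lapply(radii, function(r) {
    do.call(rbind, lapply(seq_len(n_draws), function(d) {
      dir <- stats::rnorm(N)
      dir <- dir / sqrt(sum(dir^2))
      data.frame(distance = r, fc = eval_at(uth0 + r * dir))
    }))
  }))
  samples <- rbind(data.frame(distance = 0, fc = reference_fc), samples)
  quad <- stats::lm(fc ~ distance + I(distance^2), data = samples)
  structure(list(samples = samples, reference_fc = reference_fc,
                 optima = combos, quadratic = stats::coef(quad)),
            class = "hetero_result")
}

#' @export
print.hetero_result <- function(x, ...) {
  cat(sprintf(
    "<hetero_result> %d combos, reference FC=%.3f, quadratic curvature=%.3g\n",
    nrow(x$optima), x$reference_fc, x$quadratic[["I(distance^2)"]]))
  invisible(x)
}
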