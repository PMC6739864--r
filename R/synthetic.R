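#' Intracellular cell parameters
#'
#' Ground-truth parameter set of a simulated simple cell: baseline membrane
#' potential `uDC` (mV), modulation depth `uAC` (mV), noise SD `sigma` (mV),
#' firing threshold `uth` (mV), FRNL exponent `kappa` and prefactor `phi`
#' (Hz/mV^kappa).
#'
#' @param uDC,uAC,sigma,uth,kappa,phi see description.
#' @return A list of class `"cell_params"`.
#' @export
cell_params <- function(uDC = -60, uAC = 12, sigma = 3, uth = -55,
                        kappa = 1, phi = 16.7) {
  stop_if_not_positive(uAC, "uAC")
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (kappa < 1) stop("kappa must be >= 1", call. = FALSE)
  structure(list(uDC = uDC, uAC = uAC, sigma = sigma, uth = uth,
                 kappa = kappa, phi = phi),
            class = "cell_params")
}

# stereotyped action-potential waveform: fast sinusoidal rise, exponential
# decay, brief after-hyperpolarisation.  Returns mV at times t (s) >= 0.
spike_waveform <- function(t, peak = 60, rise = 4e-4, decay_tau = 5e-4,
                           ahp = -3, ahp_tau = 2e-3) {
  w <- numeric(length(t))
  up <- t >= 0 & t < rise
  w[up] <- peak * sin(pi / 2 * t[up] / rise)^2
  dn <- t >= rise
  td <- t[dn] - rise
  w[dn] <- (peak - ahp) * exp(-td / decay_tau) + ahp * exp(-td / ahp_tau)
  w
}

#' Synthesise an intracellular voltage trace
#'
#' Emulates a whole-cell recording of a simple cell responding to a drifting
#' grating at its preferred parameters: each 3 s stimulus trial (preceded by
#' a 3 s gray screen at baseline) modulates the generator potential
#' sinusoidally at the 2 Hz temporal frequency (6 cycles per trial), with a
#' small trial-specific phase jitter.  Membrane-potential noise follows an
#' Ornstein-Uhlenbeck process with stationary SD `sigma` and a 20 ms
#' correlation time (the smooth counterpart of iid 20 ms noise bins).
#' Spikes are drawn from an inhomogeneous Poisson process whose rate is the
#' threshold-power-law function of the generator potential, and a
#' stereotyped 1-2 ms, ~60 mV action-potential waveform is added at each
#' spike time.  All ground truth (generator potential, spike times,
#' parameters) is stored in the returned object; downstream analysis
#' operations never read it -- only tests do.
#'
#' @param params a [cell_params()].
#' @param n_trials number of stimulus trials.
#' @param sampling_rate samples per second; at least 5 kHz so spike shapes
#'   are resolved.
#' @param temporal_frequency grating drift rate, Hz.
#' @param trial_duration stimulus duration per trial, s.
#' @param gray_duration gray-screen duration preceding each trial, s.
#' @param phase_jitter_sd SD of the trial-specific phase jitter, degrees of
#'   cycle phase.
#' @return An object of class `"voltage_trace"`: list with `samples` (mV),
#'   `time` (s), `sampling_rate`, `trials` (data frame of stimulus start/end
#'   times), `spike_times` (s), and `ground_truth` (generator potential,
#'   true parameters, jitters).
#' @export
synth_trace <- function(params, n_trials = 10, sampling_rate = 10000,
                        temporal_frequency = 2, trial_duration = 3,
                        gray_duration = 3, phase_jitter_sd = 10) {
  if (sampling_rate < 5000) {
    stop("sampling_rate too low to resolve spike waveforms (need >= 5 kHz)",
         call. = FALSE)
  }
  dt <- 1 / sampling_rate
  period <- gray_duration + trial_duration
  n <- round(n_trials * period * sampling_rate)
  time <- (seq_len(n) - 1) * dt

  trial_start <- (seq_len(n_trials) - 1) * period + gray_duration
  trials <- data.frame(start = trial_start, end = trial_start + trial_duration)
  jitter <- stats::rnorm(n_trials, 0, phase_jitter_sd)

  gen <- rep(params$uDC, n)
  for (i in seq_len(n_trials)) {
    sel <- time >= trials$start[i] & time < trials$end[i]
    gen[sel] <- params$uDC + params$uAC *
      sin(2 * pi * temporal_frequency * (time[sel] - trials$start[i]) +
            deg2rad(jitter[i]))
  }

  if (params$sigma > 0) {
    a <- exp(-dt / 0.02)   # 20 ms correlation time
    eps <- stats::rnorm(n, 0, params$sigma * sqrt(1 - a^2))
    noise <- numeric(n)
    noise[1L] <- stats::rnorm(1, 0, params$sigma)
    noise <- stats::filter(eps, a, method = "recursive",
                           init = noise[1L] / 1)
    noise <- as.numeric(noise)
    gen <- gen + noise
  }

  rate <- apply_frnl(gen, frnl(params$uth, params$kappa, params$phi))
  spikes <- which(stats::runif(n) < rate * dt)
  # enforce a 2 ms absolute refractory period
  if (length(spikes) > 1L) {
    keep <- spikes[1L]
    for (s in spikes[-1L]) {
      if ((s - keep[length(keep)]) * dt >= 2e-3) keep <- c(keep, s)
    }
    spikes <- keep
  }
  spike_times <- time[spikes]

  samples <- gen
  if (length(spikes)) {
    w_len <- round(0.004 * sampling_rate)
    for (s in spikes) {
      idx <- s:min(s + w_len, n)
      samples[idx] <- samples[idx] + spike_waveform(time[idx] - time[s])
    }
  }
  structure(
    list(samples = samples, time = time, sampling_rate = sampling_rate,
         trials = trials, spike_times = spike_times,
         temporal_frequency = temporal_frequency,
         ground_truth = list(params = params, generator = gen,
                             phase_jitter = jitter)),
    class = "voltage_trace"
  )
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf(
    "<voltage_trace> %.1f s at %g kHz, %d trials, %d spikes\n",
    length(x$samples) / x$sampling_rate, x$sampling_rate / 1000,
    nrow(x$trials), length(x$spike_times)))
  invisible(x)
}

#' Miniature end-to-end fixture
#'
#' A seconds-scale model that exercises every pipeline stage: a small Gabor
#' population, a phase-variable training/test bank, a trained linear decoder
#' and an optimal-decoder posterior.  Deterministic under `set.seed()`.
#'
#' @param n_small population size.
#' @param K orientation classes.
#' @param sigma noise SD, mV.
#' @return List with `pop`, `noise`, `bank`, `decoder`, `report` (linear
#'   test performance), and `posterior` (optimal-decoder posterior on the
#'   first test rows).
#' @export
fixture_population <- function(n_small = 8, K = 3, sigma = 3) {
  pop <- make_population(N = n_small)
  nm <- noise_model(sigma = sigma)
  bank <- build_bank(pop, bank_spec(K = K, Mtheta = 2, Mphi = 8, Mrep = 6,
                                    Mrep_test = 6, phase = "fixed"), nm)
  dec <- train_linear_decoder(bank$train$u, bank$train$labels, K = K)
  pred <- decode_linear(dec, bank$test$u)
  report <- performance(pred$prob, bank$test$labels, K = K)
  gm <- generative_model(pop, nm, bank$stimuli, bank$stimuli$label,
                         nl = frnl(min(bank$train$u) - 1))
  post <- optimal_posterior(apply_frnl(bank$test$u[1:8, , drop = FALSE],
                                       gm$nl), gm)
  list(pop = pop, noise = nm, bank = bank, decoder = dec, report = report,
       posterior = post)
}
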