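#' Default FRNL threshold grid
#'
#' A grid spanning the membrane-potential distribution from well below to
#' well above: `[uDC - uAC - 3*sigma, uDC + uAC + 3*sigma]`.
#'
#' @param pop a [make_population()] object.
#' @param noise a [noise_model()].
#' @param by grid spacing, mV.
#' @return Numeric vector of thresholds, mV.
#' @export
default_threshold_grid <- function(pop, noise, by = 1) {
  s <- max(noise$sigma)
  seq(pop$uDC - pop$uAC - 3 * s, pop$uDC + pop$uAC + 3 * s, by = by)
}

#' Sweep the FRNL threshold and measure decoding performance
#'
#' For each firing threshold on a grid, transforms the bank's fixed
#' membrane-potential draws into firing rates through the threshold-power-law
#' nonlinearity, retrains the linear decoder on the training rates, and
#' evaluates fraction correct on the test rates; optionally also evaluates
#' the optimal Bayesian decoder (fraction correct, probabilistic fraction
#' correct and mutual information on a subsample of test rows) and records
#' population sparseness and the sparseness-scaled prediction
#' `(fc_opt - chance) * sparseness + chance`.  Because the membrane-potential
#' draws are reused across thresholds, the lowest grid point (below the whole
#' membrane-potential distribution) reproduces membrane-potential decoding
#' exactly.
#'
#' @param pop a [make_population()] object.
#' @param noise the [noise_model()] used to build the bank (the optimal
#'   decoder needs its standard deviation).
#' @param bank a [build_bank()] object.
#' @param thresholds threshold grid in mV; defaults to
#'   [default_threshold_grid()] with 1 mV spacing.
#' @param which `"both"`, `"linear"`, or `"optimal"`.
#' @param exponent,prefactor FRNL shape shared by all thresholds.
#' @param n_eval_optimal number of test rows (evenly subsampled) on which
#'   the optimal decoder is evaluated.
#' @param refine if `TRUE`, rerun a 0.25 mV grid one coarse step either side
#'   of the coarse linear-decoding peak so the optimum is resolved finely.
#' @param decoder_opts list of arguments passed to
#'   [train_linear_decoder()].
#' @return An object of class `"sweep_result"`: list with `table` (one row
#'   per threshold: `threshold`, `fc_linear`, `se_linear`, `sparseness`,
#'   `fc_opt`, `pfc_opt`, `mi_bits`, `fc_predicted`), `optimal_threshold`
#'   (linear-decoding argmax, ties to the lowest threshold),
#'   `normalised_optimum` `(uth_opt - uDC)/uAC`, `noise_to_signal`
#'   `sigma/uAC`, and `all_chance` (flag set when the whole grid silences
#'   the population).
#' @export
threshold_sweep <- function(pop, noise, bank, thresholds = NULL,
                            which = c("both", "linear", "optimal"),
                            exponent = 1, prefactor = 16.7,
                            n_eval_optimal = 1000, refine = FALSE,
                            decoder_opts = list()) {
  which <- match.arg(which)
  if (is.null(thresholds)) thresholds <- default_threshold_grid(pop, noise)
  thresholds <- sort(thresholds)

  gm <- NULL
  eval_idx <- NULL
  if (which != "linear") {
    gm <- generative_model(pop, noise, bank$stimuli, bank$stimuli$label)
    n_eval <- min(n_eval_optimal, nrow(bank$test$u))
    eval_idx <- unique(round(seq(1, nrow(bank$test$u), length.out = n_eval)))
  }

  one <- function(th) {
    nl <- frnl(th, exponent, prefactor)
    r_test <- apply_frnl(bank$test$u, nl)
    sp <- sparseness(r_test)
    fc_lin <- se_lin <- NA_real_
    if (which != "optimal") {
      r_train <- apply_frnl(bank$train$u, nl)
      dec <- do.call(train_linear_decoder,
                     c(list(x = r_train, labels = bank$train$labels,
                            K = bank$K), decoder_opts))
      pred <- decode_linear(dec, r_test)
      perf <- performance(predictions = pred$labels,
                          labels = bank$test$labels, K = bank$K)
      fc_lin <- perf$fc; se_lin <- perf$se
    }
    fc_o <- pfc_o <- mi_o <- NA_real_
    if (which != "linear") {
      post <- optimal_posterior(r_test[eval_idx, , drop = FALSE], gm, nl = nl)
      perf_o <- performance(post, bank$test$labels[eval_idx], K = bank$K)
      fc_o <- perf_o$fc; pfc_o <- perf_o$pfc; mi_o <- perf_o$mi_bits
    }
    c(threshold = th, fc_linear = fc_lin, se_linear = se_lin,
      sparseness = sp, fc_opt = fc_o, pfc_opt = pfc_o, mi_bits = mi_o)
  }

  tab <- as.data.frame(do.call(rbind, lapply(thresholds, one)))
  if (refine && which != "optimal") {
    peak <- tab$threshold[which.max(tab$fc_linear)]
    step <- min(diff(thresholds))
    fine <- setdiff(seq(peak - step, peak + step, by = 0.25), tab$threshold)
    if (length(fine)) {
      tab <- rbind(tab, as.data.frame(do.call(rbind, lapply(fine, one))))
      tab <- tab[order(tab$threshold), ]
      rownames(tab) <- NULL
    }
  }
  tab$fc_predicted <- if (which == "both") {
    predicted_linear_fc(tab$fc_opt, tab$sparseness, 1 / bank$K)
  } else NA_real_

  uth_opt <- norm_opt <- NA_real_
  if (which != "optimal") {
    uth_opt <- tab$threshold[which.max(tab$fc_linear)]
    norm_opt <- (uth_opt - pop$uDC) / pop$uAC
  }
  structure(
    list(table = tab, optimal_threshold = uth_opt,
         normalised_optimum = norm_opt,
         noise_to_signal = max(noise$sigma) / pop$uAC,
         all_chance = all(tab$sparseness >= 1), which = which),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d thresholds (%s)", nrow(x$table), x$which))
  if (!is.na(x$optimal_threshold)) {
    cat(sprintf("; linear optimum at %.2f mV (normalised %.3f)",
                x$optimal_threshold, x$normalised_optimum))
  }
  if (x$all_chance) cat("; WARNING: grid entirely above the MP range")
  cat("\n")
  invisible(x)
}
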