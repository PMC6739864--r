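#' Decoding performance measures
#'
#' Summarises decoding quality on an evaluation set.  Three measures are
#' computed from class posteriors: the fraction of exact class matches (FC,
#' using the maximum-posterior label with ties broken to the lowest index);
#' the probabilistic fraction correct
#' \eqn{PFC = (\prod_m p(\vartheta_m | r))^{1/M}}, the geometric mean of the
#' posterior mass on the true class; and a Monte-Carlo mutual-information
#' estimate in bits, \eqn{I = H(\vartheta) + \frac{1}{M}\sum_m \log_2
#' p(\vartheta_m|r)} with \eqn{H(\vartheta) = \log_2 K} for uniform classes.
#' `log(PFC)` equals the same Monte-Carlo average (in nats) exactly, so PFC
#' is a deterministic transform of the information estimate.
#'
#' @param posterior M x K matrix of class posteriors, or `NULL` when only
#'   hard `predictions` are available (then PFC and MI are `NA`).
#' @param labels true class labels in `1..K`, length M >= 1.
#' @param predictions optional hard labels; defaults to the posterior argmax.
#' @param K number of classes; defaults to `ncol(posterior)`.
#' @param floor lower bound applied to posterior mass on the true label
#'   before taking logs; rows at the floor are counted in `floored`.
#' @return An object of class `"performance_report"`: list with `fc`, `se`
#'   (binomial standard error of `fc`), `pfc`, `mi_bits`, `chance`, `n`,
#'   `floored`.
#' @export
performance <- function(posterior = NULL, labels, predictions = NULL,
                        K = ncol(posterior), floor = 1e-12) {
  labels <- as.integer(labels)
  M <- length(labels)
  if (M < 1L) stop("at least one evaluation trial required", call. = FALSE)
  if (is.null(predictions)) {
    if (is.null(posterior)) {
      stop("supply a posterior or hard predictions", call. = FALSE)
    }
    predictions <- max.col(posterior, ties.method = "first")
  }
  fc <- mean(predictions == labels)
  pfc <- mi <- NA_real_
  floored <- 0L
  if (!is.null(posterior)) {
    p_true <- posterior[cbind(seq_len(M), labels)]
    floored <- sum(p_true < floor)
    lp <- log(pmax(p_true, floor))
    pfc <- exp(mean(lp))
    mi <- log2(K) + mean(lp) / log(2)
  }
  structure(
    list(fc = fc, se = sqrt(fc * (1 - fc) / M), pfc = pfc, mi_bits = mi,
         chance = 1 / K, n = M, floored = floored),
    class = "performance_report"
  )
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> FC=%.3f (SE %.3f, chance %.3f, n=%d)",
              x$fc, x$se, x$chance, x$n))
  if (!is.na(x$pfc)) cat(sprintf("  PFC=%.3f  MI=%.3f bits", x$pfc, x$mi_bits))
  cat("\n")
  invisible(x)
}

#' Sparseness-scaled prediction of linear decoding performance
#'
#' The performance a linear decoder is predicted to achieve from the total
#' information available (the optimal decoder's fraction correct) and the
#' population sparseness: `(fc_opt - chance) * sparseness + chance`.
#'
#' @param fc_opt optimal-decoder fraction correct, in `[0, 1]`.
#' @param sparseness fraction of zero firing-rate entries, in `[0, 1]`.
#' @param chance chance-level fraction correct (1/K).
#' @return Predicted fraction correct in `[0, 1]`.
#' @export
predicted_linear_fc <- function(fc_opt, sparseness, chance) {
  stopifnot(all(fc_opt >= 0 & fc_opt <= 1), all(sparseness >= 0 & sparseness <= 1),
            all(chance >= 0 & chance <= 1))
  (fc_opt - chance) * sparseness + chance
}
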