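#' Train a multinomial logistic (linear) decoder
#'
#' Fits a single-layer softmax decoder of `K` classes by minimising the
#' multinomial cross-entropy with Barzilai-Borwein gradient descent.  Weights
#' (including a bias per class) may take positive and negative values.  A
#' weak L2 penalty (`l2`, default 1e-8) fixes the softmax gauge so the
#' optimum is unique; features are internally standardised (training mean and
#' SD, reapplied at test time) for optimisation conditioning, which leaves
#' the decoder's predictions invariant.
#'
#' @param x M x N matrix of responses (membrane potentials in mV or firing
#'   rates in Hz), one row per stimulus presentation.
#' @param labels integer class labels in `1..K`, length M; each class must
#'   occur at least once.
#' @param K number of classes; defaults to `max(labels)`.
#' @param max_iter iteration cap; non-convergence within the cap is flagged
#'   in the returned metadata, not silently ignored.
#' @param tol convergence tolerance on the relative objective decrease.
#' @param l2 L2 penalty fixing the softmax gauge.
#' @return An object of class `"linear_decoder"` with elements `weights`
#'   (an (N+1) x K matrix, first row the biases, on the standardised scale),
#'   `center`, `scale`, `K`, and `meta` (iterations, final objective,
#'   gradient norm, `converged` flag).
#' @seealso [decode_linear()]
#' @export
train_linear_decoder <- function(x, labels, K = max(labels),
                                 max_iter = 600L, tol = 1e-10, l2 = 1e-8) {
  x <- as.matrix(x)
  M <- nrow(x)
  labels <- as.integer(labels)
  if (length(labels) != M) stop("labels must match rows of x", call. = FALSE)
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  if (any(labels < 1L | labels > K)) stop("labels out of 1..K", call. = FALSE)
  if (length(unique(labels)) < K) {
    stop("every class must occur in the training set", call. = FALSE)
  }

  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- cbind(1, sweep(sweep(x, 2L, center), 2L, scale, `/`))
  p1 <- ncol(xs)

  y <- matrix(0, M, K)
  y[cbind(seq_len(M), labels)] <- 1

  obj_grad <- function(w) {
    eta <- xs %*% w
    eta <- eta - apply(eta, 1L, max)
    pe <- exp(eta)
    p <- pe / rowSums(pe)
    nll <- -mean(eta[cbind(seq_len(M), labels)] - log(rowSums(pe)))
    list(obj = nll + 0.5 * l2 * sum(w * w),
         grad = crossprod(xs, p - y) / M + l2 * w)
  }

  w <- matrix(0, p1, K)
  og <- obj_grad(w)
  step <- 1 / max(sqrt(sum(og$grad^2)), 1e-8)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    w_new <- w - step * og$grad
    og_new <- obj_grad(w_new)
    dw <- w_new - w
    dg <- og_new$grad - og$grad
    denom <- sum(dw * dg)
    step <- if (denom > 0) sum(dw * dw) / denom else 1 / max(sqrt(sum(og_new$grad^2)), 1e-8)
    step <- min(step, 1e6)
    rel <- abs(og$obj - og_new$obj) / max(abs(og$obj), 1e-12)
    w <- w_new
    og <- og_new
    if (rel < tol && sqrt(sum(og$grad^2)) < 1e-5) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(weights = w, center = center, scale = scale, K = K,
         meta = list(iterations = it, objective = og$obj,
                     grad_norm = sqrt(sum(og$grad^2)),
                     converged = converged)),
    class = "linear_decoder"
  )
}

#' Decode with a trained linear decoder
#'
#' Applies the softmax read-out of a trained decoder to new responses.  The
#' hard label is the maximum class probability, with ties broken to the
#' lowest class index.
#'
#' @param dec a [train_linear_decoder()] object.
#' @param x M x N matrix of responses with the same feature count as used in
#'   training.
#' @return A list with `prob` (M x K matrix of class probabilities, rows
#'   summing to 1) and `labels` (integer vector in `1..K`).
#' @export
decode_linear <- function(dec, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(dec$center)) {
    stop("feature count does not match the trained decoder", call. = FALSE)
  }
  xs <- cbind(1, sweep(sweep(x, 2L, dec$center), 2L, dec$scale, `/`))
  eta <- xs %*% dec$weights
  eta <- eta - apply(eta, 1L, max)
  pe <- exp(eta)
  prob <- pe / rowSums(pe)
  list(prob = prob, labels = max.col(prob, ties.method = "first"))
}

#' @export
print.linear_decoder <- function(x, ...) {
  cat(sprintf(
    "<linear_decoder> K=%d classes, %d features; %d iterations, objective=%.6g%s\n",
    x$K, length(x$center), x$meta$iterations, x$meta$objective,
    if (x$meta$converged) "" else " (not converged)"))
  invisible(x)
}
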