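# Internal helpers: angle conversions (degrees externally, radians
# internally) and stable log-domain reductions.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap into [0, period)
wrap_angle <- function(x, period) {
  y <- x %% period
  y[y < 0] <- y[y < 0] + period
  y
}

# row-wise log(sum(exp(x))) for a matrix, guarded against -Inf rows
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(x - m)))
}

# circular orientation distance on a 180-degree circle
orientation_distance <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

stop_if_not_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be finite and > 0", name), call. = FALSE)
  }
  invisible(x)
}
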