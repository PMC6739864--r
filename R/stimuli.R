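#' Sine-wave grating stimuli
#'
#' Constructs a data frame of full-field sine-wave grating stimuli.  A grating
#' is parameterised by its orientation, its phase relative to the line of
#' sight, its spatial period, and its Michelson contrast.  Angles are stored
#' in their principal ranges (orientation in `[0, 180)`, phase in
#' `[0, 360)`); contrast is clipped to `[0, 1]`.
#'
#' @param orientation orientation of the grating in degrees; 0 is horizontal.
#' @param phase phase of the grating relative to the line of sight, degrees.
#' @param spatial_period spatial period of the grating in degrees of visual
#'   angle; must be positive.
#' @param contrast dimensionless contrast; values outside `[0, 1]` are
#'   clipped.
#'
#' @return A data frame with class `"grating_stimuli"` and columns
#'   `orientation`, `phase`, `spatial_period`, `contrast`, one row per
#'   stimulus.  Arguments are recycled to a common length.
#' @examples
#' gratings(orientation = c(0, 45, 90), phase = 180)
#' @export
gratings <- function(orientation, phase = 180, spatial_period = 3,
                     contrast = 0.5) {
  stop_if_not_positive(spatial_period, "spatial_period")
  # a grating at orientation + 180 is the same pattern with its wave vector
  # flipped, i.e. the grating at the wrapped orientation with phase -phi;
  # wrapping applies the flip so the stored stimulus is physically identical
  n <- max(length(orientation), length(phase), length(spatial_period),
           length(contrast))
  orientation <- rep_len(orientation, n)
  phase <- rep_len(phase, n)
  flip <- (floor(orientation / 180) %% 2) == 1
  phase[flip] <- -phase[flip]
  out <- data.frame(
    orientation = wrap_angle(orientation, 180),
    phase = wrap_angle(phase, 360),
    spatial_period = spatial_period,
    contrast = pmin(pmax(contrast, 0), 1)
  )
  class(out) <- c("grating_stimuli", "data.frame")
  out
}

as_gratings <- function(x) {
  need <- c("orientation", "phase", "spatial_period", "contrast")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("stimulus table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stop_if_not_positive(x$spatial_period, "spatial_period")
  x
}
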