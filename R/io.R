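#' Serialise and restore model objects
#'
#' Plain-text persistence for the main objects: populations as JSON
#' key-value configs listing all model symbols by name (`N`, `kind`,
#' `lambda`, `delta`, `R`, `uDC`, `uAC`, the per-filter table, and any
#' calibration gains); sweep tables and response matrices as CSV with a JSON
#' metadata sidecar; voltage traces as CSV plus a JSON sidecar holding the
#' sampling rate, trial times and ground truth.
#'
#' @param pop a [make_population()] object.
#' @param path file path.
#' @return `write_*` functions return the path invisibly; `read_*` return
#'   the restored object.
#' @name serialisation
NULL

#' @rdname serialisation
#' @export
write_population <- function(pop, path) {
  obj <- list(kind = pop$kind, N = pop$N, uDC = pop$uDC, uAC = pop$uAC,
              lambda = pop$params$lambda, delta = pop$params$delta,
              R = pop$params$R, center_width = pop$params$center_width,
              surround_width = pop$params$surround_width,
              gain = pop$gain, filters = as.data.frame(pop$filters))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname serialisation
#' @export
read_population <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  filters <- as.data.frame(obj$filters)
  class(filters) <- c("gabor_filters", "data.frame")
  structure(
    list(kind = obj$kind, N = obj$N, filters = filters, uDC = obj$uDC,
         uAC = obj$uAC, gain = obj$gain,
         params = list(lambda = obj$lambda, delta = obj$delta, R = obj$R,
                       center_width = obj$center_width,
                       surround_width = obj$surround_width)),
    class = "neural_population"
  )
}

#' @rdname serialisation
#' @param sweep a [threshold_sweep()] result.
#' @param meta named list of run metadata (seed, parameter echo) written to
#'   a `.json` sidecar next to the CSV.
#' @export
write_sweep_csv <- function(sweep, path, meta = list()) {
  utils::write.csv(sweep$table, path, row.names = FALSE)
  side <- c(meta, list(optimal_threshold = sweep$optimal_threshold,
                       normalised_optimum = sweep$normalised_optimum,
                       noise_to_signal = sweep$noise_to_signal))
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname serialisation
#' @param trace a [synth_trace()] `"voltage_trace"`.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(time = trace$time, mV = trace$samples),
                   path, row.names = FALSE)
  side <- list(sampling_rate = trace$sampling_rate,
               temporal_frequency = trace$temporal_frequency,
               trials = trace$trials, spike_times = trace$spike_times,
               ground_truth = list(
                 params = unclass(trace$ground_truth$params),
                 phase_jitter = trace$ground_truth$phase_jitter))
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname serialisation
#' @export
read_trace <- function(path) {
  tab <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  gt <- side$ground_truth
  structure(
    list(samples = tab$mV, time = tab$time,
         sampling_rate = side$sampling_rate,
         trials = as.data.frame(side$trials),
         spike_times = as.numeric(unlist(side$spike_times)),
         temporal_frequency = side$temporal_frequency,
         ground_truth = list(params = do.call(cell_params, as.list(gt$params)),
                             phase_jitter = gt$phase_jitter)),
    class = "voltage_trace"
  )
}
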