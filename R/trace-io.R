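#' Write a simulated trace to delimited text
#'
#' Comma-separated columns \code{time_ms}, \code{V_mV} and the gating
#' variables \code{w}, \code{z}, \code{a}, \code{b}; the neuron parameters
#' and protocol are echoed to a JSON sidecar \code{<path>.json}.
#'
#' @param trace a \code{\link{simulate_neuron}} result.
#' @param path CSV output path.
#' @param gating include the gating columns (default \code{TRUE}).
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path, gating = TRUE) {
  df <- data.frame(time_ms = trace$times, V_mV = trace$V)
  if (gating) df <- cbind(df, w = trace$w, z = trace$z, a = trace$a,
                          b = trace$b)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(params = unclass(trace$params),
                            protocol = unclass(trace$protocol)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a time--voltage table as a trace
#'
#' Accepts the files written by \code{\link{write_trace}} as well as bare
#' two-column (time, voltage) tables, e.g. exported recordings. Without a
#' JSON sidecar the protocol is reconstructed from the time axis: stimulus
#' onset at t = 0 and \code{stim_duration} spanning the non-negative times.
#'
#' @param path CSV path.
#' @return An object of class \code{sim_result} (gating columns \code{NULL}
#'   when absent).
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    hdr <- jsonlite::read_json(side, simplifyVector = TRUE)
    params <- do.call(neuron_params, hdr$params)
    protocol <- do.call(stim_protocol, hdr$protocol[c(
      "I_stim", "I_pre", "settle_duration", "stim_duration", "dt")])
  } else {
    params <- neuron_params()
    tt <- df[[1]]
    dt <- stats::median(diff(tt))
    protocol <- stim_protocol(
      settle_duration = max(dt, -min(tt)),
      stim_duration = max(tt[tt >= 0], dt), dt = dt)
  }
  structure(list(times = df[[1]], V = df[[2]],
                 w = df$w, z = df$z, a = df$a, b = df$b,
                 params = params, protocol = protocol),
            class = "sim_result")
}

#' Classify a trace file or object
#'
#' Convenience wrapper: spike detection plus five-way classification.
#'
#' @param trace a \code{sim_result} or a path readable by
#'   \code{\link{read_trace}}.
#' @param threshold spike-detection threshold (mV).
#' @return List with \code{label} and the detected \code{spike_times}.
#' @export
classify_trace <- function(trace, threshold = 0) {
  if (is.character(trace)) trace <- read_trace(trace)
  train <- detect_spikes(trace, threshold)
  list(label = classify_spikes(train), spike_times = train$spike_times)
}
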