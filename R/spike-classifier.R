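#' Spiking-pattern labels
#'
#' The five-way categorical outcome used throughout the package, in its fixed
#' coding order: reluctant = 1, single = 2, delayed = 3, gap = 4, tonic = 5.
#'
#' @return Character vector of the five labels in code order.
#' @export
pattern_labels <- function() c("reluctant", "single", "delayed", "gap", "tonic")

.as_label <- function(code) factor(pattern_labels()[code],
                                   levels = pattern_labels())

#' Detect spikes in a simulated voltage trace
#'
#' A spike is an upward crossing of \code{threshold} within the stimulus
#' window (times in \code{[0, stim_duration]}); the spike time is the
#' linearly interpolated crossing time. A crossing only counts after the
#' voltage has been below threshold, so a spike cannot be double-counted.
#'
#' @param trace a \code{\link{simulate_neuron}} result, or any list with
#'   \code{times}, \code{V} and a \code{protocol}.
#' @param threshold detection threshold (mV).
#' @return An object of class \code{spike_train}: list with
#'   \code{spike_times} (ms, relative to stimulus onset, strictly increasing)
#'   and \code{stim_duration}.
#' @export
detect_spikes <- function(trace, threshold = 0) {
  tt <- trace$times
  V <- trace$V
  stim_dur <- trace$protocol$stim_duration
  in_win <- tt >= 0 & tt <= stim_dur
  # include the last pre-onset sample so a crossing on the first stimulus
  # step is seen
  first <- which(in_win)[1]
  idx <- if (!is.na(first) && first > 1) c(first - 1L, which(in_win)) else which(in_win)
  tt <- tt[idx]; V <- V[idx]
  above <- V >= threshold
  cross <- which(!above[-length(above)] & above[-1])
  times <- tt[cross] + (tt[cross + 1] - tt[cross]) *
    (threshold - V[cross]) / (V[cross + 1] - V[cross])
  times <- times[times >= 0 & times <= stim_dur]
  spike_train(times, stim_dur)
}

#' Construct a spike train
#'
#' @param spike_times strictly increasing spike times (ms, relative to
#'   stimulus onset).
#' @param stim_duration stimulus window length (ms).
#' @return An object of class \code{spike_train}.
#' @export
spike_train <- function(spike_times, stim_duration = 400) {
  spike_times <- as.numeric(spike_times)
  stopifnot(!is.unsorted(spike_times, strictly = TRUE),
            all(spike_times >= 0), all(spike_times <= stim_duration))
  structure(list(spike_times = spike_times, stim_duration = stim_duration),
            class = "spike_train")
}

#' Classify a spike train into one of five spiking patterns
#'
#' Decision rules, applied in order on spike times \eqn{t_1 < t_2 < \dots}
#' relative to stimulus onset:
#' \enumerate{
#'   \item no spikes: \emph{reluctant};
#'   \item one spike with latency > 100 ms: \emph{delayed};
#'   \item one spike otherwise: \emph{single};
#'   \item at least three spikes with a pause after the first spike exceeding
#'     1.5 times the following inter-spike interval,
#'     \eqn{t_2 - t_1 > 1.5 (t_3 - t_2)}: \emph{gap};
#'   \item at least two spikes with first-spike latency exceeding 1.5 times
#'     the first inter-spike interval, \eqn{t_1 > 1.5 (t_2 - t_1)}:
#'     \emph{delayed};
#'   \item otherwise: \emph{tonic}.
#' }
#' The rules are exhaustive and mutually exclusive: every train receives
#' exactly one label. Two-spike trains cannot satisfy the gap rule (no second
#' inter-spike interval) and are only eligible for delayed or tonic.
#'
#' @param train a \code{\link{spike_train}} (a bare numeric vector of spike
#'   times is also accepted).
#' @return Factor of length 1 with levels \code{pattern_labels()}.
#' @examples
#' classify_spikes(spike_train(c(5, 100, 130, 160))) # gap
#' @export
classify_spikes <- function(train) {
  if (!inherits(train, "spike_train")) train <- spike_train(train)
  t <- train$spike_times
  n <- length(t)
  if (n == 0) return(.as_label(1L))
  if (n == 1) return(.as_label(if (t[1] > 100) 3L else 2L))
  if (n >= 3 && (t[2] - t[1]) > 1.5 * (t[3] - t[2])) return(.as_label(4L))
  if (t[1] > 1.5 * (t[2] - t[1])) return(.as_label(3L))
  .as_label(5L)
}

#' Simulate and classify in one call
#'
#' @param params a \code{\link{neuron_params}} object.
#' @param protocol a \code{\link{stim_protocol}} object.
#' @param threshold spike-detection threshold (mV).
#' @return Factor label as from \code{\link{classify_spikes}}.
#' @export
classify_neuron <- function(params, protocol = stim_protocol(),
                            threshold = 0) {
  sp <- .ml_spikes_cpp(.param_vec(params), protocol$settle_duration,
                       protocol$stim_duration, protocol$I_pre,
                       protocol$I_stim, protocol$dt, threshold)
  classify_spikes(spike_train(sp, protocol$stim_duration))
}

#' @export
print.spike_train <- function(x, ...) {
  cat("<spike_train>", length(x$spike_times), "spikes in [0,",
      x$stim_duration, "] ms\n")
  if (length(x$spike_times))
    cat("  times:", paste(round(x$spike_times, 2), collapse = ", "), "\n")
  invisible(x)
}
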