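#' Record a neuron's spiking-pattern sequence across stimulus intensities
#'
#' Simulates one neuron at each stimulus intensity and classifies the
#' response, producing the pattern sequence that
#' \code{\link{infer_densities}} inverts. The default intensities are
#' 50--80 uA/cm^2 at 5 uA/cm^2 intervals.
#'
#' @param params a \code{\link{neuron_params}} object (the "true" neuron).
#' @param I_stim stimulus intensities (uA/cm^2), unique.
#' @param protocol template \code{\link{stim_protocol}} for durations and
#'   \code{dt}.
#' @param threshold spike-detection threshold (mV).
#' @return Data frame of class \code{pattern_sequence} with columns
#'   \code{I_stim} and \code{label}.
#' @export
simulate_pattern_sequence <- function(params, I_stim = seq(50, 80, by = 5),
                                      protocol = stim_protocol(),
                                      threshold = 0) {
  stopifnot(!anyDuplicated(I_stim))
  labels <- vapply(I_stim, function(I) {
    as.character(classify_neuron(params, stim_protocol(
      I_stim = I, I_pre = protocol$I_pre,
      settle_duration = protocol$settle_duration,
      stim_duration = protocol$stim_duration, dt = protocol$dt), threshold))
  }, character(1))
  pattern_sequence(I_stim, labels)
}

#' Construct a pattern sequence
#'
#' @param I_stim stimulus intensities (uA/cm^2), unique.
#' @param label pattern labels (character or factor over
#'   \code{\link{pattern_labels}}).
#' @return Data frame of class \code{pattern_sequence}.
#' @export
pattern_sequence <- function(I_stim, label) {
  stopifnot(!anyDuplicated(I_stim), length(I_stim) == length(label))
  label <- factor(as.character(label), levels = pattern_labels())
  if (anyNA(label)) stop("unknown pattern label")
  structure(data.frame(I_stim = I_stim, label = label),
            class = c("pattern_sequence", "data.frame"))
}

#' Infer conductance densities consistent with a pattern sequence
#'
#' Intersects, across stimulus intensities, the map regions carrying the
#' observed label: the result is the set of (\code{gbar_Klt},
#' \code{gbar_KA}) grid points that reproduce the whole sequence. An empty
#' set means no model neuron on the grid produces the sequence. Adding
#' intensities can only shrink the set, so rarer sequences give tighter
#' density estimates.
#'
#' @param seq a \code{\link{pattern_sequence}}.
#' @param maps a \code{\link{map_stack}} containing one map per
#'   \code{I_stim} in \code{seq} (extra maps are ignored).
#' @return An object of class \code{density_estimate}: matrix
#'   \code{consistent_points} (columns \code{g_lt}, \code{g_A}) plus
#'   per-plane region sizes in \code{plane_sizes}.
#' @export
infer_densities <- function(seq, maps) {
  stopifnot(inherits(seq, "pattern_sequence"), inherits(maps, "map_stack"))
  cond <- attr(maps, "conditions")
  grid <- maps[[1]]$grid
  keep <- matrix(TRUE, length(grid$g_lt), length(grid$g_A))
  plane_sizes <- integer(nrow(seq))
  for (k in seq_len(nrow(seq))) {
    idx <- which(cond$I_stim == seq$I_stim[k])
    if (length(idx) == 0)
      stop("no map in the stack for I_stim = ", seq$I_stim[k])
    sel <- maps[[idx[1]]]$labels == as.integer(seq$label[k])
    plane_sizes[k] <- sum(sel)
    keep <- keep & sel
  }
  ij <- which(keep, arr.ind = TRUE)
  pts <- cbind(g_lt = grid$g_lt[ij[, 1]], g_A = grid$g_A[ij[, 2]])
  structure(list(consistent_points = pts,
                 plane_sizes = data.frame(I_stim = seq$I_stim,
                                          label = seq$label,
                                          n_points = plane_sizes),
                 grid = grid),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat("<density_estimate>", nrow(x$consistent_points),
      "consistent grid points\n")
  if (nrow(x$consistent_points)) {
    r <- apply(x$consistent_points, 2, range)
    cat(sprintf("  gbar_Klt in [%.2f, %.2f], gbar_KA in [%.2f, %.2f] mS/cm2\n",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2]))
  }
  invisible(x)
}
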