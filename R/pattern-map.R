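#' Conductance-density grid specification
#'
#' Rectangular grid of (\code{gbar_Klt}, \code{gbar_KA}) nodes over which
#' spiking patterns are mapped. Defaults cover 0--20 mS/cm^2 on both axes at
#' 0.1 mS/cm^2 increments.
#'
#' @param g_lt_max,g_A_max upper bounds (mS/cm^2); lower bounds via
#'   \code{g_lt_min}, \code{g_A_min}.
#' @param step grid increment (mS/cm^2), shared by both axes unless
#'   \code{step_A} is given.
#' @param g_lt_min,g_A_min lower bounds (mS/cm^2).
#' @param step_A increment for the \code{gbar_KA} axis (defaults to
#'   \code{step}).
#' @return An object of class \code{grid_spec} with node vectors \code{g_lt}
#'   and \code{g_A}.
#' @export
grid_spec <- function(g_lt_max = 20, g_A_max = 20, step = 0.1,
                      g_lt_min = 0, g_A_min = 0, step_A = step) {
  stopifnot(step > 0, step_A > 0, g_lt_max > g_lt_min, g_A_max > g_A_min)
  g_lt <- seq(g_lt_min, g_lt_max, by = step)
  g_A <- seq(g_A_min, g_A_max, by = step_A)
  structure(list(g_lt = g_lt, g_A = g_A, step_lt = step, step_A = step_A),
            class = "grid_spec")
}

#' Map spiking patterns over the potassium-conductance plane
#'
#' Simulates and classifies the neuron at every grid node. The result is a
#' categorical matrix whose regions delimit the conductance combinations
#' producing each spiking pattern; boundaries between regions are the
#' bifurcations at which the pattern changes.
#'
#' @param grid a \code{\link{grid_spec}}.
#' @param protocol a \code{\link{stim_protocol}}.
#' @param params baseline \code{\link{neuron_params}}; its \code{gbar_Klt}
#'   and \code{gbar_KA} entries are overridden by the grid node values.
#' @param threshold spike-detection threshold (mV).
#' @return An object of class \code{pattern_map}: integer label matrix
#'   \code{labels} (rows = \code{g_lt} nodes, columns = \code{g_A} nodes,
#'   codes 1--5 per \code{\link{pattern_labels}}), plus the grid, protocol
#'   and parameters.
#' @export
build_pattern_map <- function(grid = grid_spec(), protocol = stim_protocol(),
                              params = neuron_params(), threshold = 0) {
  stopifnot(inherits(grid, "grid_spec"))
  nodes <- expand.grid(g_lt = grid$g_lt, g_A = grid$g_A)
  spikes <- .ml_sweep_cpp(.param_vec(params), nodes$g_lt, nodes$g_A,
                          protocol$settle_duration, protocol$stim_duration,
                          protocol$I_pre, protocol$I_stim, protocol$dt,
                          threshold)
  dur <- protocol$stim_duration
  codes <- vapply(spikes, function(s)
    as.integer(classify_spikes(spike_train(s, dur))), integer(1))
  labels <- matrix(codes, nrow = length(grid$g_lt), ncol = length(grid$g_A))
  structure(list(labels = labels, grid = grid, protocol = protocol,
                 params = params, threshold = threshold),
            class = "pattern_map")
}

#' Look up the pattern label at a point of the plane
#'
#' Off-grid points take the label of the nearest grid node (labels are point
#' evaluations at the nodes, not cell averages).
#'
#' @param map a \code{\link{build_pattern_map}} result.
#' @param g_lt,g_A query coordinates (mS/cm^2), vectorised.
#' @return Factor of labels, one per query point.
#' @export
map_label_at <- function(map, g_lt, g_A) {
  i <- .nearest_index(map$grid$g_lt, g_lt)
  j <- .nearest_index(map$grid$g_A, g_A)
  .as_label(map$labels[cbind(i, j)])
}

# Equidistant queries round to the even-numbered node so that ties on a
# half-step sub-grid alternate sides instead of biasing every region
# boundary in one direction.
.nearest_index <- function(nodes, x) {
  i <- findInterval(x, nodes, all.inside = TRUE)
  j <- pmin(i + 1L, length(nodes))
  d_lo <- abs(x - nodes[i])
  d_hi <- abs(nodes[j] - x)
  tie <- abs(d_lo - d_hi) < 1e-9 * (abs(d_lo) + abs(d_hi) + 1e-30)
  pick_hi <- d_hi < d_lo | (tie & j %% 2L == 0L)
  ifelse(pick_hi, j, i)
}

#' Region geometry of a pattern map
#'
#' For each label, collects the grid points in its region, their count, and
#' the region centroid (unweighted mean of the member points' coordinates).
#' Centroids drive the centre updates of the population-inverse fit.
#'
#' @param map a \code{\link{build_pattern_map}} result.
#' @return An object of class \code{region_geometry}: data frame with one
#'   row per label (\code{label}, \code{n}, \code{centroid_lt},
#'   \code{centroid_A}; centroids \code{NA} for empty regions) and the
#'   per-label point sets in attribute \code{points}.
#' @export
region_geometry <- function(map) {
  g_lt <- map$grid$g_lt[row(map$labels)]
  g_A <- map$grid$g_A[col(map$labels)]
  lab <- as.vector(map$labels)
  pts <- lapply(1:5, function(k)
    cbind(g_lt = g_lt[lab == k], g_A = g_A[lab == k]))
  geom <- data.frame(
    label = factor(pattern_labels(), levels = pattern_labels()),
    n = vapply(pts, nrow, integer(1)),
    centroid_lt = vapply(pts, function(p)
      if (nrow(p)) mean(p[, 1]) else NA_real_, numeric(1)),
    centroid_A = vapply(pts, function(p)
      if (nrow(p)) mean(p[, 2]) else NA_real_, numeric(1)))
  structure(geom, points = pts, class = c("region_geometry", "data.frame"))
}

#' Build a stack of pattern maps across stimulus or pre-pulse intensities
#'
#' One map per condition on a shared grid. Used to trace how region
#' boundaries shift with stimulus intensity or pre-stimulus membrane
#' potential, and as the input to single-neuron density inference.
#'
#' @param grid a \code{\link{grid_spec}} shared by all maps.
#' @param I_stim,I_pre numeric vectors of conditions; exactly one may have
#'   length > 1, the other is recycled.
#' @param params baseline \code{\link{neuron_params}}.
#' @param protocol template \code{\link{stim_protocol}} supplying durations
#'   and \code{dt}.
#' @param threshold spike-detection threshold (mV).
#' @return An object of class \code{map_stack}: list of \code{pattern_map}s
#'   named by condition, with the condition table in attribute
#'   \code{conditions}.
#' @export
map_stack <- function(grid = grid_spec(), I_stim = 60, I_pre = 0,
                      params = neuron_params(), protocol = stim_protocol(),
                      threshold = 0) {
  cond <- data.frame(I_stim = I_stim, I_pre = I_pre)
  maps <- lapply(seq_len(nrow(cond)), function(k) {
    pk <- stim_protocol(I_stim = cond$I_stim[k], I_pre = cond$I_pre[k],
                        settle_duration = protocol$settle_duration,
                        stim_duration = protocol$stim_duration,
                        dt = protocol$dt)
    build_pattern_map(grid, pk, params, threshold)
  })
  names(maps) <- paste0("I_stim=", cond$I_stim, ",I_pre=", cond$I_pre)
  structure(maps, conditions = cond, class = "map_stack")
}

#' @export
print.pattern_map <- function(x, ...) {
  cat("<pattern_map>", length(x$grid$g_lt), "x", length(x$grid$g_A),
      "nodes, I_stim =", x$protocol$I_stim, ", I_pre =", x$protocol$I_pre,
      "uA/cm2\n")
  print(table(.as_label(as.vector(x$labels))))
  invisible(x)
}

#' @export
plot.pattern_map <- function(x, col = c("grey85", "orange", "steelblue",
                                        "forestgreen", "firebrick"), ...) {
  graphics::image(x$grid$g_lt, x$grid$g_A, x$labels, zlim = c(1, 5),
                  col = col, xlab = "gbar_Klt (mS/cm2)",
                  ylab = "gbar_KA (mS/cm2)", useRaster = TRUE, ...)
  invisible(x)
}

#' Serialise a pattern map to delimited text plus a JSON header
#'
#' The label matrix is written as CSV with rows = \code{g_A} nodes and
#' columns = \code{g_lt} nodes (integer codes 1--5); grid, protocol and
#' neuron parameters go to a JSON sidecar \code{<path>.json}. The round trip
#' through \code{\link{read_pattern_map}} is lossless.
#'
#' @param map a \code{pattern_map}.
#' @param path CSV output path.
#' @return \code{path}, invisibly.
#' @export
write_pattern_map <- function(map, path) {
  m <- t(map$labels) # rows = g_A
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = paste0("glt_", map$grid$g_lt))
  hdr <- list(grid = list(g_lt = map$grid$g_lt, g_A = map$grid$g_A,
                          step_lt = map$grid$step_lt, step_A = map$grid$step_A),
              protocol = unclass(map$protocol),
              params = unclass(map$params),
              threshold = map$threshold,
              label_codes = stats::setNames(1:5, pattern_labels()))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a pattern map written by \code{\link{write_pattern_map}}
#'
#' @param path CSV path (expects the \code{<path>.json} sidecar beside it).
#' @return A \code{pattern_map}.
#' @export
read_pattern_map <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.csv(path))
  labels <- t(unname(m))
  storage.mode(labels) <- "integer"
  grid <- structure(list(g_lt = hdr$grid$g_lt, g_A = hdr$grid$g_A,
                         step_lt = hdr$grid$step_lt, step_A = hdr$grid$step_A),
                    class = "grid_spec")
  protocol <- do.call(stim_protocol, hdr$protocol[c(
    "I_stim", "I_pre", "settle_duration", "stim_duration", "dt")])
  params <- do.call(neuron_params, hdr$params)
  structure(list(labels = labels, grid = grid, protocol = protocol,
                 params = params, threshold = hdr$threshold),
            class = "pattern_map")
}
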