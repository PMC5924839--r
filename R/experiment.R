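#' Assemble an experiment configuration
#'
#' A named bundle of the component settings used by
#' \code{\link{run_experiment}}. Any part may be omitted; the corresponding
#' pipeline stage is skipped. Configurations round-trip through YAML via
#' \code{\link{write_experiment_config}} / \code{\link{read_experiment_config}}.
#'
#' @param name experiment name (used for file prefixes).
#' @param params,protocol,grid argument lists for
#'   \code{\link{neuron_params}}, \code{\link{stim_protocol}} and
#'   \code{\link{grid_spec}}.
#' @param traces list of \code{c(g_lt, g_A)} pairs to simulate, classify and
#'   write out.
#' @param map build (and write) the pattern map for this protocol.
#' @param forward argument list for \code{\link{bivariate_normal}}: compute
#'   analytic pattern proportions over the map.
#' @param sample list with \code{n}: draw a finite population sample and
#'   estimate empirical proportions.
#' @param fit list with optional \code{sigma} (fixed pair) or
#'   \code{sigma_search = TRUE}, plus optional \code{target} (5 proportions;
#'   defaults to the forward/sample result).
#' @param seed integer seed recorded and applied before any sampling.
#' @return An object of class \code{experiment_config}.
#' @export
experiment_config <- function(name = "experiment", params = list(),
                              protocol = list(), grid = list(),
                              traces = NULL, map = FALSE, forward = NULL,
                              sample = NULL, fit = NULL, seed = 1L) {
  structure(list(name = name, params = params, protocol = protocol,
                 grid = grid, traces = traces, map = map, forward = forward,
                 sample = sample, fit = fit, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Built-in experiment presets
#'
#' \code{"fig-patterns"} simulates the five canonical conductance settings
#' (tonic, single, delayed, gap, reluctant) at 60 uA/cm^2.
#' \code{"popA"}, \code{"popC"} and \code{"popD"} build the 60 uA/cm^2 map,
#' compute the analytic proportions of the corresponding reference
#' population (means 3 and 4 mS/cm^2, unit standard deviations, correlation
#' 0, +0.6 or -0.6) and re-fit them with fixed sigmas.
#'
#' @param name preset name.
#' @return An \code{\link{experiment_config}}.
#' @export
experiment_preset <- function(name = c("fig-patterns", "popA", "popC",
                                       "popD")) {
  name <- match.arg(name)
  if (name == "fig-patterns")
    return(experiment_config(
      name = name, protocol = list(I_stim = 60),
      traces = list(c(0, 0), c(6, 0), c(0, 8), c(0, 5), c(6, 8))))
  rho <- c(popA = 0, popC = 0.6, popD = -0.6)[[name]]
  experiment_config(
    name = name, protocol = list(I_stim = 60), map = TRUE,
    forward = list(mu_Klt = 3, mu_KA = 4, sigma_Klt = 1, sigma_KA = 1,
                   rho = rho),
    fit = list(sigma = c(1, 1)))
}

#' Run a configured experiment and write its artifacts
#'
#' Executes the configured stages in order (traces, map, forward
#' proportions, finite-sample proportions, inverse fit), writing each
#' artifact under \code{outdir} together with a plain-text log of
#' parameters, timings and warnings. Reruns with the same configuration are
#' deterministic.
#'
#' @param config an \code{\link{experiment_config}} or preset name.
#' @param outdir output directory (created if needed).
#' @param map optional pre-built \code{\link{build_pattern_map}} result to
#'   reuse instead of rebuilding (its protocol must match the config).
#' @return Invisible list of in-memory results (\code{traces}, \code{map},
#'   \code{forward}, \code{sample}, \code{fit}).
#' @export
run_experiment <- function(config, outdir = ".", map = NULL) {
  if (is.character(config)) config <- experiment_preset(config)
  stopifnot(inherits(config, "experiment_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(outdir, config$name)
  log <- character(0)
  note <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    paste0(...))
    log <<- c(log, line)
  }
  params <- do.call(neuron_params, config$params)
  protocol <- do.call(stim_protocol, config$protocol)
  grid <- do.call(grid_spec, config$grid)
  set.seed(config$seed)
  note("seed = ", config$seed)
  out <- list()

  if (!is.null(config$traces)) {
    out$traces <- lapply(seq_along(config$traces), function(k) {
      g <- config$traces[[k]]
      pk <- params; pk$gbar_Klt <- g[1]; pk$gbar_KA <- g[2]
      tr <- simulate_neuron(pk, protocol)
      cl <- classify_trace(tr)
      write_trace(tr, sprintf("%s_trace%d.csv", pre, k))
      note(sprintf("trace %d: g_Klt=%.2f g_KA=%.2f -> %s", k, g[1], g[2],
                   cl$label))
      cl
    })
  }
  if (isTRUE(config$map) || !is.null(config$forward) ||
      !is.null(config$sample) || !is.null(config$fit)) {
    if (is.null(map)) {
      t0 <- proc.time()[3]
      map <- build_pattern_map(grid, protocol, params)
      note(sprintf("map built in %.1f s", proc.time()[3] - t0))
    } else note("map supplied by caller")
    write_pattern_map(map, paste0(pre, "_map.csv"))
    out$map <- map
  }
  target <- config$fit$target
  if (!is.null(config$forward)) {
    dist <- do.call(bivariate_normal, config$forward)
    out$forward <- pattern_proportions(dist, map)
    utils::write.csv(data.frame(pattern = pattern_labels(),
                                proportion = as.numeric(out$forward)),
                     paste0(pre, "_proportions.csv"), row.names = FALSE)
    note("forward proportions: ",
         paste(sprintf("%s=%.3f", pattern_labels(),
                       as.numeric(out$forward)), collapse = " "))
    if (is.null(target)) target <- out$forward
  }
  if (!is.null(config$sample)) {
    dist <- do.call(bivariate_normal, config$forward)
    out$sample <- sample_population(dist, map, config$sample$n,
                                    seed = config$seed)
    note("sampled n = ", config$sample$n)
    if (is.null(config$forward)) target <- out$sample
  }
  if (!is.null(config$fit)) {
    stopifnot(!is.null(target))
    if (isTRUE(config$fit$sigma_search)) {
      out$fit <- fit_sigma_search(target, map)
    } else {
      sigma <- if (is.null(config$fit$sigma)) c(1, 1) else config$fit$sigma
      out$fit <- fit_proportions(target, map, sigma = sigma)
    }
    jsonlite::write_json(
      out$fit[c("mu_Klt", "mu_KA", "rho", "sigma_Klt", "sigma_KA",
                "max_error", "iterations", "status")],
      paste0(pre, "_fit.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(out$fit$history, paste0(pre, "_fit_history.csv"),
                     row.names = FALSE)
    note(sprintf("fit: mu=(%.3f, %.3f) rho=%.2f MaxError=%.4g",
                 out$fit$mu_Klt, out$fit$mu_KA, out$fit$rho,
                 out$fit$max_error))
  }
  writeLines(log, paste0(pre, "_log.txt"))
  invisible(out)
}

#' Write an experiment configuration as YAML
#'
#' @param config an \code{\link{experiment_config}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read an experiment configuration from YAML
#'
#' Unknown keys are rejected so that typos fail loudly.
#'
#' @param path YAML path.
#' @return An \code{\link{experiment_config}}.
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(x$traces)) x$traces <- lapply(x$traces, as.numeric)
  do.call(experiment_config, x)
}
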