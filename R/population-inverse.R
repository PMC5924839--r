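#' Configuration of the iterative centroid-vector fit
#'
#' @param delta stopping threshold on MaxError (fit ends once the largest
#'   absolute proportion error falls below it).
#' @param epsilon refinement threshold: once the best coarse-scan MaxError
#'   falls below it, the correlation scan switches to the fine step.
#' @param rho_coarse,rho_fine uniform candidate grids for the correlation
#'   scan, given as \code{c(min, max, step)}.
#' @param max_iterations iteration guard.
#' @param convergence_tol centre-displacement tolerance (mS/cm^2): the fit
#'   stops when one update moves the centre less than this.
#' @param mu0 initial centre (mS/cm^2); defaults to the map's grid centre
#'   when \code{NULL}.
#' @param rho0 initial (incumbent) correlation.
#' @param sigma_grid values searched by \code{\link{fit_sigma_search}}
#'   (mS/cm^2), used for both axes.
#' @return An object of class \code{fit_config}.
#' @export
fit_config <- function(delta = 0.001, epsilon = 0.003,
                       rho_coarse = c(-0.9, 0.9, 0.1),
                       rho_fine = c(-0.99, 0.99, 0.01),
                       max_iterations = 200, convergence_tol = 1e-4,
                       mu0 = NULL, rho0 = 0,
                       sigma_grid = seq(0.4, 1.6, by = 0.05)) {
  stopifnot(delta > 0, delta < epsilon, rho_coarse[3] > 0, rho_fine[3] > 0,
            max_iterations >= 1, convergence_tol > 0,
            all(sigma_grid > 0))
  structure(list(delta = delta, epsilon = epsilon, rho_coarse = rho_coarse,
                 rho_fine = rho_fine, max_iterations = max_iterations,
                 convergence_tol = convergence_tol, mu0 = mu0, rho0 = rho0,
                 sigma_grid = sigma_grid),
            class = "fit_config")
}

#' Signed errors between target and calculated proportions
#'
#' \eqn{E_i = V_{target,i} - V_{calc,i}} for the five patterns; MaxError is
#' the largest absolute error.
#'
#' @param target,calc proportion vectors over the five patterns (any
#'   numeric vector in label-code order, or \code{proportions} objects).
#' @return List with \code{E} (named, signed) and \code{max_error}.
#' @export
error_terms <- function(target, calc) {
  E <- as.numeric(target)[1:5] - as.numeric(calc)[1:5]
  names(E) <- pattern_labels()
  list(E = E, max_error = max(abs(E)))
}

#' Scan the correlation coefficient for the best proportion match
#'
#' Evaluates MaxError for each candidate correlation on the coarse grid at a
#' fixed centre; when the best coarse MaxError falls below \code{epsilon}
#' the fine grid is scanned as well. Ties are broken toward the incumbent
#' correlation, then toward the smaller magnitude.
#'
#' @param centre numeric \code{c(mu_Klt, mu_KA)}.
#' @param sigma numeric \code{c(sigma_Klt, sigma_KA)}.
#' @param target 5-entry target proportion vector.
#' @param map a \code{\link{build_pattern_map}} result.
#' @param config a \code{\link{fit_config}}.
#' @param rho_incumbent incumbent correlation used for tie-breaking.
#' @return List with \code{rho}, \code{max_error}, \code{E} and
#'   \code{below_delta} (whether the whole fit should stop here).
#' @export
optimize_rho <- function(centre, sigma, target, map, config = fit_config(),
                         rho_incumbent = config$rho0) {
  scan <- function(gridspec) {
    cand <- seq(gridspec[1], gridspec[2], by = gridspec[3])
    res <- lapply(cand, function(r) {
      v <- .bnd_volumes_cpp(map$labels, map$grid$g_lt, map$grid$g_A,
                            centre[1], centre[2], sigma[1], sigma[2], r)
      error_terms(target, v[pattern_labels()])
    })
    err <- vapply(res, `[[`, numeric(1), "max_error")
    best <- err <= min(err) + 1e-15
    tie <- which(best)
    tie <- tie[order(abs(cand[tie] - rho_incumbent), abs(cand[tie]))]
    k <- tie[1]
    list(rho = cand[k], max_error = err[k], E = res[[k]]$E)
  }
  out <- scan(config$rho_coarse)
  if (out$max_error >= config$delta && out$max_error < config$epsilon) {
    rho_incumbent <- out$rho
    fine <- scan(config$rho_fine)
    out <- fine
  }
  out$below_delta <- out$max_error < config$delta
  out
}

#' Centroid-vector update of the distribution centre
#'
#' Moves the centre toward regions whose pattern is under-represented and
#' away from over-represented ones: for each region with centroid
#' \eqn{C_i}, a unit vector from the centre toward \eqn{C_i} is scaled by
#' the signed error \eqn{E_i}, and the net sum displaces the centre.
#' Regions with nonzero error but no points (no centroid) are skipped with
#' a warning.
#'
#' @param centre numeric \code{c(mu_Klt, mu_KA)}.
#' @param E signed error vector over the five patterns.
#' @param geometry a \code{\link{region_geometry}} of the map being fitted.
#' @return New centre, numeric length 2.
#' @export
update_centre <- function(centre, E, geometry) {
  shift <- c(0, 0)
  for (i in 1:5) {
    if (E[i] == 0) next
    ci <- c(geometry$centroid_lt[i], geometry$centroid_A[i])
    if (anyNA(ci)) {
      warning("region '", pattern_labels()[i],
              "' has nonzero error but no points; term skipped")
      next
    }
    d <- ci - centre
    len <- sqrt(sum(d^2))
    if (len == 0) next
    shift <- shift + E[i] * d / len
  }
  centre + shift
}

#' Fit a density distribution to observed pattern proportions
#'
#' The iterative two-step estimator: step 1 scans the correlation
#' coefficient (coarse 0.1 grid, refined to 0.01 once MaxError drops below
#' \code{epsilon}) for the best match to the target proportions; step 2
#' updates the distribution centre by the centroid-vector rule. Steps
#' alternate until MaxError falls below \code{delta}, the centre stops
#' moving, or \code{max_iterations} is reached. Standard deviations are
#' held fixed; see \code{\link{fit_sigma_search}} for estimating them.
#'
#' @param target 5-entry proportion vector (label-code order or a
#'   \code{proportions} object). Entries that do not sum to 1 (finite
#'   samples, truncated coverage) are fitted as-is.
#' @param map a \code{\link{build_pattern_map}} result.
#' @param sigma fixed \code{c(sigma_Klt, sigma_KA)} (mS/cm^2).
#' @param config a \code{\link{fit_config}}.
#' @param engine \code{"cpp"} (default) or \code{"R"} (reference
#'   implementation composed from \code{\link{optimize_rho}} and
#'   \code{\link{update_centre}}; identical decisions, kept for
#'   cross-checking).
#' @return An object of class \code{fit_result}: estimated \code{mu_Klt},
#'   \code{mu_KA}, \code{rho}, the fixed sigmas, final \code{max_error},
#'   fitted proportions, iteration count, termination \code{status} and the
#'   per-iteration \code{history}.
#' @export
fit_proportions <- function(target, map, sigma = c(1, 1),
                            config = fit_config(),
                            engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  target <- as.numeric(target)[1:5]
  stopifnot(all(target >= -1e-12), all(target <= 1 + 1e-9),
            sum(target) <= 1 + 1e-6)
  mu0 <- config$mu0
  if (is.null(mu0))
    mu0 <- c(mean(range(map$grid$g_lt)), mean(range(map$grid$g_A)))
  if (engine == "cpp") {
    geom <- region_geometry(map)
    res <- .fit_cpp(map$labels, map$grid$g_lt, map$grid$g_A,
                    ifelse(is.na(geom$centroid_lt), 0, geom$centroid_lt),
                    ifelse(is.na(geom$centroid_A), 0, geom$centroid_A),
                    !is.na(geom$centroid_lt), target,
                    mu0[1], mu0[2], sigma[1], sigma[2], config$rho0,
                    config$delta, config$epsilon,
                    config$rho_coarse[1], config$rho_coarse[2],
                    config$rho_coarse[3],
                    config$rho_fine[1], config$rho_fine[2],
                    config$rho_fine[3],
                    config$max_iterations, config$convergence_tol)
    if (res$skipped_empty_region)
      warning("a region with nonzero error had no points; its term was skipped")
    res$skipped_empty_region <- NULL
    return(structure(res, class = "fit_result"))
  }
  .fit_r(target, map, sigma, mu0, config)
}

# Reference fit loop in R; mirrors the compiled engine step for step.
.fit_r <- function(target, map, sigma, mu0, config) {
  geom <- region_geometry(map)
  centre <- mu0
  rho <- config$rho0
  hist <- list()
  status <- "max_iterations"
  iters <- 0
  for (k in seq_len(config$max_iterations)) {
    iters <- k
    sc <- optimize_rho(centre, sigma, target, map, config, rho)
    rho <- sc$rho
    hist[[k]] <- data.frame(iteration = k, mu_Klt = centre[1],
                            mu_KA = centre[2], rho = rho,
                            max_error = sc$max_error)
    if (sc$below_delta) { status <- "converged_error"; break }
    new_centre <- update_centre(centre, sc$E, geom)
    disp <- sqrt(sum((new_centre - centre)^2))
    centre <- new_centre
    if (disp < config$convergence_tol) { status <- "converged_centre"; break }
  }
  v <- .bnd_volumes_cpp(map$labels, map$grid$g_lt, map$grid$g_A,
                        centre[1], centre[2], sigma[1], sigma[2], rho)
  et <- error_terms(target, v[pattern_labels()])
  structure(list(mu_Klt = centre[1], mu_KA = centre[2], rho = rho,
                 sigma_Klt = sigma[1], sigma_KA = sigma[2],
                 max_error = et$max_error, errors = unname(et$E),
                 fitted = v, iterations = iters, status = status,
                 history = do.call(rbind, hist)),
            class = "fit_result")
}

#' Fit including a grid search over the standard deviations
#'
#' Re-runs \code{\link{fit_proportions}} for every pair of candidate
#' standard deviations on \code{config$sigma_grid} (default 0.4--1.6
#' mS/cm^2 at 0.05 intervals) and returns the fit with the lowest final
#' MaxError. Results are independent of evaluation order; exact MaxError
#' ties resolve to the smaller \code{(sigma_Klt, sigma_KA)} pair.
#'
#' @inheritParams fit_proportions
#' @return The best \code{fit_result}, with the full per-sigma error
#'   surface (data frame \code{sigma_Klt}, \code{sigma_KA},
#'   \code{max_error}) in attribute \code{sigma_surface}.
#' @export
fit_sigma_search <- function(target, map, config = fit_config()) {
  grid <- expand.grid(sigma_Klt = config$sigma_grid,
                      sigma_KA = config$sigma_grid)
  fits <- lapply(seq_len(nrow(grid)), function(k)
    fit_proportions(target, map,
                    sigma = c(grid$sigma_Klt[k], grid$sigma_KA[k]),
                    config = config))
  surface <- cbind(grid, max_error = vapply(fits, `[[`, numeric(1),
                                            "max_error"))
  ord <- order(surface$max_error, surface$sigma_Klt, surface$sigma_KA)
  best <- fits[[ord[1]]]
  attr(best, "sigma_surface") <- surface
  best
}

#' @export
print.fit_result <- function(x, digits = 4, ...) {
  cat("<fit_result>", x$status, "after", x$iterations, "iterations\n")
  cat(sprintf("  mu_Klt = %.3f, mu_KA = %.3f, rho = %.2f (sigma = %.2f, %.2f)\n",
              x$mu_Klt, x$mu_KA, x$rho, x$sigma_Klt, x$sigma_KA))
  cat("  MaxError =", signif(x$max_error, 3), "\n")
  invisible(x)
}
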