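#' Bivariate normal distribution of potassium-conductance densities
#'
#' Describes a neuron population in which \code{gbar_Klt} and \code{gbar_KA}
#' are jointly Gaussian with means \code{mu_Klt}, \code{mu_KA}, standard
#' deviations \code{sigma_Klt}, \code{sigma_KA} (all mS/cm^2) and expression
#' correlation \code{rho}.
#'
#' @param mu_Klt,mu_KA means (mS/cm^2).
#' @param sigma_Klt,sigma_KA standard deviations (mS/cm^2), positive.
#' @param rho correlation coefficient in (-1, 1).
#' @return An object of class \code{bnd}.
#' @export
bivariate_normal <- function(mu_Klt = 3, mu_KA = 4,
                             sigma_Klt = 1, sigma_KA = 1, rho = 0) {
  stopifnot(sigma_Klt > 0, sigma_KA > 0, rho > -1, rho < 1,
            is.finite(mu_Klt), is.finite(mu_KA))
  structure(list(mu_Klt = mu_Klt, mu_KA = mu_KA, sigma_Klt = sigma_Klt,
                 sigma_KA = sigma_KA, rho = rho), class = "bnd")
}

#' Bivariate normal probability density
#'
#' Standard bivariate normal density with the quadratic form
#' \deqn{Q = \frac{(x-\mu_x)^2}{\sigma_x^2}
#'       - \frac{2\rho (x-\mu_x)(y-\mu_y)}{\sigma_x \sigma_y}
#'       + \frac{(y-\mu_y)^2}{\sigma_y^2}}
#' giving \eqn{P(x,y) = e^{-Q/(2(1-\rho^2))} /
#' (2\pi\sigma_x\sigma_y\sqrt{1-\rho^2})}.
#'
#' @param dist a \code{\link{bivariate_normal}}.
#' @param x,y evaluation coordinates (\code{gbar_Klt}, \code{gbar_KA}),
#'   vectorised.
#' @return Probability density values.
#' @export
bnd_pdf <- function(dist, x, y) {
  dx <- x - dist$mu_Klt
  dy <- y - dist$mu_KA
  r <- dist$rho
  Q <- dx^2 / dist$sigma_Klt^2 -
    2 * r * dx * dy / (dist$sigma_Klt * dist$sigma_KA) +
    dy^2 / dist$sigma_KA^2
  exp(-Q / (2 * (1 - r^2))) /
    (2 * pi * dist$sigma_Klt * dist$sigma_KA * sqrt(1 - r^2))
}

#' Expected spiking-pattern proportions of a population
#'
#' Integrates the density distribution over each pattern region of the map
#' by two-dimensional trapezoidal integration on the integration sub-grid
#' (default: the map grid itself). Each sub-grid node contributes its
#' trapezoid weight times the density to the region of its (nearest-node)
#' label, so the five volumes sum exactly to the total integrated mass
#' (\code{coverage}). Coverage falls short of 1 when appreciable
#' distribution mass lies outside the mapped domain; a warning is issued
#' below 0.999.
#'
#' @param dist a \code{\link{bivariate_normal}}.
#' @param map a \code{\link{build_pattern_map}} result.
#' @param substep optional integration sub-grid step (mS/cm^2); sub-grid
#'   nodes take the label of the nearest map node.
#' @param renormalize divide the five volumes by coverage (default
#'   \code{FALSE}: raw volumes are reported).
#' @return An object of class \code{proportions}: named numeric vector of
#'   the five pattern proportions with attribute \code{coverage}.
#' @examples
#' \dontrun{
#' map60 <- build_pattern_map(grid_spec(), stim_protocol(I_stim = 60))
#' pattern_proportions(bivariate_normal(3, 4, 1, 1, 0), map60)
#' }
#' @export
pattern_proportions <- function(dist, map, substep = NULL,
                                renormalize = FALSE) {
  stopifnot(inherits(dist, "bnd"), inherits(map, "pattern_map"))
  if (is.null(substep)) {
    gx <- map$grid$g_lt
    gy <- map$grid$g_A
    labels <- map$labels
  } else {
    gx <- seq(min(map$grid$g_lt), max(map$grid$g_lt), by = substep)
    gy <- seq(min(map$grid$g_A), max(map$grid$g_A), by = substep)
    i <- .nearest_index(map$grid$g_lt, gx)
    j <- .nearest_index(map$grid$g_A, gy)
    labels <- map$labels[i, j, drop = FALSE]
  }
  v <- .bnd_volumes_cpp(labels, gx, gy, dist$mu_Klt, dist$mu_KA,
                        dist$sigma_Klt, dist$sigma_KA, dist$rho)
  coverage <- v[["coverage"]]
  out <- v[pattern_labels()]
  if (coverage < 0.999)
    warning(sprintf("coverage %.4f < 0.999: distribution mass extends beyond the map domain", coverage))
  if (renormalize) out <- out / coverage
  structure(out, coverage = coverage, class = "proportions")
}

#' Construct a proportion vector
#'
#' @param reluctant,single,delayed,gap,tonic proportions in [0, 1].
#' @param coverage total integrated mass these proportions account for.
#' @return An object of class \code{proportions}.
#' @export
proportion_vector <- function(reluctant = 0, single = 0, delayed = 0,
                              gap = 0, tonic = 0,
                              coverage = reluctant + single + delayed +
                                gap + tonic) {
  v <- c(reluctant = reluctant, single = single, delayed = delayed,
         gap = gap, tonic = tonic)
  stopifnot(all(v >= 0), all(v <= 1), sum(v) <= coverage + 1e-9,
            coverage <= 1 + 1e-9)
  structure(v, coverage = coverage, class = "proportions")
}

#' @export
print.proportions <- function(x, digits = 4, ...) {
  print(round(unclass(x), digits))
  cat("coverage:", round(attr(x, "coverage"), digits), "\n")
  invisible(x)
}

#' Sample a finite population and estimate its pattern proportions
#'
#' Draws \code{n} neurons from the density distribution, assigns each the
#' label of the nearest map node (points outside the mapped domain,
#' including negative conductances, clamp to the nearest in-domain node so
#' every sample is counted), and returns empirical proportions. This
#' emulates the experimental situation in which proportions are estimated
#' from a limited sample of recorded neurons.
#'
#' @param dist a \code{\link{bivariate_normal}}.
#' @param map a \code{\link{build_pattern_map}} result.
#' @param n number of neurons to draw.
#' @param seed optional integer seed for reproducibility.
#' @return A \code{proportions} vector (coverage 1 by construction) with the
#'   sampled points in attribute \code{samples}.
#' @export
sample_population <- function(dist, map, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  S <- matrix(c(dist$sigma_Klt^2,
                dist$rho * dist$sigma_Klt * dist$sigma_KA,
                dist$rho * dist$sigma_Klt * dist$sigma_KA,
                dist$sigma_KA^2), 2, 2)
  pts <- MASS::mvrnorm(n, mu = c(dist$mu_Klt, dist$mu_KA), Sigma = S)
  pts <- matrix(pts, ncol = 2)
  lab <- map_label_at(map, pts[, 1], pts[, 2])
  counts <- table(lab)
  out <- structure(as.numeric(counts[pattern_labels()]) / n,
                   names = pattern_labels(), coverage = 1,
                   class = "proportions")
  attr(out, "samples") <- pts
  out
}
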