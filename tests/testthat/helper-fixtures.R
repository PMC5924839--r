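# Shared fixtures, built once per test run and cached.  Map construction is
# the expensive step (one simulation per grid node), so tests share maps:
# the full-resolution 60 uA/cm2 map for population-level checks, and
# coarser grids elsewhere.

.fixtures <- new.env(parent = emptyenv())

.cached <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# Full-resolution map (0.1 mS/cm2, 0-20 x 0-20) at I_stim = 60
map60 <- function() .cached("map60", function()
  build_pattern_map(grid_spec(), stim_protocol(I_stim = 60)))

# Coarse map (0.5 mS/cm2) at I_stim = 60
map60_coarse <- function() .cached("map60_coarse", function()
  build_pattern_map(grid_spec(step = 0.5), stim_protocol(I_stim = 60)))

# Coarse map stack over the single-neuron inference intensities
stack_coarse <- function() .cached("stack_coarse", function()
  map_stack(grid_spec(step = 0.5), I_stim = seq(50, 80, by = 5)))

# Random spike train within the stimulus window
random_train <- function(stim_duration = 400) {
  n <- sample(0:12, 1)
  spike_train(sort(runif(n, 0, stim_duration)), stim_duration)
}

# Parameter-recovery batch shared by the acceptance suite and the
# inverse-fit property tests: random true distributions, analytic targets,
# full sigma-search fits.  Sized for a practical test runtime: 25 truths,
# sigma grid at 0.1 mS/cm2 spacing, 40-iteration guard.
recovery_batch <- function() .cached("recovery_batch", function() {
  map <- map60()
  cfg <- fit_config(sigma_grid = seq(0.4, 1.6, by = 0.1),
                    max_iterations = 40)
  set.seed(20260920)
  out <- NULL
  for (k in 1:25) {
    truth <- bivariate_normal(runif(1, 1.5, 6), runif(1, 2, 8),
                              runif(1, 0.4, 1.6), runif(1, 0.4, 1.6),
                              runif(1, -0.8, 0.8))
    tgt <- suppressWarnings(pattern_proportions(truth, map))
    fit <- fit_sigma_search(tgt, map, cfg)
    out <- rbind(out, data.frame(
      mu_Klt = truth$mu_Klt, mu_KA = truth$mu_KA,
      sigma_Klt = truth$sigma_Klt, sigma_KA = truth$sigma_KA,
      rho = truth$rho, spread = 1 - max(tgt),
      est_mu_Klt = fit$mu_Klt, est_mu_KA = fit$mu_KA,
      est_sigma_Klt = fit$sigma_Klt, est_sigma_KA = fit$sigma_KA,
      est_rho = fit$rho, max_error = fit$max_error))
  }
  out
})
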