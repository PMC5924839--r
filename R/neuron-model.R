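#' Biophysical parameters of the modified Morris-Lecar neuron
#'
#' Constructs the full parameter set for a single-compartment conductance-based
#' neuron carrying an instantaneous sodium conductance, a delayed-rectifier
#' potassium conductance, a leak conductance, a low-threshold non-inactivating
#' (Kv1-type) potassium conductance \code{gbar_Klt} (gating variable \eqn{z})
#' and an inactivating A-type potassium conductance \code{gbar_KA} (current
#' proportional to \eqn{a^4 b}). Defaults are the reference values used
#' throughout the package; the two potassium densities \code{gbar_Klt} and
#' \code{gbar_KA} are the quantities swept and inferred by the higher-level
#' tools.
#'
#' @param gbar_Klt,gbar_KA maximal densities of the low-threshold and A-type
#'   potassium conductances (mS/cm^2).
#' @param C membrane capacitance (uF/cm^2).
#' @param E_Na,E_K,E_leak reversal potentials (mV).
#' @param gbar_Na,gbar_Kdr,gbar_leak maximal conductance densities (mS/cm^2).
#' @param phi_w,phi_z,phi_a,phi_b dimensionless rate scalars of the gating
#'   variables.
#' @param beta_m,beta_w,beta_z half-activation voltages (mV).
#' @param gamma_m,gamma_w,gamma_z activation slope factors (mV).
#' @return An object of class \code{neuron_params} (named list).
#' @examples
#' p <- neuron_params(gbar_Klt = 6, gbar_KA = 0)
#' @export
neuron_params <- function(gbar_Klt = 0, gbar_KA = 0,
                          C = 2, E_Na = 50, E_K = -100, E_leak = -70,
                          gbar_Na = 20, gbar_Kdr = 20, gbar_leak = 2,
                          phi_w = 0.15, phi_z = 0.15, phi_a = 1, phi_b = 1,
                          beta_m = -1.2, beta_w = -10, beta_z = -21,
                          gamma_m = 18, gamma_w = 10, gamma_z = 15) {
  p <- list(C = C, E_Na = E_Na, E_K = E_K, E_leak = E_leak,
            gbar_Na = gbar_Na, gbar_Kdr = gbar_Kdr, gbar_leak = gbar_leak,
            gbar_Klt = gbar_Klt, gbar_KA = gbar_KA,
            phi_w = phi_w, phi_z = phi_z, phi_a = phi_a, phi_b = phi_b,
            beta_m = beta_m, beta_w = beta_w, beta_z = beta_z,
            gamma_m = gamma_m, gamma_w = gamma_w, gamma_z = gamma_z)
  stopifnot(p$C > 0, p$gamma_m > 0, p$gamma_w > 0, p$gamma_z > 0)
  g <- c(p$gbar_Na, p$gbar_Kdr, p$gbar_leak, p$gbar_Klt, p$gbar_KA)
  if (any(!is.finite(unlist(p))) || any(g < 0))
    stop("conductance densities must be finite and non-negative")
  structure(p, class = "neuron_params")
}

# fixed-order numeric vector handed to the compiled integrator
.param_vec <- function(params) {
  stopifnot(inherits(params, "neuron_params"))
  as.numeric(unlist(params[c("C", "E_Na", "E_K", "E_leak",
                             "gbar_Na", "gbar_Kdr", "gbar_leak",
                             "gbar_Klt", "gbar_KA",
                             "phi_w", "phi_z", "phi_a", "phi_b",
                             "beta_m", "beta_w", "beta_z",
                             "gamma_m", "gamma_w", "gamma_z")]))
}

#' Stimulation protocol
#'
#' A settle phase (duration \code{settle_duration}, holding current
#' \code{I_pre}) lets the model relax to rest before a step stimulus of
#' density \code{I_stim} is applied for \code{stim_duration}. The pre-pulse
#' current \code{I_pre} stays on during stimulation, so the stimulus-phase
#' current is \code{I_pre + I_stim}; depolarising pre-pulses partially
#' inactivate the A-type conductance before stimulus onset.
#'
#' @param I_stim stimulus current density (uA/cm^2).
#' @param I_pre pre-pulse current density applied from the start of the
#'   settle phase onward (uA/cm^2).
#' @param settle_duration,stim_duration phase durations (ms).
#' @param dt forward-Euler integration step (ms).
#' @return An object of class \code{stim_protocol}.
#' @export
stim_protocol <- function(I_stim = 60, I_pre = 0,
                          settle_duration = 250, stim_duration = 400,
                          dt = 0.1) {
  stopifnot(dt > 0, settle_duration > 0, stim_duration > 0,
            is.finite(I_stim), is.finite(I_pre))
  structure(list(I_stim = I_stim, I_pre = I_pre,
                 settle_duration = settle_duration,
                 stim_duration = stim_duration, dt = dt),
            class = "stim_protocol")
}

#' Steady-state activation/inactivation curves
#'
#' Voltage dependence of the gating variables: \code{m}, \code{w} and \code{z}
#' follow \eqn{0.5 (1 + \tanh((V - \beta)/\gamma))}; the A-type activation and
#' inactivation gates follow \eqn{a_\infty = 1/(1 + e^{-(V+60)/8.5})} and
#' \eqn{b_\infty = 1/(1 + e^{(V+78)/6})}.
#'
#' @param V membrane potential (mV), vectorised.
#' @param params a \code{\link{neuron_params}} object.
#' @return Data frame with columns \code{m_inf}, \code{w_inf}, \code{z_inf},
#'   \code{a_inf}, \code{b_inf}, one row per voltage.
#' @export
steady_state <- function(V, params = neuron_params()) {
  stopifnot(all(is.finite(V)))
  data.frame(
    m_inf = 0.5 * (1 + tanh((V - params$beta_m) / params$gamma_m)),
    w_inf = 0.5 * (1 + tanh((V - params$beta_w) / params$gamma_w)),
    z_inf = 0.5 * (1 + tanh((V - params$beta_z) / params$gamma_z)),
    a_inf = 1 / (1 + exp(-(V + 60) / 8.5)),
    b_inf = 1 / (1 + exp((V + 78) / 6)))
}

#' Voltage-dependent gating time constants
#'
#' \eqn{\tau_w} and \eqn{\tau_z} are reciprocal-cosh functions of voltage;
#' \eqn{\tau_a} is a double-exponential well plus an additive floor of
#' 0.37 ms; \eqn{\tau_b} is 19 ms above -63 mV and double-exponential below
#' (the branch point -63 mV itself is assigned to the double-exponential
#' branch).
#'
#' @inheritParams steady_state
#' @return Data frame with columns \code{tau_w}, \code{tau_z}, \code{tau_a},
#'   \code{tau_b} (ms).
#' @export
time_constants <- function(V, params = neuron_params()) {
  stopifnot(all(is.finite(V)))
  data.frame(
    tau_w = 1 / cosh((V - params$beta_w) / (2 * params$gamma_w)),
    tau_z = 1 / cosh((V - params$beta_z) / (2 * params$gamma_z)),
    tau_a = 1 / (exp((V + 35.82) / 19.69) + exp(-(V + 79.69) / 12.7)) + 0.37,
    tau_b = ifelse(V > -63, 19,
                   1 / (exp((V + 46.05) / 5) + exp(-(V + 238.4) / 37.45))))
}

#' Time derivatives of the membrane state
#'
#' Right-hand side of the model: the membrane equation balances the applied
#' current against sodium, delayed-rectifier, low-threshold potassium, A-type
#' potassium (\eqn{a^4 b} gating) and leak currents; each gating variable
#' relaxes to its steady state at rate \eqn{\phi_x / \tau_x(V)}. The sodium
#' activation \code{m} is instantaneous and evaluated at steady state.
#'
#' @param state named numeric vector or list with entries \code{V}, \code{w},
#'   \code{z}, \code{a}, \code{b}.
#' @param I_applied applied current density (uA/cm^2).
#' @param params a \code{\link{neuron_params}} object.
#' @return Named numeric vector of derivatives \code{dV}, \code{dw},
#'   \code{dz}, \code{da}, \code{db} (per ms).
#' @export
ml_derivatives <- function(state, I_applied, params = neuron_params()) {
  s <- as.list(state)
  V <- s$V
  inf <- steady_state(V, params)
  tau <- time_constants(V, params)
  I_Na <- params$gbar_Na * inf$m_inf * (V - params$E_Na)
  I_Kdr <- params$gbar_Kdr * s$w * (V - params$E_K)
  I_Klt <- params$gbar_Klt * s$z * (V - params$E_K)
  I_KA <- params$gbar_KA * s$a^4 * s$b * (V - params$E_K)
  I_leak <- params$gbar_leak * (V - params$E_leak)
  c(dV = (I_applied - I_Na - I_Kdr - I_Klt - I_KA - I_leak) / params$C,
    dw = params$phi_w * (inf$w_inf - s$w) / tau$tau_w,
    dz = params$phi_z * (inf$z_inf - s$z) / tau$tau_z,
    da = params$phi_a * (inf$a_inf - s$a) / tau$tau_a,
    db = params$phi_b * (inf$b_inf - s$b) / tau$tau_b)
}

#' Simulate the neuron under a settle/stimulus protocol
#'
#' Integrates the model with the forward Euler method at the protocol's fixed
#' step. The state starts at \code{V = E_leak} with all gates at steady state,
#' settles for \code{settle_duration} ms under \code{I_pre}, then receives
#' \code{I_pre + I_stim} for \code{stim_duration} ms. Times in the result are
#' relative to stimulus onset (settle phase at negative times).
#'
#' @param params a \code{\link{neuron_params}} object.
#' @param protocol a \code{\link{stim_protocol}} object.
#' @param engine \code{"cpp"} (compiled, default) or \code{"R"} (plain R
#'   reference loop; identical arithmetic, used for cross-checking).
#' @return An object of class \code{sim_result}: list with \code{times},
#'   \code{V}, gating arrays \code{w}, \code{z}, \code{a}, \code{b}, and the
#'   echoed \code{params} and \code{protocol}.
#' @examples
#' res <- simulate_neuron(neuron_params(gbar_Klt = 6), stim_protocol(I_stim = 60))
#' @export
simulate_neuron <- function(params = neuron_params(),
                            protocol = stim_protocol(),
                            engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  stopifnot(inherits(protocol, "stim_protocol"))
  if (engine == "cpp") {
    tr <- .ml_trace_cpp(.param_vec(params), protocol$settle_duration,
                        protocol$stim_duration, protocol$I_pre,
                        protocol$I_stim, protocol$dt)
  } else {
    tr <- .euler_r(params, protocol)
  }
  structure(list(times = tr$times, V = tr$V,
                 w = tr$w, z = tr$z, a = tr$a, b = tr$b,
                 params = params, protocol = protocol),
            class = "sim_result")
}

# Reference integrator in plain R; same update rule as the compiled path.
.euler_r <- function(params, protocol) {
  dt <- protocol$dt
  n_settle <- round(protocol$settle_duration / dt)
  n_stim <- round(protocol$stim_duration / dt)
  n <- n_settle + n_stim + 1
  V <- w <- z <- a <- b <- numeric(n)
  s0 <- steady_state(params$E_leak, params)
  st <- c(V = params$E_leak, w = s0$w_inf, z = s0$z_inf,
          a = s0$a_inf, b = s0$b_inf)
  for (k in seq_len(n)) {
    V[k] <- st[["V"]]; w[k] <- st[["w"]]; z[k] <- st[["z"]]
    a[k] <- st[["a"]]; b[k] <- st[["b"]]
    if (!is.finite(st[["V"]]))
      stop("non-finite membrane potential at step ", k)
    I <- if (k <= n_settle) protocol$I_pre else protocol$I_pre + protocol$I_stim
    d <- ml_derivatives(st, I, params)
    st <- st + dt * c(d[["dV"]], d[["dw"]], d[["dz"]], d[["da"]], d[["db"]])
  }
  list(times = (seq_len(n) - 1 - n_settle) * dt, V = V, w = w, z = z,
       a = a, b = b, n_settle = n_settle)
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>", length(x$times), "samples, dt =", x$protocol$dt, "ms\n")
  cat("  I_stim =", x$protocol$I_stim, "uA/cm2, I_pre =", x$protocol$I_pre,
      "uA/cm2\n")
  cat("  gbar_Klt =", x$params$gbar_Klt, ", gbar_KA =", x$params$gbar_KA,
      "mS/cm2\n")
  invisible(x)
}

#' @export
plot.sim_result <- function(x, ...) {
  graphics::plot(x$times, x$V, type = "l", xlab = "time (ms)",
                 ylab = "V (mV)", ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}
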