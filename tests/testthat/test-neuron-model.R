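test_that("steady-state curves hit 0.5 at their half-activation voltages", {
  p <- neuron_params()
  expect_equal(steady_state(p$beta_m, p)$m_inf, 0.5)
  expect_equal(steady_state(p$beta_w, p)$w_inf, 0.5)
  expect_equal(steady_state(p$beta_z, p)$z_inf, 0.5)
  expect_equal(steady_state(-60, p)$a_inf, 0.5)
  expect_equal(steady_state(-78, p)$b_inf, 0.5)
  # total functions with outputs in (0, 1)
  ss <- steady_state(seq(-150, 80, by = 1), p)
  expect_true(all(as.matrix(ss) > 0 & as.matrix(ss) < 1))
})

test_that("time constants follow the stated voltage dependence", {
  p <- neuron_params()
  expect_equal(time_constants(p$beta_w, p)$tau_w, 1) # cosh(0)
  expect_equal(time_constants(0, p)$tau_b, 19)      # depolarised branch
  tc <- time_constants(seq(-150, 80, by = 1), p)
  expect_true(all(as.matrix(tc) > 0))
  # the branch point -63 mV belongs to the double-exponential branch;
  # independent evaluation of that branch:
  lower_branch <- function(V) 1 / (exp((V + 46.05) / 5) +
                                     exp(-(V + 238.4) / 37.45))
  expect_equal(time_constants(-63, p)$tau_b, lower_branch(-63))
  expect_false(isTRUE(all.equal(time_constants(-63, p)$tau_b, 19)))
  # tau_a floor: additive 0.37 ms dominates at depolarised potentials
  expect_gt(time_constants(50, p)$tau_a, 0.37)
})

test_that("derivatives vanish at a self-consistent fixed point", {
  p <- neuron_params() # g_Klt = g_KA = 0
  # resting potential: root of dV/dt with all gates at steady state
  f <- function(V) {
    s <- steady_state(V, p)
    ml_derivatives(c(V = V, w = s$w_inf, z = s$z_inf, a = s$a_inf,
                     b = s$b_inf), 0, p)[["dV"]]
  }
  V_rest <- uniroot(f, c(-90, -50), tol = 1e-12)$root
  s <- steady_state(V_rest, p)
  d <- ml_derivatives(c(V = V_rest, w = s$w_inf, z = s$z_inf, a = s$a_inf,
                        b = s$b_inf), 0, p)
  expect_true(all(abs(d) < 1e-8))
})

test_that("conductance terms drop out of the membrane equation as expected", {
  state <- c(V = -40, w = 0.2, z = 0.3, a = 0.5, b = 0.4)
  base <- neuron_params(gbar_Klt = 0, gbar_KA = 0)
  full <- neuron_params(gbar_Klt = 5, gbar_KA = 7)
  d0 <- ml_derivatives(state, 30, base)
  d1 <- ml_derivatives(state, 30, full)
  # removing both added conductances recovers the three-conductance model
  manual <- d1[["dV"]] +
    (full$gbar_Klt * state[["z"]] + full$gbar_KA * state[["a"]]^4 *
       state[["b"]]) * (state[["V"]] - full$E_K) / full$C
  expect_equal(d0[["dV"]], manual)
  # a = 0 silences the A-type current regardless of gbar_KA
  state0 <- replace(state, "a", 0)
  no_KA <- neuron_params(gbar_Klt = 5, gbar_KA = 0)
  expect_equal(ml_derivatives(state0, 30, full)[["dV"]],
               ml_derivatives(state0, 30, no_KA)[["dV"]])
})

test_that("the five reference conductance settings give the five patterns", {
  proto <- stim_protocol(I_stim = 60)
  cases <- list(tonic = c(0, 0), single = c(6, 0), delayed = c(0, 8),
                gap = c(0, 5), reluctant = c(6, 8))
  for (lab in names(cases)) {
    g <- cases[[lab]]
    expect_equal(
      as.character(classify_neuron(neuron_params(g[1], g[2]), proto)),
      lab, info = sprintf("g_Klt=%g g_KA=%g", g[1], g[2]))
  }
})

test_that("classified patterns are robust to halving the Euler step", {
  cases <- list(c(0, 0), c(6, 0), c(0, 8), c(0, 5), c(6, 8))
  for (g in cases) {
    p <- neuron_params(g[1], g[2])
    l1 <- classify_neuron(p, stim_protocol(I_stim = 60, dt = 0.1))
    l2 <- classify_neuron(p, stim_protocol(I_stim = 60, dt = 0.05))
    expect_equal(as.character(l1), as.character(l2))
  }
})

test_that("compiled and reference integrators agree", {
  p <- neuron_params(gbar_Klt = 2, gbar_KA = 3)
  proto <- stim_protocol(I_stim = 60, settle_duration = 50,
                         stim_duration = 100)
  a <- simulate_neuron(p, proto, engine = "cpp")
  b <- simulate_neuron(p, proto, engine = "R")
  expect_equal(a$times, b$times)
  expect_equal(a$V, b$V, tolerance = 1e-12)
  expect_equal(a$b, b$b, tolerance = 1e-12)
})

test_that("gating variables stay within [0, 1] throughout simulations", {
  for (g in list(c(0, 0), c(6, 8), c(1, 4), c(12, 15))) {
    tr <- simulate_neuron(neuron_params(g[1], g[2]),
                          stim_protocol(I_stim = 80))
    gates <- cbind(tr$w, tr$z, tr$a, tr$b)
    expect_true(all(gates >= 0 & gates <= 1))
  }
})

test_that("without stimulation the membrane settles to a stable rest", {
  tr <- simulate_neuron(neuron_params(gbar_Klt = 3, gbar_KA = 4),
                        stim_protocol(I_stim = 0))
  late <- tr$V[tr$times > 300]
  expect_lt(max(late) - min(late), 1e-6)
})

test_that("depolarising pre-pulses reduce A-current availability at onset", {
  p <- neuron_params(gbar_Klt = 2, gbar_KA = 6)
  b_onset <- vapply(c(0, 5, 10, 15), function(I_pre) {
    tr <- simulate_neuron(p, stim_protocol(I_stim = 60, I_pre = I_pre))
    tr$b[max(which(tr$times < 0))]
  }, numeric(1))
  expect_true(all(diff(b_onset) < 0))
})
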