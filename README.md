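# sdhspike

Spiking-pattern mapping and ion-channel density inference for spinal
superficial dorsal horn (SDH) neurons.

SDH neurons respond to sustained current injection with one of five
spiking patterns — tonic, single, delayed, gap, or reluctant — and the
same neuron can switch pattern with stimulus intensity or membrane
potential. `sdhspike` implements a conductance-based account of this
heterogeneity: a modified Morris–Lecar neuron to which a low-threshold
Kv1-type potassium conductance (density g&#773;<sub>K,lt</sub>, gating
variable *z*) and an inactivating A-type potassium conductance (density
g&#773;<sub>K,A</sub>, current ∝ *a*⁴*b*) are added,

C dV/dt = I − g̅_Na·m∞(V)(V−E_Na) − g̅_K,dr·w(V−E_K) − g̅_K,lt·z(V−E_K)
          − g̅_K,A·a⁴b(V−E_K) − g̅_leak(V−E_leak),

integrated by forward Euler at 0.1 ms. On top of the simulator the package
provides:

* **Classification** of voltage responses into the five patterns from
  inter-spike intervals (gap when the first interval exceeds 1.5× the
  second; delayed when the first-spike latency exceeds 1.5× the first
  interval, or exceeds 100 ms for lone spikes).
* **Pattern maps**: sweeps of the (g̅_K,lt, g̅_K,A) plane (default 0–20
  mS/cm² at 0.1 mS/cm²) labelling each grid node, plus region geometry
  (point sets, centroids) and map stacks across stimulus intensities or
  pre-pulses.
* **Single-neuron inference**: the set of density combinations consistent
  with an observed sequence of patterns across stimulus intensities
  (intersection of regions across planes).
* **Forward population calculation**: pattern proportions
  V_i = ∬_{R_i} P(x,y) dx dy of a bivariate normal distribution of
  densities (means μ, SDs σ, correlation ρ), by 2-D trapezoidal
  integration over the map regions; plus seeded finite-sample emulation.
* **Inverse population fit**: the iterative two-step estimator that
  recovers (μ_K,lt, μ_K,A, ρ) from observed proportions — a coarse-to-fine
  correlation scan alternating with error-scaled centroid-vector updates
  of the distribution centre — with σ estimated by grid search.

## Worked example

```r
library(sdhspike)

# one neuron: moderate A-type conductance produces gap spiking
tr <- simulate_neuron(neuron_params(gbar_Klt = 0, gbar_KA = 5),
                      stim_protocol(I_stim = 60))
classify_trace(tr)$label
#> [1] gap
head(classify_trace(tr)$spike_times)
#> [1]  4.242167 22.103032 29.552593 36.785833 43.889154 50.914033
# an early spike at 4.2 ms, a ~18 ms pause (> 1.5 x the following
# ~7 ms intervals), then resumed firing: the signature of gap spiking

# the population level: map the plane once (~40k simulations, ~half a
# minute), then integrate a density distribution over the regions
map <- build_pattern_map(grid_spec(), stim_protocol(I_stim = 60))
pr <- pattern_proportions(bivariate_normal(3, 4, 1, 1, rho = 0.6), map)
pr
#> reluctant    single   delayed       gap     tonic
#>    0.3512    0.0247    0.2181    0.3710    0.0335
#> coverage: 0.9986
# 37% of this population gap-spikes; only 0.14% of its mass lies
# outside the mapped plane (coverage 0.9986)

# invert: estimate the distribution back from its proportions
fit_proportions(pr, map, sigma = c(1, 1))
#> <fit_result> converged_error after 29 iterations
#>   mu_Klt = 2.998, mu_KA = 4.002, rho = 0.60 (sigma = 1.00, 1.00)
#>   MaxError = 0.000725
# the generating means (3, 4) and correlation 0.6 are recovered to
# within 0.002 mS/cm2 and 0.01, with all five proportions matched to
# better than 0.1%
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/sdhspike.R` (subcommands `simulate`, `classify`, `map`,
`infer-neuron`, `forward`, `sample`, `fit`, `sample-fit`, `preset`), e.g.

```sh
Rscript inst/cli/sdhspike.R map --step 0.5 --I-stim 60 --out map.csv
Rscript inst/cli/sdhspike.R forward --map map.csv --rho 0.6
```

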