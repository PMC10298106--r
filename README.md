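# synkin

Kinetic modelling and simulation of **synaptic protein–DNA complex
lifetimes** from single-molecule fluorescence dwell-time data.

Proteins such as the restriction enzyme SfiI bridge two DNA duplexes at
once. In single-molecule TIRF experiments (one duplex tethered to the
surface, a fluorophore-labelled duplex in solution), each complex shows up
as a fluorescence burst whose duration is the complex lifetime. Measured
lifetimes show a surprise: the *pre-synaptic* complex — one specific
(cognate-site) bond plus one weak non-specific bond — outlives the fully
specific synaptic complex. `synkin` implements the mean first-passage-time
(MFPT) model that explains this through *entropic rebinding multiplicity*,
plus everything needed to test it end to end on synthetic data.

## The model

Dissociation is a two-step scheme over bond count *i*:

```
state 2  <->  state 1  -->  state 0        (complex gone at i = 0)
```

Bond strengths enter through dimensionless parameters `x = exp(En/2)`
(non-specific bond, energy `En` in kT) and `y = exp(Es/2)` (specific bond,
`Es` in kT), with a base rate `u` (s⁻¹): a non-specific bond breaks at
`u/x` and forms at `u·x`, so its equilibrium constant is `x² = exp(En)`;
likewise `u/y`, `u·y`, `y²` for the specific bond. The key ingredient is
the rebinding multiplicity of an `L`-bp non-specific duplex under an
`f`-bp protein footprint,

```
m = L − f + 1            (23 bp, f = 13  ->  m = 11;  33 bp -> m = 21)
```

which multiplies the rebinding rate from state 1 (the protein can rebind
the non-specific duplex in any register — sliding, in effect). First-step
analysis of the chain gives closed-form lifetimes

```
T_nn = (2x + m·x³) / u
T_ss = (2y + y³) / u                  (length-independent)
T_ns = (x + y + m·x²·y) / u
```

At the published parameter set `x ≈ 1.7, y ≈ 5.0, u ≈ 4.6 s⁻¹` these give
12.49 s, 29.35 s and 36.0 s for the 23 bp nn/ss/ns complexes — reproducing
the measured ordering `T_ns > T_ss > T_nn`: eleven weak rebinding routes
collectively beat one strong one.

Beyond the closed forms, the package provides an exact Gillespie sampler of
the scheme, a synthetic TIRF-like trace generator (100 ms frames, 10-min
records, square bursts over Gaussian baseline noise, renewal-process event
arrivals), threshold burst detection, survival-probability analysis with
single-exponential fits (bootstrap SDs, MLE cross-check), two-sample KS
comparisons, and inversion of the lifetime equations to recover
`(x, y, u)` and the bond energies `E = 2·ln(p)`.

## Worked example

```r
library(synkin)

p <- rate_params(x = 1.7, y = 5.0, u = 4.6)
p
#> rate_params: x = 1.7, y = 5, u = 4.6 1/s
#>   bond energies: En = 1.061 kT, Es = 3.219 kT

predict_lifetime(p, complex_config("ns", 23))
#> complex_config: ns, 23/23 bp, footprint 13 bp (non-specific duplex: b)
#>   ns_23bp: 36.01 s

# simulate the three 23 bp conditions (3000 scheme-sampled events each),
# fit survival curves, compare conditions, invert the lifetime equations
cfg <- list(master_seed = 20230606,
            params = list(x = 1.7, y = 5.0, u = 4.6),
            conditions = list(
              list(label = "nn_23_23", kind = "nn", length_a = 23, n_events = 3000),
              list(label = "ss_23_23", kind = "ss", length_a = 23, n_events = 3000),
              list(label = "ns_23_23", kind = "ns", length_a = 23, n_events = 3000)))
report <- run_pipeline(cfg)
report
#> run_report: 3 condition(s)
#>   nn_23_23     tau =  12.59 +/- 0.25 s (n = 3000)
#>   ss_23_23     tau =  29.10 +/- 0.62 s (n = 3000)
#>   ns_23_23     tau =  36.64 +/- 0.78 s (n = 3000)
#>   recovered params: x = 2.71, y = 7.94, u = 17.74 1/s

compare_reference(report)
#>   condition    tau_s  tau_sd_s reference_s reference_sd_s rel_deviation
#> 1  nn_23_23 12.58849 0.2518641        12.6            0.2 -0.0009137736
#> 2  ss_23_23 29.09849 0.6229354        29.6            0.4 -0.0169428664
#> 3  ns_23_23 36.63948 0.7760056        44.7            0.8 -0.1803248106

report$ks_matrix
#>          a        b          D      p_value reject
#> 1 nn_23_23 ss_23_23 0.30866667 0.000000e+00   TRUE
#> 2 nn_23_23 ns_23_23 0.38133333 0.000000e+00   TRUE
#> 3 ss_23_23 ns_23_23 0.09633333 1.622258e-12   TRUE
```

Reading this: the fitted characteristic lifetimes recover the analytic
MFPT values (12.49 / 29.35 / 36.01 s) within their bootstrap SDs, and nn
and ss agree with the published measurements (12.6 and 29.6 s). The ns
row's −18% deviation against the measured 44.7 s is the model's own,
documented, gap — the theory predicts 36.0 s there. The KS matrix rejects
equality for every pair at α = 0.001. The "recovered params" differ from
(1.7, 5.0, 4.6) while reproducing the lifetimes because the inverse map is
ill-conditioned — see the vignette's identifiability section and
`fit_params()`'s profile output.

A command-line front end ships in `inst/exec/synkin`
(`simulate | detect | survival | fit-model | predict | run | compare`).

## Layout

- `R/kinetic_model.R` — closed-form MFPT lifetimes, multiplicity, energies
- `R/stochastic_sim.R` — exact stochastic simulation of the scheme
- `R/synthetic_data.R` — synthetic traces and dwell sets
- `R/event_detection.R` — threshold burst detection, recovery scoring
- `R/survival_analysis.R` — survival curves, exponential fits, KS tests
- `R/model_fitting.R` — parameter recovery from measured lifetimes
- `R/pipeline.R`, `R/cli.R` — config-driven runs, reference table, CLI
- `vignettes/synaptic-lifetime-kinetics.Rmd` — methods notes
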