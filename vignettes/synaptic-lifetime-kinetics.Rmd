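---
title: "Methods: MFPT kinetics of synaptic protein-DNA complex lifetimes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MFPT kinetics of synaptic protein-DNA complex lifetimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synkin)
```

## The model and its assumptions

A synaptic protein–DNA complex holds two DNA duplexes with two independent
bonds. Dissociation is modelled as a continuous-time Markov chain over the
number of intact bonds,

    state 2  <->  state 1  -->  state 0,

with the final step irreversible (the fluorescence burst ends). The model's
assumptions, stated plainly:

1. **Weakest bond breaks first.** In the mixed (ns, pre-synaptic) complex
   the non-specific bond is the one that breaks and re-forms; the specific
   bond only breaks last. The symmetric complexes (nn, ss) break either
   bond at the same rate.
2. **Symmetric energy split.** A bond of energy `E` (kT) breaks at `u/p`
   and forms at `u*p` with `p = exp(E/2)`, so the single-bond equilibrium
   constant is `p^2 = exp(E)`. `u` (s⁻¹) is the rate of an energy-neutral
   step. Other splits of `E` between on- and off-rates would change `u`'s
   interpretation but not the structure of the results.
3. **Entropic rebinding multiplicity.** From state 1, a dangling
   non-specific duplex of length `L` bp can rebind in any of
   `m = L − f + 1` registers for a footprint of `f` bp, so its rebinding
   rate is `m·u·x`. The ss complex can only re-form its specific bond
   (`m = 1` effectively). This multiplicity — not bond strength — is what
   makes the pre-synaptic complex the longest-lived.

First-step analysis gives the closed forms implemented in
`lifetime_nn/ss/ns()`:

* `T_nn = (2x + m·x³)/u`
* `T_ss = (2y + y³)/u` (no `m`, hence length-independent)
* `T_ns = (x + y + m·x²·y)/u` (`m` of the *non-specific* duplex)

`mfpt_oracle()` solves the same chain's 2×2 linear first-step system
directly and is kept as an independent check; the test suite verifies
agreement to 1e-10 relative over 1000 random parameter sets.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `x`, `y` | — | 1.7, 5.0 | published fit to the 23 bp lifetimes; `E = 2·ln p` gives 1.06 kT and 3.22 kT |
| `u` | s⁻¹ | 4.6 | published value; printed with units of seconds, but the lifetime equations require a rate, and 4.6 s⁻¹ reproduces the measured 12.5/29.3 s lifetimes |
| `footprint` | bp | 13 | length of the SfiI recognition sequence (GGCCNNNNNGGCC); gives m = 11 at 23 bp, 21 at 33 bp |
| `frame_interval` | s | 0.1 | camera resolution of the emulated recordings |
| `duration` | s | 600 | 10-min records |
| `threshold` | A.U. | 5000 | the conventional event-selection cut; baseline 500, burst amplitude 8000, noise SD 300 put both levels well clear of it |
| `min_dwell_frames` | frames | 2 | discards single-frame noise spikes; imposes a 0.2 s detection floor |
| `gap_tolerance_frames` | frames | 1 | bridges single-frame dropouts inside a burst |
| `arrival_rate` | s⁻¹ | 0.01 | association rate while a spot is unbound; sets record occupancy |

Two published numbers are deliberately *not* reproduced, because they are
internally inconsistent with the published parameters:

* The non-specific bond energy is quoted as ~0.6 kT, but `2·ln(1.7) = 1.06`
  kT. The package computes energies strictly as `E = 2·ln(p)` (0.6 kT would
  correspond to `ln(1.7)`); both numbers are surfaced, neither silently
  reconciled.
* The quoted 33 bp theory lifetimes (20.0, 58.0, 30.1 s) do not follow from
  the closed forms at (1.7, 5.0, 4.6) with m = 21, which give 23.2, 67.4
  and 29.35 s. `predict_lifetime()` reports what the model actually
  computes; the mixed-length nn rule is the arithmetic mean of the two
  pure-length lifetimes (the stated "average"), and mixed ns reports both
  branches labelled by which duplex is non-specific.

## Stochastic simulation

`sample_dwell()` is a literal event-driven (Gillespie) walk of the chain:
exponential wait in state 2, a single exponential wait at the total exit
rate in state 1, branch chosen by rate ratio. `simulate_ensemble()` draws
the same distribution in vectorised form: the number of visits to state 2
before absorption is geometric with success probability
`k10/(k10 + k12)`, and the dwell is a sum of that many i.i.d. waits in
each state — two gamma variates. The two routes are distribution-identical;
the test suite compares them by mean and KS distance so the fast path never
silently drifts from the literal one.

## What the synthetic data emulate — and what they do not

`generate_trace()` emulates one microscope spot: baseline plus Gaussian
noise on a uniform 100 ms grid, with square fluorescence bursts. Event
placement is an **alternating renewal process**: while unbound the spot
waits an exponential time at `arrival_rate` (pseudo-first-order
association), then a burst lasts one dwell drawn from the requested source,
then the spot is unbound again. This is the exact kinetics of a single
tethered duplex, bursts cannot overlap by construction, and — the property
everything downstream relies on — the planted dwells are i.i.d. draws from
the requested law.

The design replaces an earlier scheme (Poisson start times with
overlapping events rejected and redrawn) that at realistic occupancies
length-biased the planted dwells several percent short, violating the
generator's own contract. Under the renewal model the expected burst count
per record is `duration/(1/arrival_rate + mean dwell)`, not
`arrival_rate × duration`.

Not emulated: spot finding and drift correction (the pipeline starts from
per-spot traces), fluorophore photophysics (no blinking or bleaching),
multi-fluorophore spots, and any intensity structure inside a burst. A
green detection test therefore establishes that threshold/gap/minimum-dwell
logic is correct on square-burst data — not that the thresholds are right
for any particular camera.

## Detection and its resolution limits

A burst is a maximal run of frames strictly above threshold, after
bridging interior sub-tolerance gaps; runs shorter than `min_dwell_frames`
are dropped; dwell = run length × frame interval (no sub-frame
interpolation at 100 ms resolution); bursts touching a record boundary are
flagged censored and excluded by default. Two consequences, verified in the
tests: every detected dwell is frame-quantized, and at the default SNR
(amplitude 8000, threshold 5000, noise SD 300) every miss is
resolution-limited — a dwell under the 0.2 s floor or an inter-event gap
under the bridging resolution — never noise-caused. Overall recovery in the
bundled simulation study is ~98%, not 100%, precisely because an
exponential dwell law puts ~0.7% of mass under the floor.

Threshold monotonicity (raising the threshold cannot increase the event
count) holds for thresholds between the noise band and the burst band; a
threshold placed *inside* either band can split runs and is excluded from
the property.

## Survival analysis choices

* **Estimator.** S(t) = (#dwells ≥ t)/n at the sorted unique dwell values;
  the fit is unweighted least squares of `exp(-t/tau)` with amplitude fixed
  at 1 (the curve is already normalized, and floating an amplitude is not
  supported by the normalization convention). The exponential MLE — the
  sample mean, for uncensored data — is always reported alongside, and a
  >10% disagreement warns, since it flags non-exponential dwells.
* **Uncertainty.** `tau_sd` is a seeded nonparametric bootstrap over events
  (200 resamples by default); a Gauss–Newton curvature SD is also reported.
* **No binning.** Histograms are for display; fits use the step survival
  curve directly, avoiding bin-width choices.
* **Truncation.** The 0.2 s detection floor left-truncates the dwell
  sample; for lifetimes of 12 s and up this biases the fit by well under
  1% and is ignored.

## Finite records and the censoring bias

With 10-min records and 30–40 s lifetimes, dwell collection through traces
has an irreducible statistical bias: an event can only be observed complete
if it fits before the record ends, so completed dwells are length-biased
short — for exponential dwells, E[mean of completed dwells] ≈
`tau·(T − 2·tau)/(T − tau)`, about −2%, −5% and −6% for the nn, ss and ns
conditions at T = 600 s. This is the inspection paradox; it does not depend
on the arrival rate, and including the truncated final event does not
cancel it for a record that starts unbound. The test suite measures exactly
this: trace-route fits at n = 3000 land 2–3 bootstrap SDs below the
analytic lifetimes, while direct scheme-sampled dwells (no record boundary)
recover them within noise. The statistically correct repairs — a censored
exponential likelihood or a Kaplan–Meier estimator — are deliberately out
of scope here, so trace-route lifetimes should be read with this bias in
mind, exactly as real finite-record TIRF lifetimes should.

## Recovering (x, y, u): identifiability

The nn and ss equations are strictly increasing cubics in `x` and `y`, so
at any fixed `u` they invert uniquely (`solve_x_given()`,
`solve_y_given()`; bracketed root-finding on [1e-6, 1e3]). The full
three-lifetime fit (`fit_params()`) minimizes squared relative residuals
over log-parameters (L-BFGS-B, 16 seeded multi-starts, nlminb polish), but
the problem is poorly conditioned: along the manifold where nn and ss are
exact, the predicted ns lifetime moves only from `(T_nn + T_ss)/2` (u → 0)
to `(m·T_nn²·T_ss)^{1/3}` (u → ∞). Concretely, the log–log Jacobian of the
lifetimes with respect to the parameters has condition number ≈ 300 near
the published values, so a 3% lifetime perturbation can move the fitted
parameters by order 100% while reproducing the lifetimes to machine
precision. The tests assert what is actually guaranteed: exact recovery on
noise-free triples from any start, and on noisy triples an objective value
no worse than at the generating parameters.

For the measured 23 bp triple (12.6, 29.6, 44.7 s) no exact solution
exists: the attainable ns prediction tops out near 37 s. The objective then
decreases indefinitely along the manifold as `u` grows, which is why the
optimizer is box-constrained (|log p| ≤ 7) — and why the quotable result is
the always-emitted profile view ("nn/ss exact, scan u"), which at
u = 4.6 s⁻¹ gives x ≈ 1.71, y ≈ 5.02 and an ns prediction of ≈ 36.3 s,
matching the published pairing. The model's ~19% under-prediction of the
ns lifetime is a property of the model, reported, not fitted away.

## Numerical and degenerate-input conventions

* Root brackets [1e-6, 1e3] with `uniroot` tolerance 1e-12; the cubics are
  monotone so roots are unique.
* `mfpt_oracle()` refuses chains that cannot absorb (a zero forward rate).
* Seeds: every ensemble, bootstrap and pipeline stage derives its own seed;
  the pipeline uses a stated splitting rule (polynomial string hash of
  "stage:label" combined with the master seed, kept inside 32-bit range) so
  any stage can be reproduced in isolation. Seeded draws restore the
  caller's RNG state.
* Empty dwell sets, non-positive dwells, non-uniform trace grids, and
  configs with duplicate labels fail fast with named errors rather than
  propagating NaNs.

## Known limitations

* Single-exponential dwell models only; no multi-exponential mixtures, no
  censored-likelihood fitting.
* The kinetic scheme has no photophysics; bleaching-limited dwells would
  masquerade as dissociation and bias lifetimes low in real data.
* The ns scheme implements "non-specific bond breaks first" literally;
  dissociation through the specific bond first is not modelled.
* Parameter uncertainty is not propagated beyond the bootstrap on tau and
  the profile view; no posterior over (x, y, u).
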