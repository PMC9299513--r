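---
title: "Simulating and analysing whole-cell K+ currents in RPE cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing whole-cell K+ currents in RPE cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpeclamp)
```

Retinal pigment epithelial (RPE) cells express a small repertoire of K+
conductances that shape their resting potential and transepithelial
transport: a fast delayed rectifier (Kv1.3-like), a slowly activating,
non-inactivating M-current (KCNQ), a fully inactivating A-type current
(Kv1.4/Kv4.2-like), and a mild inward rectifier (Kir7.1). Whole-cell
voltage-clamp surveys of cultured human RPE report each type in only a
fraction of cells, with characteristic activation ranges, amplitudes and
drug sensitivities.

`rpeclamp` provides two halves that close on each other:

1. a **forward simulator** of whole-cell recordings from parameterised
   channel populations under episodic voltage protocols, including
   pharmacological and ion-substitution modifiers and cohort-level
   heterogeneity; and
2. the **analysis pipeline** such recordings are subjected to: liquid
   junction potential (LJP) corrected IV curves, tail-current conductance
   extraction with Boltzmann activation fits, per-cell phenotype
   classification, and cohort statistics (incidence, mean ± SEM, exact
   Mann-Whitney U).

Because the simulator's ground truth is known, every stage of the analysis
is testable by parameter recovery, which is how the package validates
itself.

## The forward model

Under ideal voltage clamp the command potential is piecewise constant
(holding → test step → optional tail), so first-order Hodgkin-Huxley gating

$$\frac{dm}{dt} = \frac{m_\infty(V) - m}{\tau}, \qquad
  m_\infty(V) = \frac{1}{1 + e^{(V_{1/2} - V)/S}}$$

has the closed-form solution
$m(t) = m_\infty + (m_0 - m_\infty)e^{-t/\tau}$ within each segment.
The simulator evaluates gates analytically at the sample times
(exponential-Euler, exact for piecewise-constant V), so accuracy does not
depend on the sample interval; halving the interval reproduces shared
samples to machine precision, which the test suite asserts.

Per-sample current (pA) is

$$I(t) = \sum_{\text{channels}} g_{max}\, m(t)\, h(t)\, r(V)\,(V - E_{rev})
       \;+\; g_{leak}(V - E_{leak}) \;+\; \varepsilon(t)$$

with one activation gate per voltage-gated family, one inactivation gate
$h$ for the A-type family only, and, for the kir family, an instantaneous
rectification factor $r(V) = 1/(1 + e^{(V - V_{r})/S_r})$ in place of a
gate (Kir7.1 gating is effectively instantaneous at whole-cell time
scales). $\varepsilon$ is i.i.d. Gaussian recording noise (default SD
3 pA), seeded per cell so that every simulation is exactly reproducible.
Capacitive transients, series-resistance and space-clamp errors,
stochastic single-channel gating and temperature scaling are deliberately
out of scope: the analyses this package implements read peaks, late means
and tails, none of which depend on them, and the tail-measurement window
starts after the region a capacitive transient would occupy.

### Default channel parameters

| family | $g_{max}$ (nS) | act. $V_{1/2}$/S (mV) | $\tau$ (ms) | other |
|---|---|---|---|---|
| delayed_rectifier | 0.72 | -10 / 12 | 5 | Ba²⁺ 0.21, TEA 0.44, AgTx2 0.49 |
| m_current | 1.8 | -37.2 / 25.7 | 150 | linopirdine 0.43 |
| a_type | 1.39 | -25 / 10 | 3 | inact. -60 / 8, $\tau_h$ 50 ms |
| kir | 0.809 | (instantaneous) | — | rect. -60 / 20; Rb⁺ ×1.523 |

The M-current activation triple ($V_{1/2} = -37.2$ mV, $S = 25.7$ mV,
$g_{max} = 1.8$ nS) and the modifier multipliers in the right column are
measured values; everything else is an explicit assumption, chosen once so
that the simulated phenotypes reproduce the reported qualitative features
and reference amplitudes: activation visible near -30 mV and ~92 pA at
+45 mV for the delayed rectifier, activation at -50 mV, ~108 pA peak and
complete inactivation within 1 s for the A-type, and activation near
-70 mV with -43 pA at a true -145 mV in the Na⁺ bath for kir. No
activation time constants are reported for these cells; the defaults are
assumptions that reproduce trace shapes, not fitted quantities. All
parameters are overridable through `channel_preset()` /
`channel_model()`.

The Rb⁺ modifier deserves a note. Replacing the 120 mM NaCl of the bath
with RbCl both moves the K-channel reversal potential (Rb⁺ is treated as a
K-like permeant, permeability ratio 1 by default, so $E_{rev}$ moves from
-91.1 mV to +3.3 mV) and increases the Kir7.1 conductance. The shipped
conductance factor 1.523 is calibrated so that, together with the enlarged
driving force at a true -145 mV, the measured current grows by the
reported ~319% — i.e. a ×4.19 current ratio, of which ×2.75 is driving
force and ×1.52 conductance. Folding the full ×4.19 into the conductance
*and* recomputing the reversal would double-count the driving-force
change.

## Solutions and the LJP convention

Reversal potentials are never hard-coded: they come from the Nernst
equation applied to the configured solutions at the configured temperature
(default 295 K). The pipette K⁺ totals the K-containing salts
(25 KCl + 83 K-gluconate = 108 mM; KOH titration ignored), and the free
K⁺ of Ames' medium — not printed on the formulation — defaults to 3.6 mM;
both are documented assumptions overridable in the YAML configuration
(`inst/extdata/default-config.yaml`).

One sign convention is used everywhere: $V_m = V_{cmd} - LJP$ (11 mV for
the Na⁺ bath, 4 mV for Rb⁺, negligible in Ames'). The simulator works in
true membrane potentials by default (`potentials = "membrane"`; sweep sets
are flagged `ljp_applied`), which keeps cross-bath comparisons at stated
corrected potentials simple; `potentials = "command"` emulates an
amplifier driving uncorrected commands, and the analysis then corrects.
All analysis outputs report corrected potentials.

## Tail-current conductance analysis

From a -10 mV holding potential, 1000 ms prepulses (-100 or -140 up to
+40 mV) are followed by a return to -10 mV. The instantaneous tail
amplitude indexes the open fraction reached at the prepulse; dividing by
the driving force gives the conductance

$$g_{K,-10\,\mathrm{mV}} = \frac{I_{K,-10\,\mathrm{mV}}}{V_m - E_K},$$

and the conductance-voltage curve is fitted by unweighted nonlinear least
squares (Levenberg-Marquardt) to the Boltzmann
$g/g_{max} = 1/(1 + e^{(V_{1/2} - V)/S})$.

Three measurement choices matter and are configurable:

* **Tail window and extrapolation.** Samples in a 2-10 ms post-onset
  window are linearly extrapolated back to the tail onset (default).
  A plain window mean (`method = "window_mean"`) underestimates every
  tail by $\approx 1 - e^{-\bar t/\tau}$ — about 4% at $\tau = 150$ ms —
  which propagates into $g_{max}$; extrapolation removes this to <0.2%.
* **Zero-activation reference.** The tail of the most hyperpolarized
  prepulse is subtracted from every sweep, cancelling leak and any
  standing current at -10 mV. With a slope factor as shallow as 25.7 mV,
  however, even a -140 mV prepulse retains ~2% open probability (8% at
  -100 mV), so the reference itself sits on the activation curve. The fit
  therefore uses the exact forward model of the measurement,
  $g(V) = g_{max}\,[B(V) - B(V_{ref})]$, whenever the curve carries its
  reference; ignoring the correction biases $g_{max}$ by 4-10% and drags
  $V_{1/2}$ with it. Pass `reference_mV = NA` for the plain Boltzmann.
* **Two $g_{max}$ readings.** Whether the reported maximum conductance is
  the largest raw tail conductance or a fitted asymptote is ambiguous in
  such analyses; the package reports both (`gv_curve$gmax_nS` raw,
  `boltzmann_fit$gmax_nS` fitted). They differ by the truncation of the
  prepulse range: the raw value is bounded by
  $B(V_{max}) - B(V_{ref}) < 1$.

With these defaults the full pipeline — simulate a noiseless M-current
cell, extract tails, build the GV, fit — returns the generator parameters
to well under 1%, and under 3 pA noise the median $V_{1/2}$ error across
seeds stays below 2 mV. Both recoveries are asserted in the test suite.
The literal "subtract from the maximum" bookkeeping is available as
`gv_from_tails(mode = "literal")` for comparison.

## Phenotype classification

How a recorded cell was "detected with" a current type is never fully
specified in survey electrophysiology. The package makes the criteria an
explicit, configurable object (`classification_criteria()`) with two
methods:

* **Matched-template regression (default).** The cell's concatenated
  sweeps are projected by least squares onto unit-conductance template
  currents of the four family presets, simulated under the cell's own
  protocols and baths, plus an ohmic-leak pair (the voltage trace and a
  constant). A family is assigned when its fitted conductance exceeds
  0.1 nS (≈ the 5×noise-SD amplitude threshold expressed as conductance
  at a ~130 mV driving force). Because co-expressed currents superpose
  linearly, the projection separates them exactly; simple amplitude
  thresholds cannot (an M-current-only cell exceeds any reasonable
  outward-current threshold at +45 mV and would masquerade as a delayed
  rectifier, and a rising M-current masks the A-type transient in
  co-expressing cells).
* **Interpretable threshold rules** (`method = "threshold"`): outward
  end-of-step current at the top step of the 50 ms protocol for the
  delayed rectifier; peak above threshold with end-of-step/peak < 0.2 for
  the A-type; sustained end-of-step (> 0.8 of peak, late/early ratio > 1)
  for the M-current; inward current at -145 mV exceeding both the
  threshold and 2× the outward current for kir. These are the rules a
  human analyst applies to single-phenotype cells; they assume the leak
  is small against the 15 pA threshold (no leak subtraction is performed
  by default, and windowed means rather than peaks are used where a noisy
  extremum would bias detection).

The template method's strength on synthetic cohorts is also its caveat on
real data: it assumes the template kinetics. For recordings whose kinetics
deviate from the presets, supply adjusted `templates`, or fall back to the
threshold rules.

## The population generator

`population_spec()` draws each family independently per cell at the
observed incidences (0.80 / 0.22 / 0.15 / 0.14), conductances from
per-family log-normals whose means equal the preset conductances
(`sdlog = 0.3`), capacitances from a log-normal with mean 27 pF, and a
fixed 0.5 nS leak to -20 mV. One master seed derives all per-cell noise
streams, so a cohort is bit-reproducible.

The printed amplitude spreads of the real recordings imply coefficients of
variation near 0.8; the generator deliberately uses ~0.3. The wider real
spread folds in cell-size and access-resistance variability that an
ideal-clamp simulator does not model, and at CV 0.8 a noticeable fraction
of cells would carry genuinely undetectable currents, making "incidence
recovery" a statement about amplitude censoring rather than about the
classifier. What the passing cohort tests show is therefore: *given*
detectable amplitudes and preset kinetics, the pipeline recovers presence
and incidence essentially without error. They do not show robustness to
kinetic variability, rundown, seal drift or endogenous currents outside
the four families — none of which the generator emulates.

## Statistics

* **Incidence** is detected/total as an integer percentage, rounded half
  away from zero — the rule that reproduces every printed pair (47/59 →
  80, 9/41 → 22, 6/41 → 15, 9/64 → 14, 11/14 → 79).
* **Mann-Whitney U** uses midranks, with the exact permutation
  distribution whenever all label assignments are enumerable (all group
  sizes ≤ 8 comfortably qualify, C(16,8) = 12870 assignments) and a
  tie-corrected normal approximation with continuity correction beyond.
  Worth knowing: the exact two-sided p at n = 3 vs 3 can never fall below
  2/20 = 0.1, so reported significances at such sizes imply an
  approximate test. Drug comparisons are computed unpaired, as the named
  test implies; whether the original comparisons were paired is unknown,
  and a paired variant is out of scope.
* **mean ± SEM** uses the n−1 sample SD; n = 1 reports SEM 0 with a
  warning. No multiple-testing correction is applied anywhere.

## Numerical choices and degenerate inputs

* Sample interval: 0.1 ms default; cohort-scale runs use 0.5 ms (the
  classification and summary windows average many samples and are
  insensitive to the grid — gate evaluation is exact at any interval).
  The shipped test suite classifies a 2000-cell cohort at 0.5 ms and
  fits 20 noisy tail analyses at 0.2 ms.
* Boltzmann fits: start at the half-range crossing for $V_{1/2}$, 15 mV
  slope, max conductance; Levenberg-Marquardt with 1e-12 parameter
  tolerance (zero-residual noiseless fits converge cleanly). Flat GV data
  are flagged non-converged with `NA` parameters rather than returning an
  arbitrary $V_{1/2}$; a non-positive fitted slope is likewise flagged.
* Baseline: mean of the final 50% of the pre-step holding segment.
* Peak: signed extremum of largest magnitude, so inward Kir peaks and
  outward Kv peaks obey one rule; ties resolve to the earliest sample.
* `percent_change()` compares current *amplitudes*
  ($100(|I_t| - |I_c|)/|I_c|$): negative = block, positive = enhancement
  for inward and outward currents alike; a sign change between control
  and test warns, since an amplitude ratio across a reversal is
  meaningless.
* Protocol invariants (increment dividing the range, sample interval
  below the step duration) and solution invariants (positive K⁺,
  temperature) are enforced at construction, not at use.

## Known limitations

* The simulator is phenomenological: one activation gate per family,
  fixed time constants, no Markov states, no stochastic gating.
* Ba²⁺ and TEA sensitivities are attached to the delayed rectifier only,
  with the measured aggregate block; their (real) partial effects on the
  other conductances default to 1 and must be configured if needed.
* The template classifier inherits the preset kinetics (above).
* ABF import is not implemented; recordings enter through the documented
  CSV/JSON bundle (`write_sweep_bundle()` / `read_sweep_bundle()`).
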