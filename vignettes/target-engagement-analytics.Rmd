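---
title: "Methods: thermal-shift target engagement and inhibitor triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal-shift target engagement and inhibitor triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engagekit)
```

# Scope

`engagekit` implements the computational side of a target-engagement
campaign: proof of in-cell binding by thermal proteome profiling
(TPP/CETSA), biochemical potency analytics, and virtual-screen
triage. Everything upstream of the protein-level quant table —
spectral searching, docking, wet-lab protocols — is out of scope; the
package consumes search-engine-style reports, docking *ranks*, and
plate reads, and a synthetic generator stands in for raw data.

# The melting-curve model and its assumptions

The soluble fraction of a protein after brief heating to temperature
$T$ is modelled as a three-parameter descending logistic

$$f(T) = p + \frac{1 - p}{1 + \exp\!\big((T - T_m)/s\big)},$$

with upper asymptote fixed at 1 because curves are normalized to a
non-denatured reference aliquot. $T_m$ (°C) is the half-denaturation
point (for $p = 0$), $s$ (°C) the transition width, and
$p \in [0, 1)$ a plateau of thermally resistant signal. The model
assumes two-state, kinetically frozen denaturation during the 3-min
heat pulse — the standard idealization for CETSA-style data. Proteins
whose aggregation is concentration- or complex-dependent will deviate;
the CV filter (below) is the practical guard against such irregular
curves.

# Normalization

Four stages, each tagging its output so they cannot run out of order:

1. **Depth scaling.** Each run's scaling factor is its
   identified-precursor count divided by the mean count over that
   condition's denaturation runs, so factors average to 1 per
   condition. Note the direction: the procedure *multiplies* by the
   factor, so deeper runs are scaled up. This matches the source
   workflow exactly; since factors hover near 1 and the per-protein
   median normalization that follows is scale-free within condition,
   the direction has little practical effect, but
   `invert_scaling = TRUE` provides the conventional correction.
   Reference runs are neither included in the mean nor rescaled.
2. **Per-protein median normalization.** Every value of a protein in
   a condition is divided by the median of its non-missing
   *denaturation* values in that condition. Reference runs do not
   contribute to the median but are divided by it, which keeps them
   commensurate for stage 3; without this the reference divisor would
   reintroduce the (arbitrary) absolute abundance scale and the final
   curves would not converge to the analytic model on clean data.
3. **Reference normalization.** Division by the protein's median
   across the condition's reference runs; proteins with no reference
   value fall back to the median over proteins of the per-protein
   reference medians. After this stage a clean curve has upper
   asymptote 1.
4. **Missing-pattern filter.** A curve (one protein, one condition,
   one replicate) is discarded when more than `max_missing = 3` of
   the 10 ladder temperatures are missing, *unless* all of the
   `first_k_required = 5` lowest temperatures are present — a curve
   complete at the low end still anchors a melting transition.

Medians of even-count sets are the mean of the two central values
(R's default). Missing values are kept as `NA` throughout — never
zero, which would corrupt medians and splines. On noiseless synthetic
data with equal depth the composed pipeline reproduces the analytic
model to machine precision; the test suite asserts 1e-9.

# Tm estimation

Per curve, in order:

* **Direct:** if any measured point lies within `tm_tolerance = 0.05`
  of relative abundance 0.5, its temperature is the Tm. When several
  qualify, the abundance closest to 0.5 wins; exact ties go to the
  lower temperature (ties are not otherwise specified by the
  procedure; lower is the conservative choice under stabilization).
* **Spline:** otherwise a natural cubic interpolating spline through
  the non-missing points is evaluated on a 0.01 °C grid across the
  ladder and the lowest grid temperature where it crosses 0.5 from
  above is returned. Curves are not forced monotone first; the
  estimator reports the first downward crossing, which on noisy
  non-monotone curves is the conservative (lowest) estimate.
* **Fallback:** with no crossing (or fewer than 4 points for the
  spline), Tm is the ladder maximum, 64 °C.

**Accuracy of the spline branch.** Interpolating a logistic with
transition width 2 °C at this 10-point ladder gives a crossing error
below 0.05 °C throughout the central Tm range (the simulator draws
true Tm from 42–58 °C, a realistic span for a mammalian proteome,
median near 50 °C). In the outermost knot intervals — true Tm below
about 41.6 °C or near 62 °C — cubic interpolation error grows to
about 0.07 °C (0.27 °C for a 1 °C transition width); this is a
property of any cubic through these knots, not of the implementation,
and the unit suite documents it with an explicit 0.1 °C edge bound.
Direct-window detection, when applicable, is exact to within
$s\cdot\lvert\log(0.45/0.55)\rvert \approx 0.2 s$ of the true Tm.

# Shift calling

ΔTm is the difference of condition means of per-replicate Tm values
(treated − vehicle; positive = stabilization). Replicates are not
paired across conditions, so a paired design is not assumed. The
p-value is a two-sided Welch t-test on the replicate Tm values — the
upstream procedure names no test, and Welch is the natural choice for
two small samples of per-replicate estimates with possibly unequal
variance; an exact permutation alternative is available
(`test = "permutation"`), though with 3 + 3 replicates its two-sided
floor is 0.1, which can never pass α = 0.05 — a caveat, not a bug.
Hits require |ΔTm| ≥ 1.5 °C (both directions: destabilization is as
real as stabilization) and p < 0.05, raw — no multiplicity
correction, matching the procedure being reimplemented;
`adjust_p = TRUE` applies Benjamini–Hochberg. The **robust** flag
requires the CV (sd/mean) of the replicate Tm values to be below 0.1
in every compared condition; the CV is computed on Tm estimates
because that is the only per-replicate quantity the pipeline
produces.

# Screen, dose–response, binding, kinetics

* Velocities are OLS slopes of fluorescence vs time (offset
  invariant, ≥3 points).
* A compound well is a hit when its velocity is ≤ 2× the mean DEAB
  (full-inhibition control) velocity. Lower signal = more inhibition;
  plates where the DMSO mean does not exceed the DEAB mean are
  rejected as degenerate. Percent inhibition is reported on the
  DMSO→DEAB scale, clipped to [0, 100].
* 4PL fits run in log-concentration space (`minpack.lm`), six
  data-driven starts (IC50 at concentration quartiles × rising and
  falling slopes), best SSE kept, |Hill| bounded to [0.2, 10], and
  asymptotes reported with top ≥ bottom. The parameterization makes
  the fit exactly invariant to concentration-unit changes.
* Binding isotherms use the 1:1 site model
  baseline + amplitude·L/(L + Kd), with a fit flagged unidentifiable
  when the amplitude is within noise of zero.
* Inhibition-mode classification fits Michaelis–Menten per inhibitor
  level (seeded from the double-reciprocal line, refined by
  Levenberg–Marquardt) and compares apparent Vmax/Km to the
  zero-inhibitor level with a 20% relative band: Vmax↓ & Km constant →
  noncompetitive; Km↑ & Vmax constant → competitive; both scaled by
  the same factor → uncompetitive; otherwise mixed. Cooperative
  kinetics are out of scope.

# Chemistry triage

Descriptors (MW, cLogP, Lipinski donors/acceptors, Ertl TPSA) come
from OpenBabel via ChemmineR/ChemmineOB. cLogP is the one descriptor
whose value is materially tool-dependent (atom-contribution schemes
differ by up to ~1 log unit); the filter windows are therefore fully
configurable and the package never treats a logP boundary as sharp
science. Defaults are the screening funnel's windows: MW < 450,
cLogP ∈ [1, 3], HBA 1–5, HBD 1–3, TPSA < 140 Å².

Fingerprints are 2048-bit, radius-2 circular (Morgan/ECFP4-class)
fingerprints implemented in the package: atom invariants (element,
heavy degree, implicit H count, formal charge, ring membership) are
iteratively re-hashed with sorted (bond order, neighbor id) lists and
folded mod 2048. The construction depends only on the molecular
graph, so SMILES atom ordering is irrelevant (tested); bit patterns
are *not* interchangeable with other toolkits' ECFP4, which only
matters if cutoffs tuned elsewhere are imported verbatim.

Diversity selection is greedy sphere exclusion in combined-rank order
(combined rank = min of the two docking ranks; ties by hybrid rank,
then id): a compound is kept iff its Tanimoto similarity to every
kept compound is < 0.52. Rank-ordered greedy keeps the best-scored
representative of each structural cluster and is deterministic given
the ranking. The cutoff is interpreted as a similarity ceiling; a
distance-floor reading is available via `as_distance = TRUE`.

# The synthetic generator

`simulate_melt_dataset()` emulates: the 10-temperature ladder
(36.9–64 °C), 2 conditions × 3 replicates plus one non-denatured
reference per condition × replicate, per-protein logistic curves (Tm
~ U(42, 58) °C, width U(1, 3) °C, plateau U(0, 0.2)), lognormal
abundance baselines, multiplicative lognormal noise (default σ =
0.05; 0.03 in the recovery studies), ~3% missing cells, `CON__`
contaminant entries, a low-peptide fraction to exercise the peptide
filter, and spiked proteins shifted by N(4, 0.5²) °C in the treated
condition only (vehicle Tm shared, mirroring ligand stabilization).
One seed drives a single generator with a fixed draw order, making
outputs byte-identical across runs. Replicate count defaults to 3,
the design the analysis targets.

What it does **not** emulate: correlated (batch) noise, intensity-
dependent missingness (censoring), irregular/multiphasic melting,
protein-protein coaggregation, or carrier effects. Passing recovery
tests therefore demonstrate correctness of the estimators under the
stated noise model, not performance on every pathology of real data —
which is precisely why the CV filter exists downstream.

`simulate_screen_plate()` draws true-hit velocities below the 2×-DEAB
cutoff and inactive compounds well above it with additive read noise;
`simulate_dose_response()` adds Gaussian noise to an exact 4PL.

# Problem sizes and tolerances in the validation suite

The recovery studies use a 2,000-protein simulation with 100 spiked
proteins (σ = 0.03, n = 3): median absolute Tm error ≈ 0.4 °C,
sensitivity 1.0 for true shifts ≥ 3 °C, false-positive rate < 0.001 —
comfortably inside the ≤ 0.5 °C / ≥ 0.9 / ≤ 0.05 targets. IC50 and Kd
recovery are checked over 100 seeded replicates at 1% noise (median
relative error ≈ 2%, target ≤ 5%). Oracle-equivalence checks (hit
calling, diversity picking, missing-pattern filter) compare against
exhaustive scans. These sizes keep the whole suite in tens of
seconds while leaving the statistical margins wide.

# Known limitations

* The spline Tm estimator is interpolation-limited near the ladder
  ends (see above); Tm values within ~1.5 °C of the ladder extremes
  carry up to ~0.1 °C additional error and fallback estimates are
  censored at 64 °C.
* Welch on n = 3 per side is underpowered; the 1.5 °C effect cutoff,
  not the p-value, does most of the selection work.
* No protein inference, FDR control, imputation, or NPARC-style
  functional testing.
* cLogP values are method-specific; cross-study logP windows should
  be recalibrated to the descriptor source.
* The 1:1 isotherm ignores ligand depletion; Kd values near the
  receptor concentration would need the quadratic model.
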