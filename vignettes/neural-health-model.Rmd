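---
title: "Modelling and measuring neural-health estimates in cochlear implant users"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring neural-health estimates in cochlear implant users}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cihealth)
```

## The problem

Cochlear implants stimulate spiral ganglion neurons (SGNs) directly, and
the condition of the stimulated neural population — "neural health" —
varies along the cochlea and between users. Three measures have been
proposed as local estimates of that condition:

* **MPI (multipulse integration)** — the drop in behavioural detection
  threshold when the pulse rate rises from 80 to 1000 pulses per second
  (pps). Reported in dB; larger values have been linked to healthier
  populations in animal work.
* **PE (polarity effect)** — the threshold difference between
  cathodic-centred and anodic-centred quadraphasic (QP) pulse trains,
  `T_cathodic - T_anodic`. Cathodic pulses preferentially excite the
  peripheral processes of SGNs and anodic pulses the central axons, so a
  negative PE (cathodic advantage) is read as a sign of surviving
  peripheral processes.
* **IPG offset** — the mean dB gap between the overlapping linear
  portions of ECAP amplitude growth functions (AGFs) measured with a
  short (8 µs) and a long (40 µs) interphase gap, both axes logarithmic.
  As a differential measure it cancels non-neural scaling factors
  (electrode position, impedance) that plague absolute ECAP features.

This package implements all three estimators, a population model of SGN
fibres that reproduces their qualitative behaviour under controlled
degeneration, the adaptive psychophysical procedure used to measure the
behavioural thresholds, and the within-subject correlation analysis used
to compare estimates across an electrode array. A synthetic-study
generator stands in for human data, so the whole pipeline is testable and
parameter recovery can be quantified.

## The fibre model

Each fibre has two spike-initiation sites — the peripheral process
(dendrite + soma) and the central axon — modelled as exponential
integrate-and-fire point processes with adaptation:

$$C \dot V = -g\,(V - V_{rest}) + g\,\Delta_T\,
  e^{(V - V_T - W)/\Delta_T} + I(t), \qquad
  \tau_w \dot W = a\,(V - V_{rest}) - W,$$

with $W \mathrel{+}= b$ on each spike. A spike is registered when $V$
exceeds $V_T + 10\,\Delta_T$; the two site spike trains are merged under
a shared 500-µs refractory period, and a peripheral spike resets the
central site after a 100-µs conduction delay (antidromic collision).

**Polarity coupling.** The signed stimulus current $s(t)$ (anodic
positive) depolarises the peripheral site when cathodic and the central
site when anodic. The non-preferred polarity acts with a reduced gain
$\rho < 1$ (`polarity_gain`): the peripheral site receives
$\mathrm{sens}_p\,(s^- - \rho_p\, s^+)$ and the central site
$\mathrm{sens}_c\,(s^+ - \rho_c\, s^-)$. Setting $\rho = 1$ recovers
strict antisymmetric coupling, but that limit is qualitatively wrong: for
a site excited by the *second* phase of a biphasic pulse, full-strength
cancellation makes the IPG threshold shift *grow* towards
$20\log_{10}(65/33) \approx 5.9$ dB as the membrane slows, so
demyelination would *increase* the IPG offset, and the polarity effect
would collapse to zero under central demyelination — both the opposite
of what degeneration experiments show. With $\rho < 1$ the cancellation
is incomplete, the late-phase IPG shift vanishes as the membrane slows,
and the anodic-centred QP advantage of a bare central axon survives
demyelination with asymptote $20\log_{10}(2 - \rho_c)$ dB. Partial
polarity selectivity is also what is observed in real fibres, whose
anodic/cathodic threshold ratios are finite.

**Degeneration manipulations** (`degeneration_spec()`):

* `peripheral_disabled` — peripheral site removed, central untouched;
* `retrograde(k)` — peripheral removed *and* the central axon
  demyelinated by multiplying its capacitance and dividing its
  conductance by $k$ (the membrane slows by $k^2$, the input coupling
  weakens by $k$);
* `simultaneous(k)` — both sites demyelinated, peripheral still enabled.

**Per-pulse stochasticity.** On every pulse, each site's threshold is
perturbed by a Gaussian factor $1 + \mathrm{rs}\cdot z$ with relative
spread `noise_rs = 0.08`. This produces graded rate-level functions and
the probability summation across pulses that detection over a 0.4-s
train relies on. Streams are derived deterministically from (population
seed, fibre, level, trial), so every simulation is exactly reproducible
and independent presentations are available by incrementing `trial`.

### Reference parameterisation and calibration

The published description of the underlying model names its ingredients
but not a usable parameter table, so the package fixes its own
realisation and calibrates it once against directional anchors, then
freezes it (`calibrate_reference_params()`):

| parameter | peripheral | central | why |
|---|---|---|---|
| membrane time constant $C/g$ | 1 ms | 800 µs | slow integration creates cross-pulse summation at 1000 pps (the single-fibre MPI rate benefit) at both sites; the central axon is somewhat faster |
| $\Delta_T$ (slope factor) | 4 | 4 | sets the latency of spike initiation; larger values make the benefit of a longer interphase gap visible |
| $V_T - V_{rest}$, $V_{reset}$ | 20, 0 | 20, 0 | dimensionless scale |
| refractory | 500 µs | 500 µs | permits partial following at 1000 pps |
| `polarity_gain` $\rho$ | 0.65 | 0.70 | see above; $\rho_c$ sets the asymptotic PE ($20\log_{10}(2-\rho_c) \approx 2.3$ dB), and $1-\rho$ the residual charge per pulse that drives 1000-pps summation |
| adaptation $a$, $b$, $\tau_w$ | 0.002, 2.5, 30 ms | 0.002, 1.5, 30 ms | spike-triggered adaptation limits sustained 1000-pps firing; the central site adapts less (axonal sites accommodate less than dendritic ones), which is what makes MPI *increase* when the peripheral processes are removed |
| sensitivity (per µA) | 0.0098 | 0.0076 | puts the healthy single-pulse threshold at 43.75 dB re 1 µA and keeps the peripheral site dominant for cathodic-leading stimuli, giving healthy fibres a cathodic QP advantage |
| `noise_rs` | 0.08 | — | feline-scale relative spread |

Calibration anchors (all verified by the test suite):

1. healthy fibres: cathodic-centred QP threshold slightly below
   anodic-centred (the magnitude is deliberately uncalibrated — only the
   sign is anchored);
2. peripheral disabled: anodic-centred QP threshold ≈ 2 dB below
   cathodic-centred, essentially unchanged by added central
   demyelination;
3. thresholds fall when the IPG grows from 8 to 40 µs, at either site;
4. population MPI (1000 fibres, 10,000-spike criterion) ≈ 4 dB at a
   3-dB threshold SD and ≈ 3 dB at 0.5 dB, larger without peripheral
   processes, and larger for 500 than for 1000 fibres at a fixed
   absolute criterion;
5. the model IPG offset falls monotonically under retrograde
   demyelination (k = 1, 2, 4) and more shallowly under simultaneous
   demyelination (k = 2, 4, 8), and is invariant (±0.3 dB) to the number
   of fibres and to the mean and SD of the firing thresholds.

The calibration was a manual grid exploration over ($\rho_p$, $\rho_c$,
$\Delta_T$, the two time constants, adaptation) against anchors 1–5;
the frozen values are the ones shipped. Exact numerical identity with
any other implementation is *not* a contract — directional behaviour
plus the calibrated anchors are.

### Numerical integration

Within a pulse footprint (and a tail while the exponential term is
live), forward Euler at `dt = 1 µs`; across the silent remainder of each
inter-pulse interval, analytic exponential relaxation of $V$ and $W$
(the $a$-coupling is ignored there; $a$ is small and $V$ is near rest).
25–42 µs phases need sub-phase resolution; 0.6–12 ms gaps do not. The
test suite checks 1-µs integration against a 0.1-µs oracle on single
pulses near threshold (same spike count, latency within 20 µs). The
exponential term is skipped when its argument is below −6 and capped at
16 to keep the state finite; a non-finite state raises an error rather
than propagating.

## Population protocols

`population_rate_level()` sums spike counts over fibres whose
threshold offsets are drawn Normal(0, SD) and applied as sensitivity
scalings at both sites. Criterion thresholds interpolate the count-level
curve linearly at the criterion (default 10,000 spikes for 1000 fibres);
the level grid is a 1-dB coarse scan centred on the (degeneration-aware)
single-pulse threshold followed by a 0.25-dB fine grid, so interpolation
error is well below the dB differences of interest.

Two protocol choices deserve explanation:

* **Fixed criterion across population sizes.** When 500- and 1000-fibre
  populations are compared, the 10,000-spike criterion is held fixed:
  that is what makes the comparison informative (with a criterion
  proportional to n, the two populations are statistically identical and
  the comparison degenerates). The `criterion` argument remains
  explicit everywhere.
* **Model IPG offset is read horizontally.** On measured ECAPs the
  package's default offset is the vertical amplitude gap on a 0.1-dB
  level grid (the equal-input reading); the classic equal-output
  (horizontal, current-shift) reading is available as a mode. On
  *simulated* spike-count AGFs, however, the vertical gap equals the
  local log-count slope times the underlying current shift, and that
  slope scales as 1/SD of the threshold distribution — so the vertical
  reading cannot be invariant to the population's threshold spread. The
  model protocol (`model_ipg_offset()`) therefore defaults to the
  horizontal reading, which is the invariant one (measured: vertical
  offsets of 15.4 vs 6.6 dB at SDs of 1 vs 3 dB; horizontal offsets
  1.09 vs 1.05 dB).

## The IPG-offset algorithm on measured AGFs

`trim_to_linear_region()` automates what was historically a manual
step, with three configurable constants: points within 1 dB of the noise
floor are excluded; trailing points whose local slope falls below 50 %
of the maximum local slope are excluded as saturation; then endpoints
are dropped (best endpoint first) until the linear fit of the survivors
reaches R² ≥ 0.95 or only two points remain. `ipg_offset()` evaluates
both trimmed curves by linear interpolation on a 0.1-dB grid over the
overlap of their included ranges (never extrapolating) and averages the
long-minus-short amplitude difference. Identity, constant-shift,
non-parallel-line and re-gridding behaviour are all pinned by exact
tests; electrodes whose curves do not overlap by at least 0.2 dB are
recorded as missing, mirroring unmeasurable electrodes in real studies.

## Psychophysics

The staircase is the clinical one-up/one-down procedure: start at the
configured "90 % of comfortable" level, step down after a heard trial
and up after a miss, 4 CL steps (≈ 0.63 dB) until two reversals, 2 CL
(≈ 0.31 dB) thereafter, stop at eight reversals, threshold = mean of
the last six reversal levels; two runs are averaged. A reversal is a
trial whose step direction differs from the previous step's; the
starting descent is not a reversal. Tracks pushed past a device limit
twice consecutively abort with a flag rather than fabricating reversals
(the source study does not state what its software did at the limits;
this is the package's rule). The loudness-scaling session and the 3-s
response window are not simulated — "comfortable" is just a
configuration ceiling, since timing is irrelevant to the threshold
logic. A golden test pins the full deterministic trial sequence, and a
1000-seed Monte-Carlo check shows < 1 CL bias against a symmetric-noise
listener's 50 % point (one-up/one-down converges to the 50 % point).

`model_listener()` closes the loop: a staircase run against the
population simulator, with detection declared when a fresh stochastic
presentation generates at least the criterion number of spikes. A
cross-module test checks that the staircase lands within 0.5 dB of the
rate-level criterion crossing.

## Statistics

`within_subject_correlation()` subtracts each subject's mean from both
measures and correlates the pooled centred values — mathematically the
ANCOVA with subject as a random factor, which a test verifies against a
general-linear-model oracle to 10⁻¹⁰. The p-value uses the pooled df
(N − n_subjects − 1); published reports sometimes print the
per-subject convention (n_subjects − 1), so both are returned
(`df`, `df_between`) rather than guessing which was intended. The
Fisher r-to-z interval across subjects defaults to the
`sd(z)/sqrt(n)` form; the fixed-variance `1/sqrt(m-3)` weighting is an
option, again because the source convention is ambiguous. Missing
electrodes and subjects without ECAPs are handled by pairwise deletion,
p-values are two-sided, and no multiplicity correction is applied.

## Synthetic studies

`generate_study()` emulates an 11-subject × 7-electrode study
(electrodes 3, 6, 9, …, 20), with three subjects lacking measurable
ECAPs and one of them lacking MPI, so missing-data paths are always
exercised. The parametric backend programs the truth directly: linear
log-log AGFs (slope 2 dB/dB, 3-CL level steps) with a programmed
vertical offset, soft floor/saturation clipping (1-dB softness) and
Gaussian amplitude noise (default 0.5 dB SD); behavioural thresholds
with programmed MPI and PE measured by real staircase runs against
cumulative-Gaussian listeners (2-CL spread). Non-neural structure —
per-subject shifts and per-electrode level offsets (SD 2 dB) — moves
both curves of each pair and both thresholds of each difference, so the
recovered metrics are unaffected; this differential-design property is
asserted to < 0.05 dB. In the `"coupled"` scenario one latent health
factor drives all three metrics (MPI up, PE down, IPG offset up); in
`"null"` the metrics are independent. The model backend instead drives
a small fibre population per electrode (survival fraction → share of
fibres with intact peripheral processes; demyelination factor →
retrograde k of the rest, capped at 2.5 to keep thresholds inside the
device range) and measures it end-to-end with model listeners.

What the generator does *not* emulate: raw ECAP waveforms and N1–P1
picking, forward-masking artefacts, impedance or electrode-position
telemetry, loudness growth, inner-hair-cell contributions. Passing
recovery tests therefore show that the *analysis pipeline* is unbiased
at realistic noise levels, not that real measurements are.

## Problem sizes

The shipped tests run the full acceptance conditions (1000 fibres,
10,000-spike criterion) for the three headline quantities, and 250–300
fibre populations (criterion scaled per fibre) for the directional
suite; those sizes give Monte-Carlo errors an order of magnitude below
the effects being asserted. `scripts/acceptance.R` recomputes the
headline quantities at the full 1000-fibre conditions from a
command-line seed.

## Known limitations

* The model is phenomenological: no channel biophysics, myelin
  geometry, three-dimensional current spread, or inner hair cells; the
  demyelination factor is a coarse stand-in for axonal pathology.
* Calibration anchors are directional and approximate; absolute
  thresholds (in µA) are arbitrary to within the sensitivity scale.
* Population MPI grows mildly with the number of fibres even at a
  per-fibre-scaled criterion, because the 1000-pps criterion crossing
  sits in the sensitive tail of the threshold distribution and larger
  samples populate that tail more densely.
* The ECAP stand-in equates compound amplitude with spiking-fibre
  count; latency, synchrony and unit-amplitude effects are ignored.
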