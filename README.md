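# cihealth

Simulation and analysis of three proposed estimates of spiral-ganglion
neural health in cochlear implant (CI) users:

* **MPI** — multipulse integration, the drop in behavioural detection
  threshold between 80 and 1000 pulses per second:
  `MPI = T(80 pps) − T(1000 pps)` in dB;
* **PE** — polarity effect, the threshold difference between cathodic-
  and anodic-centred quadraphasic pulse trains:
  `PE = T(cathodic-centred) − T(anodic-centred)` in dB (negative =
  cathodic advantage, the proposed signature of surviving peripheral
  processes);
* **IPG offset** — the mean dB difference between the overlapping linear
  portions of ECAP amplitude growth functions measured at interphase
  gaps of 8 and 40 µs, both axes logarithmic (dB re 1 µA in, dB re 1 µV
  out).

The package contains, as separately usable modules:

* charge-balanced stimulus construction (biphasic and quadraphasic pulse
  trains) and clinical current-level unit conversions
  (`I(CL) = 17.5 × 100^(CL/255)` µA, ≈ 0.157 dB per CL step);
* a population simulator of spiral ganglion fibres, each with a
  peripheral and a central exponential integrate-and-fire
  spike-initiation site

  `C dV/dt = −g (V − V_rest) + g ΔT exp((V − V_T − W)/ΔT) + I(t)`,

  with adaptation, partial polarity selectivity, per-pulse threshold
  noise, and degeneration manipulations (peripheral loss, retrograde or
  simultaneous demyelination), implemented in C++;
* the AGF linear-region trimming and IPG-offset algorithm (0.1-dB
  interpolation grid, vertical and horizontal readings);
* the adaptive one-up/one-down staircase (4→2 CL steps, 8 reversals,
  mean of the last 6) with model-driven and parametric virtual
  listeners;
* within-subject (mean-centred, random-subject ANCOVA) and
  between-subject correlation analyses with Fisher r-to-z confidence
  intervals;
* a synthetic-study generator (11 subjects × 7 electrodes, missing-ECAP
  subjects included) with parameter-recovery reporting.

## Worked example

Simulate a healthy 300-fibre population and a peripherally degenerated
one, and compute the three estimates:

```r
library(cihealth)

healthy <- sample_population(population_config(300, sd_threshold_db = 3,
                                               seed = 1))
degen <- sample_population(population_config(
  300, 3, degeneration = degeneration_spec("peripheral_disabled"),
  seed = 1))

model_mpi(healthy, criterion = 3000)   # [1] 3.99  (dB, 80 vs 1000 pps)
model_pe(healthy, criterion = 3000)    # [1] -1.93 (cathodic advantage)
model_pe(degen, criterion = 3000)      # [1] 2.54  (anodic advantage)
model_ipg_offset(healthy)              # [1] 1.04  (dB, IPG 8 -> 40 us)
```

The healthy population integrates ~4 dB between 80 and 1000 pps,
prefers cathodic-centred pulses by ~1.9 dB, and reaches equal ECAP
output at ~1.04 dB less current with the long interphase gap; removing
the peripheral processes flips the polarity preference to a ~2.5-dB
anodic advantage.

An end-to-end synthetic study with the correlation analysis:

```r
study <- generate_study(scenario = "coupled", master_seed = 7)
within_subject_correlation(study$measures, "mpi_db", "ipg_offset_db")
#> pooled-centred correlation: R(47) = 0.825, p = 3.002e-13  (n_subjects = 8)
parameter_recovery_report(study)
#>       metric  n     r bias_db rmse_db
#> 1        mpi 70 0.979   0.008   0.145
#> 2         pe 77 0.994   0.011   0.122
#> 3 ipg_offset 56 0.871  -0.045   0.286
```

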