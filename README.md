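# biosas

Automated analysis of biological small-angle X-ray scattering (BioSAXS)
data, packaged as an offline, reproducible R toolkit. It is aimed at
structural biologists and beamline scientists who need the full reduction
and first-pass analysis chain — from 2D detector frames to radius of
gyration, pair-distance distribution and molecular-mass invariants —
without a beamline attached: every stage can be exercised and validated on
synthetic data with known ground truth.

## What it computes

For a solution scattering curve `I(q)` (with `q = 4π sin(θ)/λ` in nm⁻¹):

* **Guinier analysis** — `ln I = ln I0 − (q Rg)²/3` on the low-q region,
  by three algorithms: an exhaustive window search honouring
  `qmax·Rg ≤ 1.3`, a consensus over all admissible windows, and
  Guinier-peak analysis (GPA) on the peak of `q·I(q)` at
  `qRg = √(3/2)` — the fast path for chromatography.
* **BIFT** — Bayesian indirect Fourier transform: `p(r)` with
  non-negativity and zero endpoints, a squared-second-difference
  smoothness prior, and evidence-based selection of `Dmax` and the
  regularization weight α; reports real-space `Rg` and `I0`.
* **CorMap** — exact frame-equivalence test from the longest run `C` of
  same-sign differences between two curves, with the exact fair-coin null
  distribution `P(longest run ≥ C)` (no asymptotics, valid at any n).
* **Invariants** — dimensionless Kratky plot `(qRg)²I/I0`, Porod invariant
  and volume `V_p = 2π²I0/Q_p`, volume of correlation `V_c = I0/∫qI dq`,
  `Q_R = V_c²/Rg` and the Rambo–Tainer mass estimate.
* **Reduction** — azimuthal integration, beam-stop-diode-weighted frame
  averaging (ratio of sums, with exact 1D/2D commutation), 2D subtraction,
  Poisson uncertainty propagation.
* **Pipelines** — multi-frame integration with radiation-damage screening,
  sample-changer subtract-and-analyse, and SEC-SAXS (chromatogram
  assembly, SVD rank selection, NMF, CorMap-ranked buffer extraction, CWT
  peak picking, per-fraction analysis), all replayable from JSON job
  descriptions into single-file HDF5 result bundles.

## Worked example

```r
library(biosas)

# a 3 nm sphere (Rg = 2.324 nm, Dmax = 6 nm) on buffer-free background,
# with Poisson counting noise at exposure 1e5
q <- seq(0.05, 5, length.out = 1000)
curve <- sas_curve(q, sphere_intensity(q, R = 3, I0 = 100)) |>
  add_noise(exposure = 1e5, seed = 42)

fit <- auto_guinier(curve)
fit
#> <guinier:auto> Rg = 2.365 +/- 0.00026 nm, I0 = 100.2 +/- 0.0053; window [1, 102), qRg in [0.118, 1.290], quality 0.99

pd <- bift_auto(dplyr::slice(curve, seq(1, 1000, by = 5)))
pd
#> <pddf> Dmax = 5.903 nm, alpha = 732, Rg = 2.324 nm, I0 = 100, chi2_red = 0.923, logE = -190.6 (ok)

sas_invariants(curve, fit)
#> <invariants> V_p = 112.3 nm^3, Q_p = 17.62, V_c = 4.045 nm^2, Q_R = 6.918 nm^3, mass ~ 56.2 kDa (rambo-tainer:protein:2013.1)
```

Reading the numbers: the Guinier fit lands within 1.8% of the true
Rg = 2.324 nm (the small bias is the sphere's deviation from the Guinier
law inside `qRg ≤ 1.3`, not noise); BIFT recovers the maximum diameter
within 2% of the true 6 nm and the real-space Rg essentially exactly; the
Porod volume 112.3 nm³ sits within 1% of the true sphere volume
113.1 nm³. `tidy()`/`glance()` turn any fitted object into a tibble, and
`autoplot()`/`plot_sas_report()` draw the standard four-panel figure
(curve + IFT fit, Guinier diagnostic, dimensionless Kratky, p(r)).

A SEC-SAXS run goes through the same machinery end to end:

```r
res <- run_hplc(list(schema_version = "1", pipeline = "hplc",
                     inputs = list(sec = list(kind = "default_sim", seed = 7)),
                     params = list(do_bift = FALSE)))
dplyr::bind_rows(lapply(res$fractions, glance))
```

which detects two elution fractions at the simulated peak centres and
recovers each component's Rg within 5%.

A thin command-line wrapper is included (`exec/biosas`):
`biosas simulate curve`, `biosas guinier`, `biosas bift`, `biosas cormap`,
`biosas run job.json`, `biosas extract-ascii out.h5 -o dir`, `biosas plot`.

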