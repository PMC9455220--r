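---
title: "Methods: automated BioSAXS reduction and analysis in biosas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated BioSAXS reduction and analysis in biosas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biosas)
```

# Scope and data model

`biosas` re-implements, as an offline and fully testable toolkit, the
analysis chain used for automated biological small-angle X-ray scattering
(BioSAXS): reduction of 2D detector frames into 1D curves, radiation-damage
screening, Guinier and indirect-Fourier analysis, size/mass invariants, and
the two experiment-level pipelines (sample changer and inline size-exclusion
chromatography, SEC-SAXS). Every quantity the pipelines report can be checked
against synthetic data with known ground truth, generated inside the package.

The central container is the scattering curve: a tibble with columns `q`
(scattering-vector magnitude `q = 4π sin(θ)/λ`, in inverse nanometres,
strictly increasing), `I` (intensity) and `sigma` (1-σ uncertainty).
Inverse nanometres are used internally everywhere; readers accept a declared
`angstrom^-1` unit and convert on load, because a silent factor of 10 between
conventions is the classic SAXS accident. Detector data are held as a
`frame_stack` (counts per frame, per-frame beam-stop diode reading, and a
flat-detector geometry with `q = (4π/λ) sin(atan(r/D)/2)` per pixel).

# Frame reduction and the averaging identity

Counting statistics drive every choice in the reduction module. Frames are
averaged pixel-wise as a **ratio of sums** weighted by the diode reading
`d_k`: `values = Σ F_k / Σ d_k`, with Poisson variance `Σ F_k / (Σ d_k)²`.
Averaging normalized per-frame curves instead is *not* equivalent: the
monitor-weighted 1D mean `Σ d_k I_k / Σ d_k` reproduces the
average-then-integrate route to machine precision (the package asserts
< 1e-10 relative), while the plain mean of normalized curves deviates by
more than 1e-3 as soon as monitors differ appreciably — both facts are
verified numerically in the test suite, with monitors (1, 10) for the
counter-example. The SEC pipeline averages 1D curves with inverse-variance
weights (uncertainties from azimuthal integration); the monitor-weighted
variant is available as the exact 2D-equivalent option.

Azimuthal integration uses equal-width q bins up to the detector corner,
200 bins by default; the bin statistic is the arithmetic mean of unmasked
pixel values with `σ = sqrt(Σ var)/N`. Empty bins are dropped rather than
NaN-filled so that downstream grids always satisfy the CorMap test's
exact-grid requirement. A one-count variance floor is applied to bins whose
propagated variance is exactly zero, avoiding σ = 0 artifacts on
zero-count data. The synthetic geometry is ideal (no polarization,
solid-angle or flat-field corrections); those belong to a production
integrator and are out of scope here.

# CorMap: exact longest-run equivalence testing

Two curves on the same q grid are compared by the sign pattern of their
channel-wise differences: under the null hypothesis of statistically
identical curves, each sign is a fair coin, and the observed longest run
`C` of equal signs has a known exact distribution. `prob_longest_run_ge(n, c)`
computes `P(longest run ≥ c)` by an absorbing-state dynamic programme over
the current run length — O(n·c), additions of positive terms only. For
n ≤ 50 the recursion is run in integer sequence counts, so every value is
the exact dyadic rational (the tests verify bit-exact agreement with
brute-force enumeration of all 2^n sequences up to n = 20); beyond that it
runs in probability space without overflow at any practical n, and the
log-probability is reported for values past double underflow (a fully
scaled curve pair at n = 1000 has p = 2^-999).

Channels where the two curves are *exactly* equal are dropped before the
test — a zero-probability event for continuous data, but integer-valued
synthetic counts need a deterministic rule. Frame series are screened with
two thresholds (adjacent pairs 0.01, against the first frame 0.001; both
configurable — production values are not published). Acceptance is a
contiguous prefix in time because radiation damage accumulates: once one
frame fails, it and everything after it is discarded.

# Guinier analysis

At low q, `ln I = ln I0 − (q Rg)²/3`. All fits are weighted least squares
of `ln I` on `q²` with delta-method weights `(I/σ)²`; non-positive
intensities are excluded, and a non-negative slope returns a flagged
(aggregated) result rather than NaN. Three estimators are provided:

* **`auto_guinier`** scans every window of ≥ 10 points whose
  self-consistent fit satisfies `qmax·Rg ≤ 1.3` (the classic validity
  bound) and `qmin·Rg < 1` (a guard against beam-stop-shadow points; the
  bound below is not published, so it is a documented choice). Prefix sums
  make each window fit O(1), so the scan is exhaustive. The winner
  maximizes `0.6·R² + 0.3·(length fraction) + 0.1·(1 − qmin·Rg)` — the
  weights are fixed, documented, and deliberately favour fit quality over
  window length.
* **`auto_rg_consensus`** fits all admissible windows and returns the
  inverse-variance-weighted mean of the largest *mutually consistent*
  cluster — the biggest set of window estimates within ±2% of one central
  value — plus the union of those windows. A mode-seeking ball is used
  instead of single-linkage clustering: a decaying low-q contamination
  (aggregation upturn) produces a smooth continuum of biased estimates
  with no 2% gap anywhere, and single linkage would chain straight
  through it into the clean cluster. The ball cannot be chained into.
* **`auto_gpa`** (Guinier-peak analysis) fits `q·I0·exp(−q²Rg²/3)` to
  `q·I` around the empirical peak of `q I(q)`, which for Guinier-law data
  sits exactly at `qRg = sqrt(3/2)`. After an initial fit on the
  half-height window, the window's upper edge is pulled in to
  `qRg ≤ 1.5` and the fit repeated: the raw half-height window of a
  globular particle extends to `qRg ≈ 2.4`, well past the Guinier regime,
  and biases Rg by ~5% on a sphere; the capped refit brings the median
  error to ~2.5%. GPA is the fast path used per-fraction in
  chromatography mode, with the window search as fallback.

On noiseless Guinier-form data all three return the generating Rg to 1e-6
relative. On the reference noisy sphere (R = 3 nm, so Rg = 2.324 nm,
exposure 1e5, 1000-point grid) the window search achieves ~1.8% median
error — mostly the systematic truncation bias of fitting a sphere up to
`qRg = 1.3`, not noise.

# BIFT: Bayesian indirect Fourier transform

The pair-distance distribution `p(r)` solves `I(q) = 4π ∫ p(r) sinc(qr) dr`.
The design matrix discretizes this with the trapezoid rule on a uniform r
grid (100 points by default); `p ≥ 0` with exact zeros at `r = 0` and
`r = Dmax` are enforced by construction. At fixed hyperparameters
`(Dmax, α)` the solution minimizes
`½ Σ[(I − Tp)/σ]² + α Σ (p_{j+1} − 2p_j + p_{j−1})²` — a squared
second-difference smoothness prior, the standard BIFT choice — via
non-negative least squares on the augmented system
(`pracma::lsqnonneg`). The hyperparameter evidence is a Laplace
approximation around the optimum with the Hessian restricted to the active
(p > 0) coordinates; `χ²` is reported as `χ²/(N−1)` because the effective
dof of a constrained smooth solution is ill-defined.

The automatic search is two-level: a coarse grid over Dmax (12 points
spanning 2.0–4.5 × the Guinier Rg) crossed with a 13-point α log-grid over
six decades, then Nelder–Mead refinement of `(Dmax, log10 α)` on the
evidence. The coarse stage and the refinement run on a 50-point r grid;
only the final solution is recomputed at 100 points — a pure-R NNLS solver
makes denser grids (and the much denser α grids one might use with a
compiled solver) needlessly slow without changing the optimum. Both the
maximum-evidence point and the evidence-weighted grid means are reported;
the maximum is used, for determinism.

One empirical property matters for Dmax: past the true diameter the
evidence is *flat*, because the non-negativity constraint simply assigns
zero mass to the extra r range — the Occam penalty vanishes along with the
active coordinates. The reported Dmax is therefore the support of the
maximum-evidence solution (where p exceeds 0.5% of its peak), with p
re-solved on `[0, Dmax]`. On the reference noisy sphere this lands within
3% of the true diameter 6 nm, the real-space Rg within a fraction of a
percent of `sqrt(3/5)·R`, and the recovered p(r) correlates > 0.999 with
the analytic sphere distribution at fixed true Dmax. Real-space and
Guinier Rg agree within 5% — the pipeline's own internal consistency
check.

# Invariants

The dimensionless Kratky representation `(qRg)² I/I0` vs `qRg` peaks at
`(sqrt(3), 3/e)` for globular (Guinier-like) particles and plateaus at 2
for ideal Gaussian chains; both limits are asserted analytically. The
Porod invariant `Q_p = ∫ q² I dq` is assembled from a closed-form Guinier
extrapolation on `[0, qmin]`, trapezoid quadrature over the data, and a
`K/q⁴` tail on `[qmax, ∞)`. The Porod constant K is the mean of `I q⁴`
over the last decade of q, weighted uniformly in `log q`: equal weight per
resolution interval damps the form-factor oscillations that dominate a
linear-q average, keeping the sphere volume `V_p = 2π² I0/Q_p` within 2%
of `(4/3)πR³` on dense data and within 5% even when the curve is truncated
at `qR = 4` (without the tail term the same truncation biases V_p high by
~28%). The volume of correlation `V_c = I0/∫ q I dq` is integrated to
`q_cut = 8/Rg` (capped at the data); `Q_R = V_c²/Rg` feeds the empirical
mass estimate `(Q_R/c)^k` with protein/RNA constants kept in a versioned
table (angstrom-based, converted at call time) so their provenance travels
with every result. All ratios of I-linear functionals are
intensity-scale-invariant, which the tests assert directly.

# SEC-SAXS pipeline

A run is a frames × q matrix assembled by frame id, so lost acquisition
files leave masked rows rather than shortening the chromatogram; masked
rows are excluded from every decomposition. The number of signal
components is taken from the SVD of the unmasked rows with the optimal
hard threshold `ω(β)·median(σ_i)` (aspect ratio β ≤ 1, cubic
approximation of ω): on the reference two-component run this returns 3 —
buffer plus two species. NMF (Frobenius objective, Lee–Seung
multiplicative updates) provides non-negative elution profiles and
spectra; because NMF is neither fast nor unique, determinism is imposed by
an NNDSVDa initialization (SVD-based, zeros filled with the matrix mean)
and a fixed iteration cap, making repeated runs bit-identical. On
buffer-dominated chromatograms the rank-3 factorization is only determined
*up to buffer admixture* in the component rows — an intrinsic
non-uniqueness, since moving flat background between rows changes nothing
in the reconstruction. This is exactly why the pipeline does not trust the
factor spectra for quantitative work: buffer is instead identified
per-frame by CorMap against the least-squares-scaled first singular
vector, frames are ranked from most to least buffer-like (p descending,
ties by smaller C, then frame id), and the top 30% are averaged with 1D
uncertainty propagation.

Fractions are found on the buffer-subtracted total-scattering trace:
median filter (window 5), then a Ricker-wavelet CWT over widths 5–50
frames with ridge-line linking; a ridge must persist over at least half
the width grid and reach SNR ≥ 5 (noise = median absolute CWT response at
the smallest width). Each surviving peak is expanded to where the smoothed
trace falls to 10% of peak height, and overlapping regions split at the
minimum between peaks. Pure-noise traces yield no fractions in the large
majority of seeds; isolated and 6σ-separated Gaussian peaks are found at
their true centres. Per fraction, the subtracted curves are
inverse-variance averaged and run through GPA-first Guinier, Kratky,
invariants and BIFT; a Guinier fit whose `σ_Rg ≥ 0.3·Rg` is treated as a
failure (a pure-buffer fraction must degrade to a flagged partial result,
not a number).

# What the synthetic data do and do not show

The generator produces sphere and Gaussian-chain form factors with known
`Rg`, `I0`, `Dmax`, flat buffer background, Poisson counting noise at a
configurable exposure, small detector images on an ideal geometry, and
full SEC runs (elution profiles × spectra + buffer, files of 100 frames,
optional missing blocks). Every stochastic output is fully determined by
an integer seed.

The reference conditions are: a sphere of R = 3 nm (Rg = 2.324 nm,
Dmax = 6 nm), I0 = 100 on buffer 50, exposure 1e5 on a 1000-point grid to
5 nm⁻¹ for the 1D analyses (the Guinier region then spans > 100 points);
and for SEC, 1000 frames in ten files with two spheres (R = 4 and 2.5 nm,
I0 = 100 and 80) eluting as Gaussians at frames 350 and 650 with an
8-frame width over buffer 50 at exposure 20. The SEC exposure and peak
width were chosen together for realism of the *discrimination problem*:
roughly 1e3 counts per channel per frame (1–3% noise), so that the CorMap
buffer ranking operates in its working regime — saturated, noise-free
frames make every frame "significantly" different from any reference and
reduce the ranking to floating-point coincidences, while frames carrying
more than ~10% of a component's peak concentration must remain
statistically distinguishable from buffer. Problem sizes throughout the
tests (curve lengths 100–1000 points, 64–256 px detectors, 100–200 seed
replicates) are chosen so the full suite and the acceptance script each
run in minutes on one core.

What passing these tests does *not* show: robustness to structured
backgrounds (capillary fouling, buffer mismatch), detector artifacts
(gaps, flat-field error, parallax), interparticle interference at high
concentration, or q-dependent systematic errors — the generator contains
none of these by design. Cross-implementation equality with the reference
beamline binaries is explicitly not asserted either; the three Guinier
algorithms are known not to agree bit-for-bit even among the published
implementations they mirror.

# Result containers and replay

All pipeline results go into a single HDF5 file: one NeXus-flavoured group
per stage (`entry/<k>_<stage>`), each holding a JSON copy of the exact
configuration that produced it, its outputs, and — for failed stages — the
error message; a `default_plot` entry names what a viewer should display,
and provenance (input paths, the full job JSON) is stored at the root.
The layout is validated against this package's own documentation, not the
full NeXus standard. External links to raw data are replaced by stored
path strings so result files stay portable. Jobs are plain JSON
(`schema_version` 1) and replay bit-reproducibly: every random draw is
seeded from the job itself. Stage failures degrade the job to a partial
result with later stages marked skipped, never to a crash.

# Known limitations

* The BIFT evidence is a Laplace approximation on the active set; for
  data with very few information channels the Dmax support heuristic can
  under-report by a few percent (it clips where p falls below 0.5% of its
  peak).
* The CorMap p-value is discrete; near thresholds, acceptance decisions
  on very short curves (n below a few tens of channels) are coarse.
* The NMF spectra of buffer-dominated runs carry buffer admixture (see
  above); they are descriptive, and the quantitative chain runs on
  CorMap-selected buffer and subtracted curves instead.
* The Rambo–Tainer mass calibration constants apply to real
  macromolecules; applied to ideal spheres they give order-of-magnitude
  context only, and the tests assert scale-invariance and monotonicity,
  not absolute mass.
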