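---
title: "Spot delivery errors and IMPT plan robustness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spot delivery errors and IMPT plan robustness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In pencil-beam scanning (PBS) proton therapy, a plan is a list of spots —
lateral positions (steered magnetically) and monitor units (MU) per spot at
each beam energy. The delivery system records what it actually delivered,
pulse by pulse, in machine log files. Delivered spot positions differ from
planned ones by small errors (typically well under a millimetre to about a
millimetre), and conventional robustness evaluation — which perturbs patient
setup and stopping-power calibration — ignores them entirely.

`spotrobust` implements a complete, synthetic-data-driven version of the
workflow that closes this gap:

1. generate (or parse) pulse-level log files and aggregate pulses into
   delivered spots;
2. quantify agreement between detector-measured and log-recorded spot
   positions (QA);
3. train a small feedforward network mapping planning parameters to
   delivered spot position and MU;
4. inject the predicted delivered spots back into the plan as a *pseudo log
   file* (PLF);
5. recompute dose and evaluate robustness over a scenario set, reporting
   banded DVHs, worst-case DVH indices and a 95/95 coverage verdict.

Everything runs on synthetic phantoms and plans, so every stage is testable
without clinical data.

## Pulse aggregation and the log-file dialect

The machine delivers each spot as a sequence of pulses. Per pulse the log
records target and actual position at isocenter (x = crossplane,
y = inplane, mm) and target and actual MU. A delivered spot is the
MU-weighted aggregate of its pulses:

$$x_{\mathrm{del}} = \frac{\sum_i x_i\, \mathrm{MU}_i}{\sum_i \mathrm{MU}_i},
\qquad \mathrm{MU}_{\mathrm{del}} = \sum_i \mathrm{MU}_i,$$

using *actual* (not target) pulse MUs as weights, since the quantity of
interest is where the delivered fluence went. A spot whose pulses carry
zero total MU has an undefined position; such spots are flagged and
excluded from model training but retained in QA bookkeeping.

Proprietary vendor logs have hundreds of columns; only nine fields feed
this workflow, so the package defines a minimal documented dialect
(`spotrobust-log-v1`): UTF-8 CSV, `# key=value` header lines, nine body
columns, numerics at 17 significant digits so write→parse is bit-exact.
The PLF uses the same dialect with one pulse per spot (actual = predicted,
target = planned), which makes parse(write(x)) the identity on
predictions — a property the tests assert bit-for-bit.

## The synthetic delivery-error model

`error_truth()` holds the generator's ground truth: per-axis systematic
offsets (constants or functions of gantry angle and energy), Gaussian
per-spot random scatter (`random_sigma_*_mm`), multiplicative MU noise,
and per-pulse jitter. Defaults (0.3 mm random sigma, 1% MU noise, 0.2 mm
pulse jitter, zero systematics) sit at the scale of published QA
disagreements, where position errors are Gaussian with means of order
1 mm or less.

Two choices make the generator exactly analysable:

* the planned MU is split uniformly across pulses and the spot-level
  multiplicative MU noise is distributed proportionally, so MU
  conservation holds to accumulation tolerance;
* per-pulse jitter is *recentred* within each spot (its MU-weighted mean
  is subtracted), so aggregation reproduces the drawn delivered position
  exactly rather than only in expectation. Tests exploit this to assert
  exact recovery of injected systematics.

Whether delivery errors correlate between spots of one layer is not
established; the generator exposes an optional shared per-layer offset
(`layer_shift_sigma_mm`) but defaults to independence.

QA sessions emulate an 11 × 11 spot grid measured by a scintillation
detector with 0.5 mm spatial resolution: the "recorded" position is drawn
from the truth, the "measured" position adds detector noise (default
0.15 mm SD, well under typical recorded-vs-measured deltas) and quantizes
to the resolution. Agreement statistics use the field's conventions:
per-axis mean delta, sample SD (n − 1; reported and labelled as such,
since QA tables rarely state which convention the ± values use),
per-axis RMS and the quadrature-combined RMS
$\sqrt{RMS_x^2 + RMS_y^2}$. The Gaussianity summary reports moments and a
Jarque–Bera omnibus p-value; it is descriptive only.

## The error model

The planned→delivered mapping is a shallow feedforward network:
6 inputs (target x, target y, target MU, gantry angle, snout extension,
nominal energy) → 5 tanh hidden neurons → 3 linear outputs (delivered x,
delivered y, delivered MU); 53 parameters. Features and targets are
standardized per column over the training split. The data are split
70/15/15 into train/validation/test; training minimizes the full
least-squares objective with Levenberg–Marquardt (the natural optimizer
for a network this small — the normal equations are 53 × 53), with early
stopping on validation loss (patience 20 accepted steps) and metrics
computed on the held-out test split only. A BFGS quasi-Newton fallback on
the same objective is provided and passes the same recovery properties.

R² is reported on both raw and standardized targets: raw-scale R² is
inflated by the large dynamic range of spot coordinates (predicting
"delivered ≈ planned" already explains most raw variance), so the
standardized value is the honest fit measure. Both are exposed in
`glance()`.

The model is serialized to JSON with weights at 17 significant digits;
a reloaded model yields bit-identical predictions.

## The analytic dose engine

The engine stands in for a treatment planning system's Monte Carlo dose
calculation. Only *relative* dosimetry matters for the robustness
conclusions, so per spot:

$$D(\mathbf{v}) = \mathrm{MU}\cdot \mathrm{DD}(d_{\mathrm{rad}})\cdot
\frac{1}{2\pi\sigma^2(E, d_{\mathrm{rad}})}
\exp\!\left(-\frac{r^2}{2\sigma^2(E, d_{\mathrm{rad}})}\right),$$

with radiological depth $d_{\mathrm{rad}}$ accumulated along a single
central ray per spot (phantoms are piecewise-uniform; lateral
heterogeneity scatter is out of scope), lateral distance $r$ in the
beam's-eye-view plane, and a parallel-ray beam geometry rotated in the
axial plane by the gantry angle. Snout extension is a model feature only;
no snout-dependent optics is modelled, since no such model is published
for this workflow.

Parameter choices, with defaults and rationale:

* **Range-energy law** $R(E) = \alpha E^p$, $\alpha = 0.0022$,
  $p = 1.77$ (cm, MeV): the standard clinical parameterization, accurate
  to a few percent over 70–230 MeV.
* **In-air spot size** anchored at $\sigma \approx 10$ mm at 150 MeV at
  isocenter (characteristic of compact single-room systems), scaling as
  $(150/E)^{0.9}$; spots grow substantially at low energy.
* **Depth broadening** $\sigma^2(E,d) = \sigma_{\mathrm{air}}^2(E) +
  (kd)^2$ with $k = 0.03$, giving ~3 mm extra sigma at 100 mm depth
  (multiple-Coulomb-scattering scale).
* **Depth-dose shape**: entrance plateau (sigmoid shut-off at $R$) plus a
  Gaussian Bragg peak at $R$ with peak-to-plateau ratio 3. The proximal
  peak sigma is $0.025R + 1$ mm — range straggling *plus* delivered
  energy spread; a pure-straggling width (~1.2% of R) would make any
  spread-out Bragg peak built from clinical 5 mm layer spacings
  unrealistically rippled. The distal edge is sharper
  (0.35 × the proximal sigma).
* **RBE**: a constant 1.1 folded into the MU calibration constant; doses
  are cGy(RBE) throughout.
* **Aperture**: a spot is kept iff its centroid is inside or exactly on
  the polygon (boundary-inclusive, implemented with an explicit on-edge
  test). Deleted spots deposit no dose — matching TPS behaviour — and are
  reported with their MU, because in reality a spot just beyond the
  aperture edge still contributes dose; modelling that residual dose is
  out of scope.

The engine is linear in MU and superposes spots exactly; shift
equivariance on uniform phantoms, the $e^{-1/2}$ lateral ratio at one
sigma, monotonicity of peak depth in energy and the $1/(1+f)$ density
scaling of the peak depth are asserted in tests.

## Plan generation

`generate_plan()` emulates an *optimized* plan, not a raw spot list:
energy layers cover the target's radiological depth extent plus a margin,
and two weighting steps flatten the dose the way an optimizer would —
recursive distal-to-proximal layer weighting (the distal point only
receives its own peak; proximal layers sit on the plateaus of deeper
ones) and a ridge-regularized lateral solve that produces the
edge-enhanced "horn" weights required for a level profile when the
kernel is much wider than the spot pitch. A uniform random modulation
(`mu_range`) is applied on top. Without these steps the spread-out Bragg
peak slopes by tens of percent and no margin would make a plan robust;
with them, margins behave as in clinical practice. For large
training-corpus plans where only spot geometry matters,
`optimize_weights = FALSE` skips the (O(n³) per layer) lateral solve.

Apertures are the convex beam's-eye-view outline of the target dilated by
a uniform margin (mitre offset), either one static polygon per beam or
one per energy layer; spots are placed on a lattice inside the aperture,
so every planned centroid passes the aperture test by construction. If
the lattice pitch exceeds the target extent a single centre spot is still
emitted per layer.

Normalization scales all spot MUs by one global factor so that D99% of
the target equals the prescription; dose is linear in that factor, so the
factor is computed in closed form and cross-checked against a bisection
oracle in tests.

## Robustness evaluation

The scenario set interprets "isotropic ± shifts on three axes crossed
with ±density" as the 8 corner sign combinations × 2 density scales = 16
perturbed scenarios (the published count); an axis-aligned mode (6 × 2 =
12) is exposed because the corner interpretation is a reading, not a
certainty, and comparisons against clinical tables should not assume it.
Shifts displace the beam isocenters with the patient fixed — equivalent
to rigid setup error — and density scales multiply every voxel's relative
stopping power. The predicted-spot plan reuses the clinical plan's frozen
normalization factor (no re-normalization): published nominal
predicted-plan D99 values differ from the prescription, implying exactly
that convention.

DVHs are cumulative, 1 cGy(RBE) bins by default, on a dose axis shared
across scenarios per structure. D-type indices (D99%, D0.03cc, dose to a
fixed volume) interpolate the sorted voxel-dose profile at fractional
voxel counts; V-type indices count voxels directly. A D_cc index whose
volume spans fewer than 3 voxels is flagged resolution-limited rather
than silently reported. Banded DVHs are pointwise min/max envelopes over
the perturbed scenarios, with nominal curves carried alongside (they are
not part of the perturbed set and may in principle leave the band).
Worst-case tables take extrema independently per structure-index pair —
the coldest scenario for one organ need not be the coldest for another —
and the 95/95 verdict passes iff every scenario keeps at least 95% of the
target volume at or above 95% of prescription (inclusive threshold).

## What the synthetic data does and does not show

The generator reproduces the *mechanics* of the workflow — pulse
structure, Gaussian error laws, QA quantization, aperture trimming,
scenario evaluation — under known ground truth, which is what makes exact
and statistical oracle tests possible. It does not reproduce clinical
anatomy, heterogeneous tissue, Monte Carlo transport, the vendor log
dialect, or correlated day-to-day machine drift. Published clinical
numbers that depend on those inputs (absolute DVH values of patient
plans, the model's fit metrics on a multi-patient log corpus, "one spot
deleted") are therefore *not* reproduction targets; the package instead
asserts the conventions those numbers are printed in (quadrature RMS,
percent-of-prescription, signed plan differences, the 16-scenario count)
and property-based substitutes: parameter recovery of injected error
structure at 5 × 10⁴ spots, brute-force oracle equivalence of
aggregation/DVH/index code, dose-engine analytics, and a discriminating
plan pair — a margin-generous plan that passes 95/95 in all 16 scenarios
even with model-predicted spots, against a zero-margin plan with a sharp
distal gradient that fails.

Problem sizes in tests and the acceptance workflow are chosen at desk
scale: phantoms of 28³–40³ voxels at 2.5 mm, plans of a few hundred to a
few thousand spots, training corpora around 5 × 10⁴ spots. These are the
smallest sizes at which the statistical tolerances above are meaningful.

## Numerical choices and degenerate inputs

* Seeds: every stochastic operation takes a seed; the pipeline derives
  per-stage substreams from one global seed, and reruns are
  byte-reproducible (manifests record input hashes and seeds).
* Full-precision text: log files, PLFs, plan JSON and model JSON write
  numerics with 17 significant digits; round-trips are bit-exact.
* Ties and boundaries: aperture inclusion is boundary-inclusive; the
  95/95 threshold is inclusive; D-index interpolation clamps to the
  hottest voxel below one voxel of cumulative volume.
* Degenerate inputs: an all-zero error truth reproduces the plan exactly;
  a zero-shift/zero-density config yields a single nominal-equivalent
  scenario; zero-MU spots are excluded from training; empty structure
  masks and polygons with fewer than three vertices are errors.

## Known limitations

The dose engine is analytic and parallel-beam: no nuclear halo, no
aperture edge scatter, no divergence, single-ray radiological depth. The
error model is a single global network (gantry and energy are features),
matching the workflow it implements, so strongly gantry-dependent error
regimes would need either the functional systematic terms of
`error_truth()` or a richer model. Robust *optimization* is out of
scope; only evaluation is implemented. Pulse timing and beam-current
dynamics are not modelled.
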