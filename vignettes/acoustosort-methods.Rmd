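---
title: "Models and methods behind acoustosort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind acoustosort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acoustosort)
```

acoustosort is a desk-scale digital twin of an image-activated
acoustofluidic cell sorter: a real-time deformability cytometry (RT-DC)
analysis stage feeding a focused travelling surface-acoustic-wave (TSAW)
actuator. Cells flow single-file through a narrow deformation channel, are
imaged and morphometrically characterised per frame, and — when their
features fall inside a user-defined gate — are pushed laterally by a
millisecond acoustic pulse into a target outlet. The package simulates
every stage of that loop so the arithmetic that governs such a device
(throughput limits, coincidence statistics, purity/enrichment/recovery
book-keeping) and the image pipeline that feeds it can be tested without
hardware.

This vignette records the models implemented, the parameters that matter,
the numerical choices made where the design was genuinely open, and what
the synthetic data do and do not emulate.

## The morphometric feature pipeline

The real-time analysis stage reduces each grayscale frame to per-cell
features:

1. **Background**: per-pixel temporal median over the stack
   (`estimate_background()`). The median tolerates occasional frames that
   contain a cell; a single frame cannot define a background and is
   rejected with instructions to supply one explicitly.
2. **Contour**: the absolute background-subtracted image is contoured at a
   fixed threshold (default 10 gray values) by marching squares with
   linear interpolation (`grDevices::contourLines()`), giving sub-pixel
   boundary polygons. Components enclosing less than `min_area_px`
   (default 10 px²) are discarded. Pixel-edge boundary tracing was
   rejected because the staircase perimeter biases deformation upward by
   several 0.01 — more than the whole dynamic range of interest for
   near-spherical cells.
3. **Edge refinement**: the detection threshold necessarily sits low on
   the intensity edge ramp, so the threshold iso-contour lies outside the
   true boundary. Each component is re-contoured at half its peak contrast
   — the level where a linear edge ramp crosses the geometric boundary —
   which removes an otherwise systematic ~5–10% area overestimate. Faint
   objects whose half-contrast level would fall below the detection
   threshold keep the detection contour.
4. **Features**: projected area $A$ (µm², via the pixel pitch squared),
   perimeter $l$, deformation $D = 1 - 2\sqrt{\pi A}/l$ (one minus
   circularity; 0 for a circle), area ratio (convex-hull area over raw
   contour area, a data-quality measure ≥ 1), and brightness (mean
   original gray value strictly inside the raw contour).

Two conventions needed fixing where practice varies:

- **Hull-based gating features.** Gating area and deformation are computed
  on the convex hull of the contour, while the area ratio compares hull to
  raw contour. Published gating tables bound the area ratio at 1.05–1.08
  precisely to cap hull-vs-raw discrepancy, which implies the gated
  features are hull-based; both sets are stored in the event table.
- **Brightness uses raw intensities**, not background-subtracted ones.
  Either reading is defensible; raw was chosen and is flagged here. With a
  flat background the two differ by a constant, so gates translate.

Deformation can come out marginally negative when the perimeter of a
near-perfect circle is slightly underestimated; the raw value is kept in
`deformation_unclamped` and clamped at 0 in the reported `deformation`.

A cell seen in several consecutive frames is deduplicated by centroid
tracking (expected per-frame advance along the flow ± a tolerance),
keeping the detection nearest the centre of the measurement region —
mirroring the one-frame-per-cell behaviour of a real-time system.

Smoothing before contouring (Gaussian, σ = 0.7 px) suppresses
noise-induced contour jaggedness. σ was fixed once at a value small
relative to any resolvable cell radius; it trades a negligible rounding of
true corners for perimeter stability under realistic camera noise.

## Acoustofluidic physics

All physics operations take SI inputs; the configuration layer converts
unit-annotated strings (`"0.08 ul/s"`, `"135 MHz"`) on load, because mixed
µm/µl/ms/MHz bookkeeping is the main implementation risk in this domain.

- **Transducer resonance**: $f = v/\lambda$ with $v$ the substrate SAW
  velocity (default 3978 m s⁻¹, lithium niobate) and $\lambda$ the finger
  periodicity. Fabricated devices resonate a few percent below the design
  quotient (e.g. a measured 135 MHz for a 28 µm periodicity whose design
  value is 142 MHz); the function returns the design formula and measured
  values are configured as field-frequency overrides.
- **Regime classification**: $\kappa = 2\pi d_p f / C_f$ compares particle
  circumference to the acoustic wavelength in the fluid. Above the
  threshold, anisotropic scattering makes the acoustic radiation force
  (ARF) dominant; below it, acoustic streaming drag (ASF) dominates. The
  default threshold is the empirically suggested 1.28 (at 135 MHz in a
  1487 m s⁻¹ medium this is a 2.25 µm diameter); the theoretical value 1
  is selectable. The boundary itself classifies as ASF (strict
  inequality).
- **Standing-wave force**:
  $F = -\frac{\pi P_0^2 V_p \beta_f}{2\lambda}\,\phi\,\sin(2kx)$, with
  contrast factor
  $\phi = \frac{5\rho_p - 2\rho_f}{2\rho_p + \rho_f} - \beta_p/\beta_f$
  (positive ϕ migrates to the pressure node). The wavelength in the
  denominator is taken as the fluid wavelength $C_f/f$; whether substrate
  or fluid wavelength belongs there is ambiguous in parts of the
  literature, and the choice is flagged.
- **Travelling-wave force**:
  $\langle F \rangle = Y_T \pi d_p^2 \langle E \rangle / 4$, directed away
  from the transducer. The acoustic radiation factor $Y_T$ is a
  user-supplied parameter (default 1) rather than computed from scattering
  theory — it depends on particle mechanics in a way the package does not
  model.
- **Drag and displacement**: Stokes drag $F_D = 3\pi\eta d v$, and — since
  particle Reynolds numbers are ≪ 1 — a quasi-steady pulse displacement
  $\Delta y = F\tau/(3\pi\eta d)$ (terminal velocity times pulse
  duration, inertia neglected). The effective push time is capped at the
  residence time remaining after the detection-to-pulse delay.

The time-averaged energy density $\langle E \rangle$ is configured
directly; a helper maps electrical drive power through a single
user-supplied conversion efficiency, because no electro-acoustic
conversion model is implemented. The default 100 J m⁻³ was chosen once so
that a 1 ms pulse displaces 8–15 µm cells by roughly 7–12 µm in the 10
mPa s measurement buffer — comfortably past the 5 µm bifurcation offset,
while leaving platelet-sized particles (2–3 µm) short of it, which is the
qualitative behaviour reported for such devices.

## The sorting-run model

Arrivals are a homogeneous Poisson process at rate
(concentration × flow rate); the mean-concentration treatment of arrivals
makes this the simplest consistent model. Each event:

1. is gated on its features at detection;
2. if gated (and with a configurable per-event success probability,
   default 1 — a phenomenological hook for unmodelled failure modes such
   as the z-velocity dispersion of very small particles), requests a pulse
   that fires after the detection-to-actuation delay (default 1 ms);
3. is displaced by the quasi-steady TSAW displacement computed from its
   own diameter, plus an optional additive streaming term (default 0,
   since no streaming field model is implemented);
4. exits through the target outlet iff its displacement reaches the
   bifurcation offset (default 5 µm).

**Coincidence** is resolved at the pulse onset instant: any other cell
whose residence interval (arrival time + sorting-region volume / flow
rate) contains that instant is a bystander. Evaluating coincidence at
pulse onset, rather than over the full pulse, makes the expected bystander
count exactly `rate × residence time` and the per-pulse contamination risk
`1 − exp(−λ_other)` — the closed forms the simulator is tested against.
Two policies are implemented: `"co-sort"` (default; the bystander is
pushed too, degrading purity) and `"abort"` (the pulse is suppressed,
degrading recovery while preserving purity). Recovery is measured against
pulses *requested* by the feedback logic, so aborts show up as recovery
loss — matching the operational definition of collected-over-reported
cells.

The throughput arithmetic follows from single occupancy of the sorting
region (volume $V_{SR}$, default 0.2 nl from a 50 × 130 µm region in a
30 µm-high channel): maximum in-channel concentration $1/V_{SR}$
(5 × 10⁶ ml⁻¹), maximum sorting rate = concentration × flow rate
(400 s⁻¹ at 0.08 µl s⁻¹), residence time $V_{SR}/Q$ (2.5 ms, safely above
the 1 ms pulse), and a maximum *sample* concentration rescaled by the
sheath dilution (40 × 10⁶ ml⁻¹ at 7:1).

## Gating and run metrics

Gate intervals are half-open `[lo, hi)` and "less-than" bounds are strict;
published tables mix range and bound notations, and one convention had to
be fixed and documented. The area-ratio bound is treated as a data-quality
pre-filter: events failing it are excluded from both numerator and
denominator of purity, mirroring its role as a plotting/filter gate rather
than a selection gate. Polygon gates in the deformation–size plane accept
explicit vertex lists; isoelasticity lines themselves (finite-element
derived) are out of scope, so stiffness-selection polygons must be
supplied by the user.

Initial purity (IP) is the gated percentage of the pre-sort table, target
purity (TP) that of the events collected in the target outlet, enrichment
is TP/IP (infinite with a warning when IP = 0), recovery is
collected-over-reported-sorted, and size CVs use the sample (n − 1)
standard deviation — unspecified in common practice, so fixed here.

## What the synthetic data emulate — and what they do not

`population_spec()` draws event features from parametric distributions:
projected area or physical diameter (normal or lognormal with mean and
CV), deformation truncated into [0, 1), brightness, and area ratio
reflected to ≥ 1. The shipped defaults encode the study conditions the
package is tested under: two bead populations with a 1.7 µm modal-diameter
gap at 3.2% diameter CV (the canonical sensitivity test for size-based
sorting), and blood sub-populations (lymphocytes, myeloid cells, red
cells, neutrophils, platelets) whose feature modes sit at the centres of
their published gating windows — published sources give gate bounds, not
full per-type distributions, so mode-at-gate-centre is a declared
convention, not an inference from data.

`render_frames()` rasterises cells as filled ellipses (optionally
bullet-shaped through a front–rear asymmetry term) by 4× supersampled
coverage over a uniform background with additive Gaussian noise, at a
default pixel pitch of 0.34 µm (the objective magnification is known but
the camera calibration is not; the value is configurable) and 8-bit depth
with background gray 50. Analytic ground truth (area and perimeter of each
rendered outline by dense-polygon quadrature) rides along with the stack.

Deliberately **not** emulated: physical optics (defocus, diffraction),
hydrodynamic shape dynamics (shapes are sampled, not computed from flow),
cell–cell hydrodynamic interactions, pressure-controller feedback
dynamics, and quantitative acoustic streaming fields. Passing tests
therefore demonstrate the correctness of the pipeline arithmetic and
statistics under controlled imaging conditions — not robustness to real
microscopy artefacts.

## Numerical choices and degenerate inputs

- Polygon area/perimeter by shoelace/arc-length; convex hulls via
  `grDevices::chull()`; point-in-polygon via `pracma::inpolygon()`.
- Occupancy goodness-of-fit pools the Poisson tail so every expected bin
  holds ≥ 5 counts. Occupancy is sampled at probe times on disjoint
  windows (one residence time apart), because counts sampled at nearby
  instants share arrivals and would violate the independence assumption of
  the chi-square test.
- Degenerate inputs fail loudly with typed conditions: zero-area contours,
  empty tables in purity, zero denominators in recovery, single frames in
  background estimation, out-of-field rendered objects (rejected with a
  warning, never cropped silently).
- Problem sizes used in the shipped checks: 10⁵-event streams for the
  coincidence statistics, 200 rendered ellipses (plus 20 rendered disks)
  for feature recovery, and 10⁴ events per concentration for the
  robustness sweep — sizes at which the binomial/Poisson error bars are
  far tighter than the tolerances being checked.

## Known limitations

- $Y_T$ and $\langle E \rangle$ are configuration constants; absolute
  displacement predictions are therefore only as good as the user's
  calibration of those two numbers.
- The streaming contribution to displacement is a user-set additive term,
  so streaming-dominated (κ < 1.28) sorting is not quantitatively
  predicted.
- The tracker is greedy nearest-match and assumes the configured flow
  advance; it is adequate for sparse channels, not for overlapping cells.
- Measured device resonances differ from the design quotient $v/\lambda$
  by a few percent; the package does not reconcile this, it exposes both.
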