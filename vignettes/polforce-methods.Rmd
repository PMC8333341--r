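---
title: "Mapping molecular force orientation from polarization-modulated SIM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping molecular force orientation from polarization-modulated SIM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polforce)
```

## The measurement

DNA-hairpin tension probes report piconewton receptor forces as
fluorescence: above the probe's threshold force the hairpin unfolds and a
quenched fluorophore lights up. When the fluorophore is stacked on the
terminus of the opened duplex, its transition dipole is constrained to a
disk perpendicular to the force vector **F**. Excitation with linearly
polarized light at in-plane angle $\alpha$ then makes the emitted
intensity of a pixel depend on the in-plane force angle $\phi$ and the
tilt $\theta$ (measured from the optical axis):

$$I(\alpha) = A\,\sin^2(\alpha - \phi) + c, \qquad
  c = I_{\max}\left(b + (1-b)\cos^2\theta\right), \quad
  A = I_{\max}(1-b)\sin^2\theta,$$

with $I_{\max} = A + c$ the peak of the sinusoid (proportional to the
number of opened probes regardless of orientation) and $b = 0.069$ the
fraction of time the fluorophore spends unstacked and randomly oriented.
$\phi$ is axial: $\phi$ and $\phi + 180^\circ$ are the same measurement,
a fundamental degeneracy this package does not attempt to break.

A structured-illumination microscope (SIM) provides exactly the
polarization control this needs for free: the excitation stripes and the
field **E** rotate together, so one SIM acquisition (3 stripe
orientations $\times$ $P$ phase steps, $P$ = 5 or 3) delivers three
polarization-resolved images after the stripes are averaged out. The
measured instrument triplet $\alpha = 77^\circ, 137^\circ, 17^\circ$ is
the package default; any triplet with $60^\circ$ spacing (mod
$180^\circ$) is accepted.

## The three-point fit

Because $\sin^2$ is a constant plus a second harmonic, three samples at
$60^\circ$-spaced $\alpha$ determine the sinusoid exactly. The published
closed form uses a single-argument arctangent, which is branch-ambiguous;
`fit_three_point()` instead demodulates the second harmonic,

$$z = \sum_k I_k e^{2i\alpha_k}, \qquad
  A = \tfrac{4}{3}|z|, \quad
  \phi = \tfrac{1}{2}\arg(-z) \bmod 180^\circ, \quad
  c = \bar I - A/2,$$

which is algebraically identical where the arctangent form is
nonsingular, has no quadrant errors, and (because the interpolation is
exact) coincides with least squares. The suite verifies equivalence
against an independent dense least-squares oracle to $10^{-6}$ degrees.

Two degeneracies are handled explicitly:

* **Constant intensity** ($A \approx 0$, a vertical force or no
  anisotropy): $\phi$ is undefined. Pixels with
  $A/I_{\max} < 10^{-3}$ (configurable) are flagged
  orientation-undefined. The threshold is this package's choice; the
  source material is silent on the constant case.
* **Tilt inversion**: $\theta = \cos^{-1}\sqrt{(c/I_{\max} - b)/(1-b)}$.
  The printed form of this relation in one place uses $I_{\max}/c$,
  inconsistent with its own definition elsewhere; only $c/I_{\max}$ maps
  $[b, 1]$ onto $[90^\circ, 0^\circ]$, so that form is implemented.
  Noise can push the argument outside $[0,1]$; it is clipped and the
  clip count is reported per map.

All $\phi$ arithmetic — errors, averages, histograms — runs on doubled
angles (axial circular statistics), so differences never exceed
$90^\circ$ and means are wrap-safe.

## Preprocessing

`correct_montage()` follows the standard-resolution recipe in order:
subtract the CCD baseline (default 200 counts); divide by an
illumination profile; subtract the montage-wide 1st percentile; clamp
negatives to zero. The percentile step is skipped in timelapse mode so
frame intensities remain comparable over time. The percentile is
computed per montage, not per frame (the recipe says "of the montage").
`build_illumination_profile()` builds the flat-field from uniform-slide
acquisitions: baseline subtraction, disk-kernel smoothing with a
3-pixel radius (the "rolling ball" is interpreted as grayscale
smoothing; the kernel is configurable), averaging over at least six
acquisitions (fewer is accepted with a warning), and normalization to
montage mean 1. `phase_average()` averages the $P$ phase frames per
orientation; with $2\pi/P$ phase steps the stripe term cancels exactly,
which the suite asserts to machine precision.

Frame order is orientation-major by default with a phase-major option,
since vendor exports differ. Raw ND2 ingestion is out of scope; montages
are exchanged as CSV + JSON sidecar (no TIFF library exists in the
supported dependency set, so the multi-page-TIFF interface was replaced
by an equivalent plain-text one carrying the same metadata).

## The synthetic world

`make_platelet_scene()` emulates the traction phenomenology of a spread
platelet: a lamellipodial ring (width 500 nm) whose $\phi$ points
radially, plus 0 or 2–4 inner lobes, each lobe sharing a common axis.
Tilt angles are drawn from a truncated Normal($47^\circ$, $5^\circ$) —
a generator choice consistent with the reported population tilt, not a
fixed constant of the method. Ring/lobe intensities default to
1000/800 photons, matching the experimentally relevant signal level.
`make_bead_phantom()` places in-plane dipoles tangent to a circle, the
classic control in which intensity around the perimeter at fixed
$\alpha$ is a $180^\circ$-periodic sinusoid.

`render_montage()` pushes a scene through the *forward* model: per
frame, the polarized expected intensity is striped (default modulation
0.8, period 8 px — irrelevant after phase averaging but realistic in the
raw frames), Poisson shot noise is drawn per raw frame, optional
Gaussian read noise is added, and the camera baseline is applied.
`render_timelapse()` adds attachment/spreading/retraction dynamics, an
ambient fluorescent background (default 50 photons) that photobleaches,
exponential intensity decay, and cumulative stage drift.

What the generator does **not** emulate: the optical PSF, super-resolved
structure, 3D sectioning, EM-gain excess noise, and segmentation clutter
from neighboring cells. A green end-to-end test therefore establishes
that the estimator chain is correct and well-conditioned at realistic
photon budgets — not that every property of real acquisitions is
captured.

## Monte Carlo error characterization

`mc_orientation_error()` generates ideal intensities for a true
$(\phi, \theta, I_{\max})$, adds noise, refits, and repeats (default
30,000 times), reporting random error
$\varepsilon = \langle|x - x^*|\rangle$ and systematic error
$\sigma = x - \langle x^*\rangle$ for both angles, with axial means for
$\phi$.

**Where the noise enters matters.** Noising the three phase-averaged
images directly makes the $\theta$ errors depend on $\phi$ by up to
$\sim$1.8° peak-to-peak near $\theta = 90^\circ$ at 1000 photons —
because whichever sample sits at the sinusoid minimum has the smallest
Poisson variance, and that assignment rotates with $\phi$. The actual
acquisition, however, averages $P$ raw phase frames per polarization
image, so the averaged image has variance $\mu/P$; the Monte Carlo
procedure this work adapts likewise noised raw images. The package
therefore draws Poisson noise per raw phase frame (`phase_frames = 5`
default; set 1 for the direct variant). Under this physically faithful
model the published error structure reproduces: systematic $\phi$ errors
stay below half a degree everywhere, and the $\phi$-dependence of every
error metric stays below $1^\circ$ (the acceptance suite measures
$\approx 0.86^\circ$, dominated by the $\theta$ errors at the equator).

The error surface inherits the sampling geometry's symmetry: the
triplet is $60^\circ$-spaced, so the surface is periodic in $\phi$ with
period $60^\circ$ (not $90^\circ$ — a $90^\circ$ shift maps onto a
reflected configuration and differs measurably). `phi_uniformity_histogram()`
reproduces the flat-histogram control: uniform true $\phi$ recovered
through the noisy pipeline lands within $\sim$0.15 percentage points of
the ideal 2% per bin at $n = 10^5$ pixels, far tighter than the up-to-7%
deviation reported for real platelet data, where illumination and
bleaching imperfections add systematic structure.

## Timelapse dynamics

Per-frame, two scalars: the tension area $T$ (supra-threshold pixel
count $\times$ pixel area; threshold = background mean + $3\times$
background sd by default, explicit and configurable because the original
segmentation rule is not fully specified) and the alignment parameter
$R$ (mean resultant length on doubled angles; 1 = one common axis, 0 =
isotropic; unweighted by default with optional $I_{\max}$ weighting,
since the source describes "all angles under the platelet").

Corrections run in the acquisition order: baseline/profile correction
(percentile step skipped), drift correction, photobleach correction.
Drift is estimated between successive frames by phase cross-correlation
with parabolic subpixel refinement; a normalized correlation peak below
0.15 (featureless or unrelated frames, e.g. before the cell attaches)
falls back to zero shift with a warning rather than propagating a
garbage offset through the cumulative chain. Photobleaching is fit as
$a e^{-t/\tau_b}$ on a cell-free background region and divided out; a
non-decaying background degrades to a warned no-op.

$T(t)$ is fit to the spread-then-retract curve (saturating exponential
minus a sigmoid, plus basal $T_0$) by simulated annealing — exponential
cooling, 5 restarts, bounded parameters ($\tau \in [0.1, 60]$ min,
times within the acquisition window), seeded and deterministic —
followed by L-BFGS-B refinement. $T_0$ is a free parameter (the original
fit-parameter list omits it but its definition implies it). $R(t)$ is
fit on the attachment window with $t_\mathrm{attach}$ fixed from the
$T$ fit; the trend class (increasing / decreasing / none) comes from a
Spearman rank correlation at $\alpha = 0.05$, a documented choice where
the original names no test.

Two caveats the tests quantify rather than hide. First,
$\tau_\mathrm{spread} \approx 1.7$ min is close to the 2-min sampling
interval, so its estimate is intrinsically noisy: with additive track
noise of $\sim$0.8 µm² even least squares started at the true parameters
shows $\sim$16% median error. The cohort recovery test therefore sets
the track noise to the measurement noise of this package's own imaging
pipeline (measured at test time from a rendered timelapse at 1000
photons, $\approx 0.05$ µm² in $T$ and $\approx 0.01$ in $R$ during the
live phase), under which all three headline parameters recover to well
under 15% median relative error. Second, near detachment only a handful
of pixels remain and $R$ becomes meaningless; measurement windows
exclude those frames.

## Rendering

Two display styles mirror the published figures: a colormap render (hue
= $\phi$ on a circular HSV wheel, exactly $180^\circ$-periodic, with an
optional $90^\circ$ wheel rotation; or $\theta$ on a jet-style scale)
with pixel brightness scaled to $I_{\max}$ clipped between the 35th and
99th percentiles and dimmed below the 60th-percentile mask; and a
dipole render (a segment per pixel at angle $\phi$, length
$\propto I_{\max}$, color = $\theta$, gray background). The dipole
stride defaults to 2 px for legibility at arbitrary sizes; per-pixel
plotting is a flag.

## Numerical choices

* $\phi$ stored in $[0, 180)$; all comparisons axial.
* $\theta$ argument clipped to $[0,1]$ with counted clip events.
* The tension-area model gates its exponentials at
  $t < t_\mathrm{attach}$ (otherwise $0 \cdot \infty$) and caps the
  sigmoid argument at 700.
* Degenerate (constant-$I_{\max}$) brightness scaling renders at full
  brightness rather than dividing by zero.
* Grid seeds for error surfaces are derived per grid point, so results
  are independent of evaluation order.

## Limitations

No super-resolution reconstruction (performed in vendor software in the
original work), no SIM quality scoring, no breaking of the $180^\circ$
degeneracy, no multi-cell tracking, and no within-lobe alignment
decomposition for 3–4-lobed cells — the whole-cell $R$ of such cells
understates their internal alignment, as the original analysis also
notes.
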