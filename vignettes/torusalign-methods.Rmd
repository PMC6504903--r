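---
title: "Methods: tilted-ring fitting, particle averaging and toroid metrology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tilted-ring fitting, particle averaging and toroid metrology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torusalign)
```

## The problem

Ring-shaped ("toroidal") protein assemblies at the nuclear envelope — such
as the membrane ring anchoring the yeast spindle pole body — have diameters
of 90–200 nm, at or barely above the ~100 nm lateral resolution of
structured-illumination microscopy (SIM). A single image of one such ring is
noisy, often incomplete, and randomly oriented in 3D. `torusalign`
implements the single-particle-averaging strategy for these structures:
fit a geometric ring model to each particle, transform every particle so
its ring is flat and centered, average many particles, and read diameters
and flux partitions off the average with Monte Carlo error bars. A second,
independent module quantifies acceptor-photobleaching FRET from paired
pre-/post-bleach images.

## The tilted-ring model

A circle of radius $r$ centered at $(x_c, y_c, z_c)$, tilted from the image
plane by $\theta$ and rotated about the microscope axis by $\phi$, is
parameterized by the travel angle $\rho$:

$$
\begin{aligned}
x(\rho) &= x_c - r\cos\rho\,\sin\phi + r\sin\rho\,\cos\theta\,\cos\phi,\\
y(\rho) &= y_c + r\cos\rho\,\cos\phi + r\sin\rho\,\cos\theta\,\sin\phi,\\
z(\rho) &= z_c - r\sin\rho\,\sin\theta.
\end{aligned}
$$

All geometry is carried in 0-based, voxel-center **pixel units** with axis
order $(x, y, z)$; nanometers appear only in reports, via the lateral voxel
size. One consequence worth noting: with anisotropic voxels a physical
circle is an ellipse in index space. The package treats the *index-space*
circle as the model (the simulator renders the same object, so generator
and fitter are consistent); strongly anisotropic acquisitions should be
resampled to isotropic voxels first.

### Plane crossings

The observable used for fitting is the set of eight spots where the ring
pierces four axial cross-sections through an approximate center: the planes
$x=0$, $y=0$, $x=y$ and $x=-y$ in coordinates relative to that center. For
any such plane with in-plane unit normal $\mathbf{n}$, substituting the
ring model into $\mathbf{n}\cdot(p - g) = 0$ gives

$$A\cos\rho + B\sin\rho + C = 0,$$

with $A = r(-n_x\sin\phi + n_y\cos\phi)$,
$B = r\cos\theta\,(n_x\cos\phi + n_y\sin\phi)$ and
$C = \mathbf{n}\cdot(\text{center} - g)$. We solve this exactly with the
two-argument arctangent: $\rho = \arcsin(-C/R) - \delta$ and its
supplement, where $R = \sqrt{A^2+B^2}$, $\delta = \operatorname{atan2}(A, B)$.
Printed one-argument arctangent forms of these solutions are branch
ambiguous and divide by $\cos\theta\cos\phi$-type factors; the phase-shift
form has neither problem. Both roots are wrapped into $[0, 2\pi)$ and the
pair is ordered stably — the crossing on the section's positive lateral
half first — so spots are never swapped between iterations. When
$R \approx 0$ (a tilt within numerical reach of 90° combined with an
aligned $\phi$) the closed form is bypassed in favor of a dense-sampling
bisection solver; that brute-force solver (`brute_force_crossings()`) is
also kept as an independent oracle and is compared against the analytic
solver over hundreds of random poses in the test suite, to $10^{-6}$ rad.

A subtlety we verified explicitly: $(\theta, \phi)$ and
$(\theta, \phi + 180°)$ are *not* the same circle — they agree in $x, y$
but are mirrored in $z$. The rotation angle is therefore identifiable over
the full circle (for tilted rings), and the fit scans $\phi$ over all of
$[0°, 350°]$.

## Cross-section extraction and the global fit

`extract_cross_sections()` samples the volume along strips through the
guess center at 0°, 45°, 90° and 135°, bilinearly interpolated and averaged
across a 2-pixel strip width (two parallel lines offset ±0.5 px). Each
section is a (z × lateral) image; extraction is linear in the source, a
property the tests assert.

`initialize_pose()` turns four clicked points at the approximate 0°/90°/
180°/270° crossings into a starting pose: radius from half the mean of the
two opposite-point distances, lateral center from the centroid, z center
from the maximum of the averaged z profiles through the four points, tilt
zero. Two robustness details: each column profile is peak-normalized before
averaging, so one imprecise click cannot let a single crossing dominate the
vote (for tilted rings the 0/180 and 90/270 crossing pairs straddle the
true center symmetrically in z); and when the annotation carries a `z_hint`
the maximum is searched in a window around the hinted slice.

`fit_ring()` then fits all eight spots *globally* as asymmetric 2D
Gaussians whose centers are not free parameters but functions of the pose
through the plane-crossing solutions. Per fixed grid value of $\phi$
(10° steps), a bounded Levenberg–Marquardt fit (`minpack.lm::nls.lm`,
analytic Jacobian obtained by implicit differentiation through the
crossing equation, termination at relative cost change $10^{-10}$ or 500
iterations) optimizes:

* pose: $x_c, y_c$ (each within 20% of the guess radius from the
  initialized center), $z_c$ (within one z slice of its initialization),
  $r$ (within a factor of two of its initialization), $\theta$ (in
  $[0°, 45°)$);
* one lateral and one axial Gaussian sigma, linked across all eight spots
  (the microscope's resolution does not vary spot to spot);
* per section, a pair-mean amplitude and a bounded ratio — the two
  amplitudes of a section may differ by at most a factor of two, enforced
  smoothly by the reparameterization $(m s, m/s)$ with
  $s \in [1/\sqrt2, \sqrt2]$;
* one additive baseline per section (cytoplasmic background; the
  alternative of pre-subtracting backgrounds would couple the fit to an
  extra preprocessing choice).

Weighting is uniform (least squares on raw intensities); a
Poisson-weighted variant would change little at the photon budgets
validated here and is deliberately not a knob.

The grid angle with the lowest cost wins; the full cost-versus-$\phi$
profile is returned. Implementation detail: every grid angle gets a short
bounded pass on a lattice matched to the PSF (every 2nd lateral sample,
z step about $\sigma_z/2$), each seeded with a tilt estimate read from
the antisymmetric spot z-offsets
($\Delta z \approx -\tan\theta\, t \cos(\alpha - \phi)$ across the four
section angles $\alpha$); the leading three candidates are then refined to
convergence on the standard lattice, and all profile costs are reported on
that same lattice. For essentially flat rings $\phi$ carries no
information; the fit flags `phi_undetermined` when the grid costs are
near-constant or the fitted tilt is below 3°.

`fit_quality()` renders the model sections next to the observed ones (the
machine surrogate for visual inspection) and scores the fraction of
observed section variance left unexplained (FVU, default threshold 0.5):
a model-matched fit leaves only noise, a misplaced ring leaves most of the
spot structure in the residual. Whole-section residual RMS is reported too
but is a poor pass/fail statistic, being dominated by empty background.

## Realignment and averaging

`flatten_transform()` applies the rigid rotation $R_y(-\theta)R_z(-\phi)$
about the fitted center — undoing first the azimuth, then the tilt — and
recenters the ring at the middle voxel of an odd-sized cubic canvas
(default 2.5× the fitted diameter), with trilinear resampling. Total
intensity is conserved within 1% on band-limited inputs, and re-fitting a
flattened particle returns tilt below 2–3° with the center within a pixel
— both asserted in tests. In-plane orientation is then either randomized
(seeded, uniform; used when ring inhomogeneities carry no reproducible
position) or set from a secondary channel via `orient_by_secondary()`
(e.g. pointing a half-bridge "up" before averaging).

`average_particles()` takes the voxelwise mean. A particle whose
integrated intensity exceeds three times the median of the *other*
particles is first rescaled by its ratio to that median — the
leave-one-out form matters at small n, where a 10× outlier would otherwise
drag the pooled median past its own threshold.

## Metrology

* `radial_profile()` averages bilinearly interpolated values around
  circles at 1-pixel arc spacing.
* `diameter_from_average()` draws 3-pixel-wide bands through the vertical
  and horizontal centers and fits each profile to two Gaussians with
  independent centers and amplitudes, one shared width and a constant
  baseline; the component diameter is the distance between fitted centers.
  If the two components agree within 5% (configurable) their average is
  reported; otherwise the map is flagged asymmetric and both components
  are reported separately — the behavior needed for half-bridge-bearing
  rings. A profile whose fitted separation falls below twice the fitted
  width (the bimodality limit of a two-Gaussian sum) raises a
  "diameter below resolution" error rather than returning a number.
* `monte_carlo_error()` is a residual-calibrated parametric bootstrap:
  replicates are the fitted model plus Gaussian noise at the residual SD,
  refit from the fitted parameters; the reported error is the SD of the
  replicate diameter distribution (it is an SD, not an SEM, and is labeled
  as such). Calibration against ground-truth scatter (200 independently
  simulated maps) is part of the acceptance suite: the bootstrap SD
  tracks the empirical SD within 30% and doubles when the injected noise
  doubles. One caveat the calibration exposed: the iid-residual bootstrap
  assumes homoscedastic noise, so maps whose background has been clipped
  at zero (half-normal noise in the background, full noise at the peaks)
  will be underestimated; realistic maps with a positive background
  offset do not have this problem.
* `normalize_diameters()` rescales a sample diameter by
  (reference / measured) of a fiducial channel, with the two relative
  errors combined in quadrature — compensating batch-to-batch fiducial
  variation.
* `compare_diameters()` applies Welch's two-sample, two-tailed t-test to
  the Monte Carlo diameter distributions.
* `toroid_bridge_fraction()` integrates background-subtracted flux over a
  ring annulus and a disjoint bridge sector of the sum projection and
  reports each region's share. The background is the kernel-density mode
  of the pixels outside both masks. Mask geometry is a user input;
  `truth_partition_masks()` documents the default used for simulated
  scenes (annulus of ±12 px around the ring radius; sector of ±75° around
  the bridge azimuth from the annulus edge to the image border).

## The synthetic-scene generator

`simulate_toroid_volume()` renders the ring as a uniform line emitter
along the model circle (64 sub-pixel samples per pixel of arc, trilinear
splatting — the truth must be better than the fit tolerance), adds an
optional half-bridge Gaussian blob and NPC-like background puncta,
convolves with an anisotropic Gaussian PSF (axial ≥ lateral), and applies
Poisson noise plus Gaussian read noise, all under a single integer seed.
SIM imaging is modeled only through the asymmetric Gaussian PSF — exactly
the assumption the fitting model makes — not through a structured
illumination forward model; reconstruction artifacts (honeycombing,
Wiener ringing) are out of scope, so passing tests say nothing about
robustness to them.

Default conditions, chosen once: 2 nm lateral / 2 nm axial voxels; PSF
sigmas 4 nm lateral and 12 nm axial (2 px and 6 px — the pixel-scale
validation optics used throughout the recovery suite); photon budget
$2\times10^6$ for the default 160 nm ring, scaled with radius in the
recovery experiments so the peak signal-to-noise ratio stays ≈10; read
noise 1 count. The half-bridge blob sits 60 nm beyond the ring radius
with a 20 nm sigma — adjacent to, but distinct from, the toroid, as the
biological half-bridge extends away from the core — and presets cover the
biological cases (diploid 160 nm, haploid 100 nm, a 135 nm ring versus a
170 nm fiducial, and a ring+bridge scene with a 45/55 flux split).

**Scale and resolution.** The validation regime is deliberately
*resolution-scaled*: ring diameters of 90–170 (nm-equivalent at 2 nm/px)
are imaged with the 2 px/6 px PSF, under which the two-peak profile
structure is resolvable and metrology to a few percent is meaningful. At
the instrument's true ~100 nm lateral FWHM, a thin-ring emitter of 90 nm
diameter blurs into a unimodal spot — the same physics that makes haploid
rings hard to see in real SIM data — and `diameter_from_average()`
correctly refuses it rather than reporting a compressed number.
Consequently the parameter-recovery and metrology results here validate
the *pipeline* (fitting, alignment, averaging, error calibration), not
super-resolution beyond the optics; and even above the resolution limit,
apparent diameters of thin rings under heavy blur are biased low, which
is one reason real studies normalize against a fiducial ring measured
under identical optics.

## FRET quantification

Acceptor photobleaching dequenches the donor: if a fraction $E$ of donor
excitations transferred to the acceptor, destroying the acceptor raises
donor emission by $1/(1-E)$. Per punctum the raw efficiency is

$$E_\text{raw} = \frac{D_\text{post} - D_\text{pre}}{D_\text{post}},$$

computed on background-subtracted intensities integrated over an
adaptively grown region (Gaussian pre-blur σ=1 px; local-percentile
background; noise-scaled maxima threshold; 8-connected growth down to half
the local maximum). Pre/post frames are registered by FFT
cross-correlation, and puncta whose local residual displacement exceeds
2 px are excluded as moved. The *relative* efficiency is the pair-sample
mean minus the donor-only control mean — subtraction, not division,
which is what allows small negative values when donor photobleaching
dominates — with the two group SEMs combined in quadrature and a
two-sided t-test against the control.

One bias is worth stating precisely. With multiplicative donor
photobleaching $b$ during the acceptor bleach
($D_\text{post} = D_\text{pre}(1-b)/(1-E)$ in both samples), the control
subtraction corrects the bleaching only to first order: the estimator's
expectation is $E/(1-b)$, not $E$ — for $E = 0.40$, $b = 0.05$ that is
0.421, a bias of +0.021. The generator, the estimator and the tests are
all consistent about this; an exactly unbiased estimator would require a
ratio-based correction that the subtraction convention (and the
possibility of negative values it preserves) deliberately forgoes.

## Problem sizes and numerical settings

The shipped test and acceptance experiments use: 500 random poses for the
crossing-solver oracle; 50 scenes (r 30–60 px, tilt 0–40°) for parameter
recovery; 20 particles per condition at diameters 90/135/170 with a 1.6×
canvas for end-to-end metrology; 200 replicate maps for Monte Carlo
calibration; 20 seeds for the flux partition; and 100 spots per group for
FRET. Optimizer settings: LM with analytic Jacobian, `ftol` $10^{-10}$,
500-iteration cap (short 10-iteration ranking passes across the $\phi$
grid); two-Gaussian profile fits run to `ftol` $10^{-12}$. Interpolation
is trilinear/bilinear everywhere — chosen over splines so that linearity
properties (extraction, averaging) hold exactly in tests.

## Known limitations

* Index-space geometry: anisotropic voxels require prior resampling.
* Gaussian-PSF SIM surrogate: no reconstruction artifacts are emulated.
* The z-center constraint ("within one slice") is inherited from
  acquisitions whose slice spacing exceeds the ring's z extent; with fine
  z sampling it relies on the initializer's z vote, which the
  peak-normalized profile averaging makes robust but not infallible.
* The FRET estimator's $E/(1-b)$ bias, above.
* Diameters of rings near or below the optical resolution are biased low
  by blur; fiducial normalization mitigates but does not remove this.
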