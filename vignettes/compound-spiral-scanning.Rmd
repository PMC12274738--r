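---
title: "Compound double-spiral scanning: models, phantoms and morphometry"
author: "spiralscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compound double-spiral scanning: models, phantoms and morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiralscan)
```

# The problem

Resonant MEMS mirrors inside capsule-sized photoacoustic endoscopes scan a
focused laser spot over a circular field of view while the laser fires at a
fixed pulse repetition frequency (PRF).  Spiral trajectories driven at
constant angular velocity are attractive because the mirror's two axes see
smooth, nearly sinusoidal commands: no flyback, no abrupt turns, hence
undistorted resonant operation.  But uniform angular sampling interacts
badly with spiral geometry:

* an **Archimedes spiral** (AS), $r(\theta) = a\theta$, crosses each radius
  at a constant radial pitch, so equal time spent per unit angle puts the
  cumulative fraction $\rho/R$ of all pulses inside radius $\rho$ — the
  centre is heavily oversampled (a thermal-damage risk) while the edge is
  starved;
* a **Fermat spiral** (FS), $r(\theta) = a\sqrt{\theta}$, places the
  fraction $(\rho/R)^2$ inside radius $\rho$ — areally uniform on average,
  but its *track* visits the centre rarely, so the central pixels are
  poorly covered.

The **compound Archimedes–Fermat (A-FS) pattern** joins an AS pass and an
FS pass into one continuous frame.  Each pass carries half the pulse
budget, so its central-disk pulse fraction is the average of the two
closed forms: for a central disk holding the fraction $f$ of the scan
area (radius $R\sqrt f$),

$$
P_{\mathrm{AS}}(f) = \sqrt f, \qquad
P_{\mathrm{FS}}(f) = f, \qquad
P_{\mathrm{A\text{-}FS}}(f) = \tfrac12\left(\sqrt f + f\right).
$$

At $f = 1/256$ these are $6.25\%$, $0.39\%$ and $3.32\%$; at $f = 1/64$,
$12.5\%$, $1.56\%$ and $7.03\%$.  The package's acceptance script
recomputes exactly these quantities from generated trajectories, and the
test suite verifies the discrete fractions converge to the closed forms
at rate $O(1/n)$.  Relative to AS, the compound pattern roughly halves
the central pulse load (the computed ratio at the default operating
point is 53%) while filling the edge better — both effects are asserted
by the tests on generated density maps.

# Trajectory construction

`makeTrajectory()` synthesises one frame from a `SpiralParams` object.
Defaults are the reference operating point of the scanner this package
models: a 2 mm circular FOV, PRF 200 kHz, and 33,332 pulses per frame —
the nearest even budget giving a 6 Hz frame rate (`frameRate = prf /
nPoints` exactly).  Parameters with units:

| parameter | meaning | default | why |
|---|---|---|---|
| `fovDiameter` | scan diameter (mm) | 2 | probe's circular FOV |
| `nPoints` | pulses per frame | 33,332 | 200 kHz / 6 Hz, rounded even |
| `nTurns` | revolutions per one-way pass | 16 | radial pitch $R/16$ ≈ 62 µm, matching a beam-scale pitch at this FOV; not uniquely determined by the imaging geometry, so it is exposed in the configuration and the acceptance analysis scans {8, 16, 32} |
| `prf` | pulse repetition frequency (Hz) | 2×10⁵ | laser spec |
| `startPhase` | angle of first pulse (rad) | 0 | convention |
| `passOffset` | interleaving offset (rad) | $\pi/\mathrm{nTurns}$ | half the inter-turn angle |

A frame is a sequence of passes, each spanning `nTurns` revolutions with
an equal share of the pulses.  The unwrapped angle advances monotonically
through the whole frame at constant angular velocity (the resonant
constraint); the radius follows $a\theta$ or $a\sqrt\theta$ outward and
its mirror image inward.  The first pass includes both endpoints exactly
($r = 0$ at the first pulse, $r = R$ at the last); later passes continue
from the junction.

**Pass interleaving.** If the return pass were rotated by a *fixed*
angular offset, the trajectory would jump by $R\,\delta$ at the outer
junction — orders of magnitude more than a sampling step, i.e. a
waveform discontinuity a resonant mirror cannot follow.  The package
therefore accrues the offset *linearly in angle over the return pass*:
the pass starts exactly at the junction and ends rotated by the full
$\pi/\mathrm{nTurns}$ at the centre (where rotation is invisible).  The
position stays continuous at every junction, each pass still has
constant angle increments, and the returning turns sweep through the
gaps between the outgoing ones.

**Continuity.**  All steps obey the 4×-median-step bound at the tested
budgets (1,024–65,536 pulses).  One feature deserves note: a Fermat pass
approaches $r = 0$ with radial spacing $\propto R/\sqrt m$ between its
last samples, so at very large budgets its single terminal hop into the
centre exceeds the 4×-median bound even though the underlying curve is
smooth.  The class validity check therefore exempts steps inside the
central 1% radius; `drivingWaveforms()` reports every junction jump
(ratio to the median step) so the smoothness claim is inspectable rather
than assumed.  The pure-AS outer junction is the worst regular case at
exactly 2× the median step.

**Composition.**  The default compound frame is AS-outward + FS-inward
(`as_out_fs_in`): one continuous out-and-back sweep per frame with no
flyback, which is what "double spiral" describes.  A four-pass variant
(`as_roundtrip_fs_roundtrip`, AS out/in then FS out/in) is provided for
study; it joins the two round trips at the centre, where the junction
cost is negligible.

# Sampling analysis

`densityMap()` bins pulses into a FOV-centred pixel grid (default
512×512, pixel = FOV/512) with half-open pixels, row 1 at the top, x to
columns and y to rows; a point exactly on the outer grid edge belongs to
the last pixel.  The **energy factor** is
$\log_{10}(\mathrm{counts}+1)$ normalised by its grid maximum — the
normaliser is the map maximum, chosen so the quantity is a relative,
dimensionless proxy for deposited laser energy in $[0,1]$, zero exactly
on unhit pixels.  Absolute fluence is out of scope: pulse energy is a
global scale factor that cancels in every comparison the package makes.

`centralPulseFraction()` is deliberately trivial — a percentage of
points within $R\sqrt f$ — because it is the quantity of record; the
test suite cross-checks it against an independent squared-distance
count.  `radialFillProfile()` reports, per equal-width annulus, the
fraction of pixels hit at least once and the mean count.  Two computed
facts about the default patterns are worth stating because they are
asserted by tests: AS coverage *decays* from centre to edge, and the
compound pattern's coverage *rises* toward the edge, beating AS there at
equal budget.  The compound minimum over annuli, however, sits in the
central annuli (the Fermat half rarely visits them) — homogenisation is
a trade, not a free lunch, and the package reports the full profile so
the trade is visible.

# The synthetic phantom

`makePhantom()` draws a vascular scene with exactly known ground truth:
smooth centreline curves (splines through jittered control points, or
exact straight lines and analytic hairpins depending on style),
rasterised as tubes of known diameter via a distance transform, each
vessel carrying an oxygen saturation (arteries 0.95–0.98, veins
0.60–0.75 by default — physiologic contrast) and a relative hemoglobin
concentration in [0.6, 1].  Absorption rasters at both wavelengths
follow the forward model below; the background is exactly zero.  Styles
emulate the vascular patterns endoscopic imaging encounters: dense
longitudinally parallel beds, sparse crossing grids, capillary hairpin
loops, and branching trees.  The generating graph stores analytic arc
lengths, chord lengths, diameters and branch points, so
`truthMetrics()` is an exact oracle for the morphometry suite.

What the phantom does **not** emulate: optical scattering and
depth-dependent fluence, acoustic propagation and bandwidth, speckle,
motion, and multi-layer architecture.  Passing recovery tests therefore
demonstrate the *algorithmic* chain (sampling → gridding → unmixing →
morphometry) is correct and well-conditioned, not that the system model
captures tissue physics.

Grid phantoms keep their parallel lines evenly spaced with bounded
jitter so tubes never merge; merged tubes would silently change the
ground truth the tests compare against.

# Acquisition, reconstruction, stitching

`acquire()` samples the absorption raster bilinearly at each pulse
position, adds Gaussian amplitude noise and clips at zero.
Dual-wavelength mode emits co-located 532/558 nm pulse pairs with zero
lag — the hardware's interleaving scheme is not modelled by default — and
an optional one-pulse-lag mode exists to study the misregistration that
sequential firing would cause.

`reconstruct()` grids the scattered samples.  `bin_mean` is the *raw*
mode: each pixel is the mean of the pulses that landed in it, unsampled
pixels stay at zero with `fillMask` FALSE.  Raw mode is what the
pattern-comparison experiments use, because empty pixels are precisely
the evidence of undersampling.  The two fill modes flag every filled-in
pixel in an `inpainted` mask: `nearest` propagates the chamfer-nearest
sample outward; `linear` performs harmonic (discrete-Laplace)
interpolation from the filled boundary, initialised by the nearest fill
and relaxed to convergence.  These are classical scattered-data fills;
learned restoration is explicitly out of scope.

`fitRigid()` is orthogonal Procrustes without scaling (Kabsch, SVD,
reflection excluded) on matched landmark pairs, returning the rotation,
translation and residual RMS.  `stitch()` places tiles into the union
bounding box through their transforms, sampling each tile
nearest-neighbour at mosaic pixel centres; `feather_mean` weights
overlapping contributions by each tile's distance-to-fill-boundary so
seams fade, `overwrite` lets later tiles win.

# Two-wavelength unmixing

Per pixel the photoacoustic amplitudes obey
$\mathrm{PA}(\lambda) = k\,[\varepsilon_{\mathrm{HbO_2}}(\lambda)\,C_{\mathrm{HbO_2}}
+ \varepsilon_{\mathrm{Hb}}(\lambda)\,C_{\mathrm{Hb}}]$ with $k$ the
product of the Grüneisen parameter and local fluence.  `unmix()` solves
the 2×2 system for $(k C_{\mathrm{HbO_2}}, k C_{\mathrm{Hb}})$, leaving
$k$ absorbed in the relative units; $k$ cancels in
$\mathrm{sO_2} = C_{\mathrm{HbO_2}}/(C_{\mathrm{HbO_2}}+C_{\mathrm{Hb}})$,
and relative $C_{\mathrm{HbT}}$ is read back from the 532 nm amplitude
divided by the mixture extinction.  Assumptions and choices:

* **Wavelength-independent fluence** ($k$ equal at 532 and 558 nm) — no
  fluence correction is applied; this is a documented limitation, and
  it is why all concentrations are relative.
* The packaged extinction values come from the standard Prahl (OMLC,
  1999) hemoglobin compilation, with 558 nm interpolated between the
  tabulated 556 and 560 nm rows; the near-isosbestic property at 532 nm
  (species differ by <10%) is enforced by a validity check.  All tests
  rely on forward–inverse self-consistency, never on particular
  extinction values.
* The validity mask requires fill at both wavelengths and a 532 nm
  amplitude above `ampThreshold`, defaulting to 5× a
  median-absolute-deviation noise estimate taken from filled pixels
  bordering unfilled ones (the fill fringe carries no coherent signal
  in sparse scans).  Negative component estimates are clamped to zero
  and counted; the clamp count is part of the result.

`fractionalChange()` implements the longitudinal read-out: the baseline
is the mean of the first five frames (configurable) of the FOV-mean
series and every frame is reported as (value − baseline)/baseline.

# Morphometry

`segmentVessels()` → `skeletonizeGraph()` → `computeMetrics()` computes
the five summary metrics.

* **Segmentation.** Default: Otsu's threshold on a top-hat
  background-suppressed image (disc radius 20 px), removal of objects
  under 20 px, hole filling.  The top-hat radius must exceed the vessel
  radius; hole filling should be disabled for lattice-like networks
  whose enclosed cells are genuine background.  On noiseless phantoms
  the default recovers the true mask up to a ≤1-px boundary band (a
  test asserts this).  The original system's segmentation algorithm is
  not public; Otsu is this package's own documented choice, validated
  only against synthetic truth.
* **Skeleton.** Zhang–Suen thinning, vectorised over the raster.
  Skeleton pixels are classified by the Rutovitz crossing number (0→1
  transitions around the 8-neighbourhood): 1 = endpoint, 2 = path, ≥3 =
  branch pixel; raw neighbour counts over-report at diagonal
  staircases.  Adjacent branch pixels merge into one branch-point
  cluster, so a crossing counts once.  Terminal spurs up to 10 px that
  run into a branch point — thinning artifacts of boundary roughness —
  are pruned before tracing (`pruneLength`, 0 disables).
* **Lengths.** Segment chains are lightly smoothed (moving average,
  window 5, endpoints fixed) before summing chord lengths, removing
  most of the chain-code staircase bias; VL is the sum of segment arc
  lengths, in mm.
* **Diameters.** Default: twice the Euclidean distance transform at
  each skeleton point minus one pixel — the half-pixel boundary
  correction, since the transform measures centre-to-centre while the
  mask edge lies half a pixel before the first background centre.
  Equivalent to the normal-line definition for locally straight tubes
  and far more robust; an exact normal-ray mode
  (`diameterMethod = "normal"`) implements the literal definition for
  validation.  Diameters inside bifurcation zones (within the local
  radius of a branch cluster) are excluded from MVD: there the
  transform sees the union of merging tubes, not any one vessel.
* **Tortuosity.** VT = arc/chord per segment, averaged unweighted over
  segments (a length-weighted flag exists); zero-chord loops are
  excluded.  Oracles: exactly 1 for straight fixtures, $\pi/2$ within
  2% for an analytic semicircle.
* **Fractal dimension.** The box-counting reading of
  $\mathrm{FD} = \log N(r)/\log(1/r)$: boxes anchored at the image
  origin, counts at several sides, FD = least-squares slope of
  $\log N(r)$ vs $\log(1/r)$.  A single scale makes the formula
  ill-defined, so the multi-scale regression is used, with box sides
  defaulting to powers of 2 from 2 px to a quarter of the image.
  Oracles: 1.0 for a line, 2.0 for a filled square (both exact for
  power-of-2 grids), $\log 8/\log 3 \approx 1.893$ for a three-iteration
  Sierpinski carpet measured at its natural power-of-3 box sides.

**Recovery and its limits.**  On noiseless phantoms the chain recovers
VL within 5%, branch counts within 1 per 10, MVD within 1 px and VT
within 0.05 for parallel, grid and loop scenes (tests assert this over
several seeds).  Two caveats are inherent to skeleton-based
morphometry, not bugs: VT error scales with the magnitude of VT itself,
so the 0.05 absolute band is meaningful near VT ≈ 1 but not for
hairpins with VT ≈ 10; and in branching trees whose children leave a
fork at an acute angle, the two tubes overlap for roughly one diameter
past the fork, the skeleton fuses them, and total length reads ~20% low
at realistic diameter-to-length ratios.  Branch counts still recover in
trees; length does not, and the package reports what it measures.

# Reproducibility

Every stochastic step takes an explicit integer seed and restores the
caller's RNG state.  `runPipeline()` fans a single global seed into
per-stage seeds via the fixed affine rule
`(seed * 1000003 + stage * 7919) mod (2^31 - 1)`, so any stage can be
re-run independently; the run directory contains the config echo, its
MD5 hash, the stage seeds and the package version, and a given config
and seed reproduce every artifact byte for byte (asserted by a test).
Rasters are exported as 32-bit TIFF normalised to [0,1] with the scale
recorded in a JSON sidecar, because the TIFF float path clamps to that
range.

Problem sizes used by the test and acceptance suites — chosen as the
smallest sizes at which each property is stable: trajectory laws at
1,024–65,536 pulses; density maps at 256–512 px; phantom recovery at
512 px; acquisition/reconstruction comparisons at 256 px with the full
33,332-pulse frame; the noisy unmixing experiment at 128 px over 10
seeds; the end-to-end pipeline determinism check at 128 px with an
8,334-pulse frame.
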