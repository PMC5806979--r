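---
title: "Measuring velopharyngeal motion with range images and a virtual grid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring velopharyngeal motion with range images and a virtual grid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(velogrid)
```

## The measurement problem

Velopharyngeal closure — the soft palate (velum) lifting against the
pharyngeal walls — separates the oral and nasal cavities during speech.
Conventional nasopharyngoscopy shows this motion but only qualitatively, and
the velopharynx offers almost no reliable anatomical landmarks, so classic
point-tracking kinematics do not transfer. `velogrid` implements a
landmark-free alternative built around a stereo endoscope with a projected
lattice pattern: reconstruct the soft-palate surface as a *range image*
(a raster whose pixels carry 3D millimetre coordinates) for every video frame,
parameterize an arbitrary quadrangle of mucosa with a virtual 5 × 5 grid, and
summarize the 36 grid intersections' 3D trajectories with a small number of
interpretable statistics: principal-component motion modes, the maximum shift
of the grid's centre of gravity (CoG) during sustained /a/ phonation, a
Mann–Whitney U comparison of that shift between groups, and a two-class linear
discriminant on the first two component scores.

Every stage is exercisable without hardware through a synthetic
deforming-surface renderer with analytic ground truth, which is also how the
package validates itself.

## From video to range images

**Splitting and deinterlacing.** Composite stereo video (side-by-side or
field-interleaved packing, configurable — the capture hardware defines a
signal, not a file layout) is split into per-camera sequences and the
half-height interlaced fields are restored to full height by linear
interpolation: field lines are kept on alternate rows, missing rows are the
mean of their vertical neighbours, and the final boundary row is replicated.
Deinterlacing precedes rectification and matching because the matcher assumes
full vertical resolution.

**Camera model.** Each camera follows the Tsai pinhole-with-radial-distortion
model: effective focal length $f$ (mm), first-order radial coefficient
$\kappa_1$ (mm$^{-2}$), image centre $(c_x, c_y)$, horizontal scale $s_x$ and
pixel pitch $(d_x, d_y)$ (mm/px). Pixel coordinates are 0-based, origin at the
top-left pixel centre, $x$ rightward, $y$ downward — stated once here and used
everywhere. The radial model maps *ideal* to *distorted* sensor coordinates in
closed form, $x_d = x_u (1 + \kappa_1 r_u^2)$; projection is therefore closed
form and undistortion is a fixed-point inversion (round-trip error below
$10^{-6}$ px for $|\kappa_1 r^2| < 0.5$). Calibration accepts either a config
file or a correspondence table; estimation uses Tsai's radial-alignment
constraint (planar and non-coplanar variants both provided, since nothing
constrains which target a given lab uses) followed by Levenberg–Marquardt
refinement of pose, $f$ and $\kappa_1$ with a $10^{-10}$ cost-decrease
tolerance and at most 200 iterations — desk-scale problems converge long
before. Degenerate geometry and points at or behind the camera plane raise
errors rather than returning `NaN`: in a measurement pipeline, failing loudly
beats propagating silent garbage.

**Rectification.** A shared rectifying rotation aligns the new x-axis with the
baseline so corresponding epipolar lines fall on equal rows and disparity is
purely horizontal; remapping samples the source images through the full
distortion model, performing distortion correction and row alignment in one
resampling pass. An already fronto-parallel rig rectifies to the identity.

**Stereo matching.** Disparities come from per-scanline dynamic programming
with the sampling-insensitive pixel dissimilarity: a pixel's intensity is
compared against the other scanline linearly interpolated over ±half a pixel,
symmetrized by taking the minimum of both directions. A monotone matching $M$
is scored

$$\sum_{(x_l, x_r) \in M} d(x_l, x_r) \;-\; \kappa_r |M| \;+\; \kappa_{occ} N_{occ},$$

where $N_{occ}$ counts maximal runs of unmatched pixels in either scanline
(boundary runs included). The DP is globally optimal for this objective — the
test suite proves it against exhaustive enumeration of every legal matching on
short scanlines. Defaults $\kappa_{occ} = 25$, $\kappa_r = 5$ on a 0–255
intensity scale are the cited technique's published constants; nothing in the
application fixes them, so they are exposed in the configuration. Occluded
pixels are masked invalid, never interpolated — hole handling happens later at
grid sampling under explicit rules. An optional inter-scanline consistency
filter (median check against vertical neighbours) is available but off by
default, keeping the testable core the pure per-row DP. The projected lattice
is treated purely as surface texture by the matcher. Subpixel disparity
refinement is deliberately out of scope; its absence is compensated
geometrically (see the rig design below).

**Triangulation.** For a rectified rig with focal length $f_x$ (px) and
baseline $B$, a valid disparity $d$ gives $z = f_x B / d$,
$x = (u - c_x)\,z/f_x$, $y = (v - c_y)\,z/f_y$, all in millimetres in the left
rectified camera frame — the single world frame every downstream coordinate
inherits. Timestamps are `frame_index / fps`. Surfaces whose median depth
leaves the endoscope's validated 20–60 mm working envelope trigger a warning.

## The virtual grid and what it measures

A quadrangle is drawn on the soft palate (below the hard palate, above the
uvula, excluding the lateral pharyngeal wall); its four corners are
canonicalized to clockwise-from-top-left order, and bilinear interpolation of
the corners at parameters $(j/n, i/n)$ divides it equally into an
$n \times n$ grid — $n = 5$ gives the standard 36 intersections. The grid is
defined **once**, in image coordinates on the reference (rest) frame, and held
fixed; each frame's 3D samples are bilinear interpolations of the range image
at those fixed pixel positions (a node needs at least 2 of its 4 raster
neighbours valid; weights renormalize over the valid subset). Nodes invalid in
a frame are filled from the nearest valid frame of the same node; nodes never
valid anywhere are dropped from all frames, shrinking the observation
dimensionality rather than inventing geometry. The rest frame defaults to the
first frame (pre-phonation posture) and is overridable.

A fixed image grid is an *Eulerian* measurement: it reports the motion of the
surface seen under fixed viewing rays, not of material tissue points. The two
differ whenever motion has a component tangential to the surface — the fixed
grid cannot see that component, so apparent displacement underestimates
tissue displacement. The synthetic generator therefore exposes both truths:
`ground_truth_trajectory(mode = "material")` follows fixed surface points
(with uniform spatial weighting its maximum CoG shift equals the injected
amplitude exactly), while `mode = "observed"` re-intersects the fixed pixel
rays with the deformed surface each frame — the correct reference for
validating the pipeline, because it shares the pipeline's measurement model
while being free of stereo and quantization error. Whether the original
instrument's grid was fixed or tissue-tracking is not documented anywhere we
know of; the fixed-grid reading is the simplest consistent one, and the
material/observed distinction quantifies exactly what is at stake in that
choice.

The per-frame CoG is the unweighted mean of valid node coordinates, and the
motion magnitude summary is the maximum Euclidean distance of the CoG from its
rest-frame position.

## Motion modes and group statistics

Each frame's 36 × 3 configuration, expressed relative to the rest frame, is
flattened node-major into a 108-vector; principal components of the
column-centred observation matrix (computed by SVD) give orthonormal loading
rows, descending eigenvalues and per-frame scores. The standard configuration
retains $k = 12$ component scores per frame. Eigenvector sign is inherently
arbitrary, which breaks pooling and visual comparison across subjects; each
loading is oriented so the score at the frame of maximum CoG displacement is
non-negative. PCA is fit per subject (each recording), matching how
per-subject score trajectories are visualized; pooled fits are possible by
concatenating motion matrices. `reconstruct_mode_shape()` renders the palate
configuration at chosen scores (±2 SD by convention) for mode visualization.

Group comparison of maximum CoG shifts uses the Mann–Whitney U test, two-sided
throughout, with no hard-coded significance level: exact enumeration when the
combined sample is at most 25 without ties, otherwise the normal approximation
with tie and continuity corrections. The two-class linear discriminant on
(PCS1, PCS2) uses the pooled covariance with proportional priors and reports
resubstitution accuracy — consistent with the classic software era — plus
leave-one-subject-out accuracy when subject identifiers are available, because
frame-level resubstitution is optimistic. A singular pooled covariance is
regularized by adding $10^{-8}\,\mathrm{tr}(\Sigma)/2$ to the diagonal.

## The synthetic scene

The generator emulates the study conditions: a smooth textured patch
(28 × 20 mm) at base depth $z_0 = 40$ mm — the centre of the 20–60 mm
validated envelope — deforming with peak amplitude $A = 4.7$ mm (the centre of
the reported shift magnitudes) along the posterior-superior analogue
$(0, -\sin 45^\circ, -\cos 45^\circ)$ in the camera frame, over 30 frames at
30 fps. The temporal envelope rises smoothly over the first 30 % of the
recording, holds, and falls back (zero at frame one, so the first frame is a
genuine rest frame); the spatial weighting is a smooth centred bump
$\sin(\pi s)\sin(\pi t)$, with a uniform option for closed-form checks.

The default rig is fronto-parallel: $f = 4$ mm, 0.01 mm pixel pitch (400 px
focal length), 320 × 240 raster, $\kappa_1 = 0.002$ mm$^{-2}$, baseline 8 mm.
The baseline is a deliberate design choice: with integer disparities the depth
quantum is $z^2 d_x / (f B)$, i.e. 0.5 mm at 40 mm depth, which averaging over
36 grid nodes brings into the sub-0.2 mm class that the instrument's
validation reported — the physical endoscope's stereo geometry is unpublished,
so the package states its own. Texture is surface-attached (a smooth lattice
plus two incommensurate sinusoids so every neighbourhood carries horizontal
gradient) rather than a projected moving pattern: the matcher uses the pattern
only as texture, and surface-attached texture gives exact ground-truth
correspondence. Rendering is per-pixel ray–surface intersection through the
full distortion model, solved by fixed-point iteration on the patch
parameters (exact on the base plane, a few iterations suffice for the smooth
bump); seeded Gaussian pixel noise (sd 2 on the 0–255 scale) is added last, so
two seeds share identical geometry and differ only in noise.

What the generator does **not** emulate: specular highlights and wet mucosa
reflectance, tissue-texture variation, motion blur, head or endoscope motion,
occlusion by the uvula, and photometric differences between the two cameras.
Passing the recovery studies therefore demonstrates the correctness of the
geometry and statistics chain under realistic noise and quantization — not
robustness to every clinical imaging artifact.

**Two-mode scenes.** For mode-separation studies a weaker secondary mode
(superior direction, by default) can be injected. Principal components can
only recover *orthogonal* displacement patterns, and the posterior-superior
and superior directions are 45° apart; the generator therefore
Gram–Schmidt-orthogonalizes the secondary pattern against the primary before
injection, and scales the secondary temporal profile ($\sin 2\pi \hat t$,
temporally orthogonal to the primary envelope over the recording) to the
primary envelope's standard deviation, so the injected component variance
ratio is governed by the amplitude ratio alone. With a 2:1 amplitude ratio the
eigenvalue ratio is 4 by construction, which the recovery study verifies to
within 15 % under sensor-scale coordinate noise.

## Numerical choices and degenerate inputs

* Distortion inversion: fixed point, tolerance $10^{-10}$, max 100 iterations;
  failure raises an error.
* Calibration refinement: Levenberg–Marquardt, `ftol = ptol = 1e-10`, max 200
  iterations; the rotation is re-projected onto the orthonormal manifold
  afterwards (invariants enforced to $10^{-9}$).
* DP ties are broken toward the first transition examined (contiguous match,
  then single-gap, then double-gap predecessors); any tie-broken optimum
  attains the same global cost, which is the tested contract.
* Requesting more components than `min(T - 1, 108)` warns (`rank deficiency`)
  and returns the achievable number.
* Degenerate ROIs (collinear or non-convex corners), empty frames, unequal
  scanlines, unsynchronized sequences and out-of-raster grid nodes all raise
  typed errors at the earliest stage that can detect them.

## Validation problem sizes

The shipped studies run at sizes chosen to make every check exhaustive or
well-powered while remaining desk-scale: DP optimality against full
enumeration on 100 random scanlines (length ≤ 8, disparity ≤ 3, thousands of
matchings each); calibration recovery on 20 random camera configurations
(tolerances: $f$ within 0.1 %, $\kappa_1$ within 1 %, translation within
0.01 mm); end-to-end metrology on 20 rendered 30-frame recordings of the
default scene (recovered maximum CoG shift within ±0.3 mm of the observed-mode
truth, first-mode cosine ≥ 0.98); two-mode recovery over 100 noisy replicates;
Mann–Whitney exactness for all group sizes up to 6 against full enumeration
plus a 1000-replicate type-I study at $n = 10$ vs 10; and a chance-level
discriminant check at 600 frames.

## Known limitations

Integer disparities bound single-pixel depth resolution by the rig geometry;
the CoG statistic recovers sub-quantum accuracy only through spatial
averaging. The fixed image grid measures apparent (Eulerian) motion, as
discussed above. Scanline DP enforces ordering along rows and treats rows
independently; strongly slanted or self-occluding surfaces would violate its
assumptions, though the velopharyngeal working range does not approach that
regime. The discriminant is linear and two-class by design. None of the
statistics model within-subject temporal correlation; group inference treats
one summary value per subject, which is the intended use.
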