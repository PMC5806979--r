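# velogrid

Four-dimensional, landmark-free measurement of soft-palate (velar) motion from
stereo endoscopic video.

Clinically, velopharyngeal function — the velum sealing the nasal cavity
during speech — is usually assessed by nasopharyngoscopy, which is qualitative
only. The velopharynx has almost no trackable anatomical landmarks, so
`velogrid` instead reconstructs the whole visible soft-palate surface in 3D
every frame and quantifies its motion through a fixed virtual grid. The
package is aimed at speech/cleft-palate researchers and at anyone who needs a
fully testable reference implementation of the underlying measurement chain:

1. **Range imaging** — split composite stereo video, deinterlace by linear
   interpolation, correct lens distortion with the Tsai camera model
   (calibration from a config file or from target correspondences), rectify,
   match scanlines with the sampling-insensitive Birchfield–Tomasi dynamic
   programming, and triangulate to per-frame range images (mm).
2. **Virtual grid** — divide a quadrangle drawn on the soft palate equally
   into a 5 × 5 grid and sample its 36 intersections in 3D every frame.
3. **Motion statistics** — principal-component motion modes of the 36-point
   trajectories, maximum centre-of-gravity (CoG) shift during /a/ phonation,
   Mann–Whitney U group comparison, and a linear discriminant on the first
   two component scores.
4. **Synthetic scene** — a deforming textured patch rendered through the full
   camera model with analytic ground truth, so the entire pipeline is
   validated end to end without hardware.

## The core quantities

With rectified focal length $f_x$ (px) and baseline $B$ (mm), a disparity $d$
triangulates to $z = f_x B / d$. Scanline matchings $M$ minimize

$$\sum_{(x_l,x_r)\in M} d_{BT}(x_l, x_r) - \kappa_r |M| + \kappa_{occ} N_{occ},$$

globally per row (verified against exhaustive enumeration). Grid node $(i,j)$
is the bilinear blend of the ROI corners at $(j/n, i/n)$; for frame $t$ the
flattened, rest-relative configuration $\mathbf{x}_t \in \mathbb{R}^{108}$
feeds a PCA whose first twelve scores summarize the motion, and

$$\text{max CoG shift} = \max_t \lVert \bar{\mathbf{p}}_t - \bar{\mathbf{p}}_{rest} \rVert$$

is the scalar motion magnitude compared between groups.

## Worked example

Run the full chain on the default synthetic recording (a 28 × 20 mm patch at
40 mm depth, bulging 4.7 mm posterior-superiorly over 30 frames at 30 fps):

```r
library(velogrid)

cfg <- pipeline_config(out_dir = "velogrid_out", seed = 3)
res <- run_pipeline(cfg)

round(res$max_shift_mm, 2)
#> [1] 2.16
print(res$pca)
#> pca_model: 12 components over 30 frames; explained variance %: 97.6, 0.5, 0.4, 0.3, 0.2

truth <- ground_truth_trajectory(surface_params(), default_roi(), mode = "observed")
round(cog_shift(cog_trajectory(truth)), 2)
#> [1] 2.11
```

The recovered maximum CoG shift (2.16 mm) sits within a twentieth of a
millimetre of the analytic fixed-grid truth (2.11 mm), and one dominant motion
mode carries ~98 % of the variance — the injected single-mode deformation. The
apparent shift is smaller than the injected 4.7 mm tissue amplitude because a
fixed image grid measures motion along fixed viewing rays and cannot see the
tangential component; the methods vignette
(`vignettes/velopharyngeal-motion.Rmd`) discusses this Eulerian/material
distinction, all parameter defaults, and the generator's scope.

Intermediate artifacts (rectified range PFMs, the trajectory CSV, PCA
loadings/scores, mode shapes at ±2 SD, a manifest with a config hash) land
under `out_dir`, and reruns with the same configuration are bit-identical.

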