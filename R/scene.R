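#' Parameters of the synthetic deforming surface
#'
#' A smooth textured patch at endoscopic working depth whose interior bulges
#' along a dominant direction over the recording, emulating soft-palate
#' elevation during sustained /a/ phonation: a planar base patch at depth `z0`
#' displaced by `envelope(frame) * weight(s, t) * amplitude * direction`.
#' The temporal envelope rises smoothly from 0, holds near its peak, and falls
#' back (rise-hold-fall); the spatial weight is a smooth bump centred in the
#' patch (or uniform). A warning is raised for `z0` outside the validated
#' 20-60 mm endoscope working range.
#'
#' An optional weaker secondary mode with its own direction, amplitude, and
#' temporally orthogonal profile can be injected for mode-separation studies;
#' its flattened displacement pattern is orthogonalized against the primary
#' mode's (principal components can only recover orthogonal patterns).
#'
#' @param extent patch size (mm), length-2 (x, y).
#' @param z0 base depth, mm (20-60 expected).
#' @param direction unit 3-vector of the dominant displacement; the default is
#'   the posterior-superior analogue `(0, -sin 45, -cos 45)` in the camera
#'   frame (y down, z away).
#' @param amplitude peak displacement A, mm (>= 0); default 4.7.
#' @param n_frames frames recorded (default 30).
#' @param fps frames per second (default 30).
#' @param weight `"bump"` (sin(pi s) sin(pi t)) or `"uniform"`.
#' @param amplitude2,direction2 optional secondary mode (amplitude 0 disables).
#' @return an object of class `surface_params`.
#' @export
surface_params <- function(extent = c(28, 20), z0 = 40,
                           direction = c(0, -sin(pi / 4), -cos(pi / 4)),
                           amplitude = 4.7, n_frames = 30, fps = 30,
                           weight = c("bump", "uniform"),
                           amplitude2 = 0, direction2 = c(0, 0, -1)) {
  weight <- match.arg(weight)
  stopifnot(length(extent) == 2, all(extent > 0), amplitude >= 0,
            amplitude2 >= 0, n_frames >= 1, fps > 0)
  if (z0 < 20 || z0 > 60)
    warning("base depth ", z0, " mm is outside the validated 20-60 mm working range")
  structure(list(extent = extent, z0 = z0, direction = unitize(direction),
                 amplitude = amplitude, n_frames = as.integer(n_frames),
                 fps = fps, weight = weight,
                 amplitude2 = amplitude2, direction2 = unitize(direction2)),
            class = "surface_params")
}

# Rise-hold-fall envelope on normalized time in [0, 1]: smoothstep up over
# [0, 0.3], hold at 1 over [0.3, 0.7], smoothstep down over [0.7, 1].
# envelope(0) = 0 by construction.
phonation_envelope <- function(that) {
  smooth <- function(x) x * x * (3 - 2 * x)
  ifelse(that < 0.3, smooth(pmin(pmax(that / 0.3, 0), 1)),
         ifelse(that <= 0.7, 1, 1 - smooth(pmin(pmax((that - 0.7) / 0.3, 0), 1))))
}

# Temporally orthogonal profile for the secondary mode: zero at t = 0,
# zero centred-correlation with the primary envelope over a full recording.
secondary_profile <- function(that) sin(2 * pi * that)

frame_time <- function(params, frame) {
  if (params$n_frames == 1) return(0)
  (frame - 1) / (params$n_frames - 1)
}

spatial_weight <- function(params, s, t) {
  if (params$weight == "uniform") rep(1, length(s))
  else sin(pi * s) * sin(pi * t)
}

# Scale factor equalizing the secondary profile's sample variance (over the
# recording's frame grid) with the primary envelope's, so injected mode
# variances are governed by the amplitude ratio alone.
secondary_scale <- function(params) {
  that <- vapply(seq_len(params$n_frames), function(f) frame_time(params, f),
                 numeric(1))
  s1 <- stats::sd(phonation_envelope(that))
  s2 <- stats::sd(secondary_profile(that))
  if (s2 < 1e-12) return(1)
  s1 / s2
}

# Flattened-pattern orthogonalization of the secondary mode against the
# primary, evaluated pointwise: the secondary displacement is
# w(s,t) * (d2 - proj) with proj chosen so <w d1, w d2'> = 0 over the patch,
# which reduces to plain Gram-Schmidt on the direction vectors when the two
# modes share the spatial weight.
secondary_direction_orth <- function(params) {
  d1 <- params$direction; d2 <- params$direction2
  d2o <- d2 - sum(d2 * d1) * d1
  if (sqrt(sum(d2o^2)) < 1e-9) stop("secondary direction parallel to primary")
  unitize(d2o)
}

#' Evaluate the deforming surface at patch parameters (s, t)
#'
#' Deterministic closed form: base plane point plus
#' `envelope(frame) * weight(s, t) * amplitude * direction` (plus the
#' orthogonalized secondary mode if enabled).
#'
#' @param params a [surface_params()].
#' @param s,t patch parameters in \[0, 1\] (vectors of equal length).
#' @param frame 1-based frame index.
#' @return N x 3 matrix of world coordinates, mm (left camera frame).
#' @export
surface_point <- function(params, s, t, frame) {
  stopifnot(all(s >= 0 & s <= 1), all(t >= 0 & t <= 1))
  that <- frame_time(params, frame)
  base <- cbind((s - 0.5) * params$extent[1],
                (t - 0.5) * params$extent[2],
                params$z0)
  disp <- phonation_envelope(that) * spatial_weight(params, s, t) * params$amplitude
  out <- base + disp %o% params$direction
  if (params$amplitude2 > 0) {
    d2 <- secondary_direction_orth(params)
    disp2 <- secondary_scale(params) * secondary_profile(that) *
      spatial_weight(params, s, t) * params$amplitude2
    out <- out + disp2 %o% d2
  }
  out
}

#' Rendering parameters for the synthetic stereo camera pair
#'
#' @param rig a [stereo_rig()]; default [default_rig()].
#' @param texture_period lattice/texture period, px at the base depth (>= 2).
#' @param texture_contrast peak-to-peak texture contrast, intensity units.
#' @param noise_sd additive Gaussian pixel noise standard deviation,
#'   intensity units on the 0-255 scale (>= 0).
#' @param seed integer RNG seed for the pixel noise.
#' @return an object of class `render_params`.
#' @export
render_params <- function(rig = default_rig(), texture_period = 8,
                          texture_contrast = 60, noise_sd = 2, seed = 1) {
  stopifnot(texture_period >= 2, noise_sd >= 0)
  structure(list(rig = rig, texture_period = texture_period,
                 texture_contrast = texture_contrast, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "render_params")
}

#' Default synthetic stereo rig
#'
#' Fronto-parallel pair: f = 4 mm, pixel pitch 0.01 mm (400 px focal length),
#' 320 x 240 raster, baseline 8 mm, mild radial distortion
#' (kappa1 = 0.002 mm^-2). The baseline is chosen so the integer-disparity
#' depth quantum at 40 mm is 0.5 mm (`z^2 dx / (f B)`), which averaging over
#' the 36 grid nodes brings to the sub-0.2 mm class.
#'
#' @param kappa1 radial distortion coefficient for both cameras.
#' @param baseline inter-camera distance, mm.
#' @return a [stereo_rig()].
#' @export
default_rig <- function(kappa1 = 0.002, baseline = 8) {
  intr <- camera_intrinsics(f = 4, kappa1 = kappa1, cx = 160, cy = 120,
                            sx = 1, dx = 0.01, dy = 0.01,
                            width = 320, height = 240)
  stereo_rig(intr, camera_pose(diag(3), c(0, 0, 0)),
             intr, camera_pose(diag(3), c(-baseline, 0, 0)))
}

# Surface-attached texture: a smooth lattice (projected-pattern analogue)
# plus two incommensurate sinusoids so every neighbourhood carries horizontal
# intensity gradient for the matcher.
surface_texture <- function(params, render, s, t) {
  # period in patch parameter units, from px at z0 through the left camera
  il <- render$rig$left$intrinsics
  mm_per_px <- il$dx * params$z0 / il$f
  ps <- render$texture_period * mm_per_px / params$extent[1]
  pt <- render$texture_period * mm_per_px / params$extent[2]
  lat <- 0.5 * (cos(2 * pi * s / ps) + cos(2 * pi * t / pt))
  plaid <- sin(2 * pi * (s / (2.37 * ps) + t / (3.91 * pt)))
  127.5 + render$texture_contrast * (0.35 * lat + 0.3 * plaid)
}

# Intersect the viewing ray of each (undistorted) pixel with the deformed
# surface by fixed-point iteration on the patch parameters; exact for the
# base plane, converges in a few iterations for the smooth bump.
ray_surface_params <- function(params, frame, origin, xn, yn, iters = 12) {
  that <- frame_time(params, frame)
  e1 <- phonation_envelope(that) * params$amplitude
  d1 <- params$direction
  use2 <- params$amplitude2 > 0
  if (use2) {
    d2 <- secondary_direction_orth(params)
    e2 <- secondary_scale(params) * secondary_profile(that) * params$amplitude2
  }
  s <- rep(0.5, length(xn)); t <- rep(0.5, length(xn))
  for (it in seq_len(iters)) {
    sc <- pmin(pmax(s, 0), 1); tc <- pmin(pmax(t, 0), 1)
    w <- spatial_weight(params, sc, tc)
    dx <- e1 * w * d1[1]; dy <- e1 * w * d1[2]; dz <- e1 * w * d1[3]
    if (use2) {
      w2 <- e2 * w
      dx <- dx + w2 * d2[1]; dy <- dy + w2 * d2[2]; dz <- dz + w2 * d2[3]
    }
    z <- params$z0 + dz
    x <- origin[1] + (z - origin[3]) * xn
    y <- origin[2] + (z - origin[3]) * yn
    s <- (x - dx) / params$extent[1] + 0.5
    t <- (y - dy) / params$extent[2] + 0.5
  }
  inside <- s >= 0 & s <= 1 & t >= 0 & t <= 1
  z <- params$z0 + { # final depth from converged parameters
    sc <- pmin(pmax(s, 0), 1); tc <- pmin(pmax(t, 0), 1)
    w <- spatial_weight(params, sc, tc)
    dzz <- e1 * w * params$direction[3]
    if (use2) dzz <- dzz + e2 * w * d2[3]
    dzz
  }
  list(s = s, t = t, z = z, inside = inside)
}

#' Render one synthetic stereo frame with ground truth
#'
#' Per-pixel ray-surface intersection through the full camera model
#' (distortion included), surface-attached texture, and seeded Gaussian pixel
#' noise added last. Ground-truth depth (left camera) and disparity rasters
#' are emitted from the same geometry. Off-patch background is intensity 0
#' with invalid ground truth.
#'
#' @param params a [surface_params()].
#' @param render a [render_params()].
#' @param frame 1-based frame index.
#' @return list with `left`, `right` (noisy grayscale matrices, 0-255),
#'   `true_depth` (left-camera z, `NA` off-patch), `true_disparity`
#'   (px, `NA` off-patch), `valid` (logical matrix).
#' @export
render_stereo_pair <- function(params, render, frame) {
  rig <- render$rig
  if (is.null(rig$rect_rotation)) rig <- rectify(rig)
  render_one <- function(cam, center) {
    intr <- cam$intrinsics
    h <- intr$height; w <- intr$width
    u <- matrix(0:(w - 1), h, w, byrow = TRUE)
    v <- matrix(0:(h - 1), h, w)
    ideal <- undistort_pixel(intr, cbind(as.numeric(u), as.numeric(v)))
    xc <- (ideal[, 1] - intr$cx) * intr$dx / intr$sx / intr$f
    yc <- (ideal[, 2] - intr$cy) * intr$dy / intr$f
    # viewing directions in world coordinates, parameterized by world z
    dw <- t(cam$pose$R) %*% rbind(xc, yc, 1)
    xn <- dw[1, ] / dw[3, ]
    yn <- dw[2, ] / dw[3, ]
    hit <- ray_surface_params(params, frame, center, xn, yn)
    img <- numeric(h * w)
    tex <- surface_texture(params, render,
                           pmin(pmax(hit$s, 0), 1), pmin(pmax(hit$t, 0), 1))
    img[hit$inside] <- tex[hit$inside]
    list(img = matrix(img, h, w), z = matrix(hit$z, h, w),
         inside = matrix(hit$inside, h, w))
  }
  cL <- camera_center(rig$left$pose); cR <- camera_center(rig$right$pose)
  L <- render_one(rig$left, cL)
  R <- render_one(rig$right, cR)
  if (!any(L$inside) || !any(R$inside)) stop("empty render: surface out of field of view")
  fpx <- rect_focal_px(rig)
  true_depth <- L$z
  true_depth[!L$inside] <- NA_real_
  true_disp <- fpx["fx"] * rig$baseline / true_depth
  if (render$noise_sd > 0) {
    seed_state <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    set.seed(render$seed * 1000L + frame)
    L$img <- L$img + matrix(rnorm(length(L$img), 0, render$noise_sd), nrow(L$img))
    R$img <- R$img + matrix(rnorm(length(R$img), 0, render$noise_sd), nrow(R$img))
    if (!is.null(seed_state)) assign(".Random.seed", seed_state, .GlobalEnv)
  }
  list(left = pmin(pmax(L$img, 0), 255), right = pmin(pmax(R$img, 0), 255),
       true_depth = true_depth, true_disparity = true_disp, valid = L$inside)
}

#' Analytic ground-truth trajectory of the virtual grid
#'
#' Two truths are available for a grid defined (like the pipeline's) in image
#' coordinates on the reference frame of the left rectified camera:
#' \describe{
#'   \item{`"material"`}{each node is the surface point under its pixel at the
#'     reference frame, then followed through the deformation (Lagrangian;
#'     with uniform weight its maximum centre-of-gravity shift is exactly the
#'     amplitude).}
#'   \item{`"observed"`}{each frame re-intersects the fixed pixel ray with the
#'     deformed surface (Eulerian) — the same measurement model the range
#'     pipeline applies, free of stereo and quantization error; the apparent
#'     motion omits the tangential component of the true tissue motion.}
#' }
#'
#' @param params a [surface_params()].
#' @param roi a [quadrangle_roi()] in left rectified image pixels.
#' @param rig a [stereo_rig()]; default [default_rig()].
#' @param n grid subdivisions (default 5).
#' @param mode `"material"` or `"observed"`.
#' @return a `grid_trajectory` (all nodes valid).
#' @export
ground_truth_trajectory <- function(params, roi, rig = default_rig(), n = 5,
                                    mode = c("material", "observed")) {
  mode <- match.arg(mode)
  if (is.null(rig$rect_rotation)) rig <- rectify(rig)
  grid <- make_virtual_grid(roi, n)
  ri <- rig$rect_intrinsics
  fpx <- rect_focal_px(rig)
  origin <- camera_center(rig$left$pose)
  xn <- (grid$nodes[, 1] - ri$cx) / fpx["fx"]
  yn <- (grid$nodes[, 2] - ri$cy) / fpx["fy"]
  nn <- nrow(grid$nodes)
  nf <- params$n_frames
  pts <- array(NA_real_, c(nf, nn, 3))
  if (mode == "material") {
    ref <- ray_surface_params(params, 1, origin, xn, yn)
    if (!all(ref$inside)) stop("grid out of bounds: ROI leaves the patch")
    for (f in seq_len(nf)) pts[f, , ] <- surface_point(params, ref$s, ref$t, f)
  } else {
    for (f in seq_len(nf)) {
      hit <- ray_surface_params(params, f, origin, xn, yn)
      if (!all(hit$inside)) stop("grid out of bounds: ROI leaves the patch")
      pts[f, , 1] <- origin[1] + (hit$z - origin[3]) * xn
      pts[f, , 2] <- origin[2] + (hit$z - origin[3]) * yn
      pts[f, , 3] <- hit$z
    }
  }
  structure(list(points = pts, observed = matrix(TRUE, nf, nn),
                 timestamps = (seq_len(nf) - 1) / params$fps,
                 grid = grid, kept_nodes = seq_len(nn)),
            class = "grid_trajectory")
}

#' Default quadrangle ROI for the synthetic scene
#'
#' A slightly irregular quadrangle in the central part of the patch, placed in
#' the region visible to both cameras of [default_rig()] at the default depth
#' (left-image columns below the working disparity have no counterpart in the
#' right raster and cannot be matched).
#'
#' @return a [quadrangle_roi()].
#' @export
default_roi <- function() {
  quadrangle_roi(rbind(c(104, 55), c(250, 50), c(256, 188), c(98, 193)))
}

#' Simulate a full synthetic recording to disk
#'
#' Emits left/right PNG frame sequences, true-depth PFM rasters, `roi.json`,
#' the analytic truth trajectories (material and observed) as CSV, and a
#' scene manifest.
#'
#' @param params a [surface_params()].
#' @param render a [render_params()].
#' @param out_dir output directory.
#' @param roi a [quadrangle_roi()]; default [default_roi()].
#' @return `out_dir`, invisibly.
#' @export
simulate_scene <- function(params, render, out_dir, roi = default_roi()) {
  dir.create(file.path(out_dir, "left"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "right"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  for (f in seq_len(params$n_frames)) {
    fr <- render_stereo_pair(params, render, f)
    write_image(fr$left, file.path(out_dir, "left", sprintf("frame_%04d.png", f)))
    write_image(fr$right, file.path(out_dir, "right", sprintf("frame_%04d.png", f)))
    dep <- fr$true_depth; dep[is.na(dep)] <- -1
    write_pfm(dep, file.path(out_dir, "truth", sprintf("depth_%04d.pfm", f)))
  }
  write_roi(roi, file.path(out_dir, "roi.json"))
  write_calibration(render$rig, file.path(out_dir, "calib.yaml"))
  for (mode in c("material", "observed")) {
    tr <- ground_truth_trajectory(params, roi, render$rig, mode = mode)
    write_grid_trajectory(tr, file.path(out_dir, "truth",
                                        paste0("trajectory_", mode, ".csv")))
  }
  jsonlite::write_json(list(n_frames = params$n_frames, fps = params$fps,
                            z0 = params$z0, amplitude = params$amplitude,
                            seed = render$seed),
                       file.path(out_dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
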