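#' Tsai camera intrinsics
#'
#' Pinhole camera with first-order radial distortion, in Tsai's
#' parameterization: effective focal length `f` (mm), radial coefficient
#' `kappa1` (mm^-2), image centre (`cx`, `cy`) in pixels, horizontal scale
#' `sx`, and pixel pitch (`dx`, `dy`) in mm/pixel. Pixel coordinates are
#' 0-based, origin at the top-left pixel centre, x rightward, y downward.
#'
#' The distortion maps ideal (undistorted) sensor coordinates to distorted
#' ones: `xd = xu * (1 + kappa1 * ru^2)` with `ru^2 = xu^2 + yu^2` in mm.
#'
#' @param f effective focal length, mm (> 0).
#' @param kappa1 first-order radial distortion coefficient, mm^-2.
#' @param cx,cy image centre, pixels (within the raster).
#' @param sx horizontal scale factor (> 0).
#' @param dx,dy pixel pitch, mm/pixel (> 0).
#' @param width,height raster size, pixels.
#' @return an object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(f, kappa1 = 0, cx, cy, sx = 1, dx, dy,
                              width, height) {
  stopifnot(f > 0, dx > 0, dy > 0, sx > 0,
            cx >= 0, cx < width, cy >= 0, cy < height,
            width >= 1, height >= 1)
  structure(list(f = f, kappa1 = kappa1, cx = cx, cy = cy, sx = sx,
                 dx = dx, dy = dy, width = as.integer(width),
                 height = as.integer(height)),
            class = "camera_intrinsics")
}

#' Camera pose (world-to-camera rigid transform)
#'
#' @param R 3 x 3 rotation matrix (world to camera); must be orthonormal with
#'   determinant +1 within 1e-9.
#' @param T length-3 translation, mm.
#' @return an object of class `camera_pose`.
#' @export
camera_pose <- function(R = diag(3), T = c(0, 0, 0)) {
  R <- as.matrix(R); T <- as.numeric(T)
  stopifnot(all(dim(R) == c(3, 3)), length(T) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("R is not a proper rotation matrix")
  structure(list(R = R, T = T), class = "camera_pose")
}

#' Stereo rig of two calibrated cameras
#'
#' Derives the baseline (inter-camera centre distance) and leaves rectifying
#' rotations `NULL` until [rectify()] is called.
#'
#' @param left_intrinsics,right_intrinsics [camera_intrinsics()] per camera.
#' @param left_pose,right_pose [camera_pose()] per camera.
#' @return an object of class `stereo_rig`.
#' @export
stereo_rig <- function(left_intrinsics, left_pose, right_intrinsics, right_pose) {
  c1 <- camera_center(left_pose); c2 <- camera_center(right_pose)
  baseline <- sqrt(sum((c2 - c1)^2))
  stopifnot(baseline > 0)
  structure(list(left = list(intrinsics = left_intrinsics, pose = left_pose),
                 right = list(intrinsics = right_intrinsics, pose = right_pose),
                 baseline = baseline, rect_left = NULL, rect_right = NULL,
                 rect_rotation = NULL),
            class = "stereo_rig")
}

# Optical centre in world coordinates.
camera_center <- function(pose) as.numeric(-crossprod(pose$R, pose$T))

#' Calibration target correspondences
#'
#' @param world_points N x 3 matrix, mm.
#' @param image_points N x 2 matrix, observed (distorted) pixels.
#' @return an object of class `calibration_target` with a `planar` flag
#'   (auto-detected: all points within 1e-9 mm of a common Z plane).
#' @export
calibration_target <- function(world_points, image_points) {
  world_points <- as.matrix(world_points); image_points <- as.matrix(image_points)
  stopifnot(ncol(world_points) == 3, ncol(image_points) == 2,
            nrow(world_points) == nrow(image_points))
  planar <- diff(range(world_points[, 3])) < 1e-9
  n <- nrow(world_points)
  if (planar && n < 7) stop("calibration underdetermined: planar target needs >= 7 points")
  if (!planar && n < 11) stop("calibration underdetermined: non-coplanar target needs >= 11 points")
  structure(list(world_points = world_points, image_points = image_points,
                 planar = planar), class = "calibration_target")
}

# ---- projection --------------------------------------------------------

# Ideal sensor (mm) -> distorted sensor (mm), closed form.
distort_sensor <- function(xu, yu, kappa1) {
  s <- 1 + kappa1 * (xu^2 + yu^2)
  cbind(xu * s, yu * s)
}

#' Project world points through the Tsai camera model
#'
#' Rigid transform, perspective divide, first-order radial distortion, then
#' pixel mapping. With `kappa1 = 0` this is the ideal pinhole projection.
#'
#' @param intrinsics [camera_intrinsics()].
#' @param pose [camera_pose()].
#' @param world_point length-3 vector or N x 3 matrix, mm.
#' @return N x 2 matrix of distorted pixel coordinates (a length-2 vector for a
#'   single point).
#' @export
project <- function(intrinsics, pose, world_point) {
  single <- is.null(dim(world_point))
  P <- if (single) matrix(world_point, 1, 3) else as.matrix(world_point)
  cam <- P %*% t(pose$R) + matrix(pose$T, nrow(P), 3, byrow = TRUE)
  if (any(cam[, 3] <= 0)) stop("unprojectable point: camera-frame depth z <= 0")
  xu <- intrinsics$f * cam[, 1] / cam[, 3]
  yu <- intrinsics$f * cam[, 2] / cam[, 3]
  d <- distort_sensor(xu, yu, intrinsics$kappa1)
  px <- cbind(d[, 1] * intrinsics$sx / intrinsics$dx + intrinsics$cx,
              d[, 2] / intrinsics$dy + intrinsics$cy)
  if (single) px[1, ] else px
}

#' Invert the radial distortion on a pixel
#'
#' Fixed-point inversion of the radial model, returning the ideal (pinhole)
#' pixel position of an observed (distorted) pixel. Round-trip error against
#' the forward model is below 1e-6 px for physically plausible distortion
#' (`|kappa1 * r^2| < 0.5`).
#'
#' @param intrinsics [camera_intrinsics()].
#' @param pixel length-2 vector or N x 2 matrix of distorted pixels.
#' @param max_iter,tol iteration controls of the fixed-point solve.
#' @return ideal pixel coordinates, same shape as `pixel`.
#' @export
undistort_pixel <- function(intrinsics, pixel, max_iter = 100, tol = 1e-10) {
  single <- is.null(dim(pixel))
  px <- if (single) matrix(pixel, 1, 2) else as.matrix(pixel)
  xd <- (px[, 1] - intrinsics$cx) * intrinsics$dx / intrinsics$sx
  yd <- (px[, 2] - intrinsics$cy) * intrinsics$dy
  xu <- xd; yu <- yd
  if (intrinsics$kappa1 != 0) {
    converged <- FALSE
    for (i in seq_len(max_iter)) {
      s <- 1 + intrinsics$kappa1 * (xu^2 + yu^2)
      if (any(s <= 0)) stop("distortion inversion failed: non-positive radial factor")
      xn <- xd / s; yn <- yd / s
      if (max(abs(xn - xu), abs(yn - yu)) < tol) { xu <- xn; yu <- yn; converged <- TRUE; break }
      xu <- xn; yu <- yn
    }
    if (!converged) stop("distortion inversion failed: no convergence after ", max_iter, " iterations")
  }
  out <- cbind(xu * intrinsics$sx / intrinsics$dx + intrinsics$cx,
               yu / intrinsics$dy + intrinsics$cy)
  if (single) out[1, ] else out
}

# ---- Tsai calibration --------------------------------------------------

#' Calibrate a camera from target correspondences (Tsai two-stage method)
#'
#' Stage one solves the radial-alignment constraint for the rotation and the
#' in-plane translation (planar and non-coplanar variants), followed by a
#' linear estimate of `f` and `Tz`; stage two refines pose, `f` and `kappa1`
#' jointly by Levenberg-Marquardt on the reprojection residuals (cost-decrease
#' tolerance 1e-10, at most 200 iterations). Sensor parameters
#' (`cx`, `cy`, `sx`, `dx`, `dy`) are taken from `intrinsics_init` and held
#' fixed, as in the classic formulation.
#'
#' @param target a [calibration_target()].
#' @param intrinsics_init [camera_intrinsics()] carrying the fixed sensor
#'   parameters (its `f`/`kappa1` are ignored; they are estimated).
#' @return list with elements `intrinsics`, `pose`, and `rms` (reprojection
#'   root-mean-square error in pixels).
#' @export
calibrate_tsai <- function(target, intrinsics_init) {
  P <- target$world_points
  # degenerate geometry: points (projected to the target plane) must span 2D
  ctr <- scale(P, scale = FALSE)
  if (sum(svd(ctr)$d > 1e-9 * max(1, max(abs(P)))) < 2)
    stop("calibration underdetermined: degenerate (collinear) target geometry")
  ii <- intrinsics_init
  Xd <- (target$image_points[, 1] - ii$cx) * ii$dx / ii$sx
  Yd <- (target$image_points[, 2] - ii$cy) * ii$dy

  init <- if (target$planar) tsai_stage1_planar(P, Xd, Yd)
          else tsai_stage1_noncoplanar(P, Xd, Yd)

  # stage 2: LM over axis-angle pose, T, f, kappa1
  obs <- target$image_points
  resid_fun <- function(par) {
    R <- rodrigues_to_matrix(par[1:3])
    f <- abs(par[7])
    intr <- ii; intr$f <- max(f, 1e-6); intr$kappa1 <- par[8]
    pose <- structure(list(R = R, T = par[4:6]), class = "camera_pose")
    pred <- tryCatch(project(intr, pose, P), error = function(e) NULL)
    if (is.null(pred)) return(rep(1e6, 2 * nrow(P)))
    as.numeric(pred - obs)
  }
  par0 <- c(matrix_to_rodrigues(init$R), init$T, init$f, 0)
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-10, ptol = 1e-10))
  par <- fit$par
  R <- nearest_rotation(rodrigues_to_matrix(par[1:3]))
  intr <- camera_intrinsics(f = abs(par[7]), kappa1 = par[8], cx = ii$cx,
                            cy = ii$cy, sx = ii$sx, dx = ii$dx, dy = ii$dy,
                            width = ii$width, height = ii$height)
  pose <- camera_pose(R, par[4:6])
  pred <- project(intr, pose, P)
  rms <- sqrt(mean(rowSums((pred - obs)^2)))
  list(intrinsics = intr, pose = pose, rms = rms)
}

# Radial alignment stage, non-coplanar target: solves for r1/Ty, Tx/Ty, r2/Ty.
tsai_stage1_noncoplanar <- function(P, Xd, Yd) {
  A <- cbind(Yd * P[, 1], Yd * P[, 2], Yd * P[, 3], Yd,
             -Xd * P[, 1], -Xd * P[, 2], -Xd * P[, 3])
  v <- qr.solve(A, Xd)
  absTy <- 1 / sqrt(sum(v[5:7]^2))
  build <- function(sgn) {
    Ty <- sgn * absTy
    r1 <- v[1:3] * Ty; Tx <- v[4] * Ty; r2 <- v[5:7] * Ty
    r1 <- unitize(r1); r2 <- unitize(r2 - sum(r2 * r1) * r1)
    R <- rbind(r1, r2, c(crossprod_vec(r1, r2)))
    list(R = nearest_rotation(R), Tx = Tx, Ty = Ty)
  }
  pick_pose_sign(P, Xd, Yd, list(build(1), build(-1)))
}

# Radial alignment stage, planar target (Z = 0 for all points).
tsai_stage1_planar <- function(P, Xd, Yd) {
  A <- cbind(Yd * P[, 1], Yd * P[, 2], Yd, -Xd * P[, 1], -Xd * P[, 2])
  v <- qr.solve(A, Xd)
  r11p <- v[1]; r12p <- v[2]; Txp <- v[3]; r21p <- v[4]; r22p <- v[5]
  dd <- r11p * r22p - r12p * r21p
  Sr <- r11p^2 + r12p^2 + r21p^2 + r22p^2
  Ty2 <- if (abs(dd) > 1e-12) {
    (Sr - sqrt(max(Sr^2 - 4 * dd^2, 0))) / (2 * dd^2)
  } else {
    # a whole row/column of the 2x2 block vanished; use the nonzero pair
    1 / max(r11p^2 + r21p^2, r12p^2 + r22p^2)
  }
  absTy <- sqrt(Ty2)
  cands <- list()
  for (sgn in c(1, -1)) {
    Ty <- sgn * absTy
    r11 <- r11p * Ty; r12 <- r12p * Ty; Tx <- Txp * Ty
    r21 <- r21p * Ty; r22 <- r22p * Ty
    s13 <- sqrt(max(1 - r11^2 - r12^2, 0))
    s23 <- sqrt(max(1 - r21^2 - r22^2, 0))
    for (sa in c(1, -1)) for (sb in c(1, -1)) {
      r1 <- c(r11, r12, sa * s13); r2 <- c(r21, r22, sb * s23)
      if (abs(sum(r1 * r2)) > 1e-3 && s13 > 1e-8 && s23 > 1e-8) next
      r2o <- unitize(r2 - sum(r2 * r1) * unitize(r1))
      R <- rbind(unitize(r1), r2o, crossprod_vec(unitize(r1), r2o))
      cands[[length(cands) + 1]] <- list(R = nearest_rotation(R), Tx = Tx, Ty = Ty)
    }
  }
  pick_pose_sign(P, Xd, Yd, cands)
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Among candidate (R, Tx, Ty), pick the one whose linear (f, Tz) fit yields
# positive depth, positive f, and the smallest residual; returns full init.
pick_pose_sign <- function(P, Xd, Yd, cands) {
  best <- NULL
  for (cand in cands) {
    R <- cand$R
    x <- P %*% R[1, ] + cand$Tx
    y <- P %*% R[2, ] + cand$Ty
    w <- P %*% R[3, ]
    # distortion-free: Xd ~ f x / (w + Tz), Yd ~ f y / (w + Tz)
    A <- rbind(cbind(as.numeric(y), -Yd), cbind(as.numeric(x), -Xd))
    b <- c(Yd * w, Xd * w)
    sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
    if (is.null(sol)) next
    f <- sol[1]; Tz <- sol[2]
    if (f <= 0) next
    if (any(w + Tz <= 0)) next
    res <- sqrt(mean((A %*% sol - b)^2))
    if (is.null(best) || res < best$res)
      best <- list(R = R, T = c(cand$Tx, cand$Ty, Tz), f = f, res = res)
  }
  if (is.null(best)) stop("calibration underdetermined: no consistent pose found")
  best
}

# ---- rectification -----------------------------------------------------

#' Rectify a stereo rig
#'
#' Computes a shared rectifying rotation (new x-axis along the baseline, z-axis
#' near the mean viewing direction) so that, after remapping, corresponding
#' epipolar lines lie on the same image row and disparity is purely horizontal.
#' An already fronto-parallel rig yields identity rectifying rotations.
#'
#' @param rig a [stereo_rig()].
#' @return the rig with `rect_left`, `rect_right` (per-camera rotations applied
#'   to camera coordinates) and `rect_rotation` (world to rectified frame)
#'   filled in, plus `rect_intrinsics` (ideal pinhole used after remapping).
#' @export
rectify <- function(rig) {
  c1 <- camera_center(rig$left$pose); c2 <- camera_center(rig$right$pose)
  b <- c2 - c1
  stopifnot(sqrt(sum(b^2)) > 0)
  e1 <- unitize(b)
  zmean <- unitize(as.numeric(rig$left$pose$R[3, ] + rig$right$pose$R[3, ]))
  e3 <- zmean - sum(zmean * e1) * e1
  if (sqrt(sum(e3^2)) < 1e-9) stop("degenerate rig: baseline parallel to viewing direction")
  e3 <- unitize(e3)
  e2 <- crossprod_vec(e3, e1)
  Rn <- rbind(e1, e2, e3)            # world -> rectified frame
  rownames(Rn) <- NULL
  rig$rect_rotation <- Rn
  rig$rect_left <- Rn %*% t(rig$left$pose$R)    # left-camera coords -> rectified
  rig$rect_right <- Rn %*% t(rig$right$pose$R)
  il <- rig$left$intrinsics
  rig$rect_intrinsics <- camera_intrinsics(
    f = il$f, kappa1 = 0, cx = il$cx, cy = il$cy, sx = il$sx,
    dx = il$dx, dy = il$dy, width = il$width, height = il$height)
  rig
}

# Focal lengths of the rectified pinhole in pixel units.
rect_focal_px <- function(rig) {
  ri <- rig$rect_intrinsics
  c(fx = ri$f * ri$sx / ri$dx, fy = ri$f / ri$dy)
}

#' Project a world point into the rectified cameras
#'
#' @param rig a rectified [stereo_rig()] (after [rectify()]).
#' @param world_point length-3 vector or N x 3 matrix, mm (world frame).
#' @return list with `left` and `right` N x 2 pixel matrices in the rectified
#'   rasters.
#' @export
project_rectified <- function(rig, world_point) {
  if (is.null(rig$rect_rotation)) stop("rig is not rectified; call rectify() first")
  P <- if (is.null(dim(world_point))) matrix(world_point, 1, 3) else as.matrix(world_point)
  ri <- rig$rect_intrinsics
  fpx <- rect_focal_px(rig)
  c1 <- camera_center(rig$left$pose); c2 <- camera_center(rig$right$pose)
  proj <- function(center) {
    cam <- (P - matrix(center, nrow(P), 3, byrow = TRUE)) %*% t(rig$rect_rotation)
    if (any(cam[, 3] <= 0)) stop("unprojectable point: camera-frame depth z <= 0")
    cbind(fpx["fx"] * cam[, 1] / cam[, 3] + ri$cx,
          fpx["fy"] * cam[, 2] / cam[, 3] + ri$cy)
  }
  list(left = proj(c1), right = proj(c2))
}

#' Remap a captured stereo pair into rectified geometry
#'
#' For every rectified output pixel the corresponding viewing ray is rotated
#' into the original camera, projected through the full distortion model, and
#' the source image is sampled bilinearly. This simultaneously performs the
#' distortion correction and row alignment.
#'
#' @param left,right grayscale matrices from the two cameras.
#' @param rig a rectified [stereo_rig()].
#' @return list with rectified `left` and `right` matrices.
#' @export
rectify_pair <- function(left, right, rig) {
  if (is.null(rig$rect_rotation)) rig <- rectify(rig)
  ri <- rig$rect_intrinsics
  fpx <- rect_focal_px(rig)
  h <- ri$height; w <- ri$width
  u <- matrix(0:(w - 1), h, w, byrow = TRUE)
  v <- matrix(0:(h - 1), h, w)
  xn <- (u - ri$cx) / fpx["fx"]
  yn <- (v - ri$cy) / fpx["fy"]
  remap <- function(img, cam, Rrect) {
    intr <- cam$intrinsics
    # direction in original camera coords
    d1 <- t(Rrect) %*% rbind(as.numeric(xn), as.numeric(yn), 1)
    z <- d1[3, ]
    ok <- z > 1e-9
    xu <- intr$f * d1[1, ] / z
    yu <- intr$f * d1[2, ] / z
    dd <- distort_sensor(xu, yu, intr$kappa1)
    sx_px <- dd[, 1] * intr$sx / intr$dx + intr$cx
    sy_px <- dd[, 2] / intr$dy + intr$cy
    vals <- numeric(length(z))
    vals[ok] <- bilinear_sample(img, sx_px[ok], sy_px[ok])
    matrix(vals, h, w)
  }
  list(left = remap(left, rig$left, rig$rect_left),
       right = remap(right, rig$right, rig$rect_right))
}
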