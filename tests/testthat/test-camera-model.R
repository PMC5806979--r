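test_that("projection reproduces pinhole closed forms and the distortion model", {
  intr <- camera_intrinsics(f = 4, kappa1 = 0, cx = 100, cy = 100, sx = 1,
                            dx = 0.01, dy = 0.01, width = 200, height = 200)
  pose <- camera_pose(diag(3), c(0, 0, 40))
  # optical-axis point lands on the image centre
  expect_equal(project(intr, pose, c(0, 0, 0)), c(100, 100))
  # pinhole arithmetic: x = cx + (f * 1 / 40) / dx
  pose0 <- camera_pose(diag(3), c(0, 0, 0))
  expect_equal(project(intr, pose0, c(1, 0, 40)), c(110, 100))
  # distorted projection equals an independent straight-line implementation
  intr_k <- camera_intrinsics(f = 4, kappa1 = 0.002, cx = 100, cy = 100, sx = 1,
                              dx = 0.01, dy = 0.01, width = 200, height = 200)
  expect_equal(project(intr_k, pose0, c(1, 0, 40)),
               project_oracle(intr_k, diag(3), c(0, 0, 0), c(1, 0, 40)))
  set.seed(11)
  for (i in 1:20) {
    P <- c(runif(2, -4, 4), runif(1, 20, 60))
    expect_equal(project(intr_k, pose0, P),
                 project_oracle(intr_k, diag(3), c(0, 0, 0), P),
                 tolerance = 1e-12)
  }
  # points at or behind the camera plane fail loudly
  expect_error(project(intr, pose0, c(0, 0, -5)), "unprojectable")
  expect_error(project(intr, pose0, c(1, 1, 0)), "unprojectable")
})

test_that("distortion inversion is exact in the trivial cases and round-trips", {
  intr0 <- camera_intrinsics(f = 4, kappa1 = 0, cx = 100, cy = 100, sx = 1,
                             dx = 0.01, dy = 0.01, width = 200, height = 200)
  expect_equal(undistort_pixel(intr0, c(37.5, 123.25)), c(37.5, 123.25))
  intr <- camera_intrinsics(f = 4, kappa1 = 0.05, cx = 100, cy = 100, sx = 1,
                            dx = 0.01, dy = 0.01, width = 200, height = 200)
  # zero radius: the centre is a fixed point for any kappa1
  expect_equal(undistort_pixel(intr, c(100, 100)), c(100, 100))
  # round trip distort(undistort(p)) = p within 1e-6 px over the raster
  set.seed(21)
  px <- cbind(runif(1000, 0, 199), runif(1000, 0, 199))
  ud <- undistort_pixel(intr, px)
  xu <- (ud[, 1] - intr$cx) * intr$dx / intr$sx
  yu <- (ud[, 2] - intr$cy) * intr$dy
  s <- 1 + intr$kappa1 * (xu^2 + yu^2)
  back <- cbind(xu * s * intr$sx / intr$dx + intr$cx, yu * s / intr$dy + intr$cy)
  expect_lt(max(abs(back - px)), 1e-6)
})

test_that("Tsai calibration recovers noise-free generating parameters", {
  set.seed(5)
  for (planar in c(FALSE, TRUE)) {
    cfg <- random_camera_config(planar = planar)
    cal <- calibrate_tsai(calibration_target(cfg$world, cfg$pixels),
                          init_intrinsics())
    expect_lt(abs(cal$intrinsics$f - cfg$intrinsics$f) / cfg$intrinsics$f, 0.001)
    expect_lt(abs(cal$intrinsics$kappa1 - cfg$intrinsics$kappa1) /
                abs(cfg$intrinsics$kappa1), 0.01)
    expect_lt(sqrt(sum((cal$pose$T - cfg$pose$T)^2)), 0.01)
    # rotation invariants hold after refinement
    expect_lt(max(abs(crossprod(cal$pose$R) - diag(3))), 1e-9)
    expect_equal(det(cal$pose$R), 1, tolerance = 1e-9)
  }
})

test_that("calibration fits noisy and exact data at the expected residual levels", {
  set.seed(6)
  cfg <- random_camera_config()
  noisy <- cfg$pixels + matrix(rnorm(length(cfg$pixels), 0, 0.1), ncol = 2)
  cal <- calibrate_tsai(calibration_target(cfg$world, noisy), init_intrinsics())
  expect_lte(cal$rms, 0.2)
  # planar distortion-free target: exact model fit
  intr0 <- camera_intrinsics(f = 4, kappa1 = 0, cx = 160, cy = 120, sx = 1,
                             dx = 0.01, dy = 0.01, width = 320, height = 240)
  pose <- camera_pose(rodrigues_vec(c(0.05, -0.1, 0.02)), c(1, -2, 45))
  P <- cbind(runif(15, -12, 12), runif(15, -10, 10), 0)
  cal0 <- calibrate_tsai(calibration_target(P, project(intr0, pose, P)),
                         init_intrinsics())
  expect_lt(cal0$rms, 1e-8)
  # degenerate collinear geometry is refused
  Pc <- cbind(seq(-10, 10, length.out = 12), seq(-5, 5, length.out = 12), 0)
  expect_error(
    calibrate_tsai(calibration_target(Pc, project(intr0, pose, Pc)),
                   init_intrinsics()),
    "underdetermined")
})

test_that("rectification aligns epipolar lines onto common rows", {
  # fronto-parallel rig: rectifying rotations are the identity
  rig <- default_rig(kappa1 = 0)
  rr <- rectify(rig)
  expect_lt(max(abs(rr$rect_left - diag(3))), 1e-9)
  expect_lt(max(abs(rr$rect_right - diag(3))), 1e-9)
  # 2 degree relative rotation about the vertical axis
  R2 <- rodrigues_vec(c(0, 2 * pi / 180, 0))
  rig2 <- stereo_rig(rig$left$intrinsics, camera_pose(diag(3), c(0, 0, 0)),
                     rig$right$intrinsics,
                     camera_pose(R2, as.numeric(-R2 %*% c(8, 0, 0))))
  rig2 <- rectify(rig2)
  set.seed(31)
  W <- cbind(runif(100, -10, 10), runif(100, -8, 8), runif(100, 35, 45))
  pr <- project_rectified(rig2, W)
  expect_lt(max(abs(pr$left[, 2] - pr$right[, 2])), 0.1)
  # a world rectangle lands on pairwise equal rows
  rect <- rbind(c(-5, -4, 40), c(5, -4, 40), c(5, 4, 40), c(-5, 4, 40))
  prr <- project_rectified(rig2, rect)
  expect_lt(max(abs(prr$left[, 2] - prr$right[, 2])), 0.1)
})

test_that("calibration round-trips through the config file formats", {
  rig <- default_rig()
  tmp <- tempfile(fileext = ".yaml")
  write_calibration(rig, tmp)
  rig2 <- read_calibration(tmp)
  expect_equal(rig2$left$intrinsics$f, rig$left$intrinsics$f)
  expect_equal(rig2$right$pose$T, rig$right$pose$T)
  expect_equal(rig2$baseline, rig$baseline)
  # correspondence table round trip
  set.seed(41)
  P <- cbind(runif(12, -10, 10), runif(12, -8, 8), runif(12, -5, 5))
  px <- project(rig$left$intrinsics, camera_pose(diag(3), c(0, 0, 50)), P)
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(X = P[, 1], Y = P[, 2], Z = P[, 3],
                       u = px[, 1], v = px[, 2]), csv, row.names = FALSE)
  tgt <- read_correspondences(csv)
  expect_false(tgt$planar)
  expect_equal(tgt$world_points[, 1], P[, 1])
})
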