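test_that("equal division of a quadrangle yields the expected grid nodes", {
  sq <- quadrangle_roi(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  g <- make_virtual_grid(sq, 5)
  expect_equal(nrow(g$nodes), 36)                       # (5+1)^2 intersections
  expect_equal(sort(unique(round(g$nodes[, 1], 9))), seq(0, 1, 0.2))
  expect_equal(sort(unique(round(g$nodes[, 2], 9))), seq(0, 1, 0.2))
  # n = 1: just the corners
  g1 <- make_virtual_grid(sq, 1)
  expect_equal(nrow(g1$nodes), 4)
  expect_setequal(asplit(unname(g1$nodes), 1), asplit(unname(sq$corners), 1))
  # skewed quadrangle against hand-computed bilinear blends
  sk <- quadrangle_roi(rbind(c(0, 0), c(10, 0), c(12, 8), c(-2, 8)))
  g2 <- make_virtual_grid(sk, 2)
  expect_equal(nrow(g2$nodes), 9)
  blend <- function(s, t)
    (1 - s) * (1 - t) * c(0, 0) + s * (1 - t) * c(10, 0) +
      s * t * c(12, 8) + (1 - s) * t * c(-2, 8)
  for (i in 0:2) for (j in 0:2)
    expect_equal(unname(g2$nodes[i * 3 + j + 1, ]), blend(j / 2, i / 2))
  # corner nodes coincide with the ROI corners
  expect_equal(unname(g2$nodes[1, ]), unname(sk$corners["top_left", ]))
  expect_equal(unname(g2$nodes[9, ]), unname(sk$corners["bottom_right", ]))
})

test_that("ROI corners are canonicalized and degenerate input is refused", {
  pts <- rbind(c(10, 10), c(50, 12), c(52, 40), c(8, 38))
  for (perm in list(c(3, 1, 4, 2), c(2, 4, 1, 3), 4:1)) {
    roi <- quadrangle_roi(pts[perm, ])
    expect_equal(unname(roi$corners), unname(pts))
  }
  expect_error(quadrangle_roi(rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0))),
               "invalid ROI")
  # non-convex (dart) quadrilateral
  expect_error(quadrangle_roi(rbind(c(0, 0), c(10, 0), c(2, 2), c(0, 10))),
               "invalid ROI")
})

test_that("grid nodes translate with the ROI", {
  set.seed(12)
  pts <- random_quadrangle()
  g <- make_virtual_grid(quadrangle_roi(pts), 5)
  g2 <- make_virtual_grid(quadrangle_roi(pts + matrix(c(7, -3), 4, 2, byrow = TRUE)), 5)
  expect_equal(g2$nodes, g$nodes + matrix(c(7, -3), 36, 2, byrow = TRUE))
})

test_that("grid sampling interpolates valid range pixels with explicit rules", {
  # constant plane: every node reads the constant depth
  pts <- array(0, c(20, 30, 3)); pts[, , 3] <- 30
  ri <- structure(list(points = pts, valid = matrix(TRUE, 20, 30),
                       frame_index = 1L, timestamp = 0), class = "range_image")
  g <- make_virtual_grid(quadrangle_roi(rbind(c(3, 3), c(25, 4), c(26, 16), c(2, 15))), 5)
  s <- sample_grid_3d(ri, g)
  expect_true(all(s$valid))
  expect_equal(s$points[, 3], rep(30, 36), tolerance = 1e-6)
  # node centred on a 2x2 neighbourhood with z = {10, 10, 20, 20} reads 15
  pz <- array(NA_real_, c(2, 2, 3))
  pz[, , 1] <- 0; pz[, , 2] <- 0
  pz[, , 3] <- rbind(c(10, 10), c(20, 20))
  ri2 <- structure(list(points = pz, valid = matrix(TRUE, 2, 2),
                        frame_index = 1L, timestamp = 0), class = "range_image")
  centre <- structure(list(nodes = matrix(c(0.5, 0.5), 1), n = 1L,
                           node_index = cbind(row = 1, col = 1)),
                      class = "virtual_grid")
  sc <- sample_grid_3d(ri2, centre)
  expect_equal(unname(sc$points[1, 3]), 15)
  # fewer than 2 valid neighbours invalidates the node
  ri3 <- ri2; ri3$valid <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_false(sample_grid_3d(ri3, centre)$valid)
  # out-of-raster nodes are refused
  far <- structure(list(nodes = matrix(c(40, 40), 1), n = 1L,
                        node_index = cbind(row = 1, col = 1)),
                   class = "virtual_grid")
  expect_error(sample_grid_3d(ri2, far), "grid out of bounds")
})

test_that("centroid and shift obey their arithmetic and symmetry properties", {
  p <- matrix(rep(c(1, 2, 3), each = 36), 36, 3)
  expect_equal(grid_centroid(p), c(1, 2, 3))
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(unname(grid_centroid(cube)), c(0.5, 0.5, 0.5))
  set.seed(14)
  r <- matrix(rnorm(36 * 3), 36, 3)
  expect_equal(grid_centroid(r), colMeans(r))          # independent summation
  # translation equivariance and permutation invariance
  expect_equal(grid_centroid(r + 5), grid_centroid(r) + 5)
  expect_equal(grid_centroid(r[sample(36), ]), grid_centroid(r))
  expect_error(grid_centroid(r, valid = rep(FALSE, 36)), "empty frame")
})

test_that("centre-of-gravity shift measures peak displacement from rest", {
  mk_traj <- function(pts) {
    structure(list(points = pts, observed = matrix(TRUE, dim(pts)[1], dim(pts)[2]),
                   timestamps = (seq_len(dim(pts)[1]) - 1) / 30,
                   grid = NULL, kept_nodes = seq_len(dim(pts)[2])),
              class = "grid_trajectory")
  }
  base <- matrix(rnorm(36 * 3, sd = 2), 36, 3)
  static <- aperm(array(base, c(36, 3, 5)), c(3, 1, 2))
  expect_equal(cog_shift(cog_trajectory(mk_traj(static))), 0)
  # out to distance A and back
  A <- 3.7
  prof <- c(0, 0.5, 1, 0.5, 0) * A
  pts <- static
  for (f in 1:5) pts[f, , 1] <- pts[f, , 1] + prof[f]
  traj <- mk_traj(pts)
  expect_equal(cog_shift(cog_trajectory(traj)), A)
  expect_equal(cog_trajectory(traj)$shift[1], 0)       # zero at the rest frame
  # invariance under rigid rotation of the coordinate frame
  R <- rodrigues_vec(c(0.3, -0.2, 0.9))
  rot <- pts
  for (f in 1:5) rot[f, , ] <- pts[f, , ] %*% t(R)
  expect_equal(cog_shift(cog_trajectory(mk_traj(rot))),
               cog_shift(cog_trajectory(traj)))
})

test_that("trajectories fill gaps temporally and drop dead nodes", {
  # build a 3-frame range sequence by hand: node region invalid in frame 2
  mk_ri <- function(z, valid, f) {
    pts <- array(0, c(10, 10, 3)); pts[, , 3] <- z
    structure(list(points = pts, valid = valid, frame_index = f,
                   timestamp = (f - 1) / 30), class = "range_image")
  }
  v_all <- matrix(TRUE, 10, 10)
  v_hole <- v_all; v_hole[1:4, 1:4] <- FALSE             # kills top-left nodes
  rseq <- structure(list(images = list(mk_ri(30, v_all, 1), mk_ri(31, v_hole, 2),
                                       mk_ri(32, v_all, 3)),
                         fps = 30, rig = NULL), class = "range_sequence")
  g <- make_virtual_grid(quadrangle_roi(rbind(c(1, 1), c(8, 1), c(8, 8), c(1, 8))), 5)
  tr <- grid_trajectory(rseq, g)
  expect_length(tr$kept_nodes, 36)
  expect_false(all(tr$observed[2, ]))
  # the occluded node was filled from its nearest valid frame (1 or 3)
  filled <- which(!tr$observed[2, ])
  expect_true(all(tr$points[2, filled, 3] %in% c(30, 32)))
  expect_false(anyNA(tr$points))
  # tidy CSV round trip
  csv <- tempfile(fileext = ".csv")
  write_grid_trajectory(tr, csv)
  back <- read_grid_trajectory(csv)
  expect_equal(back$points, tr$points)
  expect_equal(back$observed, tr$observed)
})
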