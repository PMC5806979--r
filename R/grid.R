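#' Quadrangle region of interest on the reference frame
#'
#' The quadrangle is drawn on the soft palate below the hard palate, above the
#' uvula, excluding the lateral pharyngeal wall; anatomically it carries no
#' landmarks, so only its four pixel corners define it. Corners given in any
#' order are canonicalized by angular sort around their centroid to clockwise
#' (in image coordinates, y down) starting at the top-left corner (smallest
#' x + y). The quadrangle must be simple, convex, and of positive area.
#'
#' @param corners 4 x 2 matrix of pixel coordinates (0-based).
#' @return an object of class `quadrangle_roi` with canonicalized `corners`
#'   ordered top-left, top-right, bottom-right, bottom-left.
#' @export
quadrangle_roi <- function(corners) {
  corners <- as.matrix(corners)
  stopifnot(all(dim(corners) == c(4, 2)))
  ctr <- colMeans(corners)
  ang <- atan2(corners[, 2] - ctr[2], corners[, 1] - ctr[1])
  ord <- order(ang)                       # ascending angle = clockwise with y down
  corners <- corners[ord, , drop = FALSE]
  start <- which.min(rowSums(corners))
  corners <- corners[((start - 1 + 0:3) %% 4) + 1, , drop = FALSE]
  # convexity + positive area via consistent cross-product signs
  cr <- numeric(4)
  for (i in 1:4) {
    a <- corners[i, ]; b <- corners[i %% 4 + 1, ]; c <- corners[(i + 1) %% 4 + 1, ]
    e1 <- b - a; e2 <- c - b
    cr[i] <- e1[1] * e2[2] - e1[2] * e2[1]
  }
  if (any(abs(cr) < 1e-12) || length(unique(sign(cr))) != 1)
    stop("invalid ROI: corners must form a convex quadrilateral with positive area")
  dimnames(corners) <- list(c("top_left", "top_right", "bottom_right", "bottom_left"),
                            c("u", "v"))
  structure(list(corners = corners), class = "quadrangle_roi")
}

#' Divide a quadrangle equally into a virtual n x n grid
#'
#' Node `(i, j)` is the bilinear blend of the four corners at parameters
#' `(j/n, i/n)`; for the standard `n = 5` this yields the 36 grid
#' intersections. Nodes are ordered row-major from the top-left, and the
#' corner nodes coincide with the ROI corners.
#'
#' @param roi a [quadrangle_roi()].
#' @param n subdivisions per side (>= 1; default 5).
#' @return an object of class `virtual_grid`: `nodes` ((n+1)^2 x 2 pixel
#'   matrix), `n`, and `node_index` ((n+1)^2 x 2, the (row, col) of each node).
#' @export
make_virtual_grid <- function(roi, n = 5) {
  stopifnot(inherits(roi, "quadrangle_roi"), n >= 1)
  cs <- roi$corners
  m <- n + 1
  s <- rep((0:n) / n, times = m)   # column parameter, varies fastest
  t <- rep((0:n) / n, each = m)    # row parameter
  blend <- function(k) {
    (1 - s) * (1 - t) * cs["top_left", k] + s * (1 - t) * cs["top_right", k] +
      s * t * cs["bottom_right", k] + (1 - s) * t * cs["bottom_left", k]
  }
  nodes <- cbind(u = blend(1), v = blend(2))
  structure(list(nodes = nodes, n = as.integer(n),
                 node_index = cbind(row = rep(1:m, each = m), col = rep(1:m, times = m))),
            class = "virtual_grid")
}

#' Sample the virtual grid in 3D from one range image
#'
#' Each node samples `range_image$points` at its (fractional) pixel position
#' by bilinear interpolation over the valid pixels among its four raster
#' neighbours, with weights renormalized over the valid subset. A node with
#' fewer than two valid neighbours is marked invalid (temporal filling is
#' applied later, at trajectory assembly).
#'
#' @param range_image a `range_image`.
#' @param grid a [make_virtual_grid()] result.
#' @return list with `points` (N x 3 mm, `NA` rows where invalid) and `valid`
#'   (logical N).
#' @export
sample_grid_3d <- function(range_image, grid) {
  h <- dim(range_image$points)[1]; w <- dim(range_image$points)[2]
  x <- grid$nodes[, 1]; y <- grid$nodes[, 2]
  if (any(x < 0 | x > w - 1 | y < 0 | y > h - 1))
    stop("grid out of bounds: node pixel outside the raster")
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  fx <- x - x0; fy <- y - y0
  nb <- function(dx, dy) cbind(y0 + dy + 1, x0 + dx + 1)
  idx <- list(nb(0, 0), nb(1, 0), nb(0, 1), nb(1, 1))
  wts <- cbind((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  vmat <- vapply(idx, function(ij) range_image$valid[ij], logical(length(x)))
  if (length(x) == 1) vmat <- matrix(vmat, nrow = 1)
  nvalid <- rowSums(vmat)
  wts <- wts * vmat
  wsum <- rowSums(wts)
  pts <- matrix(NA_real_, length(x), 3)
  for (k in 1:3) {
    ch <- range_image$points[, , k]
    vals <- vapply(idx, function(ij) ch[ij], numeric(length(x)))
    if (length(x) == 1) vals <- matrix(vals, nrow = 1)
    vals[!vmat] <- 0
    pts[, k] <- rowSums(vals * wts) / wsum
  }
  valid <- nvalid >= 2 & wsum > 0
  pts[!valid, ] <- NA_real_
  colnames(pts) <- c("x", "y", "z")
  list(points = pts, valid = valid)
}

#' Track the virtual grid through a range sequence
#'
#' The grid is defined once, in image coordinates on the reference frame, and
#' held fixed; every frame's 3D samples are taken at those pixel positions.
#' Nodes invalid in a frame are filled from the nearest valid frame of the
#' same node; nodes never valid in any frame are dropped from all frames (with
#' a message), shrinking downstream dimensionality.
#'
#' @param rseq a `range_sequence`.
#' @param grid a [make_virtual_grid()] result.
#' @return an object of class `grid_trajectory`: `points` (T x N x 3 array,
#'   mm), `observed` (T x N logical: valid before temporal filling),
#'   `timestamps` (s), `grid`, `kept_nodes` (indices into the original grid).
#' @export
grid_trajectory <- function(rseq, grid) {
  nf <- length(rseq$images)
  stopifnot(nf >= 1)
  nn <- nrow(grid$nodes)
  pts <- array(NA_real_, c(nf, nn, 3))
  obs <- matrix(FALSE, nf, nn)
  for (i in seq_len(nf)) {
    s <- sample_grid_3d(rseq$images[[i]], grid)
    pts[i, , ] <- s$points
    obs[i, ] <- s$valid
  }
  never <- colSums(obs) == 0
  if (any(never))
    message("dropping ", sum(never), " grid node(s) never valid in any frame")
  kept <- which(!never)
  pts <- pts[, kept, , drop = FALSE]
  obs <- obs[, kept, drop = FALSE]
  # temporal nearest-valid fill per node
  for (j in seq_along(kept)) {
    bad <- which(!obs[, j])
    if (length(bad) == 0) next
    good <- which(obs[, j])
    for (i in bad) {
      src <- good[which.min(abs(good - i))]
      pts[i, j, ] <- pts[src, j, ]
    }
  }
  structure(list(points = pts, observed = obs,
                 timestamps = vapply(rseq$images, `[[`, numeric(1), "timestamp"),
                 grid = grid, kept_nodes = kept),
            class = "grid_trajectory")
}

#' Export a grid trajectory as a tidy CSV table
#'
#' @param traj a `grid_trajectory`.
#' @param path output CSV (columns: frame, node_row, node_col, x_mm, y_mm,
#'   z_mm, valid).
#' @return `path`, invisibly.
#' @export
write_grid_trajectory <- function(traj, path) {
  nf <- dim(traj$points)[1]; nn <- dim(traj$points)[2]
  ni <- traj$grid$node_index[traj$kept_nodes, , drop = FALSE]
  df <- data.frame(frame = rep(seq_len(nf), each = nn),
                   node_row = rep(ni[, "row"], times = nf),
                   node_col = rep(ni[, "col"], times = nf),
                   x_mm = as.numeric(t(traj$points[, , 1])),
                   y_mm = as.numeric(t(traj$points[, , 2])),
                   z_mm = as.numeric(t(traj$points[, , 3])),
                   valid = as.logical(t(traj$observed)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a grid trajectory written by [write_grid_trajectory()]
#' @param path CSV path.
#' @return a `grid_trajectory` (with a reconstructed node index; pixel node
#'   positions are not stored in the CSV).
#' @export
read_grid_trajectory <- function(path) {
  df <- read.csv(path)
  frames <- sort(unique(df$frame))
  keys <- unique(df[df$frame == frames[1], c("node_row", "node_col")])
  nf <- length(frames); nn <- nrow(keys)
  pts <- array(NA_real_, c(nf, nn, 3))
  obs <- matrix(FALSE, nf, nn)
  for (i in seq_len(nf)) {
    sub <- df[df$frame == frames[i], ]
    pts[i, , 1] <- sub$x_mm; pts[i, , 2] <- sub$y_mm; pts[i, , 3] <- sub$z_mm
    obs[i, ] <- sub$valid
  }
  structure(list(points = pts, observed = obs,
                 timestamps = (frames - 1) / 30,
                 grid = list(node_index = as.matrix(keys), n = NA_integer_),
                 kept_nodes = seq_len(nn)),
            class = "grid_trajectory")
}

#' Centre of gravity of one frame's grid sample
#'
#' @param points N x 3 matrix of node coordinates (mm); rows may be `NA`.
#' @param valid logical vector (default: rows without `NA`).
#' @return length-3 centroid (unweighted mean over valid nodes), mm.
#' @export
grid_centroid <- function(points, valid = NULL) {
  points <- as.matrix(points)
  if (is.null(valid)) valid <- stats::complete.cases(points)
  if (!any(valid)) stop("empty frame: no valid grid nodes")
  colMeans(points[valid, , drop = FALSE])
}

#' Centre-of-gravity trajectory of a grid trajectory
#'
#' @param traj a `grid_trajectory`.
#' @param rest_frame 1-based index of the rest (pre-phonation) frame; default
#'   the first frame.
#' @return an object of class `cog_trajectory`: `centroids` (T x 3 mm),
#'   `shift` (T, Euclidean distance from the rest centroid; zero at
#'   `rest_frame`), `rest_frame`, `timestamps`.
#' @export
cog_trajectory <- function(traj, rest_frame = 1) {
  nf <- dim(traj$points)[1]
  stopifnot(rest_frame >= 1, rest_frame <= nf)
  cent <- t(vapply(seq_len(nf), function(i) grid_centroid(traj$points[i, , ]),
                   numeric(3)))
  shift <- sqrt(rowSums((cent - matrix(cent[rest_frame, ], nf, 3, byrow = TRUE))^2))
  structure(list(centroids = cent, shift = shift,
                 rest_frame = as.integer(rest_frame),
                 timestamps = traj$timestamps),
            class = "cog_trajectory")
}

#' Maximum centre-of-gravity shift during phonation
#'
#' @param cog a [cog_trajectory()].
#' @return maximum over frames of the Euclidean distance from the rest-frame
#'   centroid, mm.
#' @export
cog_shift <- function(cog) {
  stopifnot(inherits(cog, "cog_trajectory"), length(cog$shift) >= 2)
  max(cog$shift)
}
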