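`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bilinearly sample an image at fractional pixel positions
#'
#' @param img numeric matrix (rows = y, cols = x).
#' @param x,y 0-based pixel coordinates (vectors of equal length). Positions
#'   outside the raster are clamped to the border.
#' @return numeric vector of sampled intensities.
#' @keywords internal
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x1 + 1)]
  i01 <- img[cbind(y1 + 1, x0 + 1)]
  i11 <- img[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i10) + fy * ((1 - fx) * i01 + fx * i11)
}

#' Convert a colour array to grayscale by the standard luminance weights
#'
#' @param img matrix (returned unchanged) or H x W x 3 array.
#' @return numeric matrix.
#' @keywords internal
to_grayscale <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Unit-norm helper; errors on a zero vector.
unitize <- function(v) {
  n <- sqrt(sum(v^2))
  stopifnot(n > 0)
  v / n
}

#' Rotation matrix from an axis-angle (Rodrigues) vector
#' @param r length-3 numeric; direction = axis, norm = angle (radians).
#' @return 3 x 3 rotation matrix.
#' @keywords internal
rodrigues_to_matrix <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) return(diag(3))
  k <- r / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Axis-angle vector from a rotation matrix
#' @param R 3 x 3 rotation matrix.
#' @return length-3 numeric Rodrigues vector.
#' @keywords internal
matrix_to_rodrigues <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(max(ct, -1), 1)
  th <- acos(ct)
  if (th < 1e-12) return(c(0, 0, 0))
  if (abs(pi - th) < 1e-6) {
    # near 180 degrees: extract axis from R + I
    M <- (R + diag(3)) / 2
    k <- sqrt(pmax(diag(M), 0))
    # fix signs from off-diagonals
    i <- which.max(k)
    if (i == 1) { k[2] <- M[1, 2] / k[1]; k[3] <- M[1, 3] / k[1] }
    if (i == 2) { k[1] <- M[1, 2] / k[2]; k[3] <- M[2, 3] / k[2] }
    if (i == 3) { k[1] <- M[1, 3] / k[3]; k[2] <- M[2, 3] / k[3] }
    return(unitize(k) * th)
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
  ax * th
}

# Project a nearly-orthonormal matrix onto the closest rotation (SVD polar).
nearest_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}
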