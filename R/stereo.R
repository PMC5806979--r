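#' Matching parameters for the scanline stereo matcher
#'
#' Defaults follow the cited dynamic-programming technique's published
#' constants on a 0-255 intensity scale: occlusion penalty 25, match reward 5.
#'
#' @param max_disparity maximum disparity searched, px (>= 1).
#' @param kappa_occ occlusion penalty, intensity units (> 0); charged once per
#'   maximal run of unmatched pixels in either image.
#' @param kappa_r match reward, intensity units (>= 0); subtracted per match.
#' @param interrow_filter logical; optional inter-scanline consistency filter
#'   (default off, keeping the pure per-row DP): pixels whose disparity
#'   deviates from the median of their vertical neighbours by more than 1 px
#'   are marked invalid.
#' @return an object of class `match_params`.
#' @export
match_params <- function(max_disparity = 96, kappa_occ = 25, kappa_r = 5,
                         interrow_filter = FALSE) {
  stopifnot(max_disparity >= 1, kappa_occ > 0, kappa_r >= 0)
  structure(list(max_disparity = as.integer(max_disparity),
                 kappa_occ = kappa_occ, kappa_r = kappa_r,
                 interrow_filter = isTRUE(interrow_filter)),
            class = "match_params")
}

#' Sampling-insensitive pixel dissimilarity
#'
#' Measures how well left pixel `xl` matches right pixel `xr` while remaining
#' insensitive to half-pixel sampling: the distance from one pixel's intensity
#' to the other signal linearly interpolated over +/- half a pixel, symmetrized
#' by taking the minimum of the two directions. Always non-negative and never
#' larger than the plain absolute intensity difference.
#'
#' @param left_row,right_row numeric intensity vectors (one rectified scanline
#'   each).
#' @param xl,xr 0-based pixel indices; both must have neighbours on each side
#'   (`1 <= x <= length - 2`).
#' @return scalar dissimilarity in intensity units.
#' @export
pixel_dissimilarity <- function(left_row, right_row, xl, xr) {
  n <- length(left_row); m <- length(right_row)
  if (xl < 1 || xl > n - 2 || xr < 1 || xr > m - 2)
    stop("border pixel: interpolation needs a neighbour on each side")
  cpp_bt_dissim(as.numeric(left_row), as.numeric(right_row),
                as.integer(xl), as.integer(xr))
}

#' Match one rectified scanline pair by dynamic programming
#'
#' Finds the monotone matching minimizing total dissimilarity plus an
#' occlusion penalty per maximal unmatched run minus a per-match reward,
#' globally over all orderings consistent with `0 <= d <= max_disparity`
#' (disparity `d` matches left pixel `x` to right pixel `x - d`).
#'
#' @param left_row,right_row numeric intensity vectors of equal length >= 3.
#' @param params a [match_params()].
#' @return list with `disparity` (integer, `NA` where occluded), `valid`
#'   (logical), and `cost` (the optimal objective value).
#' @export
match_scanline <- function(left_row, right_row, params = match_params()) {
  if (length(left_row) != length(right_row))
    stop("unrectified input: scanlines differ in length")
  stopifnot(length(left_row) >= 3)
  cpp_match_scanline(as.numeric(left_row), as.numeric(right_row),
                     params$max_disparity, params$kappa_occ, params$kappa_r)
}

#' Compute a dense disparity map on a rectified pair
#'
#' Applies [match_scanline()] to every row. Occluded/unmatched pixels are
#' masked invalid and never interpolated; hole handling happens downstream at
#' grid sampling with explicit rules.
#'
#' @param left,right rectified grayscale matrices (equal shape) or H x W x 3
#'   arrays (converted by luminance weights).
#' @param params a [match_params()].
#' @return an object of class `disparity_map`: list with `values` (integer
#'   matrix, `NA` where invalid), `valid` (logical matrix) and `params`.
#' @export
compute_disparity_map <- function(left, right, params = match_params()) {
  left <- to_grayscale(left); right <- to_grayscale(right)
  if (!all(dim(left) == dim(right)))
    stop("unrectified input: image shapes differ")
  res <- cpp_match_image(left, right, params$max_disparity,
                         params$kappa_occ, params$kappa_r)
  values <- res$disparity
  valid <- res$valid
  if (params$interrow_filter && nrow(values) >= 3) {
    v <- values
    for (y in 2:(nrow(v) - 1)) {
      trip <- rbind(v[y - 1, ], v[y, ], v[y + 1, ])
      med <- apply(trip, 2, function(col) stats::median(col, na.rm = TRUE))
      bad <- !is.na(v[y, ]) & !is.na(med) & abs(v[y, ] - med) > 1
      valid[y, bad] <- FALSE
      values[y, bad] <- NA_integer_
    }
  }
  structure(list(values = values, valid = valid, params = params),
            class = "disparity_map")
}

#' @export
print.disparity_map <- function(x, ...) {
  cat(sprintf("disparity_map: %d x %d px, %.1f%% valid, d in [%s, %s]\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$valid),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Persist a disparity map as a PFM raster plus a PNG validity mask
#'
#' @param dmap a `disparity_map`.
#' @param pfm_path output PFM path (invalid pixels written as -1).
#' @param mask_path output PNG mask path (white = valid).
#' @return `pfm_path`, invisibly.
#' @export
write_disparity_map <- function(dmap, pfm_path, mask_path) {
  vals <- dmap$values
  vals[!dmap$valid] <- -1
  write_pfm(matrix(as.numeric(vals), nrow(vals), ncol(vals)), pfm_path)
  write_image(dmap$valid * 255, mask_path)
  invisible(pfm_path)
}
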