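#' Video sequence container
#'
#' @param frames list of grayscale matrices, all of identical shape.
#' @param fps frames per second (> 0); capture default is 30.
#' @param camera label, `"left"` or `"right"` (or `""` for composite video).
#' @return an object of class `video_sequence`.
#' @export
video_sequence <- function(frames, fps = 30, camera = "") {
  stopifnot(is.list(frames), fps > 0)
  if (length(frames) > 0) {
    d <- dim(frames[[1]])
    ok <- vapply(frames, function(f) all(dim(f) == d), logical(1))
    stopifnot(all(ok))
  }
  structure(list(frames = frames, fps = fps, camera = camera),
            class = "video_sequence")
}

#' Split composite stereo video into left and right sequences
#'
#' Supports two packings of the synchronized camera pair into one composite
#' frame: `"side_by_side"` (left half columns = left camera) and
#' `"field_interleaved"` (even rows, 0-based, = left camera field).
#'
#' @param composite a [video_sequence()] of composite frames (e.g. 1280 x 240
#'   side-by-side for two 640 x 240 camera streams).
#' @param packing `"side_by_side"` or `"field_interleaved"`.
#' @return list with `left` and `right` [video_sequence()]s.
#' @export
split_stereo_video <- function(composite, packing = c("side_by_side", "field_interleaved")) {
  packing <- match.arg(packing)
  split1 <- function(fr) {
    h <- nrow(fr); w <- ncol(fr)
    if (packing == "side_by_side") {
      if (w %% 2 != 0) stop("unknown packing: odd composite width")
      list(left = fr[, 1:(w / 2), drop = FALSE],
           right = fr[, (w / 2 + 1):w, drop = FALSE])
    } else {
      if (h %% 2 != 0) stop("unknown packing: odd composite height")
      list(left = fr[seq(1, h, by = 2), , drop = FALSE],
           right = fr[seq(2, h, by = 2), , drop = FALSE])
    }
  }
  parts <- lapply(composite$frames, split1)
  list(left = video_sequence(lapply(parts, `[[`, "left"), composite$fps, "left"),
       right = video_sequence(lapply(parts, `[[`, "right"), composite$fps, "right"))
}

#' Deinterlace a half-height field by linear interpolation
#'
#' Original field lines are preserved on alternate output rows; the missing
#' rows are the arithmetic mean of their vertical neighbours, and the final
#' boundary row is replicated.
#'
#' @param frame H x W matrix (one field, e.g. 240 rows).
#' @return 2H x W matrix (e.g. 480 rows).
#' @export
deinterlace <- function(frame) {
  h <- nrow(frame); w <- ncol(frame)
  out <- matrix(0, 2 * h, w)
  out[seq(1, 2 * h, by = 2), ] <- frame
  if (h > 1)
    out[seq(2, 2 * h - 2, by = 2), ] <- (frame[1:(h - 1), , drop = FALSE] +
                                         frame[2:h, , drop = FALSE]) / 2
  out[2 * h, ] <- frame[h, ]
  out
}

#' Triangulate a disparity map into a range image
#'
#' For valid pixels with disparity `d` in the rectified pair,
#' `z = fx * B / d`, `x = (u - cx) * z / fx`, `y = (v - cy) * z / fy`
#' (millimetres, left rectified camera frame: x right, y down, z away).
#' Pixels with `d <= 0` marked valid in the input are masked invalid and their
#' count reported via a message.
#'
#' @param disparity a `disparity_map`.
#' @param rig a rectified [stereo_rig()].
#' @param frame_index integer frame number (1-based).
#' @param fps frames/second, used for the timestamp.
#' @return an object of class `range_image`: `points` (H x W x 3, mm),
#'   `valid` (H x W logical), `frame_index`, `timestamp` (s).
#' @export
disparity_to_range <- function(disparity, rig, frame_index = 1L, fps = 30) {
  if (is.null(rig$rect_rotation)) rig <- rectify(rig)
  ri <- rig$rect_intrinsics
  fpx <- rect_focal_px(rig)
  d <- disparity$values
  valid <- disparity$valid & !is.na(d)
  nonpos <- valid & d <= 0
  if (any(nonpos)) {
    message(sum(nonpos), " valid pixels had non-positive disparity; masked invalid")
    valid[nonpos] <- FALSE
  }
  h <- nrow(d); w <- ncol(d)
  u <- matrix(0:(w - 1), h, w, byrow = TRUE)
  v <- matrix(0:(h - 1), h, w)
  z <- matrix(NA_real_, h, w)
  z[valid] <- fpx["fx"] * rig$baseline / d[valid]
  x <- (u - ri$cx) * z / fpx["fx"]
  y <- (v - ri$cy) * z / fpx["fy"]
  pts <- array(NA_real_, c(h, w, 3))
  pts[, , 1] <- x; pts[, , 2] <- y; pts[, , 3] <- z
  zmed <- stats::median(z[valid])
  if (is.finite(zmed) && (zmed < 20 || zmed > 60))
    warning("median surface depth ", round(zmed, 1),
            " mm is outside the validated 20-60 mm working range")
  structure(list(points = pts, valid = valid,
                 frame_index = as.integer(frame_index),
                 timestamp = (frame_index - 1) / fps),
            class = "range_image")
}

#' Build a range sequence from synchronized rectified-ready video
#'
#' Per frame pair: remap into rectified geometry ([rectify_pair()]), match
#' ([compute_disparity_map()]), triangulate ([disparity_to_range()]).
#'
#' @param left_seq,right_seq [video_sequence()]s of equal length (already
#'   split and deinterlaced).
#' @param rig a [stereo_rig()] (rectified internally if needed).
#' @param params a [match_params()].
#' @return an object of class `range_sequence` (list of `range_image`s plus
#'   `fps` and the rectified `rig`).
#' @export
build_range_sequence <- function(left_seq, right_seq, rig, params = match_params()) {
  if (length(left_seq$frames) != length(right_seq$frames))
    stop("unsynchronized sequences: frame counts differ")
  if (is.null(rig$rect_rotation)) rig <- rectify(rig)
  n <- length(left_seq$frames)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    rp <- rectify_pair(left_seq$frames[[i]], right_seq$frames[[i]], rig)
    dm <- compute_disparity_map(rp$left, rp$right, params)
    images[[i]] <- suppressWarnings(
      disparity_to_range(dm, rig, frame_index = i, fps = left_seq$fps))
  }
  structure(list(images = images, fps = left_seq$fps, rig = rig),
            class = "range_sequence")
}

#' Persist a range sequence as per-frame PFM/PNG pairs plus a JSON manifest
#'
#' @param rseq a `range_sequence`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_range_sequence <- function(rseq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (img in rseq$images) {
    base <- sprintf("frame_%04d", img$frame_index)
    pts <- img$points
    pts[is.na(pts)] <- 0
    write_pfm(pts, file.path(dir, paste0(base, "_xyz.pfm")))
    write_image(img$valid * 255, file.path(dir, paste0(base, "_mask.png")))
    entries[[length(entries) + 1]] <-
      list(frame_index = img$frame_index, timestamp = img$timestamp,
           xyz = paste0(base, "_xyz.pfm"), mask = paste0(base, "_mask.png"))
  }
  manifest <- file.path(dir, "sequence.json")
  jsonlite::write_json(list(fps = rseq$fps, frames = entries), manifest,
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
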