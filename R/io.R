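#' Read a grayscale image (PNG or PGM)
#'
#' Intensities are returned on a 0-255 double scale regardless of container.
#' Colour PNGs are converted by the standard luminance weights
#' (0.299 R + 0.587 G + 0.114 B) before matching, per the matcher's contract.
#'
#' @param path file path ending in `.png`, `.pgm` (binary P5 or plain P2).
#' @return numeric matrix (rows = y, cols = x), intensities in \[0, 255\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3 && dim(img)[3] >= 3) img <- to_grayscale(img[, , 1:3])
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(img * 255)
  }
  if (ext == "pgm") return(read_pgm(path))
  stop("unsupported image format: ", ext)
}

#' Write a grayscale image (PNG or PGM)
#'
#' @param img numeric matrix, intensities in \[0, 255\] (clipped on write).
#' @param path output path; format chosen by extension (`.png` or `.pgm`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(img, 0), 255)
  if (ext == "png") {
    png::writePNG(img / 255, path)
  } else if (ext == "pgm") {
    write_pgm(img, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

# Plain (P2) and binary (P5) PGM support. P2 is used for text-only fixtures.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  toks <- character(0)
  # read header tokens (width, height, maxval), skipping comments
  while (length(toks) < 3) {
    line <- readLines(con, n = 1)
    line <- sub("#.*$", "", line)
    toks <- c(toks, strsplit(trimws(line), "[[:space:]]+")[[1]])
    toks <- toks[nzchar(toks)]
  }
  w <- as.integer(toks[1]); h <- as.integer(toks[2]); maxv <- as.integer(toks[3])
  if (magic == "P5") {
    raw <- if (maxv < 256) as.numeric(readBin(con, "integer", n = w * h, size = 1, signed = FALSE))
           else as.numeric(readBin(con, "integer", n = w * h, size = 2, signed = FALSE, endian = "big"))
  } else {
    raw <- as.numeric(scan(con, what = numeric(), n = w * h, quiet = TRUE))
  }
  matrix(raw, nrow = h, ncol = w, byrow = TRUE) * (255 / maxv)
}

write_pgm <- function(img, path, binary = FALSE) {
  vals <- as.integer(round(t(pmin(pmax(img, 0), 255))))
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img)), con, eos = NULL)
    writeBin(as.raw(vals), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("P2\n%d %d\n255", ncol(img), nrow(img)), con)
    writeLines(apply(matrix(vals, ncol = ncol(img), byrow = TRUE), 1, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Write a PFM float raster
#'
#' PFM stores rows bottom-to-top as little-endian float32; one channel (`Pf`)
#' for scalar rasters such as disparity, three channels (`PF`) for x/y/z range
#' images.
#'
#' @param data numeric matrix (one channel) or H x W x 3 array.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(data, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (is.matrix(data)) data <- array(data, c(dim(data), 1))
  h <- dim(data)[1]; w <- dim(data)[2]; ch <- dim(data)[3]
  stopifnot(ch %in% c(1, 3))
  writeChar(sprintf("%s\n%d %d\n-1.0\n", if (ch == 1) "Pf" else "PF", w, h),
            con, eos = NULL)
  # bottom-to-top scanlines, channels interleaved per pixel
  vals <- numeric(h * w * ch)
  idx <- 1
  for (row in h:1) {
    px <- t(matrix(data[row, , ], nrow = w))   # ch x w
    vals[idx:(idx + w * ch - 1)] <- as.numeric(px)
    idx <- idx + w * ch
  }
  writeBin(vals, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a PFM float raster
#'
#' @param path PFM file written by [write_pfm()] or another tool.
#' @return numeric matrix (one channel) or H x W x 3 array.
#' @export
read_pfm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- trimws(readLines(con, n = 1))
  if (!magic %in% c("Pf", "PF")) stop("not a PFM file: ", path)
  ch <- if (magic == "Pf") 1L else 3L
  dims <- as.integer(strsplit(trimws(readLines(con, n = 1)), "[[:space:]]+")[[1]])
  w <- dims[1]; h <- dims[2]
  scale <- as.numeric(trimws(readLines(con, n = 1)))
  endian <- if (scale < 0) "little" else "big"
  vals <- readBin(con, "numeric", n = h * w * ch, size = 4, endian = endian)
  out <- array(0, c(h, w, ch))
  idx <- 1
  for (row in h:1) {
    px <- matrix(vals[idx:(idx + w * ch - 1)], nrow = ch)
    out[row, , ] <- t(px)
    idx <- idx + w * ch
  }
  if (ch == 1) out[, , 1] else out
}

#' Read stereo calibration from a YAML or JSON config file
#'
#' The file holds one mapping per camera (`left`, `right`) with keys `f`,
#' `kappa1`, `cx`, `cy`, `sx`, `dx`, `dy`, `width`, `height`, `R` (row-major,
#' 9 values) and `T` (3 values).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a [stereo_rig()] object.
#' @export
read_calibration <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  cam <- function(x) {
    intr <- camera_intrinsics(f = x$f, kappa1 = x$kappa1 %||% 0,
                              cx = x$cx, cy = x$cy, sx = x$sx %||% 1,
                              dx = x$dx, dy = x$dy,
                              width = x$width, height = x$height)
    pose <- camera_pose(matrix(unlist(x$R), 3, 3, byrow = TRUE), unlist(x$T))
    list(intrinsics = intr, pose = pose)
  }
  l <- cam(cfg$left); r <- cam(cfg$right)
  stereo_rig(l$intrinsics, l$pose, r$intrinsics, r$pose)
}

#' Write stereo calibration to YAML
#'
#' @param rig a [stereo_rig()].
#' @param path output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(rig, path) {
  cam <- function(intr, pose) {
    c(unclass(intr)[c("f", "kappa1", "cx", "cy", "sx", "dx", "dy", "width", "height")],
      list(R = as.numeric(t(pose$R)), T = as.numeric(pose$T)))
  }
  yaml::write_yaml(list(left = cam(rig$left$intrinsics, rig$left$pose),
                        right = cam(rig$right$intrinsics, rig$right$pose)), path)
  invisible(path)
}

#' Read a calibration-target correspondence table
#'
#' @param path CSV with columns `X,Y,Z,u,v` (world mm, image px).
#' @return a [calibration_target()].
#' @export
read_correspondences <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("X", "Y", "Z", "u", "v") %in% names(df)))
  calibration_target(as.matrix(df[, c("X", "Y", "Z")]), as.matrix(df[, c("u", "v")]))
}

#' Read a quadrangle ROI from JSON
#'
#' @param path JSON with field `corners` (4 \[u, v\] pixel pairs) and optional
#'   `reference_frame` (1-based index, default 1).
#' @return a [quadrangle_roi()] with attribute `reference_frame`.
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) stop("invalid ROI path: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi <- quadrangle_roi(matrix(unlist(cfg$corners), ncol = 2, byrow = !is.matrix(cfg$corners)))
  attr(roi, "reference_frame") <- cfg$reference_frame %||% 1
  roi
}

#' Write a quadrangle ROI to JSON
#' @param roi a [quadrangle_roi()].
#' @param path output path.
#' @param reference_frame 1-based reference frame index stored alongside.
#' @return `path`, invisibly.
#' @export
write_roi <- function(roi, path, reference_frame = 1) {
  jsonlite::write_json(list(corners = unclass(roi$corners),
                            reference_frame = reference_frame),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
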