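# Independent oracles used across tests. These deliberately re-derive results
# by brute force or closed form, without touching the implementation paths
# they check.

# Exhaustive search over every monotone matching of two scanlines under the
# disparity band, scoring sum(dissimilarity) - kr * n_match + kocc * n_runs
# (maximal unmatched runs in either scanline, boundary runs included).
enumerate_matching_cost <- function(L, R, D, kocc = 25, kr = 5) {
  W <- length(L)
  count_runs <- function(idx) {           # idx: matched 0-based positions
    un <- setdiff(0:(W - 1), idx)
    if (!length(un)) return(0)
    sum(diff(c(-10, un)) > 1)
  }
  # sampling-insensitive dissimilarity, written independently (edge-clamped)
  interp_min <- function(A, B, xa, xb) {
    half <- function(I, x, s) {
      xi <- x + s
      if (xi < 0 || xi > W - 1) I[x + 1] else (I[x + 1] + I[xi + 1]) / 2
    }
    one <- function(P, Q, xp, xq) {
      vals <- c(Q[xq + 1], half(Q, xq, -1), half(Q, xq, 1))
      lo <- min(vals); hi <- max(vals)
      max(0, P[xp + 1] - hi, lo - P[xp + 1])
    }
    min(one(A, B, xa, xb), one(B, A, xb, xa))
  }
  best <- Inf
  rec <- function(i, lastj, ms) {
    if (i == W) {
      cost <- if (length(ms)) {
        m <- do.call(rbind, ms)
        sum(vapply(seq_len(nrow(m)), function(k) interp_min(L, R, m[k, 1], m[k, 2]),
                   numeric(1))) - kr * nrow(m) +
          kocc * (count_runs(m[, 1]) + count_runs(m[, 2]))
      } else 2 * kocc
      best <<- min(best, cost)
      return(invisible())
    }
    rec(i + 1, lastj, ms)
    lo <- max(lastj + 1, i - D)
    if (lo <= i) for (j in lo:i) if (j >= 0) rec(i + 1, j, c(ms, list(c(i, j))))
  }
  rec(0, -1, list())
  best
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mw_enumerate <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  ustat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- ustat(a, b)
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(ix) ustat(pool[ix], pool[-ix]))
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Straight-line implementation of the Tsai forward model (independent of
# project()): rigid transform, perspective divide, radial distortion, pixel
# mapping.
project_oracle <- function(intr, R, T, P) {
  cam <- as.numeric(R %*% P + T)
  xu <- intr$f * cam[1] / cam[3]
  yu <- intr$f * cam[2] / cam[3]
  r2 <- xu^2 + yu^2
  xd <- xu * (1 + intr$kappa1 * r2)
  yd <- yu * (1 + intr$kappa1 * r2)
  c(xd * intr$sx / intr$dx + intr$cx, yd / intr$dy + intr$cy)
}

# A random convex quadrangle with positive area, corners in random order:
# rejection-sample 4 points whose convex hull has all 4 as vertices.
random_quadrangle <- function() {
  repeat {
    pts <- cbind(runif(4, 20, 220), runif(4, 20, 200))
    hull <- grDevices::chull(pts)
    if (length(hull) == 4) {
      a <- pts[hull[2], ] - pts[hull[1], ]
      b <- pts[hull[3], ] - pts[hull[2], ]
      if (abs(a[1] * b[2] - a[2] * b[1]) > 50) return(pts[sample(4), , drop = FALSE])
    }
  }
}

# Random plausible camera ground truth for calibration recovery runs.
random_camera_config <- function(planar = FALSE) {
  intr <- camera_intrinsics(f = runif(1, 3, 6), kappa1 = runif(1, 2e-4, 2e-3),
                            cx = 160, cy = 120, sx = 1, dx = 0.01, dy = 0.01,
                            width = 320, height = 240)
  R <- rodrigues_vec(runif(3, -0.15, 0.15))
  T <- c(runif(2, -4, 4), runif(1, 40, 60))
  n <- if (planar) 24 else 30
  P <- if (planar) cbind(runif(n, -15, 15), runif(n, -12, 12), 0)
       else cbind(runif(n, -15, 15), runif(n, -12, 12), runif(n, -10, 10))
  px <- project(intr, camera_pose(R, T), P)
  inside <- px[, 1] >= 0 & px[, 1] < 320 & px[, 2] >= 0 & px[, 2] < 240
  list(intrinsics = intr, pose = camera_pose(R, T),
       world = P[inside, , drop = FALSE], pixels = px[inside, , drop = FALSE])
}

# Small local Rodrigues (independent of the package internals).
rodrigues_vec <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) return(diag(3))
  k <- r / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Initial-guess intrinsics handed to the calibration (sensor geometry known,
# f deliberately off, kappa unknown).
init_intrinsics <- function() {
  camera_intrinsics(f = 5, kappa1 = 0, cx = 160, cy = 120, sx = 1,
                    dx = 0.01, dy = 0.01, width = 320, height = 240)
}

# Analytic two-mode grid trajectory plus the injected orthonormal patterns,
# built from the generator's primitives on the node parameter grid.
two_mode_patterns <- function(params, truth) {
  base <- truth$points[1, , ]
  s <- base[, 1] / params$extent[1] + 0.5
  t <- base[, 2] / params$extent[2] + 0.5
  w <- sin(pi * s) * sin(pi * t)
  d1 <- params$direction
  d2 <- params$direction2 - sum(params$direction2 * d1) * d1
  d2 <- d2 / sqrt(sum(d2^2))
  p1 <- as.numeric(t(w %o% d1)); p2 <- as.numeric(t(w %o% d2))
  list(p1 = p1 / sqrt(sum(p1^2)), p2 = p2 / sqrt(sum(p2^2)))
}
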