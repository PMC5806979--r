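#' Build the motion observation matrix from a grid trajectory
#'
#' Flattens each frame's grid configuration into one row, node-major then
#' x, y, z (column `3*(node-1)+coord`), and expresses all frames relative to
#' the rest-frame configuration (the rest frame is subtracted, so a static
#' trajectory yields an all-zero matrix). For the full 36-node grid the rows
#' have 108 columns.
#'
#' @param traj a `grid_trajectory` with no remaining missing entries.
#' @param rest_frame 1-based rest frame index (default 1).
#' @param subject,group optional labels carried through to the statistics.
#' @return an object of class `motion_matrix`: `X` (T x 3N), `rest` (N x 3 mm
#'   rest configuration), `timestamps`, `subject`, `group`.
#' @export
build_motion_matrix <- function(traj, rest_frame = 1, subject = NA_character_,
                                group = NA_character_) {
  pts <- traj$points
  if (anyNA(pts)) stop("non-rectangular trajectory: missing node coordinates")
  nf <- dim(pts)[1]; nn <- dim(pts)[2]
  stopifnot(nf >= 2, rest_frame >= 1, rest_frame <= nf)
  X <- matrix(0, nf, nn * 3)
  for (i in seq_len(nf)) X[i, ] <- as.numeric(t(pts[i, , ]))
  rest <- pts[rest_frame, , ]
  X <- X - matrix(as.numeric(t(rest)), nf, nn * 3, byrow = TRUE)
  structure(list(X = X, rest = rest, timestamps = traj$timestamps,
                 rest_frame = as.integer(rest_frame),
                 subject = subject, group = group),
            class = "motion_matrix")
}

#' Reshape one motion-matrix row back into an N x 3 configuration
#' @param row numeric vector of length 3N (node-major, then x, y, z).
#' @return N x 3 matrix.
#' @keywords internal
unflatten_config <- function(row) {
  matrix(row, ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Principal-component decomposition of grid motion
#'
#' Eigendecomposition of the column-centred covariance (computed via SVD of
#' the centred matrix): orthonormal loadings, descending eigenvalues, and
#' per-frame scores. The standard configuration keeps the first 12 principal
#' component scores. Each loading's sign is oriented so that the score at the
#' frame of maximum centre-of-gravity displacement is non-negative, removing
#' the eigenvector sign ambiguity that otherwise breaks pooling across
#' subjects.
#'
#' @param mm a [build_motion_matrix()] result.
#' @param k number of components retained (default 12). If `k` exceeds the
#'   achievable rank `min(T - 1, ncol)`, a warning is raised and the
#'   achievable number is returned.
#' @return an object of class `pca_model`: `mean` (3N), `loadings` (k x 3N,
#'   orthonormal rows), `eigenvalues` (k, descending), `scores` (T x k),
#'   `total_variance`, `rest`, `k`.
#' @export
fit_pca <- function(mm, k = 12) {
  X <- mm$X
  nf <- nrow(X); p <- ncol(X)
  stopifnot(nf >= 2, k >= 1)
  rank_max <- min(nf - 1, p)
  if (k > rank_max) {
    warning("rank deficiency: k = ", k, " exceeds achievable rank ", rank_max,
            "; returning ", rank_max, " components")
    k <- rank_max
  }
  mu <- colMeans(X)
  Xc <- X - matrix(mu, nf, p, byrow = TRUE)
  sv <- svd(Xc)
  eig <- sv$d^2 / (nf - 1)
  total <- sum(eig)
  loadings <- t(sv$v[, seq_len(k), drop = FALSE])
  scores <- Xc %*% t(loadings)
  # sign convention: score non-negative at the frame of max CoG displacement
  nn <- p / 3
  cogdisp <- cbind(rowMeans(X[, seq(1, p, 3), drop = FALSE]),
                   rowMeans(X[, seq(2, p, 3), drop = FALSE]),
                   rowMeans(X[, seq(3, p, 3), drop = FALSE]))
  ref <- which.max(sqrt(rowSums(cogdisp^2)))
  for (j in seq_len(k)) {
    if (scores[ref, j] < 0) {
      loadings[j, ] <- -loadings[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(mean = mu, loadings = loadings,
                 eigenvalues = eig[seq_len(k)], scores = scores,
                 total_variance = total, rest = mm$rest, k = as.integer(k),
                 subject = mm$subject, group = mm$group,
                 timestamps = mm$timestamps),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  ev <- 100 * x$eigenvalues / max(x$total_variance, .Machine$double.eps)
  cat(sprintf("pca_model: %d components over %d frames; explained variance %%: %s\n",
              x$k, nrow(x$scores),
              paste(sprintf("%.1f", head(ev, 5)), collapse = ", ")))
  invisible(x)
}

#' Reconstruct the grid configuration for one mode at a given score
#'
#' `mean + score * loading` reshaped to N x 3 and re-added to the rest
#' configuration; evaluating at scores such as -2 SD, 0, +2 SD renders the
#' soft-palate shapes associated with a motion mode. Because loadings are
#' orthonormal, the configuration moves by exactly `|score|` mm (in the
#' flattened norm) from the score-zero shape.
#'
#' @param pca a [fit_pca()] model.
#' @param component 1-based component index (<= `pca$k`).
#' @param score score value, mm.
#' @return N x 3 configuration, mm.
#' @export
reconstruct_mode_shape <- function(pca, component, score) {
  stopifnot(component >= 1, component <= pca$k)
  pca$rest + unflatten_config(pca$mean + score * pca$loadings[component, ])
}

#' Export a PCA model as JSON + CSV files
#'
#' Writes `pca.json` (mean, eigenvalues, total variance), `loadings.csv`,
#' `scores.csv`, and per-mode shape point sets `mode<k>_shapes.csv` at scores
#' -2 SD, 0 and +2 SD for the first two components.
#'
#' @param pca a [fit_pca()] model.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pca_model <- function(pca, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(mean = pca$mean, eigenvalues = pca$eigenvalues,
                            total_variance = pca$total_variance, k = pca$k),
                       file.path(dir, "pca.json"), auto_unbox = TRUE, digits = NA)
  write.csv(as.data.frame(pca$loadings), file.path(dir, "loadings.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(pca$scores), file.path(dir, "scores.csv"),
            row.names = FALSE)
  for (comp in seq_len(min(2, pca$k))) {
    sdv <- sqrt(pca$eigenvalues[comp])
    shapes <- do.call(rbind, lapply(c(-2, 0, 2), function(m) {
      sh <- reconstruct_mode_shape(pca, comp, m * sdv)
      data.frame(score_sd = m, node = seq_len(nrow(sh)),
                 x_mm = sh[, 1], y_mm = sh[, 2], z_mm = sh[, 3])
    }))
    write.csv(shapes, file.path(dir, sprintf("mode%d_shapes.csv", comp)),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Mann-Whitney U test between two groups of shift magnitudes
#'
#' U is computed from rank sums with midranks for ties. The two-sided p-value
#' is exact (full enumeration) when the combined sample size is at most 25 and
#' there are no ties, and otherwise uses the normal approximation with tie and
#' continuity corrections.
#'
#' @param group_a,group_b numeric vectors (each nonempty).
#' @return an object of class `group_test_result`: `U`, `p`, `n` (group
#'   sizes), `values` (per-subject inputs).
#' @export
mann_whitney <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  n1 <- length(group_a); n2 <- length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  if (all(group_a == group_a[1]) && all(group_b == group_a[1])) {
    warning("all values identical across both groups; p = 1")
    res <- list(statistic = c(W = n1 * n2 / 2), p.value = 1)
  } else {
    res <- suppressWarnings(
      wilcox.test(group_a, group_b, exact = (n1 + n2 <= 25) && !ties,
                  correct = TRUE))
  }
  structure(list(U = unname(res$statistic), p = res$p.value,
                 n = c(n1 = n1, n2 = n2),
                 values = list(a = group_a, b = group_b)),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n = %d vs %d), two-sided p = %.3g\n",
              x$U, x$n[1], x$n[2], x$p))
  invisible(x)
}

#' Two-class linear discriminant on the first two component scores
#'
#' Fits the pooled-covariance linear discriminant to frame-level
#' (PCS1, PCS2) observations with proportional priors, and reports the
#' resubstitution accuracy; when per-observation subject identifiers are
#' supplied, leave-one-subject-out accuracy is reported as well (frame-level
#' resubstitution is optimistic). A singular pooled covariance is regularized
#' by adding `1e-8 * trace / 2` to the diagonal (with a message).
#'
#' @param scores numeric n x 2 matrix of (PCS1, PCS2).
#' @param labels factor or character of length n with exactly two levels.
#' @param subjects optional length-n subject identifiers for the
#'   leave-one-subject-out estimate.
#' @return an object of class `discriminant_result`: `weights` (length-2),
#'   `intercept`, `predicted`, `accuracy` (resubstitution, %),
#'   `accuracy_loso` (% or `NA`), `levels`.
#' @export
discriminant_classify <- function(scores, labels, subjects = NULL) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2, nrow(scores) == length(labels))
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("discriminant requires exactly two classes, both present")
  fit <- lda2_fit(scores, labels)
  predicted <- lda2_predict(fit, scores)
  accuracy <- 100 * mean(predicted == labels)
  accuracy_loso <- NA_real_
  if (!is.null(subjects)) {
    subjects <- as.character(subjects)
    preds <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
    for (s in unique(subjects)) {
      hold <- subjects == s
      if (nlevels(droplevels(labels[!hold])) < 2) next
      f <- lda2_fit(scores[!hold, , drop = FALSE], labels[!hold])
      preds[hold] <- lda2_predict(f, scores[hold, , drop = FALSE])
    }
    accuracy_loso <- 100 * mean(preds == labels, na.rm = TRUE)
  }
  structure(list(weights = fit$w, intercept = fit$b, predicted = predicted,
                 accuracy = accuracy, accuracy_loso = accuracy_loso,
                 levels = levels(labels)),
            class = "discriminant_result")
}

# Pooled-covariance two-class LDA; decision value > 0 -> first level.
lda2_fit <- function(x, labels) {
  lv <- levels(labels)
  x1 <- x[labels == lv[1], , drop = FALSE]
  x2 <- x[labels == lv[2], , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  Sp <- ((n1 - 1) * cov(x1) + (n2 - 1) * cov(x2)) / (n1 + n2 - 2)
  if (!is.finite(rcond_2x2(Sp)) || rcond_2x2(Sp) < 1e-12) {
    message("singular pooled covariance; regularizing diagonal")
    Sp <- Sp + diag(1e-8 * sum(diag(Sp)) / 2 + 1e-12, 2)
  }
  Si <- solve(Sp)
  w <- Si %*% (m1 - m2)
  b <- -0.5 * sum((m1 + m2) * w) + log(n1 / n2)
  list(w = as.numeric(w), b = as.numeric(b), levels = lv)
}

lda2_predict <- function(fit, x) {
  dv <- as.numeric(x %*% fit$w + fit$b)
  factor(ifelse(dv > 0, fit$levels[1], fit$levels[2]), levels = fit$levels)
}

rcond_2x2 <- function(M) {
  s <- svd(M)$d
  if (s[1] == 0) 0 else s[length(s)] / s[1]
}

#' @export
print.discriminant_result <- function(x, ...) {
  cat(sprintf("linear discriminant (%s vs %s): resubstitution accuracy %.1f%%",
              x$levels[1], x$levels[2], x$accuracy))
  if (!is.na(x$accuracy_loso))
    cat(sprintf(", leave-one-subject-out %.1f%%", x$accuracy_loso))
  cat("\n")
  invisible(x)
}
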