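#' Pipeline configuration
#'
#' One configuration object drives the whole measurement chain
#' (simulate -> depth -> grid -> pca -> stats). Every numeric default of the
#' individual stages is surfaced here; the default values constitute the
#' standard configuration (n = 5 grid, k = 12 components, rest frame 1).
#'
#' @param out_dir output directory for all stage artifacts.
#' @param scene a [surface_params()] (used by the simulate stage).
#' @param render a [render_params()] (rig, texture, noise, seed).
#' @param roi a [quadrangle_roi()] or a path to a ROI JSON file.
#' @param match a [match_params()].
#' @param n grid subdivisions per side (>= 1).
#' @param k retained principal components (>= 1).
#' @param rest_frame 1-based rest frame index.
#' @param group_table optional data.frame (columns `subject`, `group`,
#'   `max_shift_mm`) for the group-statistics stage.
#' @param seed integer seed governing all pipeline randomness.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, scene = surface_params(),
                            render = render_params(), roi = default_roi(),
                            match = match_params(), n = 5, k = 12,
                            rest_frame = 1, group_table = NULL, seed = 1) {
  stopifnot(n >= 1, k >= 1, rest_frame >= 1)
  if (is.character(roi)) roi <- read_roi(roi)   # errors on a missing path
  structure(list(out_dir = out_dir, scene = scene, render = render, roi = roi,
                 match = match, n = as.integer(n), k = as.integer(k),
                 rest_frame = as.integer(rest_frame),
                 group_table = group_table, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Stable hash of an R object via its canonical serialization.
object_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full measurement pipeline
#'
#' Stages, each writing inspectable files under `out_dir` and never mutating
#' a prior stage's outputs:
#' \enumerate{
#'   \item `simulate` — render the synthetic stereo recording with ground truth;
#'   \item `depth` — rectify, match and triangulate into a range sequence;
#'   \item `grid` — build the virtual grid and its 3D trajectory;
#'   \item `pca` — motion matrix, component model, mode-shape exports;
#'   \item `stats` — centre-of-gravity shift, and (when a group table is
#'     supplied) Mann-Whitney and discriminant results.
#' }
#' A `manifest.json` records the stages, seed and config hash; rerunning with
#' the same configuration reproduces identical outputs and manifest hash.
#'
#' @param config a [pipeline_config()].
#' @return list with `trajectory`, `cog`, `pca`, `max_shift_mm`, `stats`
#'   (possibly `NULL`) and `manifest` (path).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  render <- config$render
  render$seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  stage("simulate",
        simulate_scene(config$scene, render, file.path(out, "fixtures"),
                       roi = config$roi))

  rig <- rectify(render$rig)
  frames <- seq_len(config$scene$n_frames)
  rseq <- stage("depth", {
    left <- vector("list", length(frames)); right <- left
    for (f in frames) {
      fr <- render_stereo_pair(config$scene, render, f)
      left[[f]] <- fr$left; right[[f]] <- fr$right
    }
    rs <- build_range_sequence(video_sequence(left, config$scene$fps, "left"),
                               video_sequence(right, config$scene$fps, "right"),
                               rig, config$match)
    write_range_sequence(rs, file.path(out, "range"))
    rs
  })

  traj <- stage("grid", {
    grid <- make_virtual_grid(config$roi, config$n)
    tr <- grid_trajectory(rseq, grid)
    write_grid_trajectory(tr, file.path(out, "trajectory.csv"))
    tr
  })

  pca <- stage("pca", {
    mm <- build_motion_matrix(traj, rest_frame = config$rest_frame)
    p <- fit_pca(mm, k = config$k)
    write_pca_model(p, file.path(out, "pca"))
    p
  })

  statres <- stage("stats", {
    cog <- cog_trajectory(traj, rest_frame = config$rest_frame)
    res <- list(max_shift_mm = cog_shift(cog), cog = cog)
    if (!is.null(config$group_table)) {
      gt <- config$group_table
      lv <- unique(gt$group)
      mw <- mann_whitney(gt$max_shift_mm[gt$group == lv[1]],
                         gt$max_shift_mm[gt$group == lv[2]])
      res$mann_whitney <- mw
    }
    jsonlite::write_json(list(max_shift_mm = res$max_shift_mm,
                              p_value = if (!is.null(res$mann_whitney))
                                res$mann_whitney$p else NULL),
                         file.path(out, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    res
  })

  cfg_hash <- object_hash(config[setdiff(names(config), "out_dir")])
  manifest <- list(
    stages = c("simulate", "depth", "grid", "pca", "stats"),
    seed = config$seed,
    config_hash = cfg_hash,
    n_frames = config$scene$n_frames,
    grid_n = config$n, pca_k = config$k,
    max_shift_mm = statres$max_shift_mm)
  mpath <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)

  list(trajectory = traj, cog = statres$cog, pca = pca,
       max_shift_mm = statres$max_shift_mm,
       stats = statres$mann_whitney, manifest = mpath)
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys (all optional except `out_dir`): `out_dir`,
#' `seed`, `n`, `k`, `rest_frame`, `roi` (path to a ROI JSON), `calibration`
#' (path to a calibration YAML for the rig), `scene` (mapping onto
#' [surface_params()] arguments), `render` (`texture_period`,
#' `texture_contrast`, `noise_sd`), `match` (mapping onto [match_params()]
#' arguments), and `group_table` (path to a CSV with columns
#' `subject,group,max_shift_mm`).
#'
#' @param path YAML config path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$out_dir))
  scene <- do.call(surface_params, cfg$scene %||% list())
  rig <- if (!is.null(cfg$calibration)) read_calibration(cfg$calibration)
         else default_rig()
  render <- do.call(render_params, c(list(rig = rig), cfg$render %||% list()))
  roi <- if (!is.null(cfg$roi)) read_roi(cfg$roi) else default_roi()
  match <- do.call(match_params, cfg$match %||% list())
  gt <- if (!is.null(cfg$group_table)) read.csv(cfg$group_table) else NULL
  pipeline_config(out_dir = cfg$out_dir, scene = scene, render = render,
                  roi = roi, match = match, n = cfg$n %||% 5,
                  k = cfg$k %||% 12, rest_frame = cfg$rest_frame %||% 1,
                  group_table = gt, seed = cfg$seed %||% 1)
}
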