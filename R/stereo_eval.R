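# Triangulation of the 68 stereo correspondences and the relative-pose
# evaluation protocol: median outlier filtering, false-positive statistics,
# per-position error statistics against a reference position, and the
# per-electrode error heatmap.

#' Triangulate an ordered stereo keypoint correspondence set
#'
#' Per-index disparity triangulation of the points visible in both rectified
#' views; indices invisible in either view (or with non-positive disparity)
#' are marked invalid.
#'
#' @param rect_rig a rectified `stereo_rig`.
#' @param left,right `keypoint_set`s in full-frame rectified coordinates.
#' @param position_id,frame_index,run_index bookkeeping tags.
#' @return a `grid_measurement`: `points3d` (Nx3 m, NA where invalid),
#'   `valid` (logical), plus the tags.
#' @export
triangulate_grid <- function(rect_rig, left, right, position_id = NA,
                             frame_index = NA, run_index = NA) {
  if (left$frame != "full" || right$frame != "full") {
    stop("triangulate_grid: keypoint sets must be in full-frame coordinates",
         call. = FALSE)
  }
  n <- nrow(left$points)
  both <- left$visible & right$visible
  disp <- left$points[, 1] - right$points[, 1]
  ok <- both & !is.na(disp) & disp > 0
  if (sum(ok) < 4) {
    stop("triangulate_grid: fewer than 4 mutually visible correspondences",
         call. = FALSE)
  }
  pts <- matrix(NA_real_, n, 3)
  pts[ok, ] <- triangulate(rect_rig, left$points[ok, , drop = FALSE],
                           right$points[ok, , drop = FALSE])
  structure(list(points3d = pts, valid = ok, position_id = position_id,
                 frame_index = frame_index, run_index = run_index),
            class = "grid_measurement")
}

measurement_center <- function(meas) {
  colMeans(meas$points3d[meas$valid, , drop = FALSE])
}

#' Median outlier filter over repeated measurements
#'
#' The grid is static at each position, so any measurement whose center (the
#' mean of its valid triangulated points) lies farther than `threshold` from
#' the component-wise median center is a false positive. The boundary is
#' strict: exactly-at-threshold measurements are kept.
#'
#' @param measurements list of `grid_measurement`s (>= 1).
#' @param threshold rejection distance in meters (default 0.10).
#' @return list with `kept`, `rejected` (lists), `centers`, `median_center`.
#' @export
median_outlier_filter <- function(measurements, threshold = 0.10) {
  if (!length(measurements)) stop("median_outlier_filter: need >= 1 measurement",
                                  call. = FALSE)
  centers <- t(vapply(measurements, measurement_center, numeric(3)))
  med <- apply(centers, 2, median)
  dist <- sqrt(rowSums(sweep(centers, 2, med, "-")^2))
  rej <- dist > threshold
  list(kept = measurements[!rej], rejected = measurements[rej],
       centers = centers, median_center = med)
}

#' False-positive rate of the outlier filter
#'
#' rejected / considered, where `considered` counts only frames that passed
#' the stereo acceptance rule. 0/0 is defined as 0 and flagged.
#'
#' @param considered,rejected non-negative counts, rejected <= considered.
#' @return the fraction; attribute `degenerate` is TRUE for the 0/0 case.
#' @export
false_positive_rate <- function(considered, rejected) {
  if (rejected > considered || rejected < 0) {
    stop("false_positive_rate: need 0 <= rejected <= considered", call. = FALSE)
  }
  if (considered == 0) {
    warning("false_positive_rate: 0 considered frames; defining rate as 0")
    return(structure(0, degenerate = TRUE))
  }
  structure(rejected / considered, degenerate = FALSE)
}

#' Per-electrode relative-pose error between two positions
#'
#' For each index i valid everywhere:
#' `error_i = | ||m_i(pos) - m_i(ref)|| - ||t_i(pos) - t_i(ref)|| |`,
#' the absolute difference between the measured and ground-truth Euclidean
#' displacement of that point between the reference position and the probe
#' position. Validity masks of each measurement and its truth must agree.
#'
#' @param ref_meas,pos_meas `grid_measurement`s from the pipeline.
#' @param ref_truth,pos_truth `grid_measurement`s built from ground truth.
#' @return numeric vector (meters), NA at indices not valid in all four.
#' @export
relative_pose_error <- function(ref_meas, pos_meas, ref_truth, pos_truth) {
  if (!identical(ref_meas$valid, ref_truth$valid) ||
      !identical(pos_meas$valid, pos_truth$valid)) {
    stop("relative_pose_error: validity masks of measurement and truth differ",
         call. = FALSE)
  }
  ok <- ref_meas$valid & pos_meas$valid
  dm <- sqrt(rowSums((pos_meas$points3d - ref_meas$points3d)^2))
  dt <- sqrt(rowSums((pos_truth$points3d - ref_truth$points3d)^2))
  err <- abs(dm - dt)
  err[!ok] <- NA_real_
  err
}

#' Normalized per-electrode error heatmap
#'
#' Sums each electrode's errors over all positions and divides by the
#' maximum per-electrode sum, giving a rows x cols map in [0, 1] whose
#' maximum is exactly 1 (all-zero input yields an all-zero map with a flag).
#'
#' @param electrode_errors numeric vector of per-electrode error sums
#'   (length rows*cols) or a matrix positions x electrodes to be summed.
#' @param spec a [grid_spec()].
#' @return rows x cols matrix; attribute `all_zero`.
#' @export
electrode_heatmap <- function(electrode_errors, spec = grid_spec()) {
  if (is.matrix(electrode_errors)) {
    electrode_errors <- colSums(electrode_errors, na.rm = TRUE)
  }
  ne <- spec$rows * spec$cols
  if (length(electrode_errors) != ne) {
    stop("electrode_heatmap: need one error sum per electrode", call. = FALSE)
  }
  mx <- max(electrode_errors)
  if (mx <= 0) {
    m <- matrix(0, spec$rows, spec$cols)
    attr(m, "all_zero") <- TRUE
    return(m)
  }
  m <- matrix(electrode_errors / mx, spec$rows, spec$cols, byrow = TRUE)
  attr(m, "all_zero") <- FALSE
  m
}

# Ground-truth measurement for a scene, restricted to a validity mask.
truth_measurement <- function(state, valid, position_id = NA) {
  pts <- state$points3d
  pts[!valid, ] <- NA_real_
  structure(list(points3d = pts, valid = valid, position_id = position_id,
                 frame_index = NA, run_index = NA), class = "grid_measurement")
}

# Run the detection->pose->triangulation pipeline on one stereo frame pair.
# Returns a grid_measurement or a character rejection reason.
process_stereo_frame <- function(frames, rect_rig, cfg, spec, seed) {
  dets <- list(
    left = detect_grid(frames$left$image, cfg$detector_obj,
                       truth_bbox = frames$left$bbox, seed = derive_seed(seed, 31L)),
    right = detect_grid(frames$right$image, cfg$detector_obj,
                        truth_bbox = frames$right$bbox, seed = derive_seed(seed, 32L)))
  acc <- accept_stereo(dets$left, dets$right)
  if (!acc$accepted) return(acc$reason)
  res <- try({
    kl <- estimate_pose_2d(frames$left$image, acc$left, spec,
                           factor = cfg$upscaler$factor, upscaler = cfg$upscaler$kind,
                           pose_kind = cfg$pose$kind, truth = frames$left)
    kr <- estimate_pose_2d(frames$right$image, acc$right, spec,
                           factor = cfg$upscaler$factor, upscaler = cfg$upscaler$kind,
                           pose_kind = cfg$pose$kind, truth = frames$right)
    triangulate_grid(rect_rig, kl, kr)
  }, silent = TRUE)
  if (inherits(res, "try-error")) return("pose-failure")
  res
}

#' Run the scaled-down relative-pose experiment
#'
#' Replicates the evaluation protocol in simulation: the grid is placed at
#' each measurement-grid position facing the camera, a number of stereo
#' frames is recorded per position (static scene, per-frame sensor noise),
#' each frame runs through the full pipeline, the stereo acceptance rule and
#' the per-position median outlier filter are applied, and relative-pose
#' errors against the reference position are computed with the simulator's
#' known geometry standing in as ground truth. Fully reproducible from
#' `seed`.
#'
#' @param config a pipeline configuration, see [default_config()].
#' @param seed integer master seed (overrides `config$seed`).
#' @return an `error_report`: `per_position` data.frame (position id, depth,
#'   lateral, mean/sd of the relative error, counts), `per_electrode` error
#'   sums, `heatmap`, `fp` per-depth false-positive table, `totals`.
#' @export
run_experiment <- function(config = default_config(), seed = NULL) {
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  spec <- config_grid_spec(cfg)
  rig <- config_rig(cfg)
  rect <- if (isTRUE(rig$rectified) || is_zero_distortion(rig$dist_left)) {
    r <- rig; r$rectified <- TRUE; r
  } else rectify_rig(rig)
  layout <- measurement_layout(depths = cfg$experiment$depths,
                               n_lateral = cfg$experiment$n_lateral,
                               width = cfg$experiment$width)
  scenes <- make_measurement_scenes(layout, spec)
  nf <- cfg$experiment$frames_per_position
  runs <- cfg$experiment$runs

  per_pos <- vector("list", length(scenes))
  for (si in seq_along(scenes)) {
    sc <- scenes[[si]]
    pos_seed <- derive_seed(cfg$seed, 1000L + si)
    settings <- config_render_settings(cfg, seed = pos_seed)
    clean_settings <- settings
    clean_settings$noise_sigma <- 0
    clean <- render_stereo(rect, sc$state, clean_settings)
    meas <- list(); reasons <- character(0)
    view_lost <- isTRUE(clean$left$empty) || isTRUE(clean$right$empty)
    for (run in seq_len(runs)) for (fi in seq_len(nf)) {
      if (view_lost) { reasons <- c(reasons, "out-of-frustum"); next }
      fseed <- derive_seed(pos_seed, run * 10000L + fi)
      frames <- list(
        left = add_sensor_noise(clean$left, settings$noise_sigma,
                                derive_seed(fseed, 1L)),
        right = add_sensor_noise(clean$right, settings$noise_sigma,
                                 derive_seed(fseed, 2L)))
      out <- process_stereo_frame(frames, rect, cfg, spec, fseed)
      if (is.character(out)) {
        reasons <- c(reasons, out)
      } else {
        out$position_id <- sc$id; out$frame_index <- fi; out$run_index <- run
        meas[[length(meas) + 1]] <- out
      }
    }
    considered <- length(meas)
    filt <- if (considered > 0) {
      median_outlier_filter(meas, cfg$experiment$outlier_threshold)
    } else list(kept = list(), rejected = list())
    per_pos[[si]] <- list(scene = sc, kept = filt$kept,
                          n_frames = runs * nf, n_considered = considered,
                          n_rejected_detect = runs * nf - considered,
                          n_rejected_outlier = length(filt$rejected),
                          detect_reasons = reasons)
  }

  # reference measurement: mean over kept frames at the reference position
  ref <- per_pos[[1]]
  if (!length(ref$kept)) stop("run_experiment: no accepted frames at the reference position",
                              call. = FALSE)
  ref_valid <- Reduce(`&`, lapply(ref$kept, `[[`, "valid"))
  ref_pts <- Reduce(`+`, lapply(ref$kept, `[[`, "points3d")) / length(ref$kept)
  ref_meas <- structure(list(points3d = ref_pts, valid = ref_valid,
                             position_id = ref$scene$id, frame_index = NA,
                             run_index = NA), class = "grid_measurement")
  ref_truth <- truth_measurement(ref$scene$state, ref_valid)

  ne <- spec$rows * spec$cols
  rows <- list(); el_sums <- rep(0, ne)
  for (si in seq_along(per_pos)) {
    pp <- per_pos[[si]]
    if (si == 1) {
      rows[[si]] <- data.frame(
        position_id = pp$scene$id, depth = pp$scene$depth,
        lateral = pp$scene$lateral, is_reference = TRUE,
        mean_error_m = 0, sd_frames_m = 0, sd_electrodes_m = 0,
        n_frames = pp$n_frames, n_considered = pp$n_considered,
        n_rejected_detect = pp$n_rejected_detect,
        n_rejected_outlier = pp$n_rejected_outlier, n_kept = length(pp$kept),
        stringsAsFactors = FALSE)
      next
    }
    frame_means <- numeric(0)
    el_err <- matrix(NA_real_, length(pp$kept), ne)
    for (mi in seq_along(pp$kept)) {
      m <- pp$kept[[mi]]
      tr <- truth_measurement(pp$scene$state, m$valid)
      err <- relative_pose_error(ref_meas, m, ref_truth, tr)
      el <- err[seq_len(ne)]
      frame_means <- c(frame_means, mean(el, na.rm = TRUE))
      el_err[mi, ] <- el
    }
    el_mean <- if (nrow(el_err)) colMeans(el_err, na.rm = TRUE) else rep(NA_real_, ne)
    add <- ifelse(is.na(el_mean), 0, el_mean)
    el_sums <- el_sums + add
    rows[[si]] <- data.frame(
      position_id = pp$scene$id, depth = pp$scene$depth,
      lateral = pp$scene$lateral, is_reference = FALSE,
      mean_error_m = if (length(frame_means)) mean(frame_means) else NA_real_,
      sd_frames_m = if (length(frame_means) > 1) sd(frame_means) else NA_real_,
      sd_electrodes_m = if (any(!is.na(el_mean))) sd(el_mean, na.rm = TRUE) else NA_real_,
      n_frames = pp$n_frames, n_considered = pp$n_considered,
      n_rejected_detect = pp$n_rejected_detect,
      n_rejected_outlier = pp$n_rejected_outlier, n_kept = length(pp$kept),
      stringsAsFactors = FALSE)
  }
  per_position <- do.call(rbind, rows)

  fp <- do.call(rbind, lapply(split(per_position, per_position$depth), function(d) {
    data.frame(depth = d$depth[1], considered = sum(d$n_considered),
               rejected = sum(d$n_rejected_outlier),
               rate = if (sum(d$n_considered) > 0)
                 sum(d$n_rejected_outlier) / sum(d$n_considered) else 0)
  }))
  rownames(fp) <- NULL

  structure(list(per_position = per_position, per_electrode = el_sums,
                 heatmap = electrode_heatmap(el_sums, spec), fp = fp,
                 totals = list(frames = sum(per_position$n_frames),
                               considered = sum(per_position$n_considered),
                               rejected_detect = sum(per_position$n_rejected_detect),
                               rejected_outlier = sum(per_position$n_rejected_outlier),
                               kept = sum(per_position$n_kept)),
                 seed = cfg$seed),
            class = "error_report")
}

#' Write an error report to CSV + JSON files
#'
#' @param report an `error_report` from [run_experiment()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
report_to_files <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$per_position, file.path(dir, "per_position.csv"),
            row.names = FALSE)
  write.csv(report$fp, file.path(dir, "false_positives.csv"), row.names = FALSE)
  utils::write.table(round(report$heatmap, 6), file.path(dir, "heatmap.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(totals = report$totals, seed = report$seed,
                            per_position = report$per_position),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(dir)
}
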