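# Configuration schema: a nested key-value structure (YAML on disk) with
# defaults for every block, unknown-key rejection, and unit/constraint
# checks before any stage runs.

#' Default pipeline configuration
#'
#' All units are meters and pixels. Every block can be overridden from a
#' YAML config file; [validate_config()] fills defaults and rejects unknown
#' keys.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    rig = list(fx = 450, baseline = 0.098, width = 640L, height = 480L,
               distortion = list(k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0)),
    grid = list(rows = 8L, cols = 8L, pitch = 0.005, disk_diameter = 0.004,
                n_tails = 4L, sheet_margin = 0.003),
    render = list(background = list(mode = "flat", min = 0.10, max = 0.30),
                  lighting = list(azimuth = c(0, 6.2832),
                                  elevation = c(0.7, 1.3), ambient = 0.75),
                  disk_intensity = list(mean = 0.85, sd = 0.02),
                  sheet_intensity = list(mean = 0.45, sd = 0.02),
                  cable_intensity = 0.75, blur_sigma = 0.7,
                  noise_sigma = 0.02, supersample = 4L),
    detector = list(kind = "classical", jitter_px = 0, threshold = NULL,
                    min_area = 60, max_area = 30000, nms = FALSE),
    upscaler = list(kind = "bicubic", factor = 4L),
    pose = list(kind = "classical"),
    experiment = list(depths = seq(40, 90, by = 10) / 100, n_lateral = 5L,
                      width = 0.32, frames_per_position = 30L, runs = 1L,
                      outlier_threshold = 0.10),
    out = NULL)
}

# Recursively merge user values over defaults, erroring on unknown keys.
merge_config <- function(defaults, user, path = character(0)) {
  if (!is.list(user)) return(user)
  out <- defaults
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      stop(sprintf("validate_config: unknown key `%s`", full), call. = FALSE)
    }
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.null(names(defaults[[key]]))) {
      out[[key]] <- merge_config(defaults[[key]], user[[key]], c(path, key))
    } else {
      out[key] <- list(user[[key]])   # keeps explicit NULLs in place
    }
  }
  out
}

#' Validate a pipeline configuration
#'
#' Accepts a nested list, a YAML string, or a path to a YAML file. Fills
#' defaults, rejects unknown keys, and verifies cross-field constraints,
#' naming the offending key in every error message.
#'
#' @param config list, YAML text, or file path; NULL = full defaults.
#' @return a validated configuration list (class `pipeline_config`).
#' @export
validate_config <- function(config = NULL) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.null(config)) config <- list()
  if (is.character(config) && length(config) == 1) {
    config <- if (file.exists(config)) yaml::read_yaml(config)
    else yaml::yaml.load(config)
    if (is.null(config)) config <- list()
  }
  cfg <- merge_config(default_config(), config)
  chk <- function(cond, key, msg) {
    if (!cond) stop(sprintf("validate_config: `%s` %s", key, msg), call. = FALSE)
  }
  chk(cfg$rig$baseline > 0, "rig.baseline", "must be > 0 (meters)")
  chk(cfg$rig$fx > 0, "rig.fx", "must be > 0 (pixels)")
  chk(cfg$rig$width >= 16 && cfg$rig$height >= 16, "rig.width", "sensor too small")
  chk(all(is.finite(unlist(cfg$rig$distortion))), "rig.distortion",
      "coefficients must be finite")
  chk(cfg$grid$pitch > cfg$grid$disk_diameter / 2, "grid.pitch",
      "must exceed half the disk diameter (meters)")
  chk(cfg$upscaler$factor >= 1, "upscaler.factor", "must be >= 1")
  chk(cfg$experiment$frames_per_position >= 1, "experiment.frames_per_position",
      "must be >= 1")
  chk(all(cfg$experiment$depths > 0), "experiment.depths",
      "must be positive (meters)")
  chk(cfg$experiment$outlier_threshold > 0, "experiment.outlier_threshold",
      "must be > 0 (meters)")
  chk(cfg$render$noise_sigma >= 0, "render.noise_sigma", "must be >= 0")
  chk(cfg$detector$kind %in% c("classical", "oracle", "external"),
      "detector.kind", "must be classical, oracle or external")
  cfg$detector_obj <- detector_config(
    kind = cfg$detector$kind, jitter_px = cfg$detector$jitter_px,
    threshold = cfg$detector$threshold, min_area = cfg$detector$min_area,
    max_area = cfg$detector$max_area, nms = cfg$detector$nms)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Serialize a configuration to YAML text
#' @param cfg a validated configuration.
#' @return a YAML string.
#' @export
config_to_yaml <- function(cfg) {
  cfg$detector_obj <- NULL
  class(cfg) <- "list"
  yaml::as.yaml(cfg)
}

config_grid_spec <- function(cfg) {
  grid_spec(rows = cfg$grid$rows, cols = cfg$grid$cols, pitch = cfg$grid$pitch,
            disk_diameter = cfg$grid$disk_diameter, n_tails = cfg$grid$n_tails,
            sheet_margin = cfg$grid$sheet_margin)
}

config_rig <- function(cfg) {
  d <- cfg$rig$distortion
  default_rig(fx = cfg$rig$fx, baseline = cfg$rig$baseline,
              width = cfg$rig$width, height = cfg$rig$height,
              dist_left = distortion_coeffs(d$k1, d$k2, d$k3, d$p1, d$p2),
              dist_right = distortion_coeffs(d$k1, d$k2, d$k3, d$p1, d$p2))
}

config_render_settings <- function(cfg, seed = cfg$seed) {
  r <- cfg$render
  render_settings(background = r$background, lighting = r$lighting,
                  disk_intensity = r$disk_intensity,
                  sheet_intensity = r$sheet_intensity,
                  cable_intensity = r$cable_intensity, blur_sigma = r$blur_sigma,
                  noise_sigma = r$noise_sigma, seed = seed,
                  supersample = r$supersample)
}

#' Generate the deterministic test fixture bundle
#'
#' Writes a tiny bundle used by the test suite and for demos: three labeled
#' stereo scenes at 40/60/90 cm (PNG images, label files, truth CSVs), one
#' 2x2 toy-grid scene, and one deliberately corrupted label file for negative
#' tests, plus a JSON manifest. Deterministic given the seed.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return the manifest list, invisibly written to `manifest.json`.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- validate_config(NULL)
  cfg$seed <- as.integer(seed)
  rig <- config_rig(cfg)
  rig$rectified <- TRUE
  spec <- config_grid_spec(cfg)
  scenes <- list()
  for (z in c(0.40, 0.60, 0.90)) {
    layout <- measurement_layout(depths = z, n_lateral = 1L)
    sc <- make_measurement_scenes(layout, spec)[[1]]
    settings <- config_render_settings(cfg, seed = derive_seed(seed, round(z * 100)))
    pair <- render_stereo(rig, sc$state, settings)
    base <- sprintf("scene_%02.0fcm", z * 100)
    for (side in c("left", "right")) {
      write_image_png(pair[[side]]$image, file.path(dir, sprintf("%s_%s.png", base, side)))
      write_label_file(pair[[side]], file.path(dir, sprintf("%s_%s.txt", base, side)))
    }
    grid_state_to_csv(sc$state, file.path(dir, sprintf("%s_truth.csv", base)))
    scenes[[length(scenes) + 1]] <- list(name = base, depth = z)
  }
  toy_spec <- grid_spec(rows = 2L, cols = 2L)
  toy <- canonical_grid(toy_spec, rigid_pose(diag(3), c(-0.0025, -0.0025, 0.40)))
  toy_pair <- render_stereo(rig, toy,
                            config_render_settings(cfg, seed = derive_seed(seed, 7L)))
  write_image_png(toy_pair$left$image, file.path(dir, "toy_2x2_left.png"))
  write_label_file(toy_pair$left, file.path(dir, "toy_2x2_left.txt"))
  # corrupted label: wrong field count on line 2
  writeLines(c(paste(rep("0.5", 5 + 3 * 8), collapse = " "), "0 0.5 bad"),
             file.path(dir, "corrupted_labels.txt"))
  manifest <- list(seed = seed, scenes = scenes,
                   toy = "toy_2x2_left.png", corrupted = "corrupted_labels.txt")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
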