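# Shared fixtures, built in code and cached across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# Rectified default rig (ideal pinhole, so rectification is the identity).
test_rig <- function() {
  rig <- default_rig()
  rig$rectified <- TRUE
  rig
}

# One grid scene facing the left camera at depth z (centered laterally).
scene_at <- function(z, spec = grid_spec()) {
  make_measurement_scenes(measurement_layout(depths = z, n_lateral = 1L), spec)[[1]]
}

# Rendered stereo pair of the 40 cm scene with default settings (cached:
# several files exercise detection/pose/triangulation on it).
pair_40cm <- function() {
  cached("pair_40cm", render_stereo(test_rig(), scene_at(0.40)$state,
                                    render_settings(seed = 5)))
}

# Clean render: no noise, no blur, flat background, flat lighting -- every
# pixel is exactly its material intensity.
clean_settings <- function(seed = 1) {
  render_settings(background = list(mode = "flat", min = 0.2, max = 0.2),
                  lighting = list(azimuth = c(0, 0), elevation = c(1.5708, 1.5708),
                                  ambient = 1),
                  disk_intensity = list(mean = 0.85, sd = 0),
                  sheet_intensity = list(mean = 0.45, sd = 0),
                  blur_sigma = 0, noise_sigma = 0, seed = seed)
}

# A labeled frame built by hand (for resampling/label bookkeeping tests).
fake_frame <- function(img, keypoints, bbox, visible = rep(TRUE, nrow(keypoints))) {
  structure(list(image = img, bbox = bbox, keypoints = keypoints,
                 visible = visible, empty = FALSE), class = "labeled_frame")
}

# A grid measurement built by hand (for filter/statistic tests).
fake_measurement <- function(points3d, valid = rep(TRUE, nrow(points3d)),
                             position_id = NA) {
  structure(list(points3d = points3d, valid = valid, position_id = position_id,
                 frame_index = NA, run_index = NA), class = "grid_measurement")
}

# Exact-projection keypoint sets of a state in both rectified views.
truth_keypoints <- function(rig, state) {
  poses <- rig_camera_poses(rig)
  pl <- project(rig$left, rig$dist_left, poses$left, state$points3d)
  pr <- project(rig$right, rig$dist_right, poses$right, state$points3d)
  list(left = keypoint_set(pl$pixels, pl$visible, "full"),
       right = keypoint_set(pr$pixels, pr$visible, "full"))
}

# Brute-force one-to-one assignment by permutation enumeration (independent
# oracle for the matching step).
brute_force_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, ncol = length(v)))
    out <- NULL
    for (i in seq_along(v)) out <- rbind(out, cbind(v[i], perms(v[-i])))
    out
  }
  if (n == m) {
    P <- perms(seq_len(m))
    best <- Inf
    for (r in seq_len(nrow(P))) {
      tot <- sum(cost[cbind(seq_len(n), P[r, ])])
      if (tot < best) best <- tot
    }
    best
  } else {
    combs <- utils::combn(m, n)
    best <- Inf
    for (j in seq_len(ncol(combs))) {
      P <- perms(combs[, j])
      for (r in seq_len(nrow(P))) {
        tot <- sum(cost[cbind(seq_len(n), P[r, ])])
        if (tot < best) best <- tot
      }
    }
    best
  }
}

# All n! permutations of 1..n as a matrix (iterative insertion construction).
all_permutations <- function(n) {
  P <- matrix(1L, 1, 1)
  for (k in 2:n) {
    blocks <- vector("list", k)
    for (j in seq_len(k)) {
      left <- if (j > 1) P[, seq_len(j - 1), drop = FALSE] else NULL
      right <- if (j <= k - 1) P[, j:(k - 1), drop = FALSE] else NULL
      blocks[[j]] <- cbind(left, k, right)
    }
    P <- do.call(rbind, blocks)
  }
  P
}
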