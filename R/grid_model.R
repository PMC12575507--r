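# Geometry of the 64-electrode ioECoG grid: an 8x8 array of conductive disks
# in a flexible silicone sheet, plus four cable "tails" leaving one edge.
# The tails break the grid's 4-fold rotational symmetry, which is what makes
# electrode numbering recoverable from images.

#' Electrode grid specification
#'
#' Defaults describe an Ad-Tech style 64-electrode grid: 8x8 disks, 5 mm
#' pitch, 4 mm disk diameter, four cables ("tails") leaving one edge.
#' Electrode indexing is row-major starting at the corner diagonally opposite
#' the tail edge: electrode 1 = grid-frame origin, electrodes 57..64 form the
#' row adjacent to the tails.
#'
#' @param rows,cols electrode counts per axis.
#' @param pitch inter-electrode distance in meters.
#' @param disk_diameter electrode disk diameter in meters.
#' @param n_tails number of cable keypoints (one per cable).
#' @param tail_offsets optional `n_tails` x 2 matrix of tail keypoint
#'   positions in the grid plane (meters). Default: spaced one pitch apart
#'   along the edge adjacent to the last electrode row, one disk diameter
#'   beyond it.
#' @param sheet_margin silicone sheet margin beyond electrode centers, meters.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(rows = 8L, cols = 8L, pitch = 0.005, disk_diameter = 0.004,
                      n_tails = 4L, tail_offsets = NULL, sheet_margin = 0.003) {
  rows <- as.integer(rows); cols <- as.integer(cols); n_tails <- as.integer(n_tails)
  if (rows < 2 || cols < 2) stop("grid_spec: need at least a 2x2 grid", call. = FALSE)
  if (pitch <= disk_diameter / 2) {
    stop("grid_spec: pitch must exceed half the disk diameter", call. = FALSE)
  }
  if (is.null(tail_offsets)) {
    if (n_tails > 0) {
      # centered along the tail edge, one pitch apart, one disk beyond the edge
      xc <- (cols - 1) / 2 * pitch
      xs <- xc + (seq_len(n_tails) - (n_tails + 1) / 2) * pitch
      tail_offsets <- cbind(xs, rep((rows - 1) * pitch + disk_diameter, n_tails))
    } else {
      tail_offsets <- matrix(numeric(0), 0, 2)
    }
  }
  tail_offsets <- matrix(as.numeric(tail_offsets), ncol = 2)
  if (nrow(tail_offsets) != n_tails) {
    stop("grid_spec: tail_offsets must have n_tails rows", call. = FALSE)
  }
  structure(list(rows = rows, cols = cols, pitch = pitch,
                 disk_diameter = disk_diameter, n_tails = n_tails,
                 tail_offsets = tail_offsets, sheet_margin = sheet_margin),
            class = "grid_spec")
}

n_keypoints <- function(spec) spec$rows * spec$cols + spec$n_tails

# Planar keypoint coordinates in the grid frame (z = 0), ordered row-major
# electrodes then tails.
grid_plane_points <- function(spec) {
  rc <- expand.grid(c = seq_len(spec$cols), r = seq_len(spec$rows))
  # row-major: electrode index i = (r-1)*cols + c
  el <- cbind((rc$c - 1) * spec$pitch, (rc$r - 1) * spec$pitch)
  rbind(el, spec$tail_offsets)
}

point_labels <- function(spec) {
  c(rep("electrode", spec$rows * spec$cols), rep("tail", spec$n_tails))
}

#' Canonical (flat) grid state
#'
#' Places the undeformed grid at a rigid pose: electrode (r, c) sits at
#' `((c-1) * pitch, (r-1) * pitch, 0)` in the grid frame and electrode 1 at
#' the grid-frame origin; tails extend beyond the last electrode row.
#'
#' @param spec a [grid_spec()].
#' @param pose [rigid_pose()] of the grid frame in the world frame.
#' @return object of class `grid_state` with fields `spec`, `points3d`
#'   (68x3 for the default spec, world meters), `pose`, `deform_params`.
#' @export
canonical_grid <- function(spec = grid_spec(), pose = rigid_pose()) {
  p2 <- grid_plane_points(spec)
  pts <- cbind(p2, 0)
  structure(list(spec = spec, points3d = pose_apply(pose, pts), pose = pose,
                 deform_params = deform_params(0, 0, 0)),
            class = "grid_state")
}

#' Deformation parameters for the grid sheet
#'
#' The sheet deformation is a cylindrical bend (the dominant mode of a
#' silicone sheet resting on a curved cortex) plus a smooth low-order random
#' height field, followed by edge-length relaxation so the sheet bends
#' without stretching (near-isometry).
#'
#' @param bend_curvature signed curvature of the cylindrical bend, 1/m
#'   (0 = flat; 10 means a 100 mm bend radius).
#' @param bend_axis_angle in-plane angle of the bend axis, radians.
#' @param field_amplitude standard deviation of the random smooth height
#'   field coefficients, meters.
#' @param relax_iters edge-length relaxation sweeps restoring near-isometry.
#' @param max_curvature,max_amplitude accepted parameter bounds; exceeding
#'   them raises an invalid-parameter error in [deform()].
#' @return object of class `deform_params`.
#' @export
deform_params <- function(bend_curvature = 0, bend_axis_angle = 0,
                          field_amplitude = 0, relax_iters = 120L,
                          max_curvature = 20, max_amplitude = 0.0025) {
  structure(list(bend_curvature = bend_curvature,
                 bend_axis_angle = bend_axis_angle,
                 field_amplitude = field_amplitude,
                 relax_iters = as.integer(relax_iters),
                 max_curvature = max_curvature,
                 max_amplitude = max_amplitude),
            class = "deform_params")
}

# Evaluate and restore the RNG around a seeded computation.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Index pairs of nearest-neighbor electrode edges (112 for 8x8).
neighbor_edges <- function(spec) {
  idx <- matrix(seq_len(spec$rows * spec$cols), nrow = spec$rows,
                ncol = spec$cols, byrow = TRUE)
  horiz <- cbind(as.vector(idx[, -spec$cols]), as.vector(idx[, -1]))
  vert <- cbind(as.vector(idx[-spec$rows, ]), as.vector(idx[-1, ]))
  rbind(horiz, vert)
}

#' Deform a grid state
#'
#' Applies the bend + random-field deformation in the grid frame, relaxes
#' nearest-neighbor edge lengths back to the pitch (the silicone sheet bends
#' but does not stretch), and re-applies the grid pose. Deterministic given
#' `seed`; zero-amplitude parameters return the input exactly.
#'
#' @param state a [canonical_grid()] state.
#' @param params a [deform_params()].
#' @param seed integer seed for the random height field.
#' @return a deformed `grid_state`.
#' @export
deform <- function(state, params = deform_params(), seed = 1L) {
  spec <- state$spec
  if (abs(params$bend_curvature) > params$max_curvature) {
    stop("deform: bend_curvature exceeds the isometry-preserving bound", call. = FALSE)
  }
  if (params$field_amplitude < 0 || params$field_amplitude > params$max_amplitude) {
    stop("deform: field_amplitude outside [0, max_amplitude]", call. = FALSE)
  }
  if (params$bend_curvature == 0 && params$field_amplitude == 0) {
    return(state)
  }
  p2 <- grid_plane_points(spec)
  th <- params$bend_axis_angle
  # coordinates along/across the bend direction, centered on the sheet
  ctr <- colMeans(p2[seq_len(spec$rows * spec$cols), , drop = FALSE])
  u <- (p2[, 1] - ctr[1]) * cos(th) + (p2[, 2] - ctr[2]) * sin(th)
  v <- -(p2[, 1] - ctr[1]) * sin(th) + (p2[, 2] - ctr[2]) * cos(th)
  if (params$bend_curvature != 0) {
    R <- 1 / params$bend_curvature
    ub <- R * sin(u / R)
    z <- R * (1 - cos(u / R))
  } else {
    ub <- u
    z <- rep(0, length(u))
  }
  x <- ctr[1] + ub * cos(th) - v * sin(th)
  y <- ctr[2] + ub * sin(th) + v * cos(th)
  pts <- cbind(x, y, z)
  if (params$field_amplitude > 0) {
    ext <- max(spec$pitch * (max(spec$rows, spec$cols) - 1), 1e-6)
    un <- (p2[, 1] - ctr[1]) / (ext / 2)
    vn <- (p2[, 2] - ctr[2]) / (ext / 2)
    # quadratic + cubic monomials: smooth, zero-mean-slope modes only
    basis <- cbind(un^2, un * vn, vn^2, un^3, un^2 * vn, un * vn^2, vn^3)
    coef <- with_seed(seed, rnorm(ncol(basis), sd = params$field_amplitude))
    pts[, 3] <- pts[, 3] + drop(basis %*% coef)
    # edge-length relaxation: pull nearest-neighbor electrode edges (and the
    # tail attachment) back to their rest lengths
    edges <- neighbor_edges(spec)
    rest <- rep(spec$pitch, nrow(edges))
    if (spec$n_tails > 0) {
      flat <- grid_plane_points(spec)
      for (k in seq_len(spec$n_tails)) {
        ti <- spec$rows * spec$cols + k
        d2 <- rowSums(sweep(flat[seq_len(spec$rows * spec$cols), , drop = FALSE],
                            2, flat[ti, ], "-")^2)
        anchor <- which.min(d2)
        edges <- rbind(edges, c(anchor, ti))
        rest <- c(rest, sqrt(d2[anchor]))
      }
    }
    # Jacobi-style length relaxation; corrections are averaged over each
    # vertex's edge degree so simultaneous updates cannot overshoot
    lev <- seq_len(nrow(pts))
    f1 <- factor(edges[, 1], levels = lev); f2 <- factor(edges[, 2], levels = lev)
    deg <- pmax(tabulate(edges[, 1], nrow(pts)) + tabulate(edges[, 2], nrow(pts)), 1)
    for (it in seq_len(params$relax_iters)) {
      d <- pts[edges[, 2], ] - pts[edges[, 1], ]
      len <- sqrt(rowSums(d^2))
      corr <- d * ((len - rest) / pmax(len, 1e-12)) * 0.5
      for (ax in 1:3) {
        acc <- as.vector(tapply(corr[, ax], f1, sum, default = 0)) -
          as.vector(tapply(corr[, ax], f2, sum, default = 0))
        pts[, ax] <- pts[, ax] + acc / deg
      }
    }
  }
  out <- state
  out$points3d <- pose_apply(state$pose, pts)
  out$deform_params <- params
  attr(out$deform_params, "seed") <- seed
  out
}

#' Nearest-neighbor electrode edge lengths of a grid state
#'
#' Used to verify near-isometry: an accepted deformation keeps every
#' nearest-neighbor electrode distance within a few percent of the pitch.
#' @param state a `grid_state`.
#' @return numeric vector of 3D edge lengths (meters).
#' @export
grid_edge_lengths <- function(state) {
  edges <- neighbor_edges(state$spec)
  d <- state$points3d[edges[, 2], ] - state$points3d[edges[, 1], ]
  sqrt(rowSums(d^2))
}

#' Export a grid state as CSV
#'
#' Columns: index, x, y, z (meters, world frame), label (electrode/tail).
#' @param state a `grid_state`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
grid_state_to_csv <- function(state, path) {
  df <- data.frame(index = seq_len(nrow(state$points3d)),
                   x = state$points3d[, 1], y = state$points3d[, 2],
                   z = state$points3d[, 3], label = point_labels(state$spec))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
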