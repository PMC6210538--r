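# ---- synthetic supine articulated figure -----------------------------------
# A 2-D stick-figure proxy for an overhead recording of a supine infant:
# a 14-joint kinematic tree posed by forward kinematics, limb segments
# rendered as textured anti-aliased strips, a torso quad and a head disc on
# a plain noisy background.  Ground-truth joints and generating angles are
# exact by construction.

#' Configuration of the synthetic articulated figure
#'
#' Joint-angle ranges are per *edge* (named by the child part): the angle at
#' the parent joint between the incoming bone and the new segment, in
#' degrees (180 = straight).  `bend_sign` fixes which way each side bends so
#' the figure is left/right asymmetric; texture phase differs per side as an
#' additional asymmetry cue.
#'
#' @param image_size `c(rows, cols)` of the rendered frames.
#' @param limb_width Strip width in pixels.
#' @param head_radius Head disc radius in pixels.
#' @param lengths Named segment lengths in pixels (child part -> distance
#'   from its parent joint).
#' @param angle_ranges Named list of `c(lo, hi)` degree ranges per edge.
#' @param bend_sign Named bend direction (+1 / -1) per edge.
#' @param background Background intensity in `[0, 1]`.
#' @param texture_amp Relative amplitude of the axial stripe texture.
#' @param texture_period Stripe period in pixels.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param head_x,head_y Ranges for the sampled head position.
#' @param axis_deg Range of the body-axis direction (0 = along +x).
#' @param margin Minimum distance of any joint from the canvas border.
#' @return A named list of class `figure_config`.
#' @export
figure_config <- function(image_size = c(120L, 160L),
                          limb_width = 11,
                          head_radius = 11,
                          lengths = c(neck = 16,
                                      l_shoulder = 14, r_shoulder = 14,
                                      l_elbow = 22, r_elbow = 22,
                                      l_hand = 20, r_hand = 20,
                                      l_hip = 38, r_hip = 38,
                                      l_knee = 26, r_knee = 26,
                                      l_foot = 24, r_foot = 24),
                          angle_ranges = list(neck = c(172, 180),
                                              l_shoulder = c(95, 140), r_shoulder = c(95, 140),
                                              l_elbow = c(75, 150), r_elbow = c(75, 150),
                                              l_hand = c(70, 160), r_hand = c(70, 160),
                                              l_hip = c(162, 178), r_hip = c(162, 178),
                                              l_knee = c(115, 165), r_knee = c(115, 165),
                                              l_foot = c(95, 170), r_foot = c(95, 170)),
                          bend_sign = c(neck = 1,
                                        l_shoulder = 1, r_shoulder = -1,
                                        l_elbow = -1, r_elbow = 1,
                                        l_hand = 1, r_hand = -1,
                                        l_hip = 1, r_hip = -1,
                                        l_knee = 1, r_knee = -1,
                                        l_foot = -1, r_foot = 1),
                          background = 0.15,
                          texture_amp = 0.22,
                          texture_period = 7,
                          noise_sd = 0.02,
                          head_x = c(20, 28), head_y = c(52, 68),
                          axis_deg = c(-8, 8),
                          margin = 7) {
  stopifnot(all(lengths > 0), limb_width > 0, head_radius > 0)
  for (r in angle_ranges)
    if (r[1L] < 0 || r[2L] > 180 || r[1L] > r[2L])
      stop("angle ranges must lie within [0, 180]")
  structure(list(image_size = as.integer(image_size), limb_width = limb_width,
                 head_radius = head_radius, lengths = lengths,
                 angle_ranges = angle_ranges, bend_sign = bend_sign,
                 background = background, texture_amp = texture_amp,
                 texture_period = texture_period, noise_sd = noise_sd,
                 head_x = head_x, head_y = head_y, axis_deg = axis_deg,
                 margin = margin),
            class = "figure_config")
}

rot2 <- function(v, deg) {
  a <- deg * pi / 180
  c(cos(a) * v[1L] - sin(a) * v[2L], sin(a) * v[1L] + cos(a) * v[2L])
}

# Forward kinematics: joints from edge angles, head position and body axis.
figure_fk <- function(angles, head, phi, config, tree = infant_tree()) {
  joints <- matrix(NA_real_, length(tree$parts), 2L,
                   dimnames = list(tree$parts, c("x", "y")))
  joints["head", ] <- head
  axis_dir <- c(cos(phi * pi / 180), sin(phi * pi / 180))
  for (ch in setdiff(tree$order, tree$root)) {
    pa <- tree$parent[[ch]]
    gp <- tree$parent[[pa]]
    in_dir <- if (is.na(gp)) axis_dir else {
      v <- joints[pa, ] - joints[gp, ]
      v / sqrt(sum(v^2))
    }
    out_dir <- rot2(in_dir, config$bend_sign[[ch]] * (180 - angles[[ch]]))
    joints[ch, ] <- joints[pa, ] + config$lengths[[ch]] * out_dir
  }
  joints
}

#' Sample a random figure pose
#'
#' Draws every edge angle uniformly from its configured range, the head
#' position and body-axis direction from theirs, and runs forward
#' kinematics down the tree.  Poses whose joints leave the canvas margin are
#' resampled (bounded retries).
#'
#' @param config A [figure_config()].
#' @param tree The kinematic tree (default [infant_tree()]).
#' @param max_retries Resampling budget before giving up.
#' @return List with `joints` (14 x 2 matrix, 0-based pixel coordinates),
#'   `angles` (named generating angles per edge, degrees), `head`, `phi`.
#' @export
sample_pose <- function(config = figure_config(), tree = infant_tree(),
                        max_retries = 50L) {
  h <- config$image_size[1L]; w <- config$image_size[2L]
  m <- config$margin
  for (i in seq_len(max_retries)) {
    angles <- vapply(config$angle_ranges, function(r) stats::runif(1, r[1L], r[2L]),
                     numeric(1L))
    head <- c(stats::runif(1, config$head_x[1L], config$head_x[2L]),
              stats::runif(1, config$head_y[1L], config$head_y[2L]))
    phi <- stats::runif(1, config$axis_deg[1L], config$axis_deg[2L])
    joints <- figure_fk(angles, head, phi, config, tree)
    if (all(joints[, "x"] >= m & joints[, "x"] <= w - 1 - m &
            joints[, "y"] >= m & joints[, "y"] <= h - 1 - m))
      return(list(joints = joints, angles = angles, head = head, phi = phi))
  }
  stop("could not sample a pose inside the canvas after ", max_retries,
       " retries; enlarge the image or narrow the angle ranges")
}

# Paint an anti-aliased textured capsule (segment p -> q of width w) onto img.
paint_capsule <- function(img, p, q, w, base, amp, period, phase,
                          antialias = TRUE) {
  h <- nrow(img); wd <- ncol(img)
  X <- matrix(0:(wd - 1L), h, wd, byrow = TRUE)
  Y <- matrix(0:(h - 1L), h, wd)
  v <- q - p
  L2 <- sum(v^2)
  t <- if (L2 == 0) matrix(0, h, wd) else
    pmin(pmax(((X - p[1L]) * v[1L] + (Y - p[2L]) * v[2L]) / L2, 0), 1)
  dx <- X - (p[1L] + t * v[1L])
  dy <- Y - (p[2L] + t * v[2L])
  d <- sqrt(dx^2 + dy^2)
  cov <- if (antialias) pmin(1, pmax(0, w / 2 + 0.5 - d)) else
    (d <= w / 2) + 0
  if (!any(cov > 0)) return(img)
  val <- base * (1 + amp * cos(2 * pi * (t * sqrt(L2)) / period + phase))
  val <- pmin(pmax(val, 0), 1)
  img * (1 - cov) + val * cov
}

paint_disc <- function(img, c0, r, base, antialias = TRUE) {
  h <- nrow(img); wd <- ncol(img)
  X <- matrix(0:(wd - 1L), h, wd, byrow = TRUE)
  Y <- matrix(0:(h - 1L), h, wd)
  d <- sqrt((X - c0[1L])^2 + (Y - c0[2L])^2)
  cov <- if (antialias) pmin(1, pmax(0, r + 0.5 - d)) else (d <= r) + 0
  img * (1 - cov) + base * cov
}

# Convex-quad fill (torso), hard-edged; the surrounding capsules soften it.
paint_quad <- function(img, pts, base) {
  h <- nrow(img); wd <- ncol(img)
  X <- matrix(0:(wd - 1L), h, wd, byrow = TRUE)
  Y <- matrix(0:(h - 1L), h, wd)
  inside <- matrix(TRUE, h, wd)
  n <- nrow(pts)
  # winding sign from the polygon itself so vertex order doesn't matter
  cr <- function(i, P) {
    a <- pts[i, ]; b <- pts[i %% n + 1L, ]
    (b[1L] - a[1L]) * (P$y - a[2L]) - (b[2L] - a[2L]) * (P$x - a[1L])
  }
  cent <- colMeans(pts)
  for (i in seq_len(n)) {
    s <- cr(i, list(x = cent[1L], y = cent[2L]))
    if (s == 0) next
    inside <- inside & (cr(i, list(x = X, y = Y)) * sign(s) >= 0)
  }
  img[inside] <- base
  img
}

segment_style <- function(ch) {
  base <- switch(ch,
                 neck = 0.85,
                 l_shoulder = 0.62, r_shoulder = 0.62,
                 l_hip = 0.58, r_hip = 0.58,
                 l_elbow = 0.72, r_elbow = 0.72,
                 l_hand = 0.78, r_hand = 0.78,
                 l_knee = 0.68, r_knee = 0.68,
                 l_foot = 0.74, r_foot = 0.74,
                 0.7)
  phase <- if (startsWith(ch, "l_")) pi / 2 else if (startsWith(ch, "r_")) 0 else pi / 4
  list(base = base, phase = phase)
}

#' Render one synthetic frame
#'
#' Draws the torso quad, every limb segment as a textured strip of the
#' configured width, and the head disc, then adds Gaussian noise.  The
#' returned annotation is the exact generating joint set.
#'
#' @param pose A pose from [sample_pose()] (or any list with `joints`).
#' @param config A [figure_config()].
#' @param tree The kinematic tree.
#' @param antialias Feather strip borders over 1 px (default `TRUE`); with
#'   `FALSE` the foreground is the exact point-in-strip set.
#' @param noise Add Gaussian pixel noise (default `TRUE`; uses the current
#'   RNG stream).
#' @param id Frame identifier stored in the annotation.
#' @return An `annotated_frame`: list with `image`, `joints`, `visible`,
#'   `id`.
#' @export
render_frame <- function(pose, config = figure_config(), tree = infant_tree(),
                         antialias = TRUE, noise = TRUE, id = "frame") {
  h <- config$image_size[1L]; w <- config$image_size[2L]
  img <- matrix(config$background, h, w)
  J <- pose$joints
  quad <- rbind(J["l_shoulder", ], J["r_shoulder", ], J["r_hip", ], J["l_hip", ])
  img <- paint_quad(img, quad, 0.55)
  for (ch in setdiff(tree$order, tree$root)) {
    pa <- tree$parent[[ch]]
    st <- segment_style(ch)
    img <- paint_capsule(img, J[pa, ], J[ch, ], config$limb_width,
                         st$base, config$texture_amp, config$texture_period,
                         st$phase, antialias)
  }
  img <- paint_disc(img, J["head", ], config$head_radius, 0.88, antialias)
  if (noise && config$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w)
    img <- pmin(pmax(img, 0), 1)
  }
  structure(list(image = img, joints = J,
                 visible = stats::setNames(rep(TRUE, nrow(J)), rownames(J)),
                 id = id),
            class = "annotated_frame")
}

#' @export
print.annotated_frame <- function(x, ...) {
  cat(sprintf("<annotated_frame> %s: %d x %d px, %d joints\n", x$id,
              nrow(x$image), ncol(x$image), nrow(x$joints)))
  invisible(x)
}

# Overwrite the strips of the given parts with background (self-occlusion
# stand-in); returns the masked image.
mask_parts <- function(img, pose, config, parts, tree = infant_tree()) {
  for (ch in intersect(setdiff(tree$order, tree$root), parts)) {
    pa <- tree$parent[[ch]]
    img <- paint_capsule(img, pose$joints[pa, ], pose$joints[ch, ],
                         config$limb_width + 2, config$background, 0, 1, 0)
  }
  img
}

#' Generate an independent set of annotated training frames
#'
#' @param n Number of frames.
#' @param config A [figure_config()].
#' @param seed RNG seed (full determinism).
#' @return List of `annotated_frame` objects with random poses.
#' @export
generate_training_frames <- function(n, config = figure_config(), seed = 1L) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    pose <- sample_pose(config)
    fr <- render_frame(pose, config, id = sprintf("train_%04d", i))
    attr(fr, "pose") <- pose
    fr
  }))
}

#' Generate human-free negative frames
#'
#' Background plus noise and a few random bright bars and blobs, so that
#' negatives are not trivially separable from the figure by mean intensity.
#'
#' @inheritParams generate_training_frames
#' @param clutter Add random bright bars and discs (default `TRUE`); with
#'   `FALSE` negatives are plain background plus noise.
#' @return List of grayscale matrices.
#' @export
generate_negative_frames <- function(n, config = figure_config(), seed = 1L,
                                     clutter = TRUE) {
  h <- config$image_size[1L]; w <- config$image_size[2L]
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    img <- matrix(config$background, h, w)
    for (k in seq_len(if (clutter) stats::rpois(1, 2) else 0L)) {
      p <- c(stats::runif(1, 0, w - 1), stats::runif(1, 0, h - 1))
      ang <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 15, 60)
      q <- p + len * c(cos(ang), sin(ang))
      img <- paint_capsule(img, p, q, stats::runif(1, 5, 14),
                           stats::runif(1, 0.4, 0.9), config$texture_amp,
                           config$texture_period, stats::runif(1, 0, 2 * pi))
    }
    if (clutter && stats::runif(1) < 0.5)
      img <- paint_disc(img, c(stats::runif(1, 0, w - 1), stats::runif(1, 0, h - 1)),
                        stats::runif(1, 6, 14), stats::runif(1, 0.5, 0.9))
    if (config$noise_sd > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w)
    pmin(pmax(img, 0), 1)
  }))
}

#' Default per-edge sinusoidal motion program
#'
#' @param config A [figure_config()] (amplitudes are clamped into its angle
#'   ranges at generation time).
#' @return Named list per edge: `list(amp, period, phase)` in degrees /
#'   frames / radians.
#' @export
default_motion <- function(config = figure_config()) {
  list(neck = list(amp = 2, period = 90, phase = 0),
       l_shoulder = list(amp = 10, period = 80, phase = 0),
       r_shoulder = list(amp = 12, period = 65, phase = 1.1),
       l_elbow = list(amp = 18, period = 55, phase = 0.4),
       r_elbow = list(amp = 16, period = 60, phase = 2.0),
       l_hand = list(amp = 20, period = 45, phase = 1.6),
       r_hand = list(amp = 18, period = 70, phase = 0.9),
       l_hip = list(amp = 3, period = 95, phase = 0.2),
       r_hip = list(amp = 3, period = 85, phase = 1.4),
       l_knee = list(amp = 15, period = 55, phase = 2.4),
       r_knee = list(amp = 14, period = 75, phase = 0.7),
       l_foot = list(amp = 18, period = 65, phase = 1.2),
       r_foot = list(amp = 16, period = 85, phase = 2.8))
}

#' Generate a synthetic video sequence with ground truth
#'
#' Each edge angle follows its (clamped) sinusoid around the midpoint of its
#' configured range; the head position and body axis are sampled once, so
#' per-frame joint displacement stays small and bounded.  An optional
#' occlusion schedule masks stated limbs over stated frame ranges (their
#' strips are painted over with background and their ground-truth visibility
#' flags drop).
#'
#' @param config A [figure_config()].
#' @param motion Per-edge motion program, see [default_motion()].
#' @param n_frames Number of frames (>= 1).
#' @param seed RNG seed.
#' @param occlusion Optional list of `list(parts =, from =, to =)` entries.
#' @param tree The kinematic tree.
#' @details The pixel-noise field is drawn once per sequence and reused on
#'   every frame, so a frozen motion program yields bit-identical frames.
#' @return List with `frames` (list of matrices), `trajectory` (`frame`,
#'   `part`, `x`, `y`, `visible`), `angles` (`frame`, `joint`, `theta`,
#'   keyed by the vertex joint), `poses` (per-frame pose lists) and
#'   `max_step` (largest per-frame joint displacement, px).
#' @export
generate_sequence <- function(config = figure_config(),
                              motion = default_motion(config),
                              n_frames = 50L, seed = 1L, occlusion = NULL,
                              tree = infant_tree()) {
  stopifnot(n_frames >= 1L)
  aj <- angle_joints(tree)
  withr::with_seed(seed, {
    head <- c(stats::runif(1, config$head_x[1L], config$head_x[2L]),
              stats::runif(1, config$head_y[1L], config$head_y[2L]))
    phi <- stats::runif(1, config$axis_deg[1L], config$axis_deg[2L])
    noise_field <- if (config$noise_sd > 0)
      matrix(stats::rnorm(prod(config$image_size), 0, config$noise_sd),
             config$image_size[1L], config$image_size[2L]) else 0
    edges <- names(config$angle_ranges)
    frames <- vector("list", n_frames)
    poses <- vector("list", n_frames)
    traj <- vector("list", n_frames)
    angs <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      theta <- vapply(edges, function(e) {
        r <- config$angle_ranges[[e]]
        mid <- mean(r)
        m <- motion[[e]]
        v <- if (is.null(m)) mid else
          mid + m$amp * sin(2 * pi * (t - 1) / m$period + m$phase)
        min(max(v, r[1L]), r[2L])
      }, numeric(1L))
      pose <- list(joints = figure_fk(theta, head, phi, config, tree),
                   angles = theta, head = head, phi = phi)
      vis <- stats::setNames(rep(TRUE, length(tree$parts)), tree$parts)
      fr <- render_frame(pose, config, tree, noise = FALSE,
                         id = sprintf("seq_%04d", t))
      img <- pmin(pmax(fr$image + noise_field, 0), 1)
      if (!is.null(occlusion)) {
        for (oc in occlusion) {
          if (t >= oc$from && t <= oc$to) {
            img <- mask_parts(img, pose, config, oc$parts, tree)
            vis[oc$parts] <- FALSE
          }
        }
      }
      frames[[t]] <- img
      poses[[t]] <- pose
      traj[[t]] <- data.frame(frame = t, part = rownames(pose$joints),
                              x = pose$joints[, "x"], y = pose$joints[, "y"],
                              visible = vis[rownames(pose$joints)],
                              stringsAsFactors = FALSE)
      angs[[t]] <- data.frame(frame = t, joint = aj$joint,
                              theta = unname(theta[aj$child]),
                              stringsAsFactors = FALSE)
    }
    trajectory <- do.call(rbind, traj)
    rownames(trajectory) <- NULL
    angles <- do.call(rbind, angs)
    rownames(angles) <- NULL
    steps <- vapply(seq_len(n_frames - 1L), function(t)
      max(sqrt(rowSums((poses[[t + 1L]]$joints - poses[[t]]$joints)^2))),
      numeric(1L))
    list(frames = frames, trajectory = trajectory, angles = angles,
         poses = poses, max_step = if (length(steps)) max(steps) else 0)
  })
}
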