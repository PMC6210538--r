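#' Part-filter response at one location
#'
#' Cross-correlation of a part template with the HOG cells under its
#' footprint, anchored at the top-left cell `l = c(x, y)`.
#'
#' @param filter Numeric array `patch x patch x bins` of template weights.
#' @param level A [hog_level()].
#' @param l Anchor cell `c(x, y)`, 0-based.
#' @return Scalar response.
#' @export
filter_response <- function(filter, level, l) {
  pc <- dim(filter)[1L]
  dlev <- dim(level$cells)
  if (l[1L] < 0 || l[2L] < 0 || l[1L] + pc > dlev[2L] || l[2L] + pc > dlev[1L])
    stop("filter footprint out of bounds at (", l[1L], ", ", l[2L], ")")
  sum(filter * level$cells[l[2L] + seq_len(pc), l[1L] + seq_len(pc), , drop = FALSE])
}

#' Full response map of a part filter over a level
#'
#' @inheritParams filter_response
#' @return Matrix over valid anchor cells, indexed `[y + 1, x + 1]`.
#' @export
filter_response_map <- function(filter, level) {
  cpp_xcorr(level$cells, filter)
}

#' Spring deformation feature
#'
#' @param l_a,l_b Cell coordinates `c(x, y)` of the child and parent parts.
#' @return `c(dx, dy, dx^2, dy^2)` with `dx = x_a - x_b`, `dy = y_a - y_b`.
#' @export
deformation_feature <- function(l_a, l_b) {
  dx <- l_a[1L] - l_b[1L]
  dy <- l_a[2L] - l_b[2L]
  c(dx, dy, dx^2, dy^2)
}

#' Spring deformation score for one edge
#'
#' The score contribution of placing child `a` at `l_a` when its parent `b`
#' sits at `l_b`, with rest offset `anchor`: minus the inner product of the
#' deformation weights with the displacement feature of
#' `l_a - l_b - anchor`.  Zero when the child sits exactly at its rest
#' location.
#'
#' @param zeta Length-4 deformation weights `[dx, dy, dx^2, dy^2]`.
#' @param l_a,l_b Cell coordinates `c(x, y)`.
#' @param anchor Rest offset `c(ax, ay)` of the child relative to the parent.
#' @return Scalar score (non-positive for zero linear terms).
#' @export
deformation_score <- function(zeta, l_a, l_b, anchor = c(0, 0)) {
  d <- c(l_a[1L] - l_b[1L] - anchor[1L], l_a[2L] - l_b[2L] - anchor[2L])
  -sum(zeta * c(d, d^2))
}

# Max-plus spring message (compiled path).  score is the child's total score
# matrix [y, x]; returns for every parent cell the best child score minus
# the spring penalty, plus 1-based argmax indices.
spring_message <- function(score, zeta, anchor) {
  cpp_spring_max(score, zeta[1L], zeta[3L], zeta[2L], zeta[4L],
                 anchor[1L], anchor[2L])
}

# Explicit O(n^2) reference used by tests as the oracle for the separable
# compiled pass.  Identical tie-breaking: smallest (y, x).
spring_message_ref <- function(score, zeta, anchor) {
  nr <- nrow(score); nc <- ncol(score)
  val <- matrix(-Inf, nr, nc)
  argy <- argx <- matrix(1L, nr, nc)
  for (px in seq_len(nc)) {
    for (py in seq_len(nr)) {
      best <- -Inf; by <- 1L; bx <- 1L
      for (cy in seq_len(nr)) {
        for (cx in seq_len(nc)) {
          dx <- (cx - px) - anchor[1L]
          dy <- (cy - py) - anchor[2L]
          v <- score[cy, cx] - (zeta[1L] * dx + zeta[2L] * dy +
                                zeta[3L] * dx^2 + zeta[4L] * dy^2)
          if (v > best) { best <- v; by <- cy; bx <- cx }
        }
      }
      val[py, px] <- best; argy[py, px] <- by; argx[py, px] <- bx
    }
  }
  list(val = val, argy = argy, argx = argx)
}

# Valid-placement mask for one level given a pixel-space search box
# c(x0, y0, x1, y1): TRUE where the patch center falls inside the box.
level_region_mask <- function(level, region, patch_cells) {
  dlev <- dim(level$cells)
  vr <- dlev[1L] - patch_cells + 1L
  vc <- dlev[2L] - patch_cells + 1L
  if (vr < 1L || vc < 1L) return(NULL)
  if (is.null(region)) return(matrix(TRUE, vr, vc))
  cx <- cell_center_px(0:(vc - 1L), level$cell_size_px, level$scale, patch_cells)
  cy <- cell_center_px(0:(vr - 1L), level$cell_size_px, level$scale, patch_cells)
  okx <- cx >= region[1L] & cx <= region[3L]
  oky <- cy >= region[2L] & cy <= region[4L]
  outer(oky, okx, "&")
}

#' Detect body-part configurations in a feature pyramid
#'
#' Dynamic-programming inference over the kinematic tree: per pyramid level,
#' filter responses are computed for every (part, state), messages are
#' passed from the leaves to the root (maximizing over each child's location
#' and state with the quadratic spring penalty and the pairwise
#' co-occurrence prior), and full configurations are recovered from argmax
#' backpointers at the best root placements.  Candidates across all levels
#' are returned sorted by score; ties resolve to the smallest
#' (level, y, x, state).
#'
#' @param model A trained [body_model()].
#' @param pyramid A [hog_pyramid()] built with the model's feature settings.
#' @param search_region Optional pixel-space box `c(x0, y0, x1, y1)` in the
#'   original image restricting every part's patch center (whole-body
#'   temporal search restriction); `NULL` searches the full frame.
#' @param max_candidates Maximum number of root candidates to backtrack.
#' @param root_nms Optional IoU threshold: greedily suppress root placements
#'   whose patch boxes overlap a better-scoring candidate above it *before*
#'   backtracking (equivalent to running [nms()] on the result, but cheaper;
#'   used by hard-negative mining to diversify candidates).
#' @return List of `pose_estimate` objects, best first.  Empty (with a
#'   warning) if the search region excludes every placement.
#' @export
infer_pose <- function(model, pyramid, search_region = NULL,
                       max_candidates = 20L, root_nms = NULL) {
  if (!is.null(search_region) &&
      (search_region[3L] < search_region[1L] || search_region[4L] < search_region[2L])) {
    warning("empty search region: no detections")
    return(list())
  }
  pc <- model$config$patch_cells
  tree <- model$tree
  nonroot <- setdiff(tree$order, tree$root)
  tabs <- list()   # per-level DP tables for backtracking
  cand <- list()
  for (li in seq_along(pyramid$levels)) {
    level <- pyramid$levels[[li]]
    mask <- level_region_mask(level, search_region, pc)
    if (is.null(mask)) next
    if (!any(mask)) next
    local <- list()   # per part: list over states of (response + unary)
    for (p in tree$parts) {
      local[[p]] <- lapply(seq_len(model$states[[p]]), function(s) {
        r <- filter_response_map(model$filters[[p]][[s]], level) +
          model$unary[[p]][s]
        r[!mask] <- -Inf
        r
      })
    }
    msg <- list(); arg <- list()
    total <- local  # accumulates children messages, leaf -> root
    for (ch in rev(nonroot)) {
      pa <- tree$parent[[ch]]
      Sa <- model$states[[ch]]; Sb <- model$states[[pa]]
      msg[[ch]] <- vector("list", Sb)
      arg[[ch]] <- vector("list", Sb)
      for (sb in seq_len(Sb)) {
        bestv <- NULL; by <- bx <- bs <- NULL
        for (sa in seq_len(Sa)) {
          sm <- spring_message(total[[ch]][[sa]],
                               model$zeta[[ch]][sa, sb, ],
                               model$anchor[[ch]][sa, sb, ])
          v <- sm$val + model$pairwise[[ch]][sa, sb]
          if (is.null(bestv)) {
            bestv <- v; by <- sm$argy; bx <- sm$argx
            bs <- matrix(sa, nrow(v), ncol(v))
          } else {
            upd <- v > bestv |
              (v == bestv & (sm$argy < by | (sm$argy == by & sm$argx < bx)))
            bestv[upd] <- v[upd]; by[upd] <- sm$argy[upd]
            bx[upd] <- sm$argx[upd]; bs[upd] <- sa
          }
        }
        msg[[ch]][[sb]] <- bestv
        arg[[ch]][[sb]] <- list(y = by, x = bx, s = bs)
      }
      for (sb in seq_len(Sb))
        total[[pa]][[sb]] <- total[[pa]][[sb]] + msg[[ch]][[sb]]
    }
    root <- tree$root
    for (s in seq_len(model$states[[root]])) {
      sc <- total[[root]][[s]] + model$bias
      fin <- which(is.finite(sc), arr.ind = TRUE)
      if (!nrow(fin)) next
      cand[[length(cand) + 1L]] <-
        data.frame(level = li, state = s, y = fin[, 1L], x = fin[, 2L],
                   score = sc[fin])
    }
    tabs[[li]] <- list(level = level, local = local, arg = arg, total = total)
  }
  if (!length(cand)) {
    warning("no valid placements in any pyramid level")
    return(list())
  }
  cand <- do.call(rbind, cand)
  ord <- order(-cand$score, cand$level, cand$y, cand$x, cand$state)
  cand <- cand[ord, , drop = FALSE]
  if (!is.null(root_nms) && nrow(cand) > 1L) {
    half <- vapply(cand$level, function(li)
      pyramid$levels[[li]]$cell_size_px * pc / (2 * pyramid$levels[[li]]$scale),
      numeric(1L))
    cx <- vapply(seq_len(nrow(cand)), function(i)
      cell_center_px(cand$x[i] - 1L, pyramid$levels[[cand$level[i]]]$cell_size_px,
                     pyramid$levels[[cand$level[i]]]$scale, pc), numeric(1L))
    cy <- vapply(seq_len(nrow(cand)), function(i)
      cell_center_px(cand$y[i] - 1L, pyramid$levels[[cand$level[i]]]$cell_size_px,
                     pyramid$levels[[cand$level[i]]]$scale, pc), numeric(1L))
    keep <- logical(nrow(cand))
    alive <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!alive[i]) next
      keep[i] <- TRUE
      if (sum(keep) >= max_candidates) break
      bi <- c(cx[i] - half[i], cy[i] - half[i], cx[i] + half[i], cy[i] + half[i])
      js <- which(alive & seq_len(nrow(cand)) > i)
      for (j in js) {
        bj <- c(cx[j] - half[j], cy[j] - half[j], cx[j] + half[j], cy[j] + half[j])
        if (box_iou(bi, bj) > root_nms) alive[j] <- FALSE
      }
    }
    cand <- cand[keep, , drop = FALSE]
  }
  n <- min(nrow(cand), max_candidates)
  lapply(seq_len(n), function(i)
    backtrack_pose(model, tabs, cand$level[i], cand$state[i],
                   cand$y[i], cand$x[i], cand$score[i]))
}

# Recover the full part configuration from the DP argmax tables.
backtrack_pose <- function(model, tabs, li, s_root, y, x, score) {
  tree <- model$tree
  tab <- tabs[[li]]
  level <- tab$level
  pc <- model$config$patch_cells
  n <- length(tree$parts)
  place <- data.frame(part = tree$parts, state = NA_integer_,
                      x = NA_integer_, y = NA_integer_,
                      score = NA_real_, stringsAsFactors = FALSE)
  rownames(place) <- tree$parts
  place[tree$root, c("state", "x", "y")] <- list(s_root, x - 1L, y - 1L)
  for (ch in setdiff(tree$order, tree$root)) {
    pa <- tree$parent[[ch]]
    sp <- place[pa, "state"]
    a <- tab$arg[[ch]][[sp]]
    py <- place[pa, "y"] + 1L; px <- place[pa, "x"] + 1L
    place[ch, c("state", "x", "y")] <-
      list(a$s[py, px], a$x[py, px] - 1L, a$y[py, px] - 1L)
  }
  for (p in tree$parts)
    place[p, "score"] <- tab$local[[p]][[place[p, "state"]]][place[p, "y"] + 1L,
                                                            place[p, "x"] + 1L]
  px <- cell_center_px(place$x, level$cell_size_px, level$scale, pc)
  py <- cell_center_px(place$y, level$cell_size_px, level$scale, pc)
  parts <- data.frame(part = place$part, state = place$state,
                      cx = place$x, cy = place$y, score = place$score,
                      x = px, y = py, visible = TRUE,
                      stringsAsFactors = FALSE)
  structure(list(level = li, scale = level$scale,
                 cell_size_px = level$cell_size_px, patch_cells = pc,
                 score = score, parts = parts),
            class = "pose_estimate")
}

#' @export
print.pose_estimate <- function(x, ...) {
  cat(sprintf("<pose_estimate> score %.3f, level %d (scale %.3f), %d/%d parts visible\n",
              x$score, x$level, x$scale, sum(x$parts$visible), nrow(x$parts)))
  invisible(x)
}

# Root patch box in original-image pixels: c(x0, y0, x1, y1).
root_box <- function(pose, root) {
  i <- match(root, pose$parts$part)
  half <- pose$cell_size_px * (pose$patch_cells %||% 5L) / (2 * pose$scale)
  c(pose$parts$x[i] - half, pose$parts$y[i] - half,
    pose$parts$x[i] + half, pose$parts$y[i] + half)
}

box_iou <- function(a, b) {
  ix <- max(0, min(a[3L], b[3L]) - max(a[1L], b[1L]))
  iy <- max(0, min(a[4L], b[4L]) - max(a[2L], b[2L]))
  inter <- ix * iy
  area <- function(z) (z[3L] - z[1L]) * (z[4L] - z[2L])
  u <- area(a) + area(b) - inter
  if (u <= 0) return(0)
  inter / u
}

#' Greedy non-maximum suppression over pose candidates
#'
#' Keeps the best-scoring candidate, suppresses any candidate whose root
#' patch box overlaps it above `overlap_threshold`
#' (intersection-over-union), and repeats on the remainder.
#'
#' @param candidates List of `pose_estimate` objects (any order).
#' @param overlap_threshold IoU above which a candidate is suppressed
#'   (default 0.3).
#' @param root Name of the root part (boxes are taken around it).
#' @return Score-sorted list of surviving candidates.
#' @export
nms <- function(candidates, overlap_threshold = 0.3, root = "head") {
  if (!length(candidates)) return(candidates)
  sc <- vapply(candidates, function(p) p$score, numeric(1L))
  candidates <- candidates[order(-sc)]
  boxes <- lapply(candidates, root_box, root = root)
  keep <- logical(length(candidates))
  alive <- rep(TRUE, length(candidates))
  for (i in seq_along(candidates)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i < length(candidates)) {
      for (j in (i + 1L):length(candidates)) {
        if (alive[j] && box_iou(boxes[[i]], boxes[[j]]) > overlap_threshold)
          alive[j] <- FALSE
      }
    }
    alive[i] <- FALSE
  }
  candidates[keep]
}

#' Flag occluded parts by score thresholding
#'
#' Parts whose local score (filter response plus unary co-occurrence at the
#' chosen placement) falls below the threshold are flagged occluded.  Their
#' locations are retained but downstream angle computation and metrics skip
#' them.
#'
#' @param pose A `pose_estimate`.
#' @param omega_score Scalar threshold, or a named per-part vector (missing
#'   parts fall back to `-Inf`, i.e. always visible).
#' @return The pose with updated `parts$visible`.
#' @export
apply_occlusion_threshold <- function(pose, omega_score) {
  th <- if (length(omega_score) == 1L && is.null(names(omega_score))) {
    rep(omega_score, nrow(pose$parts))
  } else {
    v <- omega_score[pose$parts$part]
    v[is.na(v)] <- -Inf
    v
  }
  pose$parts$visible <- pose$parts$score >= th
  pose
}

#' Temporal search-space restriction from the previous frame
#'
#' Returns the axis-aligned bounding box of the previous frame's joint
#' estimates dilated by `omega_dist` pixels on every side and clipped to the
#' image; exhaustive full-frame search is then needed only for the first
#' frame.
#'
#' @param prev_pose The `pose_estimate` from frame t-1.
#' @param omega_dist Dilation in pixels (level-0 scale).
#' @param image_shape `c(rows, cols)` of the frame.
#' @return Pixel box `c(x0, y0, x1, y1)`.
#' @export
restrict_search_space <- function(prev_pose, omega_dist, image_shape) {
  x <- prev_pose$parts$x; y <- prev_pose$parts$y
  c(max(0, min(x) - omega_dist), max(0, min(y) - omega_dist),
    min(image_shape[2L] - 1, max(x) + omega_dist),
    min(image_shape[1L] - 1, max(y) + omega_dist))
}

#' Detect the infant pose in a single frame
#'
#' Convenience wrapper: builds the pyramid (unless one is supplied), runs
#' [infer_pose()], applies [nms()] and the occlusion threshold, and in
#' single-subject mode returns only the best surviving pose.
#'
#' @param model A trained [body_model()].
#' @param frame Grayscale image matrix, or a prebuilt [hog_pyramid()].
#' @param search_region Optional pixel box, see [infer_pose()].
#' @param omega_score Occlusion threshold; defaults to the thresholds stored
#'   in the model.
#' @param overlap_threshold NMS overlap (default 0.3).
#' @param single_subject If `TRUE` (default) return one `pose_estimate`;
#'   otherwise the NMS survivor list.
#' @param max_candidates Passed to [infer_pose()].
#' @return A `pose_estimate` (or list of them), or `NULL` if nothing was
#'   detected.
#' @export
detect_frame <- function(model, frame, search_region = NULL,
                         omega_score = model$omega_score,
                         overlap_threshold = 0.3, single_subject = TRUE,
                         max_candidates = 20L) {
  pyr <- if (inherits(frame, "hog_pyramid")) frame else
    build_pyramid(frame, model$config$cell_size_px, model$config$bins,
                  model$config$interval, model$config$min_level_px,
                  model$config$normalize,
                  max_scale = model$config$train_scale %||% 1)
  cands <- infer_pose(model, pyr, search_region, max_candidates)
  if (!length(cands)) return(NULL)
  cands <- nms(cands, overlap_threshold, model$tree$root)
  cands <- lapply(cands, apply_occlusion_threshold, omega_score = omega_score)
  if (single_subject) cands[[1L]] else cands
}

#' Detect poses over a frame sequence with temporal restriction
#'
#' Runs exhaustive detection on the first frame only; every later frame is
#' searched inside the previous pose's bounding box dilated by `omega_dist`
#' pixels.  A periodic full-frame search can be forced with
#' `full_search_every`.
#'
#' @param model A trained [body_model()].
#' @param frames List of grayscale matrices or PNG paths.
#' @param omega_dist Search dilation in pixels (default 30).
#' @param full_search_every Force a full-frame search every N frames
#'   (`Inf` = first frame only).
#' @inheritParams detect_frame
#' @return List of `pose_estimate` objects (or `NULL` entries).
#' @export
detect_sequence <- function(model, frames, omega_dist = 30,
                            full_search_every = Inf,
                            omega_score = model$omega_score,
                            overlap_threshold = 0.3, max_candidates = 20L) {
  poses <- vector("list", length(frames))
  prev <- NULL
  for (i in seq_along(frames)) {
    img <- if (is.character(frames[[i]])) read_frame(frames[[i]]) else frames[[i]]
    region <- NULL
    full <- is.null(prev) || (is.finite(full_search_every) &&
                              (i - 1L) %% full_search_every == 0L)
    if (!full) region <- restrict_search_space(prev, omega_dist, dim(img))
    pose <- detect_frame(model, img, region, omega_score,
                         overlap_threshold, TRUE, max_candidates)
    if (is.null(pose) && !is.null(region)) {
      # restriction starved the search; recover with a full-frame pass
      pose <- detect_frame(model, img, NULL, omega_score,
                           overlap_threshold, TRUE, max_candidates)
    }
    poses[[i]] <- pose
    if (!is.null(pose)) prev <- pose
  }
  poses
}
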