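# ---- training: annotations, augmentation, state clustering, structSVM -----

#' Construct an annotated frame
#'
#' @param image Grayscale matrix (intensities in `[0, 1]`).
#' @param joints 14 x 2 matrix of 0-based pixel coordinates `(x, y)` with
#'   part names as row names.
#' @param id Source identifier.
#' @return An object of class `annotated_frame`.
#' @export
annotated_frame <- function(image, joints, id = "frame") {
  stopifnot(is.matrix(image), is.matrix(joints), ncol(joints) == 2L)
  if (is.null(rownames(joints))) stop("joints must have part names as row names")
  colnames(joints) <- c("x", "y")
  if (any(joints[, "x"] < 0 | joints[, "x"] > ncol(image) - 1 |
          joints[, "y"] < 0 | joints[, "y"] > nrow(image) - 1))
    stop("all joints must lie inside the image")
  structure(list(image = image, joints = joints,
                 visible = stats::setNames(rep(TRUE, nrow(joints)), rownames(joints)),
                 id = id),
            class = "annotated_frame")
}

# Affine-warp an image by output <- A %*% input + t on 0-based (x, y)
# coordinates, sampling bilinearly; out-of-canvas samples take `fill`.
warp_affine <- function(image, A, t, out_dim, fill) {
  h <- out_dim[1L]; w <- out_dim[2L]
  Ai <- solve(A)
  X <- matrix(0:(w - 1L), h, w, byrow = TRUE)
  Y <- matrix(0:(h - 1L), h, w)
  sx <- Ai[1L, 1L] * (X - t[1L]) + Ai[1L, 2L] * (Y - t[2L])
  sy <- Ai[2L, 1L] * (X - t[1L]) + Ai[2L, 2L] * (Y - t[2L])
  inside <- sx >= 0 & sx <= ncol(image) - 1 & sy >= 0 & sy <= nrow(image) - 1
  sx <- pmin(pmax(sx, 0), ncol(image) - 1)
  sy <- pmin(pmax(sy, 0), nrow(image) - 1)
  x0 <- floor(sx); y0 <- floor(sy)
  x1 <- pmin(x0 + 1, ncol(image) - 1); y1 <- pmin(y0 + 1, nrow(image) - 1)
  fx <- sx - x0; fy <- sy - y0
  iv <- function(yy, xx) image[cbind(as.vector(yy) + 1L, as.vector(xx) + 1L)]
  out <- iv(y0, x0) * (1 - fy) * (1 - fx) + iv(y0, x1) * (1 - fy) * fx +
    iv(y1, x0) * fy * (1 - fx) + iv(y1, x1) * fy * fx
  out <- matrix(out, h, w)
  out[!inside] <- fill
  out
}

# Left/right part-label swap under horizontal flip (head/neck are their own
# mirror images).
flip_part_name <- function(p) {
  ifelse(startsWith(p, "l_"), sub("^l_", "r_", p),
         ifelse(startsWith(p, "r_"), sub("^r_", "l_", p), p))
}

#' Augment an annotated frame by rotation and horizontal flip
#'
#' Each rotation (degrees, about the image center) produces one variant;
#' with `flip = TRUE` a horizontally mirrored copy of each is added, with
#' left/right part labels swapped.  Joint annotations are mapped by the same
#' affine transform as the pixels (stored in attribute `"transform"` as
#' `list(A, t)` so that `joints_variant = joints %*% t(A) + t`).  If a
#' rotation pushes any joint outside the canvas the variant is padded to
#' contain it (logged via `message()`), never dropped.
#'
#' @param frame An [annotated_frame()].
#' @param rotations Numeric degree set (default the classical
#'   `-15, -10, ..., +15` recipe).
#' @param flip Add mirrored variants (default `TRUE`).
#' @param fill Fill intensity for pixels rotated in from outside the canvas
#'   (default: median image intensity).
#' @return List of `annotated_frame` variants of length
#'   `length(rotations) * (1 + flip)`.
#' @export
augment <- function(frame, rotations = seq(-15, 15, by = 5), flip = TRUE,
                    fill = NULL) {
  if (!length(rotations)) rotations <- 0
  stopifnot(all(is.finite(rotations)))
  if (is.null(fill)) fill <- stats::median(frame$image)
  h <- nrow(frame$image); w <- ncol(frame$image)
  ctr <- c((w - 1) / 2, (h - 1) / 2)
  out <- list()
  for (r in rotations) {
    a <- r * pi / 180
    A <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
    t0 <- ctr - A %*% ctr
    jr <- frame$joints %*% t(A) + matrix(t0, nrow(frame$joints), 2L, byrow = TRUE)
    pad_lo <- pmax(0, ceiling(-apply(jr, 2L, min)))
    pad_hi <- pmax(0, ceiling(apply(jr, 2L, max) - c(w - 1, h - 1)))
    t1 <- t0 + pad_lo
    od <- c(h + pad_lo[2L] + pad_hi[2L], w + pad_lo[1L] + pad_hi[1L])
    if (any(pad_lo > 0 | pad_hi > 0))
      message(sprintf("augment: rotation %g deg padded canvas to %d x %d",
                      r, od[1L], od[2L]))
    img <- warp_affine(frame$image, A, t1, od, fill)
    joints <- frame$joints %*% t(A) + matrix(t1, nrow(frame$joints), 2L, byrow = TRUE)
    dimnames(joints) <- dimnames(frame$joints)
    fr <- structure(list(image = img, joints = joints, visible = frame$visible,
                         id = sprintf("%s_rot%+g", frame$id, r)),
                    class = "annotated_frame")
    attr(fr, "transform") <- list(A = A, t = as.numeric(t1))
    out[[length(out) + 1L]] <- fr
    if (flip) {
      wf <- ncol(img)
      Af <- matrix(c(-1, 0, 0, 1), 2L, 2L) %*% A
      tf <- c(wf - 1, 0) + c(-1, 1) * t1
      jf <- joints
      jf[, 1L] <- (wf - 1) - joints[, 1L]
      rownames(jf) <- flip_part_name(rownames(joints))
      jf <- jf[rownames(frame$joints), , drop = FALSE]
      visf <- frame$visible
      names(visf) <- flip_part_name(names(frame$visible))
      imgf <- img[, rev(seq_len(wf)), drop = FALSE]
      frf <- structure(list(image = imgf, joints = jf,
                            visible = visf[rownames(frame$joints)],
                            id = sprintf("%s_rot%+g_flip", frame$id, r)),
                       class = "annotated_frame")
      attr(frf, "transform") <- list(A = Af, t = as.numeric(tf), flipped = TRUE)
      out[[length(out) + 1L]] <- frf
    }
  }
  out
}

#' Per-frame bounding-box (part patch) size
#'
#' For every frame, the length of each limb (tree edge) is divided by the
#' training-set median length of that limb; the frame's patch side is the
#' 75% quantile of those ratios (linear-interpolation quantile, R type 7)
#' times the base patch size.  Zero-length limbs (coincident joints) are
#' excluded from the quantile and logged.
#'
#' @param frames List of [annotated_frame()]s.
#' @param tree A [kinematic_tree()].
#' @param base_patch_px Base patch side in pixels (template cells x cell
#'   size).
#' @param q Quantile level (default 0.75).
#' @return Numeric vector of per-frame box sides in pixels.
#' @export
bbox_size <- function(frames, tree = infant_tree(), base_patch_px = 40,
                      q = 0.75) {
  if (!length(frames)) stop("need at least one frame")
  nonroot <- setdiff(tree$order, tree$root)
  len <- vapply(frames, function(f)
    vapply(nonroot, function(ch) {
      d <- f$joints[ch, ] - f$joints[tree$parent[[ch]], ]
      sqrt(sum(d^2))
    }, numeric(1L)), numeric(length(nonroot)))
  len <- matrix(len, nrow = length(nonroot))  # edges x frames
  med <- apply(len, 1L, stats::median)
  vapply(seq_along(frames), function(i) {
    ratio <- len[, i] / med
    drop <- len[, i] == 0 | med == 0
    if (any(drop)) {
      message(sprintf("bbox_size: frame %d has %d zero-length limb(s), excluded",
                      i, sum(drop)))
      ratio <- ratio[!drop]
    }
    if (!length(ratio)) stop("frame ", i, " has no measurable limbs")
    unname(stats::quantile(ratio, q, type = 7)) * base_patch_px
  }, numeric(1L))
}

#' Cluster relative displacements into part states
#'
#' k-means (10 restarts, best inertia kept) on the 2-D displacements of a
#' part relative to its parent; each cluster is one appearance state and its
#' centroid becomes the spring rest offset.  Clusters are relabeled in
#' lexicographic centroid order so labels are stable across runs.
#'
#' @param points n x 2 matrix of displacements.
#' @param S Number of states (1 <= S <= n).
#' @param seed RNG seed.
#' @param nstart k-means restarts (default 10).
#' @return List with `labels` (length n), `centroids` (S x 2),
#'   `tot_withinss`.
#' @export
cluster_states <- function(points, S, seed = 1L, nstart = 10L) {
  points <- as.matrix(points)
  if (S > nrow(points)) stop("S must not exceed the number of points")
  if (S < 1L) stop("S must be positive")
  km <- withr::with_seed(seed,
    stats::kmeans(points, centers = S, nstart = nstart, iter.max = 100L))
  ord <- order(km$centers[, 1L], km$centers[, 2L])
  relab <- match(seq_len(S), ord)
  list(labels = relab[km$cluster],
       centroids = km$centers[ord, , drop = FALSE],
       tot_withinss = km$tot.withinss)
}

#' Select the state count per part by BIC
#'
#' For each candidate `S`, runs [cluster_states()] and evaluates
#' `BIC = n * ln(R / n) + k * ln(n)` with `R` the residual sum of squares to
#' the assigned centroids and `k = S (d + 1)`, `d = 2`; the `S` with the
#' minimum BIC wins (ties to the smallest `S`).  A perfect fit (`R = 0`)
#' wins immediately, guarding the logarithm.
#'
#' @param points n x 2 displacement matrix.
#' @param S_range Candidate cluster counts (each <= n).
#' @param seed RNG seed.
#' @return List with `S` (selected) and `table` (data frame `S`, `R`,
#'   `bic`).
#' @export
bic_select <- function(points, S_range, seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  S_range <- sort(unique(as.integer(S_range)))
  if (any(S_range > n)) stop("every S in the range must be <= the number of points")
  n_distinct <- nrow(unique(points))
  tab <- do.call(rbind, lapply(S_range, function(S) {
    if (S > n_distinct)         # unfittable: fewer distinct points than centers
      return(data.frame(S = S, R = NA_real_, bic = Inf))
    cs <- cluster_states(points, S, seed)
    R <- cs$tot_withinss
    bic <- if (R <= .Machine$double.eps) -Inf else
      n * log(R / n) + (S * 3) * log(n)
    data.frame(S = S, R = R, bic = bic)
  }))
  list(S = tab$S[which.min(tab$bic)], table = tab)
}

#' Training configuration
#'
#' @param C Regularization weight (> 0).
#' @param states_per_part Integer (shared), named integer vector, or
#'   `"bic"` to select per part via [bic_select()].
#' @param bic_range Candidate S values when `states_per_part = "bic"`.
#' @param rotations,flip Augmentation recipe applied to positives
#'   (`NULL` rotations = no augmentation).
#' @param folds Cross-validation folds for [cross_validate()].
#' @param seed RNG seed controlling clustering, constraint ordering and any
#'   tie randomization.
#' @param eps_def Lower clamp for quadratic deformation weights.
#' @param max_passes Outer training passes (mine + optimize).
#' @param neg_top_k Hard-negative root candidates mined per negative image
#'   per pass.
#' @param mine_nms Optional overlap threshold used to diversify mined
#'   candidates (greedy suppression of near-duplicate root placements before
#'   caching); `NULL` (default) caches the plain top-k.
#' @param cache_cap Maximum cached hard negatives per image.
#' @param mine_rounds Maximum mine-and-optimize rounds within one pass (a
#'   pass ends early once mining finds no new margin violations).
#' @param inner_sweeps Maximum dual coordinate descent sweeps per pass.
#' @param inner_tol Stop a pass when the largest projected dual gradient
#'   falls below this.
#' @param feature Feature settings, see [feature_config()].
#' @return A named list of class `training_config`.
#' @export
training_config <- function(C = 0.1, states_per_part = 3L, bic_range = 1:6,
                            rotations = NULL, flip = FALSE, folds = 10L,
                            seed = 1L, eps_def = 1e-4, max_passes = 8L,
                            neg_top_k = 10L, mine_nms = NULL, cache_cap = 80L,
                            mine_rounds = 10L,
                            inner_sweeps = 1000L, inner_tol = 1e-5,
                            feature = feature_config()) {
  if (C <= 0) stop("C must be positive")
  if (identical(states_per_part, "bic") && !length(bic_range))
    stop("bic_range must be non-empty when states_per_part = 'bic'")
  structure(list(C = C, states_per_part = states_per_part,
                 bic_range = bic_range, rotations = rotations, flip = flip,
                 folds = as.integer(folds), seed = as.integer(seed),
                 eps_def = eps_def, max_passes = as.integer(max_passes),
                 neg_top_k = as.integer(neg_top_k), mine_nms = mine_nms,
                 cache_cap = as.integer(cache_cap),
                 mine_rounds = as.integer(mine_rounds),
                 inner_sweeps = as.integer(inner_sweeps),
                 inner_tol = inner_tol, feature = feature),
            class = "training_config")
}

# Warp positives to the canonical scale where the frame's part patch equals
# the base patch, compute their level-0 HOG and continuous anchor-cell
# coordinates.
prepare_positives <- function(frames, tree, feat) {
  base <- feat$patch_cells * feat$cell_size_px
  sides <- bbox_size(frames, tree, base)
  lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    fac <- (feat$train_scale %||% 1) * base / sides[i]
    img <- if (abs(fac - 1) < 1e-9) f$image else resize_bilinear(f$image, fac)
    joints <- (f$joints + 0.5) * fac - 0.5
    level <- compute_hog(img, feat$cell_size_px, feat$bins, feat$normalize)
    cc <- (joints + 0.5) / feat$cell_size_px - feat$patch_cells / 2
    dlev <- dim(level$cells)
    place <- cbind(pmin(pmax(round(cc[, 1L]), 0), dlev[2L] - feat$patch_cells),
                   pmin(pmax(round(cc[, 2L]), 0), dlev[1L] - feat$patch_cells))
    dimnames(place) <- list(rownames(joints), c("x", "y"))
    list(level = level, joints = joints, cell_cont = cc, place = place,
         scale_factor = fac, id = f$id)
  })
}

# Cluster displacement-to-parent per part (root uses minus the displacement
# of its first child), giving states, per-frame labels and spring anchors.
assign_states <- function(prep, tree, config) {
  parts <- tree$parts
  n <- length(prep)
  disp <- list()
  for (p in parts) {
    if (p == tree$root) {
      ch <- tree$children[[p]][1L]
      disp[[p]] <- t(vapply(prep, function(z) z$cell_cont[p, ] - z$cell_cont[ch, ],
                            numeric(2L)))
    } else {
      pa <- tree$parent[[p]]
      disp[[p]] <- t(vapply(prep, function(z) z$cell_cont[p, ] - z$cell_cont[pa, ],
                            numeric(2L)))
    }
  }
  spp <- config$states_per_part
  states <- vapply(seq_along(parts), function(i) {
    p <- parts[i]
    S <- if (identical(spp, "bic")) {
      rng <- config$bic_range[config$bic_range <= n]
      bic_select(disp[[p]], rng, config$seed + i)$S
    } else if (length(spp) > 1L) as.integer(spp[[p]]) else as.integer(spp)
    min(S, n)
  }, integer(1L))
  names(states) <- parts
  labels <- matrix(NA_integer_, n, length(parts), dimnames = list(NULL, parts))
  centroids <- list()
  for (i in seq_along(parts)) {
    p <- parts[i]
    cs <- cluster_states(disp[[p]], states[[p]], config$seed + i)
    labels[, p] <- cs$labels
    centroids[[p]] <- cs$centroids
  }
  nonroot <- setdiff(tree$order, tree$root)
  anchors <- list()
  for (ch in nonroot) {
    pa <- tree$parent[[ch]]
    A <- array(0, c(states[[ch]], states[[pa]], 2L))
    for (sa in seq_len(states[[ch]])) {
      for (sb in seq_len(states[[pa]])) {
        sel <- labels[, ch] == sa & labels[, pa] == sb
        A[sa, sb, ] <- if (any(sel)) colMeans(disp[[ch]][sel, , drop = FALSE]) else
          centroids[[ch]][sa, ]
      }
    }
    anchors[[ch]] <- A
  }
  list(states = states, labels = labels, centroids = centroids,
       anchors = anchors)
}

#' Build the sparse structured feature vector of one configuration
#'
#' Returns the vector `Phi(I, z)` such that the configuration score equals
#' the inner product of the model's flat parameter vector with `Phi`: HOG
#' patches fill the filter slots of the active states, minus the
#' displacement features fill the deformation slots, indicators fill the
#' co-occurrence slots, and the last entry is 1 for the bias.
#'
#' @param model A [body_model()] (shapes and anchors; weights unused).
#' @param level A [hog_level()].
#' @param placements Data frame `part`, `state`, `x`, `y` (0-based cells).
#' @return Numeric vector, same length as [model_beta()].
#' @export
build_feature_vector <- function(model, level, placements) {
  lay <- beta_layout(model)
  phi <- numeric(lay$length)
  pc <- model$config$patch_cells
  pl <- placements[match(model$tree$parts, placements$part), , drop = FALSE]
  for (i in seq_along(model$tree$parts)) {
    p <- model$tree$parts[i]; s <- pl$state[i]
    patch <- level$cells[pl$y[i] + seq_len(pc), pl$x[i] + seq_len(pc), , drop = FALSE]
    phi[lay$filters[[p]][s] + seq_len(lay$filter_len)] <- as.vector(patch)
    phi[lay$unary[[p]] + s] <- 1
  }
  for (ch in setdiff(model$tree$order, model$tree$root)) {
    pa <- model$tree$parent[[ch]]
    ic <- match(ch, model$tree$parts); ip <- match(pa, model$tree$parts)
    sc <- pl$state[ic]; sp <- pl$state[ip]
    d <- c(pl$x[ic] - pl$x[ip], pl$y[ic] - pl$y[ip]) - model$anchor[[ch]][sc, sp, ]
    nstate <- dim(model$zeta[[ch]])[1L]
    # zeta slot (sc, sp, k) at offset + (sc-1) + nstate*(sp-1) + nstate*nsp*(k-1)
    nsp <- dim(model$zeta[[ch]])[2L]
    idx <- lay$zeta[[ch]] + (sc - 1L) + nstate * (sp - 1L) +
      nstate * nsp * (0:3) + 1L
    phi[idx] <- -c(d, d^2)
    phi[lay$pairwise[[ch]] + (sc - 1L) + nstate * (sp - 1L) + 1L] <- 1
  }
  phi[lay$bias + 1L] <- 1
  phi
}

# Dual coordinate descent on
#   min_beta 1/2 ||beta - beta0||^2 + C (sum_i xi_i)
# with one slack per positive and one shared slack per negative image
# (constraint groups).  PhiT columns are the constraints (y = +1 positives,
# y = -1 mined negatives); alpha is warm-started between passes.  The
# cyclic sweep itself runs compiled (cpp_dcd).
dcd_optimize <- function(PhiT, y, group, C, beta, alpha, sweeps, tol) {
  res <- cpp_dcd(PhiT, as.numeric(y), as.integer(group), C,
                 beta, alpha, as.integer(sweeps), tol)
  list(beta = as.numeric(res$beta), alpha = as.numeric(res$alpha),
       sweeps = res$sweeps)
}

#' Train a body model with a structured SVM
#'
#' Pipeline: optional augmentation; per-frame patch sizing and canonical
#' rescaling; k-means state clustering (count fixed or BIC-selected) with
#' spring anchors from cluster means; then margin training.  Positives
#' contribute one constraint each at their annotated configuration
#' (score >= +1); every possible root placement in a negative image is a
#' negative constraint (score <= -1), handled by mining the top-k
#' highest-scoring configurations per negative image per pass into a hard
#' negative cache whose members share one slack variable per image.  The
#' quadratic program is solved by dual coordinate descent over one
#' constraint at a time, regularized toward the spring-prior initialization
#' (deformations start at `[0, 0, 0.01, 0.01]`), with quadratic deformation
#' weights clamped to at least `eps_def` after every pass.  The true primal
#' objective (exact inference gives the exact max over negative
#' configurations) is logged once per pass.
#'
#' @param positives List of [annotated_frame()]s.
#' @param negatives List of grayscale matrices without a figure.
#' @param config A [training_config()].
#' @return List with `model` (trained [body_model()]), `log` (per-pass data
#'   frame: `pass`, `objective`, `n_cache`, `n_sv`), `pos_margins`,
#'   `neg_margins` (best fresh configuration score per negative image at the
#'   final weights) and `neg_cache_margins` (scores of every cached mined
#'   negative).
#' @export
train_model <- function(positives, negatives, config = training_config()) {
  stopifnot(length(positives) >= 1L, length(negatives) >= 1L)
  tree <- infant_tree()
  feat <- config$feature
  if (!is.null(config$rotations))
    positives <- unlist(lapply(positives, augment, rotations = config$rotations,
                               flip = config$flip), recursive = FALSE)
  prep <- prepare_positives(positives, tree, feat)
  st <- assign_states(prep, tree, config)
  model <- body_model(tree, st$states, feat)
  model$anchor <- st$anchors
  lay <- beta_layout(model)
  npos <- length(prep)
  pos_place <- lapply(seq_len(npos), function(i) {
    data.frame(part = tree$parts,
               state = st$labels[i, tree$parts],
               x = prep[[i]]$place[tree$parts, "x"],
               y = prep[[i]]$place[tree$parts, "y"],
               stringsAsFactors = FALSE)
  })
  PhiT <- vapply(seq_len(npos), function(i)
    build_feature_vector(model, prep[[i]]$level, pos_place[[i]]),
    numeric(lay$length))                 # constraints as columns
  PhiT <- matrix(PhiT, nrow = lay$length)
  neg_pyr <- lapply(negatives, function(img)
    build_pyramid(img, feat$cell_size_px, feat$bins, feat$interval,
                  feat$min_level_px, feat$normalize,
                  max_scale = feat$train_scale %||% 1))
  beta0 <- model_beta(model)    # spring prior: the regularization center
  beta <- beta0
  y <- rep(1, npos)
  group <- seq_len(npos)        # one slack per positive
  alpha <- numeric(npos)
  keys <- character(0)
  neg_group_of <- integer(0)
  log_rows <- list()
  C <- config$C
  prev_obj <- Inf
  for (pass in seq_len(config$max_passes)) {
    # mine-and-optimize to a fixed point: on exit no configuration in any
    # negative image violates its margin beyond the cached constraints, so
    # the logged objective (with the exact inference max) is the true primal
    # at the current weights and is non-increasing across passes
    added_any <- FALSE
    neg_max <- rep(-Inf, length(negatives))
    for (round in seq_len(config$mine_rounds)) {
      model <- model_set_beta(model, beta)
      new_cols <- list(); new_group <- integer(0)
      for (j in seq_along(negatives)) {
        cands <- suppressWarnings(
          infer_pose(model, neg_pyr[[j]],
                     max_candidates = config$neg_top_k,
                     root_nms = config$mine_nms))
        if (!length(cands)) next
        neg_max[j] <- cands[[1L]]$score
        for (cd in cands) {
          if (cd$score <= -1) break   # score-sorted: the rest are satisfied
          key <- paste(j, cd$level, paste(cd$parts$state, cd$parts$cx,
                                          cd$parts$cy, collapse = ";"))
          if (key %in% keys) next
          if (sum(neg_group_of == j) + sum(new_group == j) >= config$cache_cap)
            next
          pl <- data.frame(part = cd$parts$part, state = cd$parts$state,
                           x = cd$parts$cx, y = cd$parts$cy,
                           stringsAsFactors = FALSE)
          lev <- neg_pyr[[j]]$levels[[cd$level]]
          new_cols[[length(new_cols) + 1L]] <-
            build_feature_vector(model, lev, pl)
          new_group <- c(new_group, j)
          keys <- c(keys, key)
        }
      }
      if (!length(new_cols)) break
      added_any <- TRUE
      PhiT <- cbind(PhiT, do.call(cbind, new_cols))
      y <- c(y, rep(-1, length(new_cols)))
      group <- c(group, npos + new_group)
      alpha <- c(alpha, numeric(length(new_cols)))
      neg_group_of <- c(neg_group_of, new_group)
      res <- dcd_optimize(PhiT, y, group, C, beta, alpha,
                          config$inner_sweeps, config$inner_tol)
      beta <- res$beta; alpha <- res$alpha
      # clamp quadratic spring weights; absorb the shift into the prior so
      # the dual bookkeeping stays exact, then re-polish so the clamp does
      # not leave residual margin violations
      clamped <- clamp_quadratic(model, beta, config$eps_def, lay)
      if (any(clamped != beta)) {
        beta0 <- beta0 + (clamped - beta)
        beta <- clamped
        res <- dcd_optimize(PhiT, y, group, C, beta, alpha,
                            config$inner_sweeps, config$inner_tol)
        beta <- res$beta; alpha <- res$alpha
      }
    }
    obj <- 0.5 * sum((beta - beta0)^2) +
      C * sum(pmax(0, 1 - crossprod(PhiT[, seq_len(npos), drop = FALSE], beta))) +
      C * sum(pmax(0, 1 + neg_max[is.finite(neg_max)]))
    if (!is.finite(obj)) stop("training objective is not finite; aborting")
    log_rows[[pass]] <- data.frame(pass = pass, objective = obj,
                                   n_cache = length(neg_group_of),
                                   n_sv = sum(alpha > 1e-12))
    if (!added_any && abs(obj - prev_obj) < 1e-9 * max(1, abs(obj))) break
    prev_obj <- obj
  }
  model <- model_set_beta(model, beta)
  logdf <- do.call(rbind, log_rows)
  neg_max <- vapply(seq_along(negatives), function(j) {
    cands <- suppressWarnings(infer_pose(model, neg_pyr[[j]], max_candidates = 1L))
    if (length(cands)) cands[[1L]]$score else -Inf
  }, numeric(1L))
  pos_margins <- as.numeric(crossprod(PhiT[, seq_len(npos), drop = FALSE], beta))
  neg_cache_margins <- if (ncol(PhiT) > npos)
    as.numeric(crossprod(PhiT[, -seq_len(npos), drop = FALSE], beta)) else numeric(0)
  # occlusion threshold: 10th percentile of per-part local scores on the
  # training positives
  part_scores <- vapply(seq_len(npos), function(i) {
    vapply(tree$parts, function(p) {
      s <- st$labels[i, p]
      filter_response(model$filters[[p]][[s]], prep[[i]]$level,
                      c(pos_place[[i]]$x[match(p, tree$parts)],
                        pos_place[[i]]$y[match(p, tree$parts)])) +
        model$unary[[p]][s]
    }, numeric(1L))
  }, numeric(length(tree$parts)))
  model$omega_score <- apply(matrix(part_scores, nrow = length(tree$parts)), 1L,
                             stats::quantile, probs = 0.1, type = 7)
  names(model$omega_score) <- tree$parts
  list(model = model, log = logdf, pos_margins = pos_margins,
       neg_margins = neg_max, neg_cache_margins = neg_cache_margins,
       states = st$states, config = config)
}

clamp_quadratic <- function(model, beta, eps_def, lay = beta_layout(model)) {
  for (ch in names(lay$zeta)) {
    dz <- dim(model$zeta[[ch]])
    nq <- dz[1L] * dz[2L]
    idx <- lay$zeta[[ch]] + c((2L * nq + 1L):(4L * nq))
    beta[idx] <- pmax(beta[idx], eps_def)
  }
  beta
}

#' Select the regularization parameter by cross-validation
#'
#' Two-stage multi-resolution search: a coarse (log-spaced) grid is scored
#' by k-fold cross-validation on the positives (negatives are shared across
#' folds), then a narrow grid (winner x 1/3, x 1, x 3) is scored around the
#' stage-1 winner.  The selection metric is the mean held-out worst-case
#' accuracy at a threshold of half the base patch size; ties go to the
#' smallest C.
#'
#' @param positives,negatives As in [train_model()].
#' @param C_grid Coarse candidate values.
#' @param config Base [training_config()] (its `C` is overridden, `folds`
#'   and `seed` are used).
#' @return List with `best_C`, `coarse` and `refined` score tables.
#' @export
cross_validate <- function(positives, negatives, C_grid,
                           config = training_config()) {
  folds <- config$folds
  npos <- length(positives)
  if (folds > npos) stop("folds must not exceed the number of positives")
  fold_id <- withr::with_seed(config$seed,
                              sample(rep_len(seq_len(folds), npos)))
  omega <- config$feature$patch_cells * config$feature$cell_size_px / 2
  score_C <- function(C) {
    accs <- vapply(seq_len(folds), function(k) {
      tr <- positives[fold_id != k]
      te <- positives[fold_id == k]
      cfg <- config; cfg$C <- C
      fit <- train_model(tr, negatives, cfg)
      poses <- lapply(te, function(f) detect_frame(fit$model, f$image,
                                                   omega_score = -Inf))
      ok <- !vapply(poses, is.null, logical(1L))
      if (!any(ok)) return(0)
      pred <- poses_to_trajectory(poses[ok], frames = which(ok))
      truth <- do.call(rbind, lapply(which(ok), function(i)
        data.frame(frame = i, part = rownames(te[[i]]$joints),
                   x = te[[i]]$joints[, "x"], y = te[[i]]$joints[, "y"],
                   visible = TRUE, stringsAsFactors = FALSE)))
      wca(pred, truth, omega) * mean(ok)
    }, numeric(1L))
    mean(accs)
  }
  C_grid <- sort(unique(C_grid))
  coarse <- data.frame(C = C_grid,
                       score = vapply(C_grid, score_C, numeric(1L)))
  best <- coarse$C[coarse$score == max(coarse$score)][1L]
  if (length(C_grid) == 1L)
    return(list(best_C = best, coarse = coarse, refined = coarse))
  refine_grid <- sort(unique(c(best / 3, best, best * 3)))
  refined <- data.frame(C = refine_grid,
                        score = vapply(refine_grid, function(C)
                          if (C == best) coarse$score[coarse$C == best] else score_C(C),
                          numeric(1L)))
  best_r <- refined$C[refined$score == max(refined$score)][1L]
  list(best_C = best_r, coarse = coarse, refined = refined)
}
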