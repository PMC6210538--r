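# Independent reference implementations ("oracles") used to check the
# package's optimized code paths, plus small fixture builders.  Every oracle
# here is written as plainly as possible (pixel loops, full enumeration) and
# must stay independent of the implementation it checks.

# Pixel-loop HOG oracle: central differences with clamped borders, unsigned
# orientation, hard assignment of the full magnitude to one bin per pixel.
hog_oracle <- function(img, cell, bins) {
  h <- nrow(img); w <- ncol(img)
  rows <- h %/% cell; cols <- w %/% cell
  out <- array(0, c(rows, cols, bins))
  for (y in seq_len(rows * cell)) {
    for (x in seq_len(cols * cell)) {
      gx <- img[y, min(x + 1, w)] - img[y, max(x - 1, 1)]
      gy <- img[min(y + 1, h), x] - img[max(y - 1, 1), x]
      mag <- sqrt(gx^2 + gy^2)
      ori <- atan2(gy, gx) %% pi
      b <- (floor(ori / (pi / bins)) %% bins) + 1
      cr <- (y - 1) %/% cell + 1
      cc <- (x - 1) %/% cell + 1
      out[cr, cc, b] <- out[cr, cc, b] + mag
    }
  }
  out
}

# Triple-loop cross-correlation oracle for part-filter response maps.
xcorr_oracle <- function(cells, filt) {
  dc <- dim(cells); df <- dim(filt)
  vr <- dc[1L] - df[1L] + 1L; vc <- dc[2L] - df[2L] + 1L
  out <- matrix(0, vr, vc)
  for (y in seq_len(vr)) {
    for (x in seq_len(vc)) {
      s <- 0
      for (m in seq_len(df[1L]))
        for (n in seq_len(df[2L]))
          for (d in seq_len(df[3L]))
            s <- s + filt[m, n, d] * cells[y + m - 1L, x + n - 1L, d]
      out[y, x] <- s
    }
  }
  out
}

# Sort-based linear-interpolation quantile oracle (type-7 definition).
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  unname(x[lo] + (h - lo) * (x[hi] - x[lo]))
}

# O(n^2) reference NMS over pose candidates (root patch boxes, IoU).
nms_oracle <- function(cands, thr, root = "head") {
  box <- function(p) {
    i <- match(root, p$parts$part)
    half <- p$cell_size_px * p$patch_cells / (2 * p$scale)
    c(p$parts$x[i] - half, p$parts$y[i] - half,
      p$parts$x[i] + half, p$parts$y[i] + half)
  }
  iou <- function(a, b) {
    ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    ar <- function(z) (z[3] - z[1]) * (z[4] - z[2])
    if (ar(a) + ar(b) - inter <= 0) return(0)
    inter / (ar(a) + ar(b) - inter)
  }
  ord <- order(-vapply(cands, function(p) p$score, numeric(1)))
  cands <- cands[ord]
  kept <- list()
  for (p in cands) {
    if (!any(vapply(kept, function(q) iou(box(p), box(q)) > thr, logical(1))))
      kept[[length(kept) + 1L]] <- p
  }
  kept
}

# Random tiny model + matching random feature level for DP-vs-enumeration
# checks.  Caps the joint configuration count so full enumeration stays
# tractable.
random_tiny_model <- function(seed, max_parts = 5L, max_grid = 6L,
                              max_states = 3L, max_configs = 5e5) {
  withr::with_seed(seed, {
    n_parts <- sample(2:max_parts, 1L)
    parts <- letters[seq_len(n_parts)]
    parent <- c(NA, parts[vapply(seq_len(n_parts - 1L), function(i)
      sample.int(i, 1L), integer(1L))])
    names(parent) <- parts
    tree <- kinematic_tree(parts, parent)
    repeat {
      g <- sample(2:max_grid, 1L)
      states <- sample(seq_len(max_states), n_parts, replace = TRUE)
      if (prod(g * g * states) <= max_configs) break
    }
    names(states) <- parts
    d <- sample(2:4, 1L)
    cfg <- feature_config(cell_size_px = 4L, bins = d)
    m <- body_model(tree, states, cfg)
    m <- model_set_beta(m, stats::rnorm(length(model_beta(m))) * 0.5)
    for (ch in setdiff(parts, tree$root)) {
      m$anchor[[ch]][] <- stats::runif(length(m$anchor[[ch]]), -2, 2)
      # keep quadratic terms positive as the model invariant requires
      m$zeta[[ch]][, , 3L] <- abs(m$zeta[[ch]][, , 3L]) + 1e-3
      m$zeta[[ch]][, , 4L] <- abs(m$zeta[[ch]][, , 4L]) + 1e-3
    }
    pc <- cfg$patch_cells
    lev <- hog_level(array(stats::rnorm((g + pc - 1L)^2 * d),
                           c(g + pc - 1L, g + pc - 1L, d)),
                     cell_size_px = 4L, scale = 1, bins = d)
    list(model = m, level = lev, grid = g)
  })
}

as_one_level_pyramid <- function(level) {
  structure(list(levels = list(level), interval = 2L,
                 cell_size_px = level$cell_size_px, bins = level$bins,
                 normalize = "none",
                 image_dim = dim(level$cells)[1:2] * level$cell_size_px),
            class = "hog_pyramid")
}

# Full enumeration of every (location x state) assignment, vectorized over
# configurations.  Ties resolve to the lexicographically smallest
# configuration in root-first part order with per-part key (y, x, state),
# matching the documented inference tie-break.
enumerate_best <- function(model, level) {
  tree <- model$tree
  parts <- tree$order                 # root first
  pc <- model$config$patch_cells
  dlev <- dim(level$cells)
  g_y <- dlev[1L] - pc + 1L; g_x <- dlev[2L] - pc + 1L
  # per-part placement tables ordered by (y, x, s)
  tab <- lapply(parts, function(p) {
    pl <- expand.grid(s = seq_len(model$states[[p]]), x = 0:(g_x - 1L),
                      y = 0:(g_y - 1L))
    pl <- pl[order(pl$y, pl$x, pl$s), , drop = FALSE]
    pl$resp <- vapply(seq_len(nrow(pl)), function(i)
      filter_response(model$filters[[p]][[pl$s[i]]], level,
                      c(pl$x[i], pl$y[i])) + model$unary[[p]][pl$s[i]],
      numeric(1L))
    pl
  })
  names(tab) <- parts
  sizes <- vapply(tab, nrow, integer(1L))
  idx <- do.call(expand.grid, lapply(rev(sizes), seq_len))[, length(sizes):1, drop = FALSE]
  names(idx) <- parts
  score <- rep(model$bias, nrow(idx))
  for (p in parts) score <- score + tab[[p]]$resp[idx[[p]]]
  for (ch in setdiff(tree$order, tree$root)) {
    pa <- tree$parent[[ch]]
    sa <- tab[[ch]]$s[idx[[ch]]]; sb <- tab[[pa]]$s[idx[[pa]]]
    dx <- tab[[ch]]$x[idx[[ch]]] - tab[[pa]]$x[idx[[pa]]] -
      model$anchor[[ch]][cbind(sa, sb, 1L)]
    dy <- tab[[ch]]$y[idx[[ch]]] - tab[[pa]]$y[idx[[pa]]] -
      model$anchor[[ch]][cbind(sa, sb, 2L)]
    score <- score -
      (model$zeta[[ch]][cbind(sa, sb, 1L)] * dx +
       model$zeta[[ch]][cbind(sa, sb, 2L)] * dy +
       model$zeta[[ch]][cbind(sa, sb, 3L)] * dx^2 +
       model$zeta[[ch]][cbind(sa, sb, 4L)] * dy^2) +
      model$pairwise[[ch]][cbind(sa, sb)]
  }
  best <- max(score)
  ties <- which(score == best)
  if (length(ties) > 1L) {
    keys <- do.call(order, lapply(parts, function(p) idx[[p]][ties]))
    ties <- ties[keys[1L]]
  }
  win <- ties[1L]
  placements <- do.call(rbind, lapply(parts, function(p) {
    r <- tab[[p]][idx[[p]][win], ]
    data.frame(part = p, state = r$s, x = r$x, y = r$y,
               stringsAsFactors = FALSE)
  }))
  list(score = best, placements = placements)
}

# Compact 80 x 80 figure for fast end-to-end training fixtures.
small_fig <- function(noise_sd = 0.02) {
  figure_config(image_size = c(80, 80),
                limb_width = 7, head_radius = 7,
                lengths = c(neck = 10, l_shoulder = 9, r_shoulder = 9,
                            l_elbow = 13, r_elbow = 13, l_hand = 11,
                            r_hand = 11, l_hip = 22, r_hip = 22,
                            l_knee = 15, r_knee = 15, l_foot = 13,
                            r_foot = 13),
                head_x = c(12, 16), head_y = c(36, 46), margin = 4,
                noise_sd = noise_sd)
}

# Tiny fast training setup shared by the training/pipeline unit tests.
tiny_training_config <- function(...) {
  defaults <- list(C = 0.1, states_per_part = 2L, max_passes = 2L,
                   neg_top_k = 5L, mine_rounds = 3L, inner_sweeps = 300L,
                   feature = feature_config(cell_size_px = 4L, bins = 9L,
                                            min_level_px = 40L))
  do.call(training_config, utils::modifyList(defaults, list(...)))
}

# Three compact well-separated 2-D clusters (uniform discs, small samples):
# the regime in which the ln(n)-penalized cluster-count criterion is
# consistent.
three_cluster_points <- function(seed, per_cluster = 10L, half_width = 0.8) {
  withr::with_seed(seed, {
    centers <- matrix(c(0, 0, 10, 0, 5, 9), 3, 2, byrow = TRUE)
    do.call(rbind, lapply(1:3, function(k)
      sweep(matrix(stats::runif(2 * per_cluster, -half_width, half_width),
                   per_cluster, 2), 2, centers[k, ], "+")))
  })
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb <- function(x) x * (x - 1) / 2
  sij <- sum(comb(tab))
  si <- sum(comb(rowSums(tab)))
  sj <- sum(comb(colSums(tab)))
  n <- comb(sum(tab))
  exp_ <- si * sj / n
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
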