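test_that("the rotation-and-flip recipe yields 14 exactly-transformed variants", {
  cfg <- small_fig()
  fr <- withr::with_seed(2, render_frame(sample_pose(cfg), cfg, id = "f"))
  out <- augment(fr)
  expect_length(out, 14L)
  for (v in out) {
    tf <- attr(v, "transform")
    mapped <- fr$joints %*% t(tf$A) +
      matrix(tf$t, nrow(fr$joints), 2, byrow = TRUE)
    if (isTRUE(tf$flipped)) {
      rownames(mapped) <- babydpm:::flip_part_name(rownames(fr$joints))
      mapped <- mapped[rownames(fr$joints), ]
    }
    expect_lt(max(abs(mapped - v$joints)), 0.5)
  }
  # identity recipe returns the frame unchanged
  id <- augment(fr, rotations = numeric(0), flip = FALSE)
  expect_length(id, 1L)
  expect_equal(id[[1]]$joints, fr$joints, tolerance = 1e-12)
  expect_equal(id[[1]]$image, fr$image, tolerance = 1e-12)
})

test_that("flipping swaps left/right labels and mirrors coordinates", {
  cfg <- small_fig()
  fr <- withr::with_seed(3, render_frame(sample_pose(cfg), cfg, id = "f"))
  fl <- augment(fr, rotations = 0, flip = TRUE)[[2]]
  w <- ncol(fr$image)
  expect_equal(unname(fl$joints["r_elbow", ]),
               unname(c(w - 1 - fr$joints["l_elbow", "x"],
                        fr$joints["l_elbow", "y"])),
               tolerance = 1e-9)
  expect_equal(unname(fl$joints["head", "x"]),
               unname(w - 1 - fr$joints["head", "x"]), tolerance = 1e-9)
  expect_identical(fl$image, fr$image[, rev(seq_len(w))])
})

test_that("rotations that push joints off-canvas pad instead of dropping", {
  img <- matrix(0.5, 40, 40)
  joints <- rbind(corner = c(38, 1), center = c(20, 20))
  fr <- annotated_frame(img, joints, "edge")
  expect_message(out <- augment(fr, rotations = 30, flip = FALSE), "padded")
  v <- out[[1]]
  expect_true(all(v$joints[, 1] >= 0 & v$joints[, 1] <= ncol(v$image) - 1))
  expect_true(all(v$joints[, 2] >= 0 & v$joints[, 2] <= nrow(v$image) - 1))
})

test_that("patch sizing follows the 75% quantile of limb-length ratios", {
  cfg <- small_fig()
  frames <- withr::with_seed(4, lapply(1:6, function(i)
    render_frame(sample_pose(cfg), cfg, id = paste0("f", i))))
  # identical frames: every ratio is 1, side equals the base patch
  same <- rep(frames[1], 4)
  expect_equal(bbox_size(same, base_patch_px = 40), rep(40, 4))
  # one frame scaled 2x among identical frames gets a 2x box
  big <- frames[[1]]
  big$joints <- big$joints * 2
  big$image <- matrix(0.2, 2 * nrow(big$image), 2 * ncol(big$image))
  mix <- c(rep(frames[1], 4), list(big))
  sides <- bbox_size(mix, base_patch_px = 40)
  expect_equal(sides[5], 80)
  expect_equal(sides[1:4], rep(40, 4))
  # random sets agree with the sort-based quantile oracle
  sides2 <- bbox_size(frames, base_patch_px = 30)
  tr <- infant_tree()
  nonroot <- setdiff(tr$order, tr$root)
  len <- sapply(frames, function(f) sapply(nonroot, function(ch)
    sqrt(sum((f$joints[ch, ] - f$joints[tr$parent[[ch]], ])^2))))
  med <- apply(len, 1, median)
  for (i in seq_along(frames))
    expect_equal(sides2[i], quantile_oracle(len[, i] / med, 0.75) * 30,
                 tolerance = 1e-12)
  # coincident joints are excluded with a log message
  degen <- frames[[1]]
  degen$joints["l_hand", ] <- degen$joints["l_elbow", ]
  expect_message(bbox_size(c(frames[1:3], list(degen))), "zero-length")
})

test_that("k-means state clustering recovers well-separated displacement modes", {
  set.seed(10)
  blobs <- rbind(matrix(rnorm(100, 0, 0.4), 50, 2),
                 sweep(matrix(rnorm(100, 0, 0.4), 50, 2), 2, c(8, 0), "+"),
                 sweep(matrix(rnorm(100, 0, 0.4), 50, 2), 2, c(4, 7), "+"))
  truth <- rep(1:3, each = 50)
  cs <- cluster_states(blobs, 3, seed = 1)
  expect_equal(adjusted_rand_index(cs$labels, truth), 1.0)
  # S = 1 collapses to the mean
  one <- cluster_states(blobs, 1, seed = 1)
  expect_equal(as.numeric(one$centroids), colMeans(blobs), tolerance = 1e-9)
  # duplicating every point leaves the centroids unchanged
  dup <- cluster_states(rbind(blobs, blobs), 3, seed = 1)
  expect_equal(dup$centroids, cs$centroids, tolerance = 1e-9)
  expect_error(cluster_states(blobs[1:2, ], 3), "exceed")
  # determinism under a fixed seed
  expect_identical(cluster_states(blobs, 3, seed = 7),
                   cluster_states(blobs, 3, seed = 7))
})

test_that("BIC selects the generating cluster count and guards perfect fits", {
  # compact well-separated clusters at small sample size: the regime where
  # the ln(n) penalty can balance the linear-in-n fit term
  blobs <- three_cluster_points(1)
  sel <- bic_select(blobs, 1:8, seed = 2)
  expect_identical(sel$S, 3L)
  expect_equal(nrow(sel$table), 8L)
  # n identical points: R = 0 at S = 1, the guard wins immediately;
  # S beyond the distinct-point count is marked unfittable, not an error
  same <- matrix(1, 10, 2)
  sel0 <- bic_select(same, 1:2, seed = 1)
  expect_identical(sel0$S, 1L)
  expect_true(is.infinite(sel0$table$bic[1]))
  expect_identical(sel0$table$bic[2], Inf)
  expect_error(bic_select(blobs[1:3, ], 1:10), "<=")
})

test_that("the structured feature vector reproduces the configuration score", {
  for (s in c(41, 42, 43)) {
    tm <- random_tiny_model(s)
    beta <- model_beta(tm$model)
    withr::with_seed(s, {
      g <- tm$grid
      pl <- data.frame(part = tm$model$tree$parts,
                       state = vapply(tm$model$states, function(S)
                         sample.int(S, 1L), integer(1L)),
                       x = sample(0:(g - 1), length(tm$model$states), TRUE),
                       y = sample(0:(g - 1), length(tm$model$states), TRUE))
    })
    phi <- build_feature_vector(tm$model, tm$level, pl)
    expect_equal(sum(beta * phi), score_configuration(tm$model, tm$level, pl),
                 tolerance = 1e-6)
  }
})

test_that("feature vectors are local: a one-state change touches only its slots", {
  tm <- random_tiny_model(44)
  m <- tm$model
  # find a part with >= 2 states
  p2 <- names(which(m$states >= 2L))[1]
  skip_if(is.na(p2), "random model has single-state parts only")
  pl <- data.frame(part = m$tree$parts, state = 1L, x = 1L, y = 1L)
  pl2 <- pl
  pl2$state[pl2$part == p2] <- 2L
  f1 <- build_feature_vector(m, tm$level, pl)
  f2 <- build_feature_vector(m, tm$level, pl2)
  changed <- which(f1 != f2)
  lay <- babydpm:::beta_layout(m)
  allowed <- c()
  for (s in 1:2) allowed <- c(allowed, lay$filters[[p2]][s] + seq_len(lay$filter_len))
  allowed <- c(allowed, lay$unary[[p2]] + 1:2)
  for (ch in names(lay$zeta)) {
    if (ch == p2 || m$tree$parent[[ch]] == p2) {
      allowed <- c(allowed, lay$zeta[[ch]] + seq_along(m$zeta[[ch]]),
                   lay$pairwise[[ch]] + seq_along(m$pairwise[[ch]]))
    }
  }
  expect_true(all(changed %in% allowed))
  # a zero image zeroes the filter slots but not the structural slots
  lev0 <- hog_level(array(0, dim(tm$level$cells)), 4, 1, dim(tm$level$cells)[3])
  f0 <- build_feature_vector(m, lev0, pl)
  for (p in m$tree$parts)
    expect_true(all(f0[lay$filters[[p]][1] + seq_len(lay$filter_len)] == 0))
  expect_identical(f0[lay$bias + 1L], 1)
})

test_that("training on a tiny separable set is reproducible and C-monotone", {
  cfg <- small_fig()
  tr <- generate_training_frames(10, cfg, seed = 21)
  ng <- generate_negative_frames(3, cfg, seed = 22, clutter = FALSE)
  fit1 <- train_model(tr, ng, tiny_training_config())
  fit2 <- train_model(tr, ng, tiny_training_config())
  expect_identical(model_beta(fit1$model), model_beta(fit2$model))
  expect_true(all(diff(fit1$log$objective) <= 1e-6))
  norms <- vapply(c(1e-4, 1e-2, 1), function(C) {
    f <- train_model(tr, ng, tiny_training_config(C = C))
    sqrt(sum(model_beta(f$model)^2))
  }, numeric(1))
  expect_true(all(diff(norms) >= -1e-9))
})

test_that("cross-validation handles singleton grids, ties and refinement", {
  cfg <- small_fig()
  tr <- generate_training_frames(6, cfg, seed = 31)
  ng <- generate_negative_frames(2, cfg, seed = 32, clutter = FALSE)
  base <- tiny_training_config(folds = 3L, max_passes = 1L, mine_rounds = 2L)
  expect_error(cross_validate(tr[1:2], ng, 0.1,
                              tiny_training_config(folds = 3L)), "folds")
  single <- cross_validate(tr, ng, 0.1, base)
  expect_identical(single$best_C, 0.1)
  expect_identical(single$refined, single$coarse)
  two <- cross_validate(tr, ng, c(0.05, 0.5), base)
  # refinement includes the coarse winner, so it can never score worse
  expect_gte(max(two$refined$score), max(two$coarse$score))
  # identical scores tie toward the smallest C
  if (length(unique(two$coarse$score)) == 1L)
    expect_identical(two$coarse$C[1], min(two$coarse$C))
})
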