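test_that("filter responses match direct cross-correlation", {
  set.seed(5)
  d <- 4L
  lev <- hog_level(array(rnorm(10 * 10 * d), c(10, 10, d)), 4, 1, d)
  zero <- array(0, c(5, 5, d))
  for (x in 0:5) for (y in 0:5)
    expect_identical(filter_response(zero, lev, c(x, y)), 0)
  # self-correlation equals the squared Frobenius norm of the patch
  patch <- lev$cells[3:7, 2:6, , drop = FALSE]
  expect_equal(filter_response(array(patch, dim(patch)), lev, c(1, 2)),
               sum(patch^2), tolerance = 1e-12)
  filt <- array(rnorm(5 * 5 * d), c(5, 5, d))
  expect_equal(filter_response_map(filt, lev), xcorr_oracle(lev$cells, filt),
               tolerance = 1e-9)
  expect_error(filter_response(filt, lev, c(6, 0)), "out of bounds")
})

test_that("deformation features follow the displacement arithmetic", {
  expect_identical(deformation_feature(c(2, 3), c(2, 3)), c(0, 0, 0, 0))
  expect_identical(deformation_feature(c(5, 7), c(2, 3)), c(3, 4, 9, 16))
  f1 <- deformation_feature(c(5, 7), c(2, 3))
  f2 <- deformation_feature(c(2, 3), c(5, 7))
  expect_identical(f2[1:2], -f1[1:2])
  expect_identical(f2[3:4], f1[3:4])
})

test_that("spring scores penalize deviation from the rest offset", {
  # the conventional initialization, displaced (3, 4) from the anchor
  expect_equal(deformation_score(c(0, 0, 0.01, 0.01), c(3, 4), c(0, 0)), -0.25)
  expect_identical(deformation_score(c(0.3, -0.2, 0.05, 0.08),
                                     c(4, 1), c(2, 3), anchor = c(2, -2)), 0)
  z <- c(0, 0, 0.02, 0.03)
  vals <- sapply(0:5, function(dx) deformation_score(z, c(dx, 0), c(0, 0)))
  expect_true(all(vals <= 0))
  expect_true(all(diff(vals) < 0))
  set.seed(9)
  for (i in 1:100) {
    z <- c(rnorm(2), runif(2, 0, 1))
    la <- runif(2, -5, 5); lb <- runif(2, -5, 5); an <- runif(2, -2, 2)
    dd <- la - lb - an
    expect_equal(deformation_score(z, la, lb, an),
                 -sum(z * c(dd, dd^2)), tolerance = 1e-12)
  }
})

test_that("the compiled spring message equals the explicit O(n^2) reference", {
  set.seed(21)
  for (i in 1:10) {
    s <- matrix(rnorm(7 * 9), 7, 9)
    if (i > 7) s[sample(63, 10)] <- -Inf   # masked placements
    z <- c(runif(1, -0.2, 0.2), runif(1, -0.2, 0.2),
           runif(1, 0.001, 0.3), runif(1, 0.001, 0.3))
    an <- runif(2, -3, 3)
    a <- babydpm:::spring_message(s, z, an)
    b <- babydpm:::spring_message_ref(s, z, an)
    expect_equal(a$val, b$val, tolerance = 1e-12)
    expect_identical(a$argy, b$argy)
    expect_identical(a$argx, b$argx)
  }
})

test_that("DP inference equals exhaustive enumeration on fixture models", {
  # 2-part chain, 4x4 valid grid, 2 states per part
  withr::with_seed(31, {
    tree <- kinematic_tree(c("a", "b"), c(a = NA, b = "a"))
    m <- body_model(tree, c(a = 2L, b = 2L), feature_config(4L, 3L))
    m <- model_set_beta(m, rnorm(length(model_beta(m))) * 0.5)
    m$zeta$b[, , 3:4] <- abs(m$zeta$b[, , 3:4]) + 1e-3
    m$anchor$b[] <- runif(length(m$anchor$b), -2, 2)
    lev <- hog_level(array(rnorm(8 * 8 * 3), c(8, 8, 3)), 4, 1, 3)
  })
  best <- infer_pose(m, as_one_level_pyramid(lev), max_candidates = 1)[[1]]
  oracle <- enumerate_best(m, lev)
  expect_equal(best$score, oracle$score, tolerance = 1e-9)
  expect_identical(best$parts[, c("state", "cx", "cy")],
                   stats::setNames(oracle$placements[
                     match(best$parts$part, oracle$placements$part),
                     c("state", "x", "y")], c("state", "cx", "cy")),
                   ignore_attr = TRUE)

  # 5-part star, single state
  withr::with_seed(32, {
    parts <- c("r", "c1", "c2", "c3", "c4")
    tree <- kinematic_tree(parts, c(r = NA, c1 = "r", c2 = "r", c3 = "r", c4 = "r"))
    st <- stats::setNames(rep(1L, 5), parts)
    m2 <- body_model(tree, st, feature_config(4L, 2L))
    m2 <- model_set_beta(m2, rnorm(length(model_beta(m2))) * 0.5)
    for (ch in parts[-1]) {
      m2$zeta[[ch]][, , 3:4] <- abs(m2$zeta[[ch]][, , 3:4]) + 1e-3
      m2$anchor[[ch]][] <- runif(2, -2, 2)
    }
    lev2 <- hog_level(array(rnorm(8 * 8 * 2), c(8, 8, 2)), 4, 1, 2)
  })
  best2 <- infer_pose(m2, as_one_level_pyramid(lev2), max_candidates = 1)[[1]]
  oracle2 <- enumerate_best(m2, lev2)
  expect_equal(best2$score, oracle2$score, tolerance = 1e-9)
})

test_that("a flat zero model returns the bias and the documented tie-break", {
  tm <- random_tiny_model(55)
  m <- model_set_beta(tm$model, numeric(length(model_beta(tm$model))))
  m$bias <- 0.5
  for (ch in setdiff(m$tree$parts, m$tree$root)) m$anchor[[ch]][] <- 0
  best <- infer_pose(m, as_one_level_pyramid(tm$level), max_candidates = 1)[[1]]
  expect_identical(best$score, 0.5)
  # smallest (y, x, state) everywhere
  expect_true(all(best$parts$cx == 0L))
  expect_true(all(best$parts$cy == 0L))
  expect_true(all(best$parts$state == 1L))
})

test_that("backtracked placements reproduce the reported root score", {
  for (s in c(71, 72, 73)) {
    tm <- random_tiny_model(s)
    cands <- infer_pose(tm$model, as_one_level_pyramid(tm$level),
                        max_candidates = 3)
    for (cd in cands) {
      pl <- data.frame(part = cd$parts$part, state = cd$parts$state,
                       x = cd$parts$cx, y = cd$parts$cy)
      expect_equal(score_configuration(tm$model, tm$level, pl), cd$score,
                   tolerance = 1e-6)
    }
  }
})

test_that("greedy NMS equals the quadratic reference on random candidate sets", {
  set.seed(61)
  tm <- random_tiny_model(61)
  pyr <- as_one_level_pyramid(tm$level)
  cands <- infer_pose(tm$model, pyr, max_candidates = 30)
  survivors <- nms(cands, 0.3, tm$model$tree$root)
  reference <- nms_oracle(cands, 0.3, tm$model$tree$root)
  expect_identical(vapply(survivors, function(p) p$score, numeric(1)),
                   vapply(reference, function(p) p$score, numeric(1)))
  # subset property and pairwise non-overlap
  expect_true(all(vapply(survivors, function(p) p$score, numeric(1)) %in%
                    vapply(cands, function(p) p$score, numeric(1))))
  # two identical candidates collapse to one
  expect_length(nms(c(cands[1], cands[1]), 0.3, tm$model$tree$root), 1L)
  # disjoint candidates all survive under zero overlap
  far <- cands[[1]]
  far$parts$x <- far$parts$x + 1000
  expect_length(nms(list(cands[[1]], far), 0.3, tm$model$tree$root), 2L)
})

test_that("root-level NMS inside inference matches NMS after backtracking", {
  tm <- random_tiny_model(62)
  pyr <- as_one_level_pyramid(tm$level)
  a <- infer_pose(tm$model, pyr, max_candidates = 8, root_nms = 0.3)
  b <- nms(infer_pose(tm$model, pyr, max_candidates = 100), 0.3,
           tm$model$tree$root)
  expect_length(a, min(8L, length(b)))
  expect_equal(vapply(a, function(p) p$score, numeric(1)),
               vapply(b[seq_along(a)], function(p) p$score, numeric(1)))
})

test_that("occlusion thresholding flags low-scoring parts", {
  tm <- random_tiny_model(81)
  pose <- infer_pose(tm$model, as_one_level_pyramid(tm$level),
                     max_candidates = 1)[[1]]
  expect_true(all(apply_occlusion_threshold(pose, -Inf)$parts$visible))
  hi <- max(pose$parts$score) + 1
  expect_false(any(apply_occlusion_threshold(pose, hi)$parts$visible))
  named <- stats::setNames(rep(-Inf, nrow(pose$parts)), pose$parts$part)
  named[pose$parts$part[1]] <- pose$parts$score[1] + 1
  flags <- apply_occlusion_threshold(pose, named)$parts$visible
  expect_false(flags[1]); expect_true(all(flags[-1]))
})

test_that("search-space restriction dilates and clips the previous pose box", {
  pose <- structure(list(parts = data.frame(x = c(30, 70), y = c(40, 80))),
                    class = "pose_estimate")
  expect_equal(restrict_search_space(pose, 20, c(200, 200)),
               c(10, 20, 90, 100))
  # saturating dilation reaches the full frame
  expect_equal(restrict_search_space(pose, 1e4, c(120, 160)),
               c(0, 0, 159, 119))
  expect_warning(out <- infer_pose(random_tiny_model(1)$model,
                                   as_one_level_pyramid(random_tiny_model(1)$level),
                                   search_region = c(10, 10, 5, 5)), "empty")
  expect_length(out, 0L)
})

test_that("restricting the search never increases the best score", {
  for (s in c(91, 92)) {
    tm <- random_tiny_model(s)
    pyr <- as_one_level_pyramid(tm$level)
    full <- infer_pose(tm$model, pyr, max_candidates = 1)[[1]]
    g_px <- dim(tm$level$cells)[1] * 4
    box <- c(0, 0, g_px / 2, g_px / 2)
    restricted <- suppressWarnings(infer_pose(tm$model, pyr, box,
                                              max_candidates = 1))
    if (length(restricted))
      expect_lte(restricted[[1]]$score, full$score + 1e-9)
    # a region containing the whole frame reproduces the unrestricted result
    same <- infer_pose(tm$model, pyr, c(-1e3, -1e3, 1e3, 1e3),
                       max_candidates = 1)[[1]]
    expect_equal(same$score, full$score, tolerance = 1e-12)
    expect_identical(same$parts$cx, full$parts$cx)
  }
})
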