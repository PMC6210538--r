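test_that("joint angles reproduce closed-form fixtures", {
  expect_equal(joint_angle(c(1, 0), c(0, 0), c(0, 1)), 90)
  expect_equal(joint_angle(c(-2, 0), c(0, 0), c(5, 0)), 180)
  expect_equal(joint_angle(c(2, 0), c(0, 0), c(2, 2)), 45)
  expect_true(is.na(joint_angle(c(0, 0), c(0, 0), c(1, 1))))
})

test_that("angles are invariant under similarity transforms", {
  set.seed(17)
  for (i in 1:200) {
    pts <- matrix(rnorm(6, sd = 10), 3, 2)
    if (any(duplicated(pts))) next
    th0 <- joint_angle(pts[1, ], pts[2, ], pts[3, ])
    a <- runif(1, 0, 2 * pi); s <- runif(1, 0.1, 10); t <- rnorm(2, sd = 50)
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    q <- s * pts %*% t(R) + matrix(t, 3, 2, byrow = TRUE)
    expect_equal(joint_angle(q[1, ], q[2, ], q[3, ]), th0, tolerance = 1e-6)
  }
})

test_that("motion encoding produces per-joint series with gaps at occlusions", {
  tr <- infant_tree()
  aj <- angle_joints(tr)
  expect_setequal(aj$joint, c("l_shoulder", "r_shoulder", "l_elbow", "r_elbow",
                              "l_hip", "r_hip", "l_knee", "r_knee"))
  # a static pose yields a constant series
  pose <- withr::with_seed(3, sample_pose(figure_config()))
  traj <- do.call(rbind, lapply(1:20, function(f)
    data.frame(frame = f, part = rownames(pose$joints),
               x = pose$joints[, "x"], y = pose$joints[, "y"], visible = TRUE)))
  ang <- encode_motion(traj, tr)
  expect_equal(nrow(ang), 20L * 8L)
  for (j in unique(ang$joint))
    expect_equal(diff(range(ang$theta[ang$joint == j])), 0)
  # flipping the frame horizontally leaves unsigned angles unchanged
  traj_f <- traj; traj_f$x <- 159 - traj_f$x
  expect_equal(encode_motion(traj_f, tr)$theta, ang$theta, tolerance = 1e-9)
  # occluding the knee opens gaps at the knee and hip angles
  traj_o <- traj
  traj_o$visible[traj_o$part == "l_knee"] <- FALSE
  ang_o <- encode_motion(traj_o, tr)
  expect_true(all(is.na(ang_o$theta[ang_o$joint %in% c("l_knee", "l_hip")])))
  expect_false(anyNA(ang_o$theta[ang_o$joint == "r_knee"]))
})

test_that("ground-truth joints reproduce the programmed angle series", {
  sq <- generate_sequence(figure_config(), n_frames = 40, seed = 12)
  rec <- encode_motion(sq$trajectory)
  m <- merge(rec, sq$angles, by = c("frame", "joint"))
  expect_gt(nrow(m), 0)
  expect_lt(max(abs(m$theta.x - m$theta.y)), 0.5)
})

test_that("AJPE matches fixtures and a per-frame loop oracle", {
  pose <- withr::with_seed(4, sample_pose(figure_config()))
  truth <- do.call(rbind, lapply(1:10, function(f)
    data.frame(frame = f, part = rownames(pose$joints),
               x = pose$joints[, "x"], y = pose$joints[, "y"], visible = TRUE)))
  expect_equal(suppressMessages(ajpe(truth, truth))$mean, 0)
  off <- truth
  off$x[off$part == "l_hand"] <- off$x[off$part == "l_hand"] + 3
  off$y[off$part == "l_hand"] <- off$y[off$part == "l_hand"] + 4
  a <- suppressMessages(ajpe(off, truth))
  expect_equal(unname(a$per_part["l_hand"]), 5)
  expect_equal(sum(a$per_part), 5)
  # random offsets against an explicit loop
  set.seed(31)
  noisy <- truth
  noisy$x <- noisy$x + rnorm(nrow(noisy))
  noisy$y <- noisy$y + rnorm(nrow(noisy))
  a2 <- suppressMessages(ajpe(noisy, truth))
  for (p in unique(truth$part)) {
    errs <- c()
    for (f in 1:10) {
      i <- which(noisy$frame == f & noisy$part == p)
      j <- which(truth$frame == f & truth$part == p)
      errs <- c(errs, sqrt((noisy$x[i] - truth$x[j])^2 +
                           (noisy$y[i] - truth$y[j])^2))
    }
    expect_equal(unname(a2$per_part[p]), mean(errs), tolerance = 1e-12)
  }
  # millimeter conversion is a pure rescale
  a3 <- ajpe(noisy, truth, mm_per_px = 2.5)
  expect_equal(a3$mean, 2.5 * a2$mean, tolerance = 1e-12)
  expect_error(suppressMessages(ajpe(noisy[0, ], truth)), "matched")
})

test_that("WCA counts whole frames and is monotone in its threshold", {
  pose <- withr::with_seed(5, sample_pose(figure_config()))
  truth <- do.call(rbind, lapply(1:10, function(f)
    data.frame(frame = f, part = rownames(pose$joints),
               x = pose$joints[, "x"], y = pose$joints[, "y"], visible = TRUE)))
  expect_equal(wca(truth, truth, 1), 100)
  bad <- truth
  i <- which(bad$frame == 7 & bad$part == "head")
  bad$x[i] <- bad$x[i] + 50
  expect_equal(wca(bad, truth, 10), 90)
  ths <- c(0.5, 1, 5, 20, 60, 100)
  vals <- vapply(ths, function(om) wca(bad, truth, om), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("angle MAE matches fixtures and a loop oracle", {
  ang <- expand.grid(frame = 1:30, joint = c("l_knee", "r_knee"))
  ang$theta <- runif(nrow(ang), 0, 180)
  expect_equal(mae_angles(ang, ang)$mean, 0)
  shifted <- ang
  shifted$theta[shifted$joint == "l_knee"] <-
    shifted$theta[shifted$joint == "l_knee"] + 2
  m <- mae_angles(shifted, ang)
  expect_equal(unname(m$per_joint["l_knee"]), 2, tolerance = 1e-12)
  expect_equal(unname(m$per_joint["r_knee"]), 0)
  set.seed(8)
  noisy <- ang; noisy$theta <- noisy$theta + rnorm(nrow(noisy))
  m2 <- mae_angles(noisy, ang)
  for (j in c("l_knee", "r_knee")) {
    e <- abs(noisy$theta[noisy$joint == j] - ang$theta[ang$joint == j])
    expect_equal(unname(m2$per_joint[j]), mean(e), tolerance = 1e-12)
  }
  gap <- ang; gap$theta[1] <- NA
  expect_equal(mae_angles(gap, ang)$mean, 0)
  expect_error(mae_angles(transform(ang, theta = NA), ang), "overlapping")
})
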