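test_that("forward kinematics is exact for straight limbs", {
  cfg <- figure_config(image_size = c(400, 400), head_x = c(50, 50),
                       head_y = c(200, 200), axis_deg = c(0, 0))
  angles <- stats::setNames(rep(180, length(cfg$angle_ranges)),
                            names(cfg$angle_ranges))
  J <- babydpm:::figure_fk(angles, c(50, 200), 0, cfg)
  # all segments collinear along the +x body axis
  expect_true(all(abs(J[, "y"] - 200) < 1e-9))
  tr <- infant_tree()
  for (ch in setdiff(tr$order, tr$root)) {
    d <- J[ch, ] - J[tr$parent[[ch]], ]
    expect_equal(sqrt(sum(d^2)), unname(cfg$lengths[[ch]]), tolerance = 1e-9)
  }
})

test_that("sampled poses are deterministic and reproduce their angles", {
  cfg <- figure_config()
  p1 <- withr::with_seed(9, sample_pose(cfg))
  p2 <- withr::with_seed(9, sample_pose(cfg))
  expect_identical(p1, p2)
  tr <- infant_tree()
  for (ch in setdiff(tr$order, c("head", "neck"))) {
    pa <- tr$parent[[ch]]; gp <- tr$parent[[pa]]
    rec <- joint_angle(p1$joints[ch, ], p1$joints[pa, ], p1$joints[gp, ])
    expect_equal(rec, unname(p1$angles[[ch]]), tolerance = 1e-6)
  }
  # an impossible canvas triggers the bounded-retry error
  tiny <- figure_config(image_size = c(40, 40), margin = 18,
                        head_x = c(20, 20), head_y = c(20, 20))
  expect_error(withr::with_seed(1, sample_pose(tiny, max_retries = 5)),
               "retries")
})

test_that("hard-edged rendering equals the point-in-shape oracle", {
  cfg <- figure_config(background = 0, texture_amp = 0, noise_sd = 0)
  pose <- withr::with_seed(21, sample_pose(cfg))
  fr <- render_frame(pose, cfg, antialias = FALSE, noise = FALSE)
  mask <- fr$image > 0
  # independent per-pixel geometry: distance to each capsule, the head disc
  # and the torso quad
  tr <- infant_tree()
  J <- pose$joints
  segs <- lapply(setdiff(tr$order, tr$root), function(ch)
    rbind(J[tr$parent[[ch]], ], J[ch, ]))
  quad <- rbind(J["l_shoulder", ], J["r_shoulder", ], J["r_hip", ], J["l_hip", ])
  in_quad <- function(x, y) {
    cent <- colMeans(quad)
    for (i in 1:4) {
      a <- quad[i, ]; b <- quad[i %% 4 + 1, ]
      s <- (b[1] - a[1]) * (cent[2] - a[2]) - (b[2] - a[2]) * (cent[1] - a[1])
      v <- (b[1] - a[1]) * (y - a[2]) - (b[2] - a[2]) * (x - a[1])
      if (v * sign(s) < 0) return(FALSE)
    }
    TRUE
  }
  seg_dist <- function(x, y, s) {
    v <- s[2, ] - s[1, ]
    t <- ((x - s[1, 1]) * v[1] + (y - s[1, 2]) * v[2]) / sum(v^2)
    t <- min(max(t, 0), 1)
    sqrt((x - s[1, 1] - t * v[1])^2 + (y - s[1, 2] - t * v[2])^2)
  }
  oracle <- matrix(FALSE, nrow(fr$image), ncol(fr$image))
  for (yy in seq_len(nrow(fr$image))) {
    for (xx in seq_len(ncol(fr$image))) {
      x <- xx - 1; y <- yy - 1
      fg <- sqrt(sum((c(x, y) - J["head", ])^2)) <= cfg$head_radius ||
        in_quad(x, y)
      if (!fg) {
        for (s in segs) {
          if (seg_dist(x, y, s) <= cfg$limb_width / 2) { fg <- TRUE; break }
        }
      }
      oracle[yy, xx] <- fg
    }
  }
  expect_identical(mask, oracle)
  # every joint lies on rendered foreground
  for (p in rownames(J))
    expect_true(mask[round(J[p, "y"]) + 1, round(J[p, "x"]) + 1])
})

test_that("rendering and sequences are bit-reproducible under a seed", {
  cfg <- figure_config()
  f1 <- generate_training_frames(2, cfg, seed = 5)
  f2 <- generate_training_frames(2, cfg, seed = 5)
  expect_identical(f1[[2]]$image, f2[[2]]$image)
  s1 <- generate_sequence(cfg, n_frames = 4, seed = 6)
  s2 <- generate_sequence(cfg, n_frames = 4, seed = 6)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$trajectory, s2$trajectory)
  n1 <- generate_negative_frames(3, cfg, seed = 7)
  n2 <- generate_negative_frames(3, cfg, seed = 7)
  expect_identical(n1, n2)
})

test_that("sequences respect their motion program", {
  cfg <- figure_config()
  # zero amplitudes freeze the figure
  frozen <- lapply(default_motion(cfg), function(m) { m$amp <- 0; m })
  sq0 <- generate_sequence(cfg, motion = frozen, n_frames = 5, seed = 3)
  expect_identical(sq0$frames[[1]], sq0$frames[[5]])
  expect_equal(sq0$max_step, 0)
  # programmed sinusoid appears exactly in the ground-truth series: the
  # vertex angle at l_knee is generated by the l_foot edge program
  sq <- generate_sequence(cfg, n_frames = 60, seed = 3)
  got <- sq$angles$theta[sq$angles$joint == "l_knee"]
  mk <- default_motion(cfg)$l_foot
  rk <- cfg$angle_ranges$l_foot
  prog_knee <- pmin(pmax(mean(rk) + mk$amp *
                           sin(2 * pi * (0:59) / mk$period + mk$phase),
                         rk[1]), rk[2])
  expect_equal(got, prog_knee, tolerance = 1e-12)
  # per-frame joint displacement stays small and bounded
  expect_gt(sq$max_step, 0)
  expect_lt(sq$max_step, 10)
})

test_that("the occlusion schedule masks limbs and flags ground truth", {
  cfg <- figure_config()
  oc <- list(list(parts = c("l_elbow", "l_hand"), from = 3, to = 5))
  sq <- generate_sequence(cfg, n_frames = 6, seed = 4, occlusion = oc)
  v <- sq$trajectory
  expect_false(any(v$visible[v$frame == 4 & v$part %in% c("l_elbow", "l_hand")]))
  expect_true(all(v$visible[v$frame == 2 | v$frame == 6]))
  # the masked frame really differs from the unmasked render
  sq_plain <- generate_sequence(cfg, n_frames = 6, seed = 4)
  expect_false(identical(sq$frames[[4]], sq_plain$frames[[4]]))
  expect_identical(sq$frames[[1]], sq_plain$frames[[1]])
})
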