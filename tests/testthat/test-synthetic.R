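test_that("skeleton sampling is deterministic, symmetric and proportional", {
  cfg <- synth_config()
  s1 <- poselift:::with_rng(5, sample_skeleton(cfg))
  s2 <- poselift:::with_rng(5, sample_skeleton(cfg))
  expect_identical(s1, s2)
  L <- s1$lengths
  expect_true(all(L > 0))
  expect_gte(s1$stature, 1500); expect_lte(s1$stature, 1900)
  # vertical chain sums to the stature within 5%
  chain <- L[["ankle_height"]] + L[["calf"]] + L[["thigh"]] + L[["trunk"]] +
    L[["shoulder_to_crown"]]
  expect_lt(abs(chain - s1$stature) / s1$stature, 0.05)
  # bilateral symmetry is by construction: one length per segment, and the
  # generated canonical pose has equal left/right limb lengths
  cp <- canonical_pose(s1)
  d <- function(a, b) sqrt(sum((cp$coords[kp_index(a), ] - cp$coords[kp_index(b), ])^2))
  expect_equal(d("left_hip", "left_knee"), d("right_hip", "right_knee"))
  expect_equal(d("left_shoulder", "left_elbow"), d("right_shoulder", "right_elbow"))
})

test_that("forward kinematics keeps bone lengths exact and angles in range", {
  cfg <- synth_config()
  sk <- poselift:::with_rng(6, sample_skeleton(cfg))
  L <- sk$lengths
  segpairs <- list(c("left_hip", "left_knee", "thigh"),
                   c("right_knee", "right_ankle", "calf"),
                   c("left_shoulder", "left_elbow", "upper_arm"),
                   c("right_elbow", "right_wrist", "forearm"))
  poselift:::with_rng(7, {
    for (k in 1:50) {
      p <- sample_pose3d(sk, cfg)
      for (sp in segpairs) {
        dist <- sqrt(sum((p$coords[kp_index(sp[1]), ] -
                            p$coords[kp_index(sp[2]), ])^2))
        expect_equal(dist, unname(L[[sp[3]]]), tolerance = 1e-9)
      }
      # interior elbow angle within the configured anatomical range
      for (s in c("left", "right")) {
        e <- p$coords[kp_index(paste0(s, "_elbow")), ]
        ang <- joint_angle(p$coords[kp_index(paste0(s, "_shoulder")), ] - e,
                           p$coords[kp_index(paste0(s, "_wrist")), ] - e)
        expect_gte(ang, (cfg$elbow_angle_range_deg[1] - 1e-6) * pi / 180)
        expect_lte(ang, (cfg$elbow_angle_range_deg[2] + 1e-6) * pi / 180)
      }
      # root-relative: pelvis at the origin
      expect_equal(pelvis_root(p), c(0, 0, 0), tolerance = 1e-9)
    }
  })
})

test_that("rendering projects exactly at zero noise and occludes as missingness", {
  cfg0 <- synth_config(noise_sigma_px = 0, occlusion_prob = 0)
  sk <- poselift:::with_rng(8, sample_skeleton(cfg0))
  p <- poselift:::with_rng(9, sample_pose3d(sk, cfg0))
  smp <- poselift:::with_rng(10, render_sample(p, cfg0))
  expect_true(all(smp$pose2d$valid))
  # 2D equals the pinhole projection of the placed 3D pose
  cam_coords <- sweep(smp$gt$coords, 2, smp$root_cam, `+`)
  expect_equal(smp$pose2d$coords, project(cam_coords, smp$cam), tolerance = 1e-9)
  # the clean geometry satisfies the constant-limb-length relation: the
  # depth solver recovers the true depth offset along sampled bones
  lay <- wb_layout()
  for (e in c(5, 40, 100)) {
    pr <- lay$edges[e, "parent"]; ch <- lay$edges[e, "child"]
    P1 <- cam_coords[pr, ]; P2 <- cam_coords[ch, ]
    L <- sqrt(sum((P1 - P2)^2))
    roots <- limb_depth_offsets(project(P1, smp$cam), project(P2, smp$cam),
                                P1[3], L, smp$cam)
    expect_lt(min(abs(roots - (P2[3] - P1[3]))), 1e-6 * max(1, L))
  }
  # full occlusion leaves only the root hips observable
  cfg1 <- synth_config(occlusion_prob = 1)
  smp1 <- poselift:::with_rng(11, render_sample(p, cfg1))
  expect_equal(which(smp1$pose2d$valid), unname(wb_layout()$root_hips))
  expect_true(all(smp1$pose2d$confidence[!smp1$pose2d$valid] == 0))
  expect_true(all(smp1$pose2d$coords[!smp1$pose2d$valid, ] == 0))
})

test_that("pixel noise has the configured scale", {
  cfg <- synth_config(noise_sigma_px = 1, occlusion_prob = 0)
  sk <- poselift:::with_rng(12, sample_skeleton(cfg))
  devs <- poselift:::with_rng(13, {
    out <- c()
    for (k in 1:80) {
      p <- sample_pose3d(sk, cfg)
      smp <- render_sample(p, cfg)
      out <- c(out, smp$pose2d$coords - smp$clean2d)
    }
    out
  })
  expect_gt(sd(devs), 0.97)
  expect_lt(sd(devs), 1.03)
})

test_that("CoG of generated poses lies within the vertical extent", {
  cfg <- synth_config()
  tab <- anthro_table("M")
  sk <- poselift:::with_rng(14, sample_skeleton(cfg))
  poselift:::with_rng(15, {
    for (k in 1:20) {
      p <- sample_pose3d(sk, cfg)
      cog <- body_cog(p, tab)
      expect_gte(cog[2], min(p$coords[, 2]))
      expect_lte(cog[2], max(p$coords[, 2]))
    }
  })
})

test_that("benchmarks are reproducible with disjoint skeleton splits", {
  cfg <- synth_config(n_train = 60, n_val = 20, n_test = 20, seed = 7)
  b1 <- make_benchmark(cfg, poses_per_skeleton = 10)
  b2 <- make_benchmark(cfg, poses_per_skeleton = 10)
  expect_identical(b1$train$kp2d, b2$train$kp2d)
  expect_identical(b1$test$kp3d, b2$test$kp3d)
  expect_identical(b1$manifest$config_hash, b2$manifest$config_hash)
  ids <- list(b1$train$skeleton_id, b1$val$skeleton_id, b1$test$skeleton_id)
  expect_length(intersect(ids[[1]], ids[[2]]), 0)
  expect_length(intersect(ids[[1]], ids[[3]]), 0)
  expect_length(intersect(ids[[2]], ids[[3]]), 0)
  # default desk benchmark sizes
  dc <- synth_config()
  expect_equal(c(dc$n_train, dc$n_val, dc$n_test), c(2000, 400, 400))
  # ground truth is root-relative: hip midpoint at the origin
  h <- wb_layout()$root_hips
  expect_equal(as.numeric((b1$train$kp3d[1, h[1], ] + b1$train$kp3d[1, h[2], ]) / 2),
               c(0, 0, 0), tolerance = 1e-9)
  # different seeds give different data
  b3 <- make_benchmark(synth_config(n_train = 60, n_val = 20, n_test = 20,
                                    seed = 8), poses_per_skeleton = 10)
  expect_false(identical(b1$train$kp2d, b3$train$kp2d))
})
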