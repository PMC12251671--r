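test_that("parameter count matches the analytic formula", {
  for (cfg in list(lift_config(), desk_profile(),
                   lift_config(hidden = 32, depth = 2, heads = 4,
                               cross_layers = 2, multi_hypothesis = TRUE))) {
    p <- init_lift_params(cfg, seed = 1)
    expect_identical(length(poselift:::tree_flatten(p)), count_lift_params(cfg))
  }
  expect_error(lift_config(hidden = 30, heads = 4))   # not divisible
})

test_that("compiled attention and layer-norm kernels match the R references", {
  set.seed(13)
  for (case in list(c(B = 3, Tq = 7, Tk = 5, h = 1, d = 6),
                    c(B = 2, Tq = 9, Tk = 9, h = 3, d = 12),
                    c(B = 4, Tq = 5, Tk = 11, h = 2, d = 8))) {
    Q <- matrix(rnorm(case["B"] * case["Tq"] * case["d"]), ncol = case["d"])
    K <- matrix(rnorm(case["B"] * case["Tk"] * case["d"]), ncol = case["d"])
    V <- matrix(rnorm(case["B"] * case["Tk"] * case["d"]), ncol = case["d"])
    a <- poselift:::.att_core_fwd(Q, K, V, case["B"], case["Tq"], case["Tk"],
                                  case["h"])
    b <- poselift:::att_core_fwd_ref(Q, K, V, case["B"], case["Tq"],
                                     case["Tk"], case["h"])
    expect_equal(a$O, b$O, tolerance = 1e-12)
    expect_equal(as.numeric(a$A), as.numeric(b$A), tolerance = 1e-12)
  }
  X <- matrix(rnorm(400), 50, 8)
  p <- list(g = runif(8, 0.5, 1.5), b = rnorm(8))
  expect_equal(poselift:::ln_fwd(X, p)$Y, poselift:::ln_fwd_ref(X, p)$Y,
               tolerance = 1e-12)
})

test_that("network forward pass is deterministic and batch-consistent", {
  cfg <- lift_config(hidden = 8, depth = 1, heads = 2, cross_layers = 1,
                     dropout = 0.2, ffn_mult = 2)
  params <- init_lift_params(cfg, seed = 2)
  lay <- wb_layout()
  set.seed(3)
  X1 <- matrix(rnorm(133 * 2, 0, 0.5), 133, 2)
  X <- rbind(X1, X1)                      # same pose twice
  Bf <- poselift:::batch_bone_features(X, 2, lay$edges)
  y1 <- poselift:::lift_forward_core(params, X, Bf, cfg, 2, train = FALSE)$Y
  y2 <- poselift:::lift_forward_core(params, X, Bf, cfg, 2, train = FALSE)$Y
  expect_identical(y1, y2)                          # deterministic at inference
  expect_equal(y1[1:133, ], y1[134:266, ])          # batch consistency
  expect_true(all(is.finite(y1)))                   # untrained smoke
  # dropout only acts in training mode
  set.seed(4)
  yt <- poselift:::lift_forward_core(params, X, Bf, cfg, 2, train = TRUE)$Y
  expect_false(isTRUE(all.equal(yt, y1)))
})

test_that("backpropagation matches finite differences through the full network", {
  cfg <- lift_config(hidden = 8, depth = 1, heads = 2, cross_layers = 1,
                     dropout = 0, ffn_mult = 2)
  params <- init_lift_params(cfg, seed = 5)
  lay <- wb_layout()
  set.seed(6)
  B <- 2
  X <- matrix(rnorm(B * 133 * 2, 0, 0.5), B * 133, 2)
  Bf <- poselift:::batch_bone_features(X, B, lay$edges)
  dY <- matrix(rnorm(B * 133 * 3, 0, 0.01), B * 133, 3)
  obj <- function(p) sum(poselift:::lift_forward_core(p, X, Bf, cfg, B)$Y * dY)
  fw <- poselift:::lift_forward_core(params, X, Bf, cfg, B)
  gr <- poselift:::lift_backward_core(dY, fw, params, cfg)
  leaves <- list(c("embed", "Wp"), c("embed", "pos_j"), c("head", "Wh"))
  for (lf in leaves) {
    M <- params[[lf[1]]][[lf[2]]]
    i <- sample(length(M), 1)
    eps <- 1e-6
    pp <- params; pp[[lf[1]]][[lf[2]]][i] <- M[i] + eps
    pm <- params; pm[[lf[1]]][[lf[2]]][i] <- M[i] - eps
    fd <- (obj(pp) - obj(pm)) / (2 * eps)
    expect_equal(gr[[lf[1]]][[lf[2]]][i], fd, tolerance = 1e-4,
                 label = paste(lf, collapse = "$"))
  }
  nested <- list(list("cross", 1, "att_jb", "Wk"), list("cross", 1, "ffn_j", "W1"),
                 list("enc", 1, "att", "Wv"), list("enc", 1, "ln1", "g"))
  for (lf in nested) {
    M <- params[[lf[[1]]]][[lf[[2]]]][[lf[[3]]]][[lf[[4]]]]
    i <- sample(length(M), 1)
    eps <- 1e-6
    pp <- params; pp[[lf[[1]]]][[lf[[2]]]][[lf[[3]]]][[lf[[4]]]][i] <- M[i] + eps
    pm <- params; pm[[lf[[1]]]][[lf[[2]]]][[lf[[3]]]][[lf[[4]]]][i] <- M[i] - eps
    fd <- (obj(pp) - obj(pm)) / (2 * eps)
    expect_equal(gr[[lf[[1]]]][[lf[[2]]]][[lf[[3]]]][[lf[[4]]]][i], fd,
                 tolerance = 1e-4, label = paste(unlist(lf), collapse = "$"))
  }
})

test_that("optimization descends on a fixed batch", {
  cfg <- lift_config(hidden = 8, depth = 1, heads = 2, cross_layers = 1,
                     dropout = 0, ffn_mult = 2)
  params <- init_lift_params(cfg, seed = 7)
  state <- poselift:::adamw_init(params)
  lay <- wb_layout()
  bench <- tiny_benchmark()
  tr <- poselift:::prepare_split(bench$train, lay, 256)
  rows <- 1:(8 * 133)
  X <- tr$Xj[rows, ]; G <- tr$T3[rows, ]
  w <- cog_weights(anthro_table("M"), lay)
  losses <- numeric(50)
  for (step in 1:50) {
    Bf <- poselift:::batch_bone_features(X, 8, lay$edges)
    fw <- poselift:::lift_forward_core(params, X, Bf, cfg, 8, train = FALSE)
    dY <- matrix(0, 8 * 133, 3)
    tot <- 0
    for (b in 1:8) {
      rr <- ((b - 1) * 133 + 1):(b * 133)
      r <- poselift:::.loss_total(fw$Y[rr, ], G[rr, ], rep(TRUE, 133), w,
                                  lay$edges, loss_weights())
      tot <- tot + r$total / 8
      dY[rr, ] <- r$grad / 8
    }
    losses[step] <- tot
    g <- poselift:::lift_backward_core(dY, fw, params, cfg)
    st <- poselift:::adamw_step(params, g, state, lr = 3e-3)
    params <- st$params; state <- st$state
  }
  expect_lt(losses[50], losses[1])
})

test_that("fit records history, improves validation error and round-trips", {
  fit <- tiny_fit()
  expect_s3_class(fit, "poselift")
  expect_equal(nrow(fit$history), 2)
  expect_true(all(is.finite(fit$history$train_total)))
  expect_lte(tail(fit$history$val_mpjpe, 1), fit$history$val_mpjpe[1])
  # checkpoint serialization reproduces the validation MPJPE exactly
  f <- tempfile(fileext = ".rds")
  save_poselift(fit, f)
  fit2 <- load_poselift(f)
  lay <- wb_layout()
  va <- poselift:::prepare_split(tiny_benchmark()$val, lay, 256)
  m1 <- poselift:::eval_mpjpe(fit$params, fit$model, va, lay$edges)
  m2 <- poselift:::eval_mpjpe(fit2$params, fit2$model, va, lay$edges)
  expect_equal(m1, m2, tolerance = 1e-6)
  expect_equal(m1, fit$val_mpjpe, tolerance = 1e-6)
  # refits with the same seed are identical
  fit3 <- poselift(tiny_benchmark(), training = desk_training(seed = 4, epochs = 2))
  expect_equal(fit3$val_mpjpe, fit$val_mpjpe)
  # methods
  expect_output(print(fit), "MPJPE")
  expect_equal(dim(residuals(fit)), c(32, 133))
  expect_length(coef(fit), fit$n_params)
})

test_that("predict lifts single poses and splits", {
  fit <- tiny_fit()
  bench <- tiny_benchmark()
  arr <- predict(fit, bench$test)
  expect_equal(dim(arr), c(32, 133, 3))
  p2 <- pose2d(bench$test$kp2d[1, , ], confidence = bench$test$conf[1, ],
               valid = bench$test$valid[1, ])
  p3 <- predict(fit, p2)
  expect_s3_class(p3, "pose3d")
  expect_equal(p3$frame, "root_relative")
  expect_equal(arr[1, , ], unname(p3$coords), tolerance = 1e-9)
  expect_equal(p3$coords, lift_forward(fit, p2)$coords)
  expect_error(predict(fit, list(a = 1)), "pose2d")
})

test_that("multi-hypothesis training and reprojection selection work", {
  cfg <- lift_config(hidden = 8, depth = 1, heads = 2, cross_layers = 1,
                     dropout = 0, ffn_mult = 2, multi_hypothesis = TRUE)
  fit <- poselift(tiny_benchmark(), model = cfg,
                  training = desk_training(seed = 9, epochs = 1))
  expect_true(!is.null(fit$params$head2))
  # selection: ground truth beats a corrupted candidate under reprojection
  cam <- camera(1200, 1200)
  set.seed(10)
  gt_cam <- random_pose3d(14, scale = 200, frame = "camera")
  gt_cam$coords[, 3] <- gt_cam$coords[, 3] + 4000
  obs <- pose2d(project(gt_cam$coords, cam))
  bad <- gt_cam
  bad$coords <- bad$coords + matrix(rnorm(399, 0, 80), 133, 3)
  sel <- select_hypothesis(list(bad, gt_cam), obs, cam)
  expect_equal(sel$coords, gt_cam$coords)
  # single candidate returned unchanged; ties break to the first
  expect_equal(select_hypothesis(list(bad), obs, cam)$coords, bad$coords)
  tie <- select_hypothesis(list(gt_cam, gt_cam), obs, cam)
  expect_equal(attr(tie, "reprojection_error")[1],
               attr(tie, "reprojection_error")[2])
  expect_error(select_hypothesis(list(), obs, cam), "candidate")
  # root-relative candidates need a root position
  rr <- root_center(gt_cam)
  expect_error(select_hypothesis(list(rr), obs, cam), "root_position")
  sel2 <- select_hypothesis(list(rr), obs, cam,
                            root_position = pelvis_root(gt_cam))
  expect_s3_class(sel2, "pose3d")
})

test_that("learning-rate schedule combines cosine annealing and step drops", {
  t1 <- train_config(epochs = 10, lr = 1e-2, lr_drop_epochs = integer(0),
                     cosine = TRUE)
  expect_equal(poselift:::lr_at_epoch(t1, 1), 1e-2)
  expect_lt(poselift:::lr_at_epoch(t1, 10), poselift:::lr_at_epoch(t1, 5))
  t2 <- train_config(epochs = 210, lr = 1e-3)
  expect_equal(poselift:::lr_at_epoch(t2, 170) /
                 (poselift:::lr_at_epoch(t2, 169) *
                    (0.5 * (1 + cos(pi * 169 / 210))) /
                    (0.5 * (1 + cos(pi * 168 / 210)))), 0.1, tolerance = 1e-9)
  t3 <- train_config(epochs = 10, lr = 1e-2, lr_drop_epochs = integer(0),
                     cosine = FALSE)
  expect_equal(poselift:::lr_at_epoch(t3, 7), 1e-2)
  expect_error(train_config(epochs = 100, lr_drop_epochs = c(170, 200)))
})
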