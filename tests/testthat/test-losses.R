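mask_only <- function(pose, idx) {
  pose$valid <- seq_len(133) %in% idx
  pose
}

test_that("position loss is the mean per-joint Euclidean distance", {
  gt <- random_pose3d(1)
  expect_equal(loss_position(gt, gt), 0)
  lay <- wb_layout()
  pr <- gt
  pr$coords[1, ] <- pr$coords[1, ] + c(3, 4, 0)
  expect_equal(loss_position(mask_only(pr, 1), mask_only(gt, 1)), 5)
  pr2 <- gt
  pr2$coords[2, 1] <- pr2$coords[2, 1] + 10
  expect_equal(loss_position(mask_only(pr2, 1:2), mask_only(gt, 1:2)), 5)
  expect_error(loss_position(mask_only(pr, integer(0)), gt))
  # squared variant
  expect_equal(loss_position(mask_only(pr, 1), mask_only(gt, 1), squared = TRUE), 25)
})

test_that("CoG-distance loss vanishes under rigid motions and matches a
           from-scratch recomputation", {
  tab <- anthro_table("M")
  lay <- wb_layout()
  gt <- random_pose3d(2)
  expect_equal(loss_cog(gt, gt, tab), 0)
  # rigid translation of the prediction alone leaves distances-to-own-CoG
  # unchanged -> loss 0
  tr <- gt
  tr$coords <- tr$coords + rep(c(50, -30, 20), each = 133)
  expect_equal(loss_cog(tr, gt, tab), 0, tolerance = 1e-18)
  # joint rigid motion of both poses leaves the loss unchanged
  pr <- random_pose3d(3)
  base <- loss_cog(pr, gt, tab)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  mv <- function(p) { p$coords <- p$coords %*% t(R) + rep(c(1, 2, 3), each = 133); p }
  expect_equal(loss_cog(mv(pr), mv(gt), tab), base, tolerance = 1e-9)
  # from-scratch oracle
  w <- cog_weights(tab, lay)
  g <- sqrt(rowSums(sweep(pr$coords, 2, colSums(pr$coords * w))^2))
  gh <- sqrt(rowSums(sweep(gt$coords, 2, colSums(gt$coords * w))^2))
  expect_equal(loss_cog(pr, gt, tab), mean((g - gh)^2), tolerance = 1e-9)
  # missing endpoint -> error
  bad <- pr; bad$valid[kp_index("left_knee")] <- FALSE
  expect_error(loss_cog(bad, gt, tab), "CoG")
})

test_that("bone loss combines direction and length consistency", {
  lay <- wb_layout()
  gt <- random_pose3d(4)
  expect_equal(loss_bone(gt, gt), 0)
  # single-bone tree via masks: left_hip -> left_knee
  idx <- kp_index(c("left_hip", "left_knee"))
  gt1 <- random_pose3d(5)
  gt1$coords[idx[1], ] <- 0
  gt1$coords[idx[2], ] <- c(1, 0, 0)
  # 90-degree rotation at equal length, lambda 0 -> cosine term 1
  pr1 <- gt1
  pr1$coords[idx[2], ] <- c(0, 1, 0)
  expect_equal(loss_bone(mask_only(pr1, idx), mask_only(gt1, idx), lambda = 0), 1)
  # doubled bone, same direction, gt length 1, lambda 1 -> 0 + 1
  pr2 <- gt1
  pr2$coords[idx[2], ] <- c(2, 0, 0)
  expect_equal(loss_bone(mask_only(pr2, idx), mask_only(gt1, idx), lambda = 1), 1)
  # invariant under common translation
  pr <- random_pose3d(6)
  base <- loss_bone(pr, gt)
  sh <- function(p) { p$coords <- p$coords + rep(c(9, -9, 4), each = 133); p }
  expect_equal(loss_bone(sh(pr), sh(gt)), base)
  expect_error(loss_bone(mask_only(pr, 1), mask_only(gt, 1)), "bone")
})

test_that("total loss is the weighted sum and reduces to the position loss", {
  tab <- anthro_table("M")
  lay <- wb_layout()
  gt <- random_pose3d(7)
  pr <- random_pose3d(8)
  w111 <- loss_weights(1, 1, 1)
  tot <- loss_total(pr, gt, tab, weights = w111)
  parts <- attr(tot, "breakdown")
  expect_equal(as.numeric(tot), sum(parts), tolerance = 1e-12)
  expect_equal(parts[["position"]], loss_position(pr, gt))
  expect_equal(parts[["cog"]], loss_cog(pr, gt, tab))
  expect_equal(parts[["bone"]], loss_bone(pr, gt))
  # (1, 0, 0) reduction
  expect_equal(as.numeric(loss_total(pr, gt, tab, weights = loss_weights(1, 0, 0))),
               loss_position(pr, gt))
  expect_equal(as.numeric(loss_total(gt, gt, tab, weights = w111)), 0)
  # arbitrary weights
  w <- loss_weights(0.5, 2, 0.25)
  expect_equal(as.numeric(loss_total(pr, gt, tab, weights = w)),
               0.5 * parts[["position"]] + 2 * parts[["cog"]] +
                 0.25 * parts[["bone"]], tolerance = 1e-12)
})

test_that("analytic loss gradients match finite differences", {
  lay <- wb_layout()
  tab <- anthro_table("M")
  w <- cog_weights(tab, lay)
  set.seed(9)
  P <- matrix(rnorm(133 * 3, 0, 0.4), 133, 3)
  G <- matrix(rnorm(133 * 3, 0, 0.4), 133, 3)
  mask <- rep(TRUE, 133)
  funs <- list(
    position = function(X) poselift:::.loss_position(X, G, mask),
    cog = function(X) poselift:::.loss_cog(X, G, w, mask),
    bone = function(X) poselift:::.loss_bone(X, G, lay$edges, mask, lambda = 1),
    total = function(X) {
      r <- poselift:::.loss_total(X, G, mask, w, lay$edges, loss_weights(1, 1, 1))
      list(value = r$total, grad = r$grad)
    })
  for (nm in names(funs)) {
    f <- funs[[nm]]
    gr <- f(P)$grad
    for (k in 1:20) {
      i <- sample(133, 1); j <- sample(3, 1)
      eps <- 1e-6
      Pp <- P; Pp[i, j] <- Pp[i, j] + eps
      Pm <- P; Pm[i, j] <- Pm[i, j] - eps
      fd <- (f(Pp)$value - f(Pm)$value) / (2 * eps)
      expect_equal(gr[i, j], fd, tolerance = 1e-4,
                   label = sprintf("%s grad [%d,%d]", nm, i, j))
    }
  }
})

test_that("mpjpe averages distances over part groups", {
  lay <- wb_layout()
  gt <- random_pose3d(10)
  expect_equal(mpjpe(gt, gt), 0)
  pr <- gt
  pr$coords[, 3] <- pr$coords[, 3] + 44.49
  for (g in c("whole_body", "body", "face", "hands"))
    expect_equal(mpjpe(pr, gt, g), 44.49)
  # whole-body equals the count-weighted combination of the parts
  pr2 <- random_pose3d(11)
  parts <- vapply(c("body", "face", "hands"), function(g) mpjpe(pr2, gt, g),
                  numeric(1))
  ns <- vapply(c("body", "face", "hands"),
               function(g) length(lay$part_groups[[g]]), numeric(1))
  expect_equal(mpjpe(pr2, gt, "whole_body"), sum(parts * ns) / sum(ns))
  # random masks match a brute-force loop
  set.seed(12)
  m <- runif(133) > 0.3
  prm <- pr2; prm$valid <- m
  d <- sqrt(rowSums((pr2$coords - gt$coords)^2))
  expect_equal(mpjpe(prm, gt, "whole_body"), mean(d[m]))
  # contract errors
  expect_error(mpjpe(mask_only(pr2, 1), gt, "face"), "empty")
  cf <- gt; cf$frame <- "camera"
  expect_error(mpjpe(pr2, cf), "frames")
})

test_that("percent_change formalizes the printed improvement statements", {
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(112.3, 44.49, digits = 1), 60.4)
  expect_equal(percent_change(67.50, 44.49), 34.0889, tolerance = 1e-4)
  expect_error(percent_change(0, 10))
  expect_error(percent_change(-5, 10))
})

test_that("eval_report reports the four groups in protocol order", {
  gt <- array(rnorm(2 * 133 * 3, 0, 100), c(2, 133, 3))
  pr <- gt
  pr[, , 2] <- pr[, , 2] + 10
  rep <- eval_report(pr, gt)
  expect_equal(rep$group, c("whole_body", "body", "face", "hands"))
  expect_equal(rep$mpjpe_mm, rep(10, 4))
  expect_equal(rep$n_joints, c(133L, 23L, 68L, 42L))
  expect_equal(eval_report(gt, gt)$mpjpe_mm, rep(0, 4))
})
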