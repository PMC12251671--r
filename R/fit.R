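# Fitting interface: poselift() trains the dual-branch cross-attention
# lifting network on a synthetic (or externally assembled) paired 2D/3D
# benchmark and returns a classed model object with the usual methods.

prepare_split <- function(split, layout, scale2d) {
  n <- dim(split$kp2d)[1]
  h <- layout$root_hips
  ru <- (split$kp2d[, h[1], 1] + split$kp2d[, h[2], 1]) / 2
  rv <- (split$kp2d[, h[1], 2] + split$kp2d[, h[2], 2]) / 2
  U <- (split$kp2d[, , 1] - ru) / scale2d
  V <- (split$kp2d[, , 2] - rv) / scale2d
  U[!split$valid] <- 0
  V[!split$valid] <- 0
  Xj <- cbind(as.vector(t(U)), as.vector(t(V)))
  T3 <- cbind(as.vector(t(split$kp3d[, , 1])),
              as.vector(t(split$kp3d[, , 2])),
              as.vector(t(split$kp3d[, , 3]))) / 1000
  list(n = n, Xj = Xj, T3 = T3, valid = as.vector(t(split$valid)))
}

# direction + log-length features for all bones of a sample-major batch
batch_bone_features <- function(Xj, B, edges, eps = 1e-8) {
  off <- rep((seq_len(B) - 1L) * 133L, each = nrow(edges))
  pr <- rep(edges[, "parent"], B) + off
  ch <- rep(edges[, "child"], B) + off
  D <- Xj[ch, , drop = FALSE] - Xj[pr, , drop = FALSE]
  len <- sqrt(rowSums(D^2))
  dir <- D / ifelse(len > 0, len, 1)
  dir[len == 0, ] <- 0
  cbind(dir, log(len + eps))
}

lift_predict_core <- function(params, cfg, Xj, B, edges) {
  Bf <- batch_bone_features(Xj, B, edges)
  lift_forward_core(params, Xj, Bf, cfg, B, train = FALSE)
}

#' Fit the physics-constrained lifting model
#'
#' Trains the dual-branch cross-attention network to lift root-centred 2D
#' whole-body keypoints to root-relative 3D, under the combined objective:
#' mean per-joint position loss, centre-of-gravity distance loss (computed
#' through the anthropometric mass distribution) and bone direction/length
#' consistency loss. Optimization is AdamW with a cosine-annealed learning
#' rate and optional step drops; train-time augmentation applies random
#' in-plane rotation, 2D scaling and left/right flips consistently to the
#' 2D inputs and 3D targets.
#'
#' Losses are computed in normalized units (2D pixels divided by
#' \code{scale2d}, 3D millimetres divided by 1000) so the three terms are
#' commensurate at the default weights (1, 1, 1).
#'
#' @param data a \code{pose_benchmark} from \code{\link{make_benchmark}} (or
#'   a list with \code{train} and \code{val} splits in the same layout).
#' @param model a \code{\link{lift_config}}.
#' @param training a \code{\link{train_config}}.
#' @param gender anthropometric table used by the CoG loss.
#' @param scale2d 2D normalization half-width in pixels (recorded in the
#'   model object).
#' @param verbose print per-epoch progress.
#' @return object of class \code{poselift}: the trained parameters, configs,
#'   normalization constants, per-epoch \code{history} (train loss terms,
#'   learning rate, validation MPJPE in mm), and validation residuals.
#' @seealso \code{\link{predict.poselift}}, \code{\link{save_poselift}}
#' @export
poselift <- function(data, model = desk_profile(), training = desk_training(),
                     gender = "M", scale2d = 256, verbose = FALSE) {
  layout <- wb_layout()
  table <- anthro_table(gender, layout = layout)
  cogw <- cog_weights(table, layout)
  edges <- layout$edges
  tr <- prepare_split(data$train, layout, scale2d)
  va <- prepare_split(data$val, layout, scale2d)
  params <- init_lift_params(model, seed = training$seed)
  state <- adamw_init(params)
  W <- training$weights
  hist <- vector("list", training$epochs)
  mirror <- layout$mirror
  rot_max <- 15 * pi / 180
  val_m <- NA_real_
  with_rng(training$seed + 1L, {
    for (e in seq_len(training$epochs)) {
      lr <- lr_at_epoch(training, e)
      ord <- sample.int(tr$n)
      nb <- ceiling(tr$n / training$batch_size)
      tot <- c(total = 0, position = 0, cog = 0, bone = 0)
      for (bi in seq_len(nb)) {
        idx <- ord[(((bi - 1) * training$batch_size + 1):
                      min(bi * training$batch_size, tr$n))]
        B <- length(idx)
        rows <- rep((idx - 1L) * 133L, each = 133L) + rep(1:133, B)
        Xb <- tr$Xj[rows, , drop = FALSE]
        Tb <- tr$T3[rows, , drop = FALSE]
        if (training$augment) {
          fs <- stats::runif(B) < 0.5
          if (any(fs)) {
            kp <- rep(1:133, B)
            kp[rep(fs, each = 133)] <- rep(mirror, sum(fs))
            perm <- rep((seq_len(B) - 1L) * 133L, each = 133L) + kp
            Xb <- Xb[perm, , drop = FALSE]
            Tb <- Tb[perm, , drop = FALSE]
            neg <- rep(fs, each = 133)
            Xb[neg, 1] <- -Xb[neg, 1]
            Tb[neg, 1] <- -Tb[neg, 1]
          }
          th <- rep(stats::runif(B, -rot_max, rot_max), each = 133)
          co <- cos(th); si <- sin(th)
          Xb <- cbind(co * Xb[, 1] - si * Xb[, 2],
                      si * Xb[, 1] + co * Xb[, 2])
          Tb <- cbind(co * Tb[, 1] - si * Tb[, 2],
                      si * Tb[, 1] + co * Tb[, 2], Tb[, 3])
          sc <- rep(stats::runif(B, 0.8, 1.2), each = 133)
          Xb <- Xb * sc
        }
        Bf <- batch_bone_features(Xb, B, edges)
        fw <- lift_forward_core(params, Xb, Bf, model, B, train = TRUE)
        dY <- matrix(0, B * 133L, 3)
        dY2 <- if (model$multi_hypothesis) matrix(0, B * 133L, 3) else NULL
        bl <- c(total = 0, position = 0, cog = 0, bone = 0)
        for (b in seq_len(B)) {
          rr <- ((b - 1) * 133 + 1):(b * 133)
          r <- .loss_total(fw$Y[rr, , drop = FALSE], Tb[rr, , drop = FALSE],
                           rep(TRUE, 133), cogw, edges, W)
          bl <- bl + c(r$total, r$position, r$cog, r$bone)
          dY[rr, ] <- r$grad / B
          if (model$multi_hypothesis) {
            r2 <- .loss_total(fw$Y2[rr, , drop = FALSE], Tb[rr, , drop = FALSE],
                              rep(TRUE, 133), cogw, edges, W)
            bl["total"] <- bl["total"] + r2$total
            dY2[rr, ] <- r2$grad / B
          }
        }
        bl <- bl / B
        if (!all(is.finite(bl)))
          stop(sprintf("non-finite loss at epoch %d batch %d (seed %d)",
                       e, bi, training$seed))
        grads <- lift_backward_core(dY, fw, params, model, dY2 = dY2)
        st <- adamw_step(params, grads, state, lr, training$weight_decay)
        params <- st$params
        state <- st$state
        tot <- tot + bl
      }
      tot <- tot / nb
      val_m <- eval_mpjpe(params, model, va, edges)
      hist[[e]] <- data.frame(epoch = e, lr = lr, train_total = tot["total"],
                              train_position = tot["position"],
                              train_cog = tot["cog"], train_bone = tot["bone"],
                              val_mpjpe = val_m, row.names = NULL)
      if (verbose)
        message(sprintf("epoch %d/%d lr=%.2e loss=%.4f val MPJPE=%.1f mm",
                        e, training$epochs, lr, tot["total"], val_m))
    }
  })
  history <- do.call(rbind, hist)
  pred_val <- predict_core_split(params, model, va, edges)
  resid <- val_residuals(pred_val, va)
  structure(list(params = params, model = model, training = training,
                 gender = gender, scale2d = scale2d, history = history,
                 val_mpjpe = val_m, val_residuals = resid,
                 layout_hash = layout_hash(),
                 n_params = length(tree_flatten(params))),
            class = "poselift")
}

predict_core_split <- function(params, cfg, sp, edges, chunk = 128L) {
  out <- matrix(0, sp$n * 133L, 3)
  i <- 1L
  while (i <= sp$n) {
    j <- min(i + chunk - 1L, sp$n)
    rows <- ((i - 1L) * 133L + 1L):(j * 133L)
    out[rows, ] <- lift_predict_core(params, cfg,
                                     sp$Xj[rows, , drop = FALSE],
                                     j - i + 1L, edges)$Y
    i <- j + 1L
  }
  out
}

val_residuals <- function(pred, sp) {
  d <- sqrt(rowSums((pred - sp$T3)^2)) * 1000
  matrix(d, sp$n, 133, byrow = TRUE)
}

eval_mpjpe <- function(params, cfg, sp, edges) {
  mean(val_residuals(predict_core_split(params, cfg, sp, edges), sp))
}

#' Predict 3D poses from 2D inputs
#'
#' @param object a fitted \code{poselift} model.
#' @param newdata either a single \code{pose2d} (camera-frame pixels; hips
#'   must be valid so it can be root-centred) or a benchmark split (list with
#'   \code{kp2d}, \code{valid}).
#' @param ... unused.
#' @return a root-relative \code{pose3d} (mm) for a single pose, or an
#'   n x 133 x 3 array for a split.
#' @export
predict.poselift <- function(object, newdata, ...) {
  layout <- wb_layout()
  edges <- layout$edges
  if (inherits(newdata, "pose2d")) {
    r <- pelvis_root(newdata, layout)
    X <- sweep(newdata$coords, 2, r) / object$scale2d
    X[!newdata$valid, ] <- 0
    Y <- lift_predict_core(object$params, object$model, X, 1L, edges)$Y
    return(pose3d(Y * 1000, frame = "root_relative"))
  }
  if (!is.list(newdata) || is.null(newdata$kp2d))
    stop("newdata must be a pose2d or a benchmark split")
  sp <- prepare_split(newdata, layout, object$scale2d)
  Y <- predict_core_split(object$params, object$model, sp, edges)
  arr <- array(0, c(sp$n, 133, 3))
  for (k in 1:3) arr[, , k] <- matrix(Y[, k] * 1000, sp$n, 133, byrow = TRUE)
  arr
}

#' Single-pose forward pass
#'
#' Thin wrapper over \code{\link{predict.poselift}} for one 2D pose;
#' deterministic at inference (dropout disabled).
#'
#' @param object a fitted \code{poselift} model.
#' @param pose a \code{pose2d}.
#' @return a root-relative \code{pose3d}.
#' @export
lift_forward <- function(object, pose) predict(object, pose)

#' @export
print.poselift <- function(x, ...) {
  m <- x$model
  cat("Physics-constrained 2D->3D whole-body lifting model\n")
  cat(sprintf("  architecture: hidden %d, %d heads, %d cross + %d encoder layers (%s parameters)\n",
              m$hidden, m$heads, m$cross_layers, m$depth,
              format(x$n_params, big.mark = ",")))
  cat(sprintf("  training: %d epochs, batch %d, lr %.1e, loss weights (%g, %g, %g)\n",
              x$training$epochs, x$training$batch_size, x$training$lr,
              x$training$weights$w_pos, x$training$weights$w_cog,
              x$training$weights$w_bone))
  cat(sprintf("  validation MPJPE: %.2f mm\n", x$val_mpjpe))
  invisible(x)
}

#' @export
summary.poselift <- function(object, ...) {
  print(object)
  lay <- wb_layout()
  cat("\nvalidation MPJPE by part group (mm):\n")
  for (g in names(lay$part_groups)) {
    idx <- lay$part_groups[[g]]
    cat(sprintf("  %-10s %8.2f\n", g, mean(object$val_residuals[, idx])))
  }
  invisible(object)
}

#' @export
plot.poselift <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  h <- x$history
  graphics::plot(h$epoch, h$train_total, type = "b", pch = 16,
                 xlab = "epoch", ylab = "training loss (normalized units)",
                 main = "training loss")
  graphics::plot(h$epoch, h$val_mpjpe, type = "b", pch = 16,
                 xlab = "epoch", ylab = "validation MPJPE (mm)",
                 main = "validation error")
  invisible(x)
}

#' @export
residuals.poselift <- function(object, ...) object$val_residuals

#' @export
coef.poselift <- function(object, ...) tree_flatten(object$params)

#' Save / load a fitted model
#'
#' The checkpoint stores the parameters, both configurations, the
#' normalization constant and the layout hash; loading refuses a checkpoint
#' built against a different keypoint layout.
#'
#' @param object a \code{poselift} model.
#' @param path file path.
#' @return \code{save_poselift} returns \code{path} invisibly;
#'   \code{load_poselift} returns the model.
#' @export
save_poselift <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_poselift
#' @export
load_poselift <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "poselift")) stop("not a poselift checkpoint")
  if (!identical(obj$layout_hash, layout_hash()))
    stop("checkpoint layout hash does not match the installed layout")
  obj
}

#' Select the pose hypothesis most consistent with the 2D input
#'
#' Given several candidate 3D poses, returns the one whose pinhole
#' reprojection is closest (mean Euclidean pixel error over valid keypoints)
#' to the observed 2D pose. Ties break to the lowest-index candidate.
#'
#' @param candidates list of \code{pose3d} objects. Camera-frame poses are
#'   projected directly; root-relative poses require \code{root_position}.
#' @param pose the observed \code{pose2d} (pixels, principal-point-relative).
#' @param cam a \code{camera}.
#' @param root_position camera-frame position (mm) of the pelvis root, used
#'   to place root-relative candidates.
#' @return the selected \code{pose3d}, with attribute
#'   \code{"reprojection_error"} (the per-candidate mean pixel errors).
#' @export
select_hypothesis <- function(candidates, pose, cam, root_position = NULL) {
  if (length(candidates) == 0) stop("no candidate poses")
  errs <- vapply(candidates, function(p) {
    coords <- p$coords
    if (identical(p$frame, "root_relative")) {
      if (is.null(root_position))
        stop("root_position required for root-relative candidates")
      coords <- sweep(coords, 2, root_position, `+`)
    }
    m <- p$valid & pose$valid
    uv <- project(coords[m, , drop = FALSE], cam)
    mean(sqrt(rowSums((uv - pose$coords[m, , drop = FALSE])^2)))
  }, numeric(1))
  out <- candidates[[which.min(errs)]]
  attr(out, "reprojection_error") <- errs
  out
}
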