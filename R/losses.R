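# Training losses and evaluation metrics. Each loss has a matrix-level core
# returning value + analytic gradient w.r.t. the predicted coordinates
# (used by the training loop and by the finite-difference gradient tests),
# and a pose3d-level exported wrapper.

.loss_position <- function(P, G, mask, squared = FALSE) {
  n <- sum(mask)
  if (n == 0) stop("loss_position: no valid joints")
  R <- P - G
  d2 <- rowSums(R^2)
  grad <- matrix(0, nrow(P), 3)
  if (squared) {
    val <- sum(d2[mask]) / n
    grad[mask, ] <- 2 * R[mask, , drop = FALSE] / n
  } else {
    d <- sqrt(d2)
    val <- sum(d[mask]) / n
    nz <- mask & d > 0
    grad[nz, ] <- R[nz, , drop = FALSE] / (n * d[nz])
  }
  list(value = val, grad = grad)
}

.loss_cog <- function(P, G, w, mask, squared = TRUE) {
  n <- sum(mask)
  if (n == 0) stop("loss_cog: no valid joints")
  Cp <- colSums(P * w)
  Cg <- colSums(G * w)
  Up <- sweep(P, 2, Cp)
  g <- sqrt(rowSums(Up^2))
  gh <- sqrt(rowSums(sweep(G, 2, Cg)^2))
  diff <- ifelse(mask, g - gh, 0)
  U <- Up / ifelse(g > 0, g, 1)
  U[g == 0 | !mask, ] <- 0
  if (squared) {
    val <- sum(diff[mask]^2) / n
    S <- colSums(diff * U)
    grad <- (2 / n) * (diff * U - outer(w, S))
  } else {
    val <- sum(abs(diff[mask])) / n
    sg <- sign(diff)
    S <- colSums(sg * U)
    grad <- (1 / n) * (sg * U - outer(w, S))
  }
  list(value = val, grad = grad)
}

.loss_bone <- function(P, G, edges, mask, lambda = 1, squared_len = FALSE) {
  Bp <- P[edges[, "child"], , drop = FALSE] - P[edges[, "parent"], , drop = FALSE]
  Bg <- G[edges[, "child"], , drop = FALSE] - G[edges[, "parent"], , drop = FALSE]
  emask <- mask[edges[, "parent"]] & mask[edges[, "child"]]
  nb <- sqrt(rowSums(Bp^2))
  nbh <- sqrt(rowSums(Bg^2))
  emask <- emask & nbh > 0
  m <- sum(emask)
  if (m == 0) stop("loss_bone: no valid bones")
  dot <- rowSums(Bp * Bg)
  cosv <- ifelse(nb > 0, dot / (pmax(nb, .Machine$double.xmin) * nbh), 0)
  D <- Bp - Bg
  dlen <- sqrt(rowSums(D^2))
  lenterm <- if (squared_len) dlen^2 else dlen
  val <- sum((1 - cosv[emask]) + lambda * lenterm[emask]) / m
  # gradient w.r.t. each predicted bone vector
  gB <- matrix(0, nrow(edges), 3)
  nzc <- emask & nb > 0
  gB[nzc, ] <- -(Bg[nzc, , drop = FALSE] / (nb[nzc] * nbh[nzc])) +
    cosv[nzc] * Bp[nzc, , drop = FALSE] / nb[nzc]^2
  if (squared_len) {
    gB[emask, ] <- gB[emask, , drop = FALSE] +
      2 * lambda * D[emask, , drop = FALSE]
  } else {
    nzl <- emask & dlen > 0
    gB[nzl, ] <- gB[nzl, , drop = FALSE] +
      lambda * D[nzl, , drop = FALSE] / dlen[nzl]
  }
  gB <- gB / m
  grad <- matrix(0, nrow(P), 3)
  for (k in 1:3) {
    grad[, k] <- grad[, k] +
      rowsum_safe(gB[, k], edges[, "child"], nrow(P)) -
      rowsum_safe(gB[, k], edges[, "parent"], nrow(P))
  }
  list(value = val, grad = grad)
}

rowsum_safe <- function(x, group, n) {
  out <- numeric(n)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s
  out
}

.loss_total <- function(P, G, mask, w_cog, edges, weights) {
  lp <- .loss_position(P, G, mask, squared = weights$squared_position)
  out <- list(position = lp$value, cog = 0, bone = 0)
  grad <- weights$w_pos * lp$grad
  if (weights$w_cog > 0) {
    lc <- .loss_cog(P, G, w_cog, mask, squared = weights$squared_cog)
    out$cog <- lc$value
    grad <- grad + weights$w_cog * lc$grad
  }
  if (weights$w_bone > 0) {
    lb <- .loss_bone(P, G, edges, mask, lambda = weights$lambda_bone,
                     squared_len = weights$squared_bone_length)
    out$bone <- lb$value
    grad <- grad + weights$w_bone * lb$grad
  }
  out$total <- weights$w_pos * out$position + weights$w_cog * out$cog +
    weights$w_bone * out$bone
  out$grad <- grad
  out
}

#' Loss term weights
#'
#' Weights of the combined training objective: total = w_pos * position +
#' w_cog * CoG-distance + w_bone * bone. Defaults (1, 1, 1) with the bone
#' length penalty scaled by \code{lambda_bone} = 1 in normalized units.
#' The \code{squared_*} switches select the squared variants of each term
#' (the defaults follow the printed forms: unsquared joint distance, squared
#' CoG-distance difference, unsquared bone length difference).
#'
#' @param w_pos,w_cog,w_bone nonnegative term weights.
#' @param lambda_bone weight of the bone-length term inside the bone loss.
#' @param squared_position,squared_cog,squared_bone_length logical variants.
#' @return object of class \code{loss_weights}.
#' @export
loss_weights <- function(w_pos = 1, w_cog = 1, w_bone = 1, lambda_bone = 1,
                         squared_position = FALSE, squared_cog = TRUE,
                         squared_bone_length = FALSE) {
  stopifnot(w_pos >= 0, w_cog >= 0, w_bone >= 0, lambda_bone >= 0)
  structure(list(w_pos = w_pos, w_cog = w_cog, w_bone = w_bone,
                 lambda_bone = lambda_bone,
                 squared_position = squared_position,
                 squared_cog = squared_cog,
                 squared_bone_length = squared_bone_length),
            class = "loss_weights")
}

joint_mask <- function(pred, gt) {
  m <- pred$valid & gt$valid
  if (!any(m)) stop("no jointly valid keypoints")
  m
}

#' Mean per-joint position loss
#'
#' Mean Euclidean distance between predicted and ground-truth keypoints over
#' jointly valid joints — the standard position loss, identical in form to
#' the MPJPE metric.
#'
#' @param pred,gt \code{pose3d} objects (same frame).
#' @param squared use squared distances instead.
#' @return scalar (mm).
#' @export
loss_position <- function(pred, gt, squared = FALSE) {
  .loss_position(pred$coords, gt$coords, joint_mask(pred, gt), squared)$value
}

#' Centre-of-gravity distance loss
#'
#' For each keypoint, the distance g_i from the predicted keypoint to the
#' predicted whole-body CoG is compared with the same distance in the ground
#' truth; the loss is the mean squared difference. Because both distances
#' are measured to the pose's own CoG, the loss is invariant under a common
#' rigid motion of both poses.
#'
#' @param pred,gt \code{pose3d} objects.
#' @param table an \code{anthro_table} defining the mass distribution.
#' @param layout a \code{wb_layout}.
#' @param squared use squared differences (default TRUE, printed form).
#' @return scalar.
#' @export
loss_cog <- function(pred, gt, table = anthro_table("M"),
                     layout = wb_layout(), squared = TRUE) {
  need <- unique(unlist(lapply(table$segments, function(s) c(s$proximal, s$distal))))
  if (!all(pred$valid[need] & gt$valid[need]))
    stop("loss_cog: segment endpoint keypoint(s) invalid; CoG not computable")
  w <- cog_weights(table, layout)
  .loss_cog(pred$coords, gt$coords, w, joint_mask(pred, gt), squared)$value
}

#' Bone consistency loss
#'
#' Mean over valid bones of (1 - cosine similarity between predicted and
#' ground-truth bone vectors) plus lambda times the Euclidean norm of their
#' difference: direction consistency plus limb-length consistency.
#' Zero-length ground-truth bones are masked. Invariant under a common
#' translation of both poses.
#'
#' @param pred,gt \code{pose3d} objects.
#' @param layout a \code{wb_layout}.
#' @param lambda weight of the length term.
#' @param squared_len use the squared length difference.
#' @return scalar.
#' @export
loss_bone <- function(pred, gt, layout = wb_layout(), lambda = 1,
                      squared_len = FALSE) {
  .loss_bone(pred$coords, gt$coords, layout$edges, joint_mask(pred, gt),
             lambda, squared_len)$value
}

#' Combined training loss
#'
#' Weighted sum of the position, CoG-distance and bone losses. With weights
#' (1, 0, 0) it reduces exactly to \code{\link{loss_position}}.
#'
#' @param pred,gt \code{pose3d} objects.
#' @param table an \code{anthro_table}.
#' @param layout a \code{wb_layout}.
#' @param weights a \code{\link{loss_weights}}.
#' @return scalar total loss with attribute \code{"breakdown"} (named vector
#'   of the three unweighted terms).
#' @export
loss_total <- function(pred, gt, table = anthro_table("M"),
                       layout = wb_layout(), weights = loss_weights()) {
  mask <- joint_mask(pred, gt)
  w <- cog_weights(table, layout)
  r <- .loss_total(pred$coords, gt$coords, mask, w, layout$edges, weights)
  structure(r$total, breakdown = c(position = r$position, cog = r$cog,
                                   bone = r$bone))
}

#' Mean per-joint position error (MPJPE)
#'
#' Average Euclidean distance between predicted and ground-truth joints over
#' the requested part group, in millimetres. Both poses must be in the same
#' (root-relative) frame.
#'
#' @param pred,gt \code{pose3d} objects.
#' @param group index set, or the name of a part group in the layout
#'   (\code{"whole_body"}, \code{"body"}, \code{"face"}, \code{"hands"}).
#' @param layout a \code{wb_layout}.
#' @return scalar (mm).
#' @export
mpjpe <- function(pred, gt, group = "whole_body", layout = wb_layout()) {
  if (!identical(pred$frame, gt$frame))
    stop("mpjpe: poses are in different frames")
  if (is.character(group)) group <- layout$part_groups[[match.arg(
    group, names(layout$part_groups))]]
  m <- logical(133)
  m[group] <- TRUE
  m <- m & pred$valid & gt$valid
  if (!any(m)) stop("mpjpe: empty effective group")
  mean(sqrt(rowSums((pred$coords[m, , drop = FALSE] -
                     gt$coords[m, , drop = FALSE])^2)))
}

#' Relative improvement in percent
#'
#' 100 * (reference - ours) / reference: the improvement of \code{ours} over
#' \code{reference}, positive when ours is smaller (better for error
#' metrics).
#'
#' @param reference baseline value (> 0).
#' @param ours compared value.
#' @param digits optional rounding of the result.
#' @return percentage.
#' @export
percent_change <- function(reference, ours, digits = NULL) {
  if (any(reference <= 0)) stop("percent_change: reference must be > 0")
  p <- 100 * (reference - ours) / reference
  if (!is.null(digits)) p <- round(p, digits)
  p
}

#' Part-wise MPJPE evaluation report
#'
#' @param pred,gt lists of \code{pose3d} objects (paired) or n x 133 x 3
#'   arrays of root-relative coordinates.
#' @param layout a \code{wb_layout}.
#' @return data.frame with columns \code{group}, \code{n_joints},
#'   \code{mpjpe_mm} in the order whole_body, body, face, hands.
#' @export
eval_report <- function(pred, gt, layout = wb_layout()) {
  as_list <- function(x) {
    if (is.array(x) && length(dim(x)) == 3)
      lapply(seq_len(dim(x)[1]), function(i)
        pose3d(x[i, , ], frame = "root_relative"))
    else x
  }
  pred <- as_list(pred); gt <- as_list(gt)
  stopifnot(length(pred) == length(gt), length(pred) > 0)
  groups <- c("whole_body", "body", "face", "hands")
  vals <- vapply(groups, function(g)
    mean(vapply(seq_along(pred), function(i)
      mpjpe(pred[[i]], gt[[i]], g, layout), numeric(1))), numeric(1))
  data.frame(group = groups,
             n_joints = vapply(groups, function(g)
               length(layout$part_groups[[g]]), integer(1)),
             mpjpe_mm = as.numeric(vals), row.names = NULL)
}
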