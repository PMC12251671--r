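#' Bone vectors of a pose
#'
#' Computes the 132 bone vectors of the skeleton tree, child minus parent in
#' the fixed edge order, together with their Euclidean lengths. Works for 2D
#' (pixels) and 3D (millimetres) poses. A bone is valid only if both of its
#' endpoint keypoints are valid.
#'
#' @param pose a \code{pose2d} or \code{pose3d}.
#' @param layout a \code{wb_layout}.
#' @return object of class \code{bone_vectors}: list with \code{vectors}
#'   (132 x 2 or 132 x 3), \code{lengths} (132), \code{valid} (132 logical),
#'   \code{edges}.
#' @export
bone_vectors <- function(pose, layout = wb_layout()) {
  e <- layout$edges
  v <- pose$coords[e[, "child"], , drop = FALSE] -
    pose$coords[e[, "parent"], , drop = FALSE]
  structure(list(vectors = v, lengths = sqrt(rowSums(v^2)),
                 valid = pose$valid[e[, "parent"]] & pose$valid[e[, "child"]],
                 edges = e), class = "bone_vectors")
}

#' Reconstruct a root-relative pose from bone vectors
#'
#' Cumulative summation of bone vectors from the tree root. Exact inverse of
#' \code{\link{bone_vectors}} on root-relative poses: the tree root keypoint
#' is placed at its root-relative position (supplied via \code{root_coord},
#' default the origin) and every other keypoint is parent + bone.
#'
#' @param bv a \code{bone_vectors}.
#' @param layout a \code{wb_layout}.
#' @param root_coord coordinate of the tree-root keypoint (default origin).
#' @return coordinate matrix 133 x k.
#' @export
pose_from_bones <- function(bv, layout = wb_layout(), root_coord = NULL) {
  k <- ncol(bv$vectors)
  coords <- matrix(NA_real_, 133, k)
  coords[layout$tree_root, ] <- if (is.null(root_coord)) numeric(k) else root_coord
  e <- bv$edges
  # edges are ordered by child; parents can come later, so iterate in
  # topological order of the tree
  remaining <- rep(TRUE, nrow(e))
  while (any(remaining)) {
    ready <- remaining & !is.na(coords[e[, "parent"], 1])
    if (!any(ready)) stop("bone tree is not connected")
    coords[e[ready, "child"], ] <- coords[e[ready, "parent"], , drop = FALSE] +
      bv$vectors[ready, , drop = FALSE]
    remaining[ready] <- FALSE
  }
  coords
}

#' Angle between two bone vectors
#'
#' arccos of the cosine similarity, with the cosine clamped to [-1, 1] so
#' collinear vectors never raise a domain error. Symmetric in its arguments.
#'
#' @param prox_vec,dist_vec nonzero 3-vectors (or 2-vectors).
#' @return angle in radians, in [0, pi].
#' @export
joint_angle <- function(prox_vec, dist_vec) {
  n1 <- sqrt(sum(prox_vec^2)); n2 <- sqrt(sum(dist_vec^2))
  if (n1 == 0 || n2 == 0) stop("joint angle undefined for zero-length bone vector")
  acos(max(-1, min(1, sum(prox_vec * dist_vec) / (n1 * n2))))
}

#' Direction-plus-log-length bone feature
#'
#' The pre-projection feature of the bone-token branch: the unit direction
#' of the bone concatenated with log(|b| + eps). Dimension-agnostic (2D
#' bones give a 3-component feature, 3D bones a 4-component one). A
#' zero-length bone yields a zero direction part and log(eps), flagged via
#' the \code{"degenerate"} attribute.
#'
#' @param b bone vector (length 2 or 3) or matrix of bone vectors (rows).
#' @param epsilon log stabilizer (default 1e-8).
#' @return feature vector (or matrix), direction part of unit norm wherever
#'   |b| > 0.
#' @export
bone_feature <- function(b, epsilon = 1e-8) {
  v <- is.vector(b)
  b <- rbind(b)
  len <- sqrt(rowSums(b^2))
  dir <- b / ifelse(len > 0, len, 1)
  dir[len == 0, ] <- 0
  out <- cbind(dir, log(len + epsilon))
  attr(out, "degenerate") <- len == 0
  if (v) { deg <- attr(out, "degenerate"); out <- drop(out)
           attr(out, "degenerate") <- deg }
  out
}

#' Embedding configuration for the token builders
#'
#' @param dim embedding width (default 256, the published hidden size).
#' @param epsilon log stabilizer for the bone length feature.
#' @return object of class \code{embed_config}.
#' @export
embed_config <- function(dim = 256, epsilon = 1e-8) {
  stopifnot(dim > 0, epsilon > 0)
  structure(list(dim = dim, epsilon = epsilon), class = "embed_config")
}

#' Build coordinate and bone tokens from a 2D pose
#'
#' Applies the two learned linear embeddings: coordinate token i is a linear
#' map of the i-th 2D keypoint plus its learnable positional encoding; bone
#' token j is a linear map of the direction-plus-log-length feature of bone
#' j plus its positional encoding. \code{params} are as produced by
#' \code{\link{init_lift_params}} (component \code{embed}); when omitted,
#' freshly initialized parameters at \code{cfg$dim} are used.
#'
#' @param pose a \code{pose2d} (root-centred, normalized per the training
#'   pipeline).
#' @param layout a \code{wb_layout}.
#' @param cfg an \code{embed_config}.
#' @param params optional embedding parameter list (\code{Wp, bp, pos_j, Wb,
#'   bb, pos_b}).
#' @return list with \code{coord_tokens} (133 x dim) and \code{bone_tokens}
#'   (132 x dim).
#' @export
make_tokens <- function(pose, layout = wb_layout(), cfg = embed_config(),
                        params = NULL) {
  if (is.null(params)) {
    cf <- lift_config(hidden = cfg$dim, heads = 1, depth = 1, cross_layers = 1)
    params <- init_lift_params(cf, seed = 1)$embed
  }
  X <- pose$coords
  X[!pose$valid, ] <- 0
  bf <- bone_feature(bone_vectors(
    pose2d(X, pose$confidence, rep(TRUE, 133)), layout)$vectors, cfg$epsilon)
  ct <- X %*% params$Wp + rep(params$bp, each = 133) + params$pos_j
  bt <- bf %*% params$Wb + rep(params$bb, each = 132) + params$pos_b
  list(coord_tokens = ct, bone_tokens = bt)
}
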