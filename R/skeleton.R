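#' Whole-body keypoint layout
#'
#' Returns the fixed 133-keypoint whole-body layout (17 main-body, 6 foot,
#' 68 face, 21 + 21 hand keypoints, in the COCO-WholeBody order) together with
#' the bone tree, the evaluation part groups and the left/right mirror
#' permutation. The layout is read from the packaged table
#' \code{inst/extdata/wholebody_layout.csv} and cached for the session.
#'
#' The layout carries no pelvis keypoint; the pelvis root used for
#' normalization is the virtual midpoint of the two hip keypoints
#' (\code{root_hips}). The structural bone tree is rooted at the left hip,
#' with the face parented as a star at the nose and each hand rooted at its
#' wrist; any rooted spanning tree over the standard bones serves the
#' bone-vector encoding equally.
#'
#' @return An object of class \code{wb_layout}: a list with elements
#'   \code{names} (133 keypoint names), \code{parent} (parent index per
#'   keypoint, 0 for the tree root), \code{edges} (132 x 2 matrix of
#'   (parent, child) pairs ordered by child), \code{part_groups} (named list
#'   of index sets: \code{whole_body}, \code{body}, \code{face},
#'   \code{hands}), \code{mirror} (left/right swap permutation, an
#'   involution), \code{side}, and \code{root_hips} (left and right hip
#'   indices).
#' @examples
#' lay <- wb_layout()
#' length(lay$names)                       # 133
#' all(lay$mirror[lay$mirror] == 1:133)    # involution
#' @export
wb_layout <- function() {
  if (!is.null(.poselift_cache$layout)) return(.poselift_cache$layout)
  path <- system.file("extdata", "wholebody_layout.csv", package = "poselift",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 133, identical(tab$index, 1:133))
  children <- which(tab$parent > 0L)
  edges <- cbind(parent = tab$parent[children], child = children)
  groups <- list(
    whole_body = 1:133,
    body  = which(tab$group == "body"),
    face  = which(tab$group == "face"),
    hands = which(tab$group == "hands"))
  lay <- structure(list(
    names = tab$name,
    parent = tab$parent,
    edges = edges,
    part_groups = groups,
    mirror = tab$mirror,
    side = tab$side,
    root_hips = c(left = match("left_hip", tab$name),
                  right = match("right_hip", tab$name)),
    tree_root = which(tab$parent == 0L)), class = "wb_layout")
  .poselift_cache$layout <- lay
  lay
}

.poselift_cache <- new.env(parent = emptyenv())

#' @export
print.wb_layout <- function(x, ...) {
  cat("Whole-body keypoint layout: 133 keypoints, 132 bones\n")
  cat(sprintf("  part groups: body=%d face=%d hands=%d\n",
              length(x$part_groups$body), length(x$part_groups$face),
              length(x$part_groups$hands)))
  cat(sprintf("  tree root: %s; pelvis root: midpoint(%s, %s)\n",
              x$names[x$tree_root], x$names[x$root_hips[1]],
              x$names[x$root_hips[2]]))
  invisible(x)
}

#' Keypoint index lookup
#'
#' @param names character vector of keypoint names.
#' @param layout a \code{wb_layout}.
#' @return integer indices into the 133-keypoint order.
#' @export
kp_index <- function(names, layout = wb_layout()) {
  i <- match(names, layout$names)
  if (anyNA(i)) stop("unknown keypoint name(s): ",
                     paste(names[is.na(i)], collapse = ", "))
  i
}

#' 2D whole-body pose
#'
#' A per-frame container for 133 2D keypoints in pixels, stored relative to
#' the camera principal point, with detector confidences and a validity mask.
#'
#' @param coords 133 x 2 numeric matrix (pixels, principal-point-relative).
#' @param confidence 133 confidences in [0, 1].
#' @param valid 133 logical mask; invalid keypoints are ignored downstream.
#' @param frame coordinate frame tag, \code{"camera"} or
#'   \code{"root_relative"}.
#' @return object of class \code{pose2d}.
#' @export
pose2d <- function(coords, confidence = rep(1, nrow(coords)),
                   valid = rep(TRUE, nrow(coords)), frame = "camera") {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, nrow(coords) == 133,
            length(confidence) == 133, length(valid) == 133,
            all(confidence >= 0 & confidence <= 1))
  if (any(!is.finite(coords[valid, ]))) stop("non-finite coords at valid keypoints")
  structure(list(coords = coords, confidence = as.numeric(confidence),
                 valid = as.logical(valid), frame = frame), class = "pose2d")
}

#' 3D whole-body pose
#'
#' @param coords 133 x 3 numeric matrix in millimetres.
#' @param frame \code{"camera"} (absolute camera frame) or
#'   \code{"root_relative"} (pelvis-centred).
#' @param valid 133 logical mask.
#' @return object of class \code{pose3d}.
#' @export
pose3d <- function(coords, frame = c("camera", "root_relative"),
                   valid = rep(TRUE, nrow(coords))) {
  coords <- as.matrix(coords)
  frame <- match.arg(frame)
  stopifnot(ncol(coords) == 3, nrow(coords) == 133, length(valid) == 133)
  if (any(!is.finite(coords[valid, ]))) stop("non-finite coords at valid keypoints")
  structure(list(coords = coords, frame = frame, valid = as.logical(valid)),
            class = "pose3d")
}

#' @export
print.pose3d <- function(x, ...) {
  cat(sprintf("pose3d: 133 keypoints (mm), frame=%s, valid=%d\n",
              x$frame, sum(x$valid)))
  invisible(x)
}

#' @export
print.pose2d <- function(x, ...) {
  cat(sprintf("pose2d: 133 keypoints (px), valid=%d\n", sum(x$valid)))
  invisible(x)
}

#' Pelvis root of a pose
#'
#' Midpoint of the two hip keypoints, the virtual pelvis used for
#' root-relative normalization.
#'
#' @param pose a \code{pose2d} or \code{pose3d}.
#' @param layout a \code{wb_layout}.
#' @return numeric vector (length 2 or 3).
#' @export
pelvis_root <- function(pose, layout = wb_layout()) {
  h <- layout$root_hips
  if (!all(pose$valid[h])) stop("cannot locate pelvis root: hip keypoint(s) invalid")
  colMeans(pose$coords[h, , drop = FALSE])
}

#' Root-centre a pose
#'
#' Subtracts the virtual pelvis (hip midpoint) from every keypoint so the
#' pose becomes root-relative. Idempotent; errors if either hip is invalid.
#'
#' @inheritParams pelvis_root
#' @return pose of the same class with \code{frame = "root_relative"}.
#' @export
root_center <- function(pose, layout = wb_layout()) {
  r <- pelvis_root(pose, layout)
  pose$coords <- sweep(pose$coords, 2, r)
  pose$frame <- "root_relative"
  pose
}

#' Mirror a pose left/right
#'
#' Negates the lateral (first) coordinate and applies the left/right swap
#' permutation to the keypoint order, so e.g. the left wrist lands in the
#' right-wrist slot with its lateral coordinate negated. An involution.
#'
#' @inheritParams pelvis_root
#' @return pose of the same class.
#' @export
flip_pose <- function(pose, layout = wb_layout()) {
  m <- layout$mirror
  coords <- pose$coords
  coords[, 1] <- -coords[, 1]
  pose$coords <- coords[m, , drop = FALSE]
  pose$valid <- pose$valid[m]
  if (!is.null(pose$confidence)) pose$confidence <- pose$confidence[m]
  pose
}
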