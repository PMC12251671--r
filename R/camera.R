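#' Pinhole camera intrinsics
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point offset in pixels (default 0: pixel
#'   coordinates are stored relative to the principal point throughout).
#' @return object of class \code{camera}.
#' @export
camera <- function(fx, fy = fx, cx = 0, cy = 0) {
  stopifnot(fx > 0, fy > 0)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy), class = "camera")
}

#' @export
print.camera <- function(x, ...) {
  cat(sprintf("pinhole camera: fx=%.1f fy=%.1f c=(%.1f, %.1f)\n",
              x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

#' Project 3D camera-frame points to pixels
#'
#' Pinhole projection u = fx * x / z + cx, v = fy * y / z + cy.
#'
#' @param pts 3-vector or n x 3 matrix, millimetres, camera frame (z > 0).
#' @param cam a \code{camera}.
#' @return 2-vector or n x 2 matrix of pixel coordinates.
#' @export
project <- function(pts, cam) {
  v <- is.vector(pts)
  pts <- rbind(pts)
  if (any(pts[, 3] <= 0)) stop("cannot project: point(s) behind camera (z <= 0)")
  uv <- cbind(cam$fx * pts[, 1] / pts[, 3] + cam$cx,
              cam$fy * pts[, 2] / pts[, 3] + cam$cy)
  if (v) drop(uv) else uv
}

#' Backproject pixels at a given depth
#'
#' Inverse of \code{\link{project}} at known depth z:
#' x = (u - cx) * z / fx, y = (v - cy) * z / fy.
#'
#' @param uv 2-vector or n x 2 matrix of pixel coordinates.
#' @param z depth(s) in millimetres (> 0).
#' @param cam a \code{camera}.
#' @return 3-vector or n x 3 matrix of camera-frame coordinates (mm).
#' @export
backproject <- function(uv, z, cam) {
  v <- is.vector(uv)
  uv <- rbind(uv)
  if (any(z <= 0)) stop("cannot backproject: depth z <= 0")
  xyz <- cbind((uv[, 1] - cam$cx) * z / cam$fx,
               (uv[, 2] - cam$cy) * z / cam$fy,
               z + numeric(nrow(uv)))
  if (v) drop(xyz) else xyz
}

#' Depth offsets consistent with a fixed limb length
#'
#' Given the pixel projections of the two endpoints of a limb, the depth z1
#' of the first endpoint and the limb length L, solves the constant-limb-
#' length relation for the depth offset dz of the second endpoint: with
#' dx = (u1 - cx) z1/fx - (u2 - cx)(z1 + dz)/fx and dy likewise,
#' dx^2 + dy^2 + dz^2 = L^2, a quadratic in dz. This is the relation that
#' makes monocular depth recovery well-posed up to a two-fold ambiguity when
#' limb lengths are known.
#'
#' @param uv1,uv2 2-vectors, pixel coordinates of the two joints.
#' @param z1 depth of joint 1 (mm, > 0).
#' @param L limb length (mm, > 0).
#' @param cam a \code{camera}.
#' @return numeric vector of 0, 1 or 2 real roots dz, sorted by |dz|
#'   (smallest depth correction first). Roots that would place joint 2
#'   behind the camera (z1 + dz <= 0) are removed and reported in the
#'   \code{"filtered"} attribute. An empty vector means no depth is
#'   consistent with the limb length.
#' @export
limb_depth_offsets <- function(uv1, uv2, z1, L, cam) {
  stopifnot(z1 > 0, L > 0)
  a <- (uv2[1] - cam$cx) / cam$fx
  c_ <- (uv2[2] - cam$cy) / cam$fy
  x0 <- (uv1[1] - cam$cx) * z1 / cam$fx - a * z1
  y0 <- (uv1[2] - cam$cy) * z1 / cam$fy - c_ * z1
  # (x0 - a dz)^2 + (y0 - c dz)^2 + dz^2 = L^2
  A <- 1 + a^2 + c_^2
  B <- -2 * (a * x0 + c_ * y0)
  C <- x0^2 + y0^2 - L^2
  disc <- B^2 - 4 * A * C
  if (disc < 0) {
    out <- numeric(0)
    attr(out, "filtered") <- numeric(0)
    return(out)
  }
  r <- sort(c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A)))
  keep <- z1 + r > 0
  out <- r[keep][order(abs(r[keep]))]
  attr(out, "filtered") <- r[!keep]
  out
}
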