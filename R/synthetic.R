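# Synthetic paired 2D/3D whole-body pose generator. It does not imitate any
# motion-capture corpus; it guarantees the structural assumptions the lifting
# method relies on: a fixed skeleton with constant limb lengths, tree
# topology, anthropometrically plausible proportions and mass geometry,
# exact pinhole projection, Gaussian pixel noise and missingness-style
# occlusion.

#' Synthetic benchmark configuration
#'
#' @param n_train,n_val,n_test split sizes (defaults 2000/400/400, the desk
#'   benchmark).
#' @param seed integer seed; all randomness flows from it.
#' @param stature_range_mm subject stature range (default 1500-1900 mm).
#' @param focal_range_px pinhole focal length range (default 1000-1500 px).
#' @param depth_range_mm subject root depth range (default 3000-6000 mm).
#' @param noise_sigma_px Gaussian pixel noise on the 2D keypoints (default 1).
#' @param occlusion_prob per-keypoint missingness probability (default 0.05;
#'   the two hip keypoints are exempt so the root stays defined).
#' @param rotation_deg,scale_range,flip_prob train-time augmentation ranges
#'   (in-plane rotation, 2D scale, left/right flip).
#' @param elbow_angle_range_deg admissible interior elbow angle (degrees).
#' @return object of class \code{synth_config}.
#' @export
synth_config <- function(n_train = 2000, n_val = 400, n_test = 400,
                         seed = 1,
                         stature_range_mm = c(1500, 1900),
                         focal_range_px = c(1000, 1500),
                         depth_range_mm = c(3000, 6000),
                         noise_sigma_px = 1.0,
                         occlusion_prob = 0.05,
                         rotation_deg = 15,
                         scale_range = c(0.8, 1.2),
                         flip_prob = 0.5,
                         elbow_angle_range_deg = c(30, 170)) {
  stopifnot(diff(stature_range_mm) >= 0, diff(focal_range_px) >= 0,
            diff(depth_range_mm) >= 0, noise_sigma_px >= 0,
            occlusion_prob >= 0, occlusion_prob <= 1,
            flip_prob >= 0, flip_prob <= 1)
  structure(list(n_train = n_train, n_val = n_val, n_test = n_test,
                 seed = as.integer(seed),
                 stature_range_mm = stature_range_mm,
                 focal_range_px = focal_range_px,
                 depth_range_mm = depth_range_mm,
                 noise_sigma_px = noise_sigma_px,
                 occlusion_prob = occlusion_prob,
                 rotation_deg = rotation_deg, scale_range = scale_range,
                 flip_prob = flip_prob,
                 elbow_angle_range_deg = elbow_angle_range_deg),
            class = "synth_config")
}

# Evaluate expr under a private RNG stream; the global RNG state is restored.
with_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

segment_proportions <- function() {
  p <- utils::read.csv(system.file("extdata", "segment_proportions.csv",
                                   package = "poselift", mustWork = TRUE))
  stats::setNames(p$fraction, p$name)
}

rot_x <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
rot_y <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))

# Rodrigues rotation of vector v about unit axis by angle a.
rotate_axis <- function(v, axis, a) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(a) + pracma::cross(axis, v) * sin(a) +
    axis * sum(axis * v) * (1 - cos(a))
}

# Any unit vector orthogonal to u.
perp_vector <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- pracma::cross(u, ref)
  p / sqrt(sum(p^2))
}

#' Sample a subject skeleton
#'
#' Draws a stature uniformly from the configured range and derives every
#' segment length as a fixed, documented proportion of the stature (packaged
#' table \code{segment_proportions.csv}; the vertical chain ankle height +
#' calf + thigh + trunk + shoulder-to-crown sums to 1.0 of stature). Left
#' and right limb lengths are equal by construction. Also builds the rigid
#' face (68-point) and hand (21-point) templates at the subject's scale,
#' symmetric under the layout's mirror permutation.
#'
#' @param cfg a \code{synth_config}. Randomness is taken from the current
#'   RNG state; wrap in \code{set.seed()} or use via
#'   \code{\link{make_benchmark}} for reproducibility.
#' @return object of class \code{wb_skeleton}: \code{stature},
#'   \code{lengths} (named, mm), \code{face_template} (68 x 3),
#'   \code{hand_template} (21 x 3, right hand; left is its mirror).
#' @export
sample_skeleton <- function(cfg = synth_config()) {
  H <- stats::runif(1, cfg$stature_range_mm[1], cfg$stature_range_mm[2])
  p <- segment_proportions()
  lengths <- p * H
  s <- lengths[["face_scale"]]
  structure(list(stature = H, lengths = lengths,
                 face_template = face_template(s),
                 hand_template = hand_template(lengths[["hand_length"]])),
            class = "wb_skeleton")
}

# 68-point rigid face template in the head frame (origin at the nose
# keypoint, +x subject-left, +y up, +z out of the face), mirror-consistent
# with the packaged layout by construction.
face_template <- function(s) {
  pts <- matrix(0, 68, 3)
  set <- function(i, x, y, z) pts[i, ] <<- c(x, y, z) * s
  # jaw 1..17 (1 on subject right); chin at 9
  for (k in 1:17) {
    phi <- pi * (k - 1) / 16
    set(k, -cos(phi) * 1.05, -0.25 - 0.95 * sin(phi), -0.35 + 0.75 * sin(phi))
  }
  # right brow 18..22
  bx <- seq(-0.85, -0.15, length.out = 5)
  for (k in 1:5) set(17 + k, bx[k], 0.45 + 0.12 * sin(pi * (k - 1) / 4), 0.25)
  # nose bridge 28..31 and nostril line 32..36
  by <- seq(0.35, 0.02, length.out = 4)
  for (k in 1:4) set(27 + k, 0, by[k], 0.15 + 0.05 * (k - 1))
  nx <- seq(-0.22, 0.22, length.out = 5)
  for (k in 1:5) set(31 + k, nx[k], -0.14 - 0.04 * (k == 3), 0.18)
  # right eye 37..42 (hexagon)
  ec <- c(-0.45, 0.28, 0.05)
  ex <- c(-0.28, -0.14, 0.12, 0.26, 0.12, -0.14)
  ey <- c(0, 0.09, 0.09, 0, -0.08, -0.08)
  for (k in 1:6) set(36 + k, ec[1] + ex[k], ec[2] + ey[k], ec[3])
  # mouth: outer 49..60, inner 61..68
  mo <- c(0, -0.55, 0.12)
  ang <- c(180, 150, 115, 90, 65, 30, 0, -30, -65, -90, -115, -150) * pi / 180
  for (k in 1:12)
    set(48 + k, mo[1] + 0.42 * cos(ang[k]), mo[2] + 0.18 * sin(ang[k]), mo[3])
  angi <- c(180, 120, 90, 60, 0, -60, -90, -120) * pi / 180
  for (k in 1:8)
    set(60 + k, mo[1] + 0.25 * cos(angi[k]), mo[2] + 0.09 * sin(angi[k]), mo[3])
  # left-side points from the mirror permutation
  lay <- wb_layout()
  fidx <- lay$part_groups$face
  fm <- lay$mirror[fidx] - fidx[1] + 1L
  for (k in 1:68)
    if (fm[k] > k) pts[fm[k], ] <- pts[k, ] * c(-1, 1, 1)
  pts
}

# 21-point right-hand rigid template in the hand frame (origin at the hand
# root, +z distal along the forearm continuation, +x thumb side). Scaled so
# the wrist-to-middle-fingertip distance equals hand_length.
hand_template <- function(hand_length) {
  fing_x <- c(0.18, 0.06, -0.06, -0.18)
  pts <- matrix(0, 21, 3)
  pts[2:5, ] <- cbind(c(0.28, 0.42, 0.52, 0.58),
                      c(-0.05, -0.08, -0.10, -0.11),
                      c(0.18, 0.34, 0.46, 0.55))
  for (f in 1:4) {
    rows <- 5 + (f - 1) * 4 + 1:4
    pts[rows, ] <- cbind(rep(fing_x[f], 4), 0, c(0.45, 0.68, 0.84, 0.95))
  }
  norm_mid <- sqrt(sum(pts[13, ]^2))  # middle_finger4 row
  pts * (hand_length / norm_mid)
}

canonical_angles <- function() {
  list(torso_pitch = 0, torso_roll = 0, torso_twist = 0,
       head_yaw = 0, head_pitch = 0,
       shoulder_polar = c(left = pi / 2, right = pi / 2),
       shoulder_azim = c(left = 0, right = pi),
       elbow_flex = c(left = 0, right = 0),
       elbow_axis_angle = c(left = 0, right = 0),
       hand_roll = c(left = 0, right = 0),
       hip_polar = c(left = 0, right = 0),
       hip_azim = c(left = pi / 2, right = pi / 2),
       knee_flex = c(left = 0, right = 0),
       knee_axis_angle = c(left = 0, right = 0),
       foot_yaw = c(left = 0, right = 0))
}

sample_angles <- function(cfg) {
  d <- pi / 180
  u <- function(a, b) stats::runif(1, a, b)
  u2 <- function(a, b) c(left = u(a, b), right = u(a, b))
  ef <- pi - cfg$elbow_angle_range_deg * d   # interior angle -> flexion
  list(torso_pitch = u(-30, 30) * d, torso_roll = u(-15, 15) * d,
       torso_twist = u(-30, 30) * d,
       head_yaw = u(-40, 40) * d, head_pitch = u(-25, 25) * d,
       shoulder_polar = u2(10 * d, 140 * d),
       shoulder_azim = u2(0, 2 * pi),
       elbow_flex = u2(min(ef), max(ef)),
       elbow_axis_angle = u2(0, 2 * pi),
       hand_roll = u2(-pi / 4, pi / 4),
       hip_polar = u2(0, 70 * d),
       hip_azim = u2(0, 2 * pi),
       knee_flex = u2(0, 120 * d),
       knee_axis_angle = u2(0, 2 * pi),
       foot_yaw = u2(-pi / 6, pi / 6))
}

#' Sample a 3D whole-body pose by forward kinematics
#'
#' Places all 133 keypoints by composing unit bone directions with the
#' skeleton's fixed lengths over the kinematic tree, so every limb length is
#' exact across samples from one skeleton. Joint angles are drawn within
#' documented anatomical ranges (e.g. interior elbow angle within
#' \code{cfg$elbow_angle_range_deg}); face and hand keypoints are placed by
#' the skeleton's rigid templates attached to the head and wrist frames.
#' The pose is returned root-relative (pelvis at the origin) in a body frame
#' with +x subject-left, +y up, +z forward.
#'
#' @param skeleton a \code{wb_skeleton}.
#' @param cfg a \code{synth_config}.
#' @param angles optional named list of joint angles (as produced internally;
#'   \code{canonical_pose} passes the neutral T-pose values). Default:
#'   sampled from the current RNG state.
#' @param layout a \code{wb_layout}.
#' @return a \code{pose3d} (root_relative, mm).
#' @export
sample_pose3d <- function(skeleton, cfg = synth_config(), angles = NULL,
                          layout = wb_layout()) {
  if (is.null(angles)) angles <- sample_angles(cfg)
  L <- skeleton$lengths
  P <- matrix(0, 133, 3)
  id <- function(n) kp_index(n, layout)
  put <- function(n, v) P[id(n), ] <<- v

  hipw <- L[["hip_width"]]
  put("left_hip", c(hipw / 2, 0, 0))
  put("right_hip", c(-hipw / 2, 0, 0))

  Rt <- rot_y(angles$torso_twist) %*% rot_x(angles$torso_pitch) %*%
    rot_z(angles$torso_roll)
  sc <- drop(Rt %*% c(0, L[["trunk"]], 0))      # shoulder centre
  lat <- drop(Rt %*% c(1, 0, 0))
  put("left_shoulder", sc + lat * L[["shoulder_width"]] / 2)
  put("right_shoulder", sc - lat * L[["shoulder_width"]] / 2)

  Rh <- Rt %*% rot_y(angles$head_yaw) %*% rot_x(angles$head_pitch)
  nose <- sc + drop(Rh %*% c(0, L[["shoulder_to_nose"]], 0.006 * skeleton$stature))
  put("nose", nose)
  fs <- L[["face_scale"]]
  put("left_eye", nose + drop(Rh %*% (c(0.45, 0.28, 0.05) * fs)))
  put("right_eye", nose + drop(Rh %*% (c(-0.45, 0.28, 0.05) * fs)))
  put("left_ear", nose + drop(Rh %*% (c(1.05, 0.1, -1.2) * fs)))
  put("right_ear", nose + drop(Rh %*% (c(-1.05, 0.1, -1.2) * fs)))
  fidx <- layout$part_groups$face
  P[fidx, ] <- t(nose + Rh %*% t(skeleton$face_template))

  for (s in c("left", "right")) {
    sgn <- if (s == "left") 1 else -1
    sh <- P[id(paste0(s, "_shoulder")), ]
    # upper arm: rotate torso-down by the polar angle about a horizontal axis
    axis <- Rt %*% c(sin(angles$shoulder_azim[s]), 0, cos(angles$shoulder_azim[s]))
    upper_dir <- rotate_axis(as.vector(Rt %*% c(0, -1, 0)), as.vector(axis),
                             angles$shoulder_polar[s])
    el <- sh + upper_dir * L[["upper_arm"]]
    put(paste0(s, "_elbow"), el)
    ax2 <- rotate_axis(perp_vector(upper_dir), upper_dir,
                       angles$elbow_axis_angle[s])
    fore_dir <- rotate_axis(upper_dir, ax2, angles$elbow_flex[s])
    wr <- el + fore_dir * L[["forearm"]]
    put(paste0(s, "_wrist"), wr)
    # hand frame: z distal along forearm, x toward thumb
    zh <- fore_dir
    xh <- rotate_axis(perp_vector(zh), zh, angles$hand_roll[s])
    yh <- pracma::cross(zh, xh)
    Rhand <- cbind(xh, yh, zh)
    tmpl <- skeleton$hand_template
    if (s == "left") tmpl <- tmpl * rep(c(-1, 1, 1), each = nrow(tmpl))
    hidx <- grep(paste0("^", s, "_(hand_root|thumb|forefinger|middle_finger|",
                        "ring_finger|pinky_finger)"), layout$names)
    P[hidx, ] <- t(wr + Rhand %*% t(tmpl))

    hp <- P[id(paste0(s, "_hip")), ]
    axl <- c(sin(angles$hip_azim[s]), 0, cos(angles$hip_azim[s]))
    thigh_dir <- rotate_axis(c(0, -1, 0), axl, angles$hip_polar[s])
    kn <- hp + thigh_dir * L[["thigh"]]
    put(paste0(s, "_knee"), kn)
    ax3 <- rotate_axis(perp_vector(thigh_dir), thigh_dir,
                       angles$knee_axis_angle[s])
    calf_dir <- rotate_axis(thigh_dir, ax3, angles$knee_flex[s])
    an <- kn + calf_dir * L[["calf"]]
    put(paste0(s, "_ankle"), an)
    # foot frame: forward roughly +z rotated by foot yaw, orthogonal to calf
    fwd <- rotate_axis(c(0, 0, 1), c(0, 1, 0), angles$foot_yaw[s])
    fwd <- fwd - calf_dir * sum(fwd * calf_dir)
    if (sum(fwd^2) < 1e-12) fwd <- perp_vector(calf_dir)
    fwd <- fwd / sqrt(sum(fwd^2))
    side <- pracma::cross(fwd, calf_dir)
    fl <- L[["foot_length"]]
    down <- calf_dir * L[["ankle_height"]]   # calf_dir points toward the ground
    put(paste0(s, "_big_toe"), an + fwd * 0.75 * fl + down + sgn * side * 0.08 * fl)
    put(paste0(s, "_small_toe"), an + fwd * 0.70 * fl + down - sgn * side * 0.12 * fl)
    put(paste0(s, "_heel"), an - fwd * 0.25 * fl + down)
  }
  # centre on the virtual pelvis (hip midpoint is already the origin)
  root_center(pose3d(P, frame = "root_relative"), layout)
}

#' Canonical (neutral) template pose
#'
#' The zero-angle pose of a skeleton: upright trunk, T-pose arms, straight
#' legs, neutral head. Useful as a fixture and as the reference for
#' anthropometric sanity checks.
#'
#' @param skeleton a \code{wb_skeleton}.
#' @param layout a \code{wb_layout}.
#' @return a \code{pose3d}.
#' @export
canonical_pose <- function(skeleton, layout = wb_layout()) {
  sample_pose3d(skeleton, synth_config(), angles = canonical_angles(),
                layout = layout)
}

#' Render a 3D pose into a synthetic camera observation
#'
#' Applies a random global yaw, places the subject in front of a sampled
#' pinhole camera, projects all keypoints, adds Gaussian pixel noise and
#' missingness-style occlusion (valid = FALSE, confidence 0, coordinates
#' zeroed; the two hips are exempt so the pelvis root stays observable).
#' The ground truth is returned root-relative in the camera orientation.
#'
#' @param pose a root-relative \code{pose3d} from \code{sample_pose3d}
#'   (body frame, +y up).
#' @param cfg a \code{synth_config}.
#' @param layout a \code{wb_layout}.
#' @return list with \code{pose2d} (pixels, principal-point-relative),
#'   \code{gt} (root-relative \code{pose3d}, mm, camera orientation),
#'   \code{cam} (a \code{camera}), \code{root_cam} (camera-frame position of
#'   the pelvis root, mm), and \code{clean2d} (noise-free projections).
#' @export
render_sample <- function(pose, cfg = synth_config(), layout = wb_layout()) {
  yaw <- stats::runif(1, 0, 2 * pi)
  Pb <- pose$coords %*% t(rot_y(yaw))
  # camera frame: x right-handed with y down, z depth
  Pc <- cbind(Pb[, 1], -Pb[, 2], Pb[, 3])
  cam <- camera(fx = stats::runif(1, cfg$focal_range_px[1], cfg$focal_range_px[2]),
                fy = stats::runif(1, cfg$focal_range_px[1], cfg$focal_range_px[2]))
  for (try in 1:20) {
    root <- c(stats::runif(1, -500, 500), stats::runif(1, -300, 300),
              stats::runif(1, cfg$depth_range_mm[1], cfg$depth_range_mm[2]))
    Pcam <- sweep(Pc, 2, root, `+`)
    if (all(Pcam[, 3] > 1)) break
    if (try == 20) stop("could not place subject in front of the camera")
  }
  clean <- project(Pcam, cam)
  uv <- clean + matrix(stats::rnorm(2 * 133, 0, cfg$noise_sigma_px), 133, 2)
  occ <- stats::runif(133) < cfg$occlusion_prob
  occ[layout$root_hips] <- FALSE
  conf <- ifelse(occ, 0, stats::runif(133, 0.6, 1))
  uv[occ, ] <- 0
  gt <- root_center(pose3d(Pcam, frame = "camera"), layout)
  list(pose2d = pose2d(uv, confidence = conf, valid = !occ),
       gt = gt, cam = cam, root_cam = root, clean2d = clean)
}

#' Generate a synthetic train/val/test benchmark
#'
#' Builds the desk-scale paired 2D/3D benchmark: splits are disjoint by
#' skeleton identity, every sample is a pinhole-projected whole-body pose
#' with noise and occlusion, and regeneration with the same seed reproduces
#' the coordinates exactly. Optionally writes the dataset to disk as CSV
#' files plus a JSON manifest.
#'
#' @param cfg a \code{synth_config}.
#' @param dir optional output directory (created if needed).
#' @param force overwrite an existing non-empty output directory.
#' @param poses_per_skeleton poses drawn per subject skeleton (default 40).
#' @return object of class \code{pose_benchmark}: list with \code{train},
#'   \code{val}, \code{test} (each: \code{kp2d} n x 133 x 2, \code{kp3d}
#'   n x 133 x 3 root-relative mm, \code{conf}, \code{valid} n x 133,
#'   \code{cam} n x 4 fx/fy/cx/cy, \code{skeleton_id}) and \code{manifest}.
#' @export
make_benchmark <- function(cfg = synth_config(), dir = NULL, force = FALSE,
                           poses_per_skeleton = 40) {
  layout <- wb_layout()
  sizes <- c(train = cfg$n_train, val = cfg$n_val, test = cfg$n_test)
  out <- list()
  skel_offset <- 0L
  with_rng(cfg$seed, {
    for (sp in names(sizes)) {
      n <- sizes[[sp]]
      n_skel <- max(1L, ceiling(n / poses_per_skeleton))
      skels <- lapply(seq_len(n_skel), function(i) sample_skeleton(cfg))
      kp2d <- array(0, c(n, 133, 2)); kp3d <- array(0, c(n, 133, 3))
      conf <- matrix(0, n, 133); valid <- matrix(TRUE, n, 133)
      camm <- matrix(0, n, 4, dimnames = list(NULL, c("fx", "fy", "cx", "cy")))
      sid <- integer(n)
      for (i in seq_len(n)) {
        k <- ((i - 1L) %% n_skel) + 1L
        smp <- render_sample(sample_pose3d(skels[[k]], cfg, layout = layout),
                             cfg, layout)
        kp2d[i, , ] <- smp$pose2d$coords
        kp3d[i, , ] <- smp$gt$coords
        conf[i, ] <- smp$pose2d$confidence
        valid[i, ] <- smp$pose2d$valid
        camm[i, ] <- unlist(smp$cam)
        sid[i] <- skel_offset + k
      }
      out[[sp]] <- list(kp2d = kp2d, kp3d = kp3d, conf = conf, valid = valid,
                        cam = camm, skeleton_id = sid)
      skel_offset <- skel_offset + n_skel
    }
  })
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  out$manifest <- list(n = as.list(sizes), seed = cfg$seed,
                       config_hash = text_hash(cfg_json),
                       layout_hash = layout_hash())
  class(out) <- "pose_benchmark"
  if (!is.null(dir)) write_benchmark(out, dir, force)
  out
}

#' @export
print.pose_benchmark <- function(x, ...) {
  cat(sprintf("synthetic pose benchmark: train=%d val=%d test=%d (seed %d)\n",
              x$manifest$n$train, x$manifest$n$val, x$manifest$n$test,
              x$manifest$seed))
  invisible(x)
}

text_hash <- function(txt) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(txt), f)
  unname(tools::md5sum(f))
}

layout_hash <- function() {
  unname(tools::md5sum(system.file("extdata", "wholebody_layout.csv",
                                   package = "poselift", mustWork = TRUE)))
}

write_benchmark <- function(bench, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop("output directory ", dir, " exists and is not empty (use force)")
  if (!dir.exists(dirname(dir)))
    stop("parent directory does not exist: ", dirname(dir))
  dir.create(dir, showWarnings = FALSE, recursive = FALSE)
  for (sp in c("train", "val", "test")) {
    d <- bench[[sp]]
    n <- dim(d$kp2d)[1]
    df <- data.frame(
      sample = rep(seq_len(n), each = 133),
      keypoint = rep(seq_len(133), times = n),
      u = as.vector(t(d$kp2d[, , 1])), v = as.vector(t(d$kp2d[, , 2])),
      x = as.vector(t(d$kp3d[, , 1])), y = as.vector(t(d$kp3d[, , 2])),
      z = as.vector(t(d$kp3d[, , 3])),
      conf = as.vector(t(d$conf)), valid = as.vector(t(d$valid)))
    utils::write.csv(df, file.path(dir, paste0(sp, "_keypoints.csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(sample = seq_len(n), d$cam,
                                skeleton_id = d$skeleton_id),
                     file.path(dir, paste0(sp, "_cameras.csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(bench$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

read_benchmark <- function(dir) {
  out <- list()
  for (sp in c("train", "val", "test")) {
    df <- utils::read.csv(file.path(dir, paste0(sp, "_keypoints.csv")))
    cm <- utils::read.csv(file.path(dir, paste0(sp, "_cameras.csv")))
    n <- max(df$sample)
    arr <- function(col, k) {
      a <- array(0, c(n, 133, k))
      for (j in seq_len(k)) a[, , j] <- matrix(df[[col[j]]], n, 133, byrow = TRUE)
      a
    }
    out[[sp]] <- list(
      kp2d = arr(c("u", "v"), 2), kp3d = arr(c("x", "y", "z"), 3),
      conf = matrix(df$conf, n, 133, byrow = TRUE),
      valid = matrix(df$valid, n, 133, byrow = TRUE),
      cam = as.matrix(cm[, c("fx", "fy", "cx", "cy")]),
      skeleton_id = cm$skeleton_id)
  }
  out$manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  class(out) <- "pose_benchmark"
  out
}
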