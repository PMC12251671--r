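#' Body-segment anthropometric table
#'
#' Loads the 15-segment mass-fraction and centroid-position table for one
#' gender, from the packaged transcription of the adult-body inertial
#' parameter tables. Segments: neck/head, upper torso, lower torso and
#' left/right thigh, calf, upper arm, forearm, hand and foot. Each segment
#' carries a relative mass coefficient k (fraction of total body mass; the
#' printed per-gender fractions sum to 99.99\% and 100.01\% and are
#' renormalized to exactly 1 by default) and the centroid split of its
#' length: the centroid lies \code{les} of the way from the proximal end
#' (the endpoint nearer the heart), so the proximal endpoint coordinate is
#' weighted by \code{lex} and the distal by \code{les}.
#'
#' Segment endpoints are expressed as keypoint index sets whose mean gives
#' the endpoint: e.g. the upper torso runs from the shoulder midpoint to the
#' virtual mid-torso (mean of shoulders and hips). Face and hand keypoints
#' other than the segment endpoints carry no mass; the 15 gross segments
#' account for all body mass.
#'
#' @param gender \code{"M"} or \code{"F"}.
#' @param renormalize logical; rescale mass fractions to sum exactly to 1
#'   (default TRUE). Set FALSE to keep the printed values.
#' @param proximal_is_les logical; if TRUE the \emph{proximal} coordinate is
#'   weighted by \code{les} instead of \code{lex} (the alternative reading of
#'   the centroid split). Default FALSE.
#' @param layout a \code{wb_layout}.
#' @return object of class \code{anthro_table}: list with \code{gender},
#'   \code{segments} (list of 15 segment specs, each with \code{name},
#'   \code{proximal}, \code{distal} keypoint index sets, \code{mass_fraction},
#'   \code{les}, \code{lex}, \code{w_prox}, \code{w_dist}), and
#'   \code{raw_mass_pct_sum} (printed-value sum before renormalization, in
#'   percent).
#' @examples
#' tab <- anthro_table("M")
#' sum(vapply(tab$segments, `[[`, 1, "mass_fraction"))  # 1
#' @export
anthro_table <- function(gender = c("M", "F"), renormalize = TRUE,
                         proximal_is_les = FALSE, layout = wb_layout()) {
  gender <- match.arg(gender)
  mass <- utils::read.csv(system.file("extdata", "segment_mass_fractions.csv",
                                      package = "poselift", mustWork = TRUE))
  cent <- utils::read.csv(system.file("extdata", "segment_centroids.csv",
                                      package = "poselift", mustWork = TRUE))
  mass <- mass[mass$gender == gender, ]
  cent <- cent[cent$gender == gender, ]
  row <- function(seg, d) d[d$segment == seg, ]
  ends <- segment_endpoints(layout)
  segs <- list()
  for (e in ends) {
    base <- sub("^(left|right)_", "", e$name)
    m <- row(base, mass)$mass_pct / 100
    cr <- row(base, cent)
    les <- cr$les / 100; lex <- cr$lex / 100
    if (abs(les + lex - 1) > 1e-6)
      stop("centroid fractions do not sum to 1 for segment ", base)
    wp <- if (proximal_is_les) les else lex
    segs[[e$name]] <- list(name = e$name, proximal = e$proximal,
                           distal = e$distal, mass_fraction = m,
                           les = les, lex = lex,
                           w_prox = wp, w_dist = 1 - wp)
  }
  raw_sum_pct <- 100 * sum(vapply(segs, `[[`, 1, "mass_fraction"))
  if (renormalize) {
    tot <- raw_sum_pct / 100
    for (i in seq_along(segs))
      segs[[i]]$mass_fraction <- segs[[i]]$mass_fraction / tot
  }
  structure(list(gender = gender, segments = segs,
                 raw_mass_pct_sum = raw_sum_pct,
                 renormalized = renormalize), class = "anthro_table")
}

# Endpoint keypoint sets for the 15 mass segments (proximal first).
# Torso endpoints use virtual points: shoulder midpoint, hip midpoint and
# mid-torso (mean of both shoulders and both hips).
segment_endpoints <- function(layout = wb_layout()) {
  kp <- function(...) kp_index(c(...), layout)
  shoulders <- kp("left_shoulder", "right_shoulder")
  hips <- kp("left_hip", "right_hip")
  midtorso <- c(shoulders, hips)
  out <- list(
    list(name = "neck", proximal = shoulders,
         distal = kp("nose", "left_ear", "right_ear")),
    list(name = "upper_torso", proximal = shoulders, distal = midtorso),
    list(name = "lower_torso", proximal = midtorso, distal = hips))
  for (s in c("left", "right")) {
    p <- function(n) paste0(s, "_", n)
    out <- c(out, list(
      list(name = p("thigh"), proximal = kp(p("hip")), distal = kp(p("knee"))),
      list(name = p("calf"), proximal = kp(p("knee")), distal = kp(p("ankle"))),
      list(name = p("upper_arm"), proximal = kp(p("shoulder")),
           distal = kp(p("elbow"))),
      list(name = p("forearm"), proximal = kp(p("elbow")),
           distal = kp(p("wrist"))),
      list(name = p("hand"), proximal = kp(p("wrist")),
           distal = kp(p("middle_finger4"))),
      list(name = p("foot"), proximal = kp(p("ankle")),
           distal = kp(p("big_toe"), p("small_toe")))))
  }
  out
}

#' @export
print.anthro_table <- function(x, ...) {
  cat(sprintf("anthro_table (%s): 15 segments, printed mass sum %.2f%%%s\n",
              x$gender, x$raw_mass_pct_sum,
              if (x$renormalized) " (renormalized to 1)" else ""))
  invisible(x)
}

#' Centre of gravity of one body segment
#'
#' Moment-synthesis centroid of a rigid segment: the proximal endpoint
#' coordinate weighted by \code{w_prox} plus the distal endpoint weighted by
#' \code{w_dist} (weights sum to 1), placing the centroid \code{les} of the
#' segment length from the proximal end under the default convention.
#'
#' @param pose a \code{pose3d}.
#' @param segment one element of \code{anthro_table()$segments}.
#' @return 3-vector, millimetres, same frame as the pose.
#' @examples
#' tab <- anthro_table("M")
#' # upper-arm centroid sits 47.8% of the way from the shoulder
#' @export
segment_cog <- function(pose, segment) {
  need <- c(segment$proximal, segment$distal)
  if (!all(pose$valid[need]))
    stop("segment '", segment$name, "' has invalid endpoint keypoint(s)")
  p <- colMeans(pose$coords[segment$proximal, , drop = FALSE])
  d <- colMeans(pose$coords[segment$distal, , drop = FALSE])
  unname(p * segment$w_prox + d * segment$w_dist)
}

#' Whole-body CoG as a linear map over keypoints
#'
#' Closes the segment-wise moment synthesis into a single weight vector w of
#' length 133 such that the whole-body centre of gravity of any pose P is
#' \code{t(w) \%*\% P}. Weights sum to 1; keypoints that are not endpoints of
#' any mass segment (most face and hand keypoints) get weight 0.
#'
#' @param table an \code{anthro_table}.
#' @param layout a \code{wb_layout}.
#' @return numeric vector of length 133 summing to 1.
#' @export
cog_weights <- function(table, layout = wb_layout()) {
  w <- numeric(133)
  for (s in table$segments) {
    np <- length(s$proximal); nd <- length(s$distal)
    w[s$proximal] <- w[s$proximal] + s$mass_fraction * s$w_prox / np
    w[s$distal] <- w[s$distal] + s$mass_fraction * s$w_dist / nd
  }
  w
}

#' Whole-body centre of gravity
#'
#' Mass-weighted sum of the 15 segment centroids (moment synthesis): each
#' segment's centroid is weighted by its relative mass coefficient k, and
#' the coefficients sum to 1, so the result is a convex combination of the
#' segment-endpoint keypoints. Translation- and rotation-equivariant.
#'
#' @param pose a \code{pose3d} with all segment-endpoint keypoints valid.
#' @param table an \code{anthro_table}.
#' @param layout a \code{wb_layout}.
#' @param renormalize_missing if TRUE, segments with invalid endpoints are
#'   dropped and the remaining mass fractions renormalized instead of
#'   raising an error.
#' @return 3-vector (mm), the CoG in the pose's frame.
#' @export
body_cog <- function(pose, table, layout = wb_layout(),
                     renormalize_missing = FALSE) {
  ok <- vapply(table$segments, function(s)
    all(pose$valid[c(s$proximal, s$distal)]), logical(1))
  if (!all(ok)) {
    if (!renormalize_missing)
      stop("missing endpoints for segment(s): ",
           paste(names(table$segments)[!ok], collapse = ", "))
    segs <- table$segments[ok]
    tot <- sum(vapply(segs, `[[`, 1, "mass_fraction"))
    acc <- c(0, 0, 0)
    for (s in segs) acc <- acc + (s$mass_fraction / tot) * segment_cog(pose, s)
    return(unname(acc))
  }
  acc <- c(0, 0, 0)
  for (s in table$segments)
    acc <- acc + s$mass_fraction * segment_cog(pose, s)
  unname(acc)
}
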