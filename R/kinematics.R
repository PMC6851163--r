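# Midline kinematics: arc-length resampling of the digitized midline,
# landmark extraction, travel direction, segment angles, undulation
# amplitudes and instantaneous velocities.

#' Resample a digitized midline to 101 equally spaced points
#'
#' Fits an arc-length-parameterized natural cubic spline through the 20
#' digitized midline points and returns 101 points equally spaced in arc
#' length from the head to the caudal peduncle. Inversion of the arc-length
#' map uses dense subdivision of the spline.
#'
#' @param m 20 x 2 matrix of digitized midline points (mm), ordered head to
#'   caudal peduncle.
#' @param n_dense Number of dense subdivisions used to invert the arc-length
#'   parameterization.
#' @return A 101 x 2 matrix of class `resampled_midline` with attribute
#'   `arc_length` (total fitted arc length, mm).
#' @export
interpolate_midline <- function(m, n_dense = 8001L) {
  m <- as.matrix(m)
  if (nrow(m) != 20L || ncol(m) != 2L) {
    stop("midline must be a 20 x 2 matrix of points", call. = FALSE)
  }
  stopifnot_finite(m, "midline coordinates")
  seg <- sqrt(rowSums((m[-1L, ] - m[-20L, ])^2))
  if (any(seg == 0)) {
    stop("duplicate consecutive midline points", call. = FALSE)
  }
  tt <- c(0, cumsum(seg))
  fx <- stats::splinefun(tt, m[, 1L], method = "natural")
  fy <- stats::splinefun(tt, m[, 2L], method = "natural")
  td <- seq(0, tt[20L], length.out = n_dense)
  xd <- fx(td); yd <- fy(td)
  arc <- c(0, cumsum(sqrt(diff(xd)^2 + diff(yd)^2)))
  total <- arc[n_dense]
  targets <- seq(0, total, length.out = 101L)
  tq <- stats::approx(arc, td, xout = targets, ties = "ordered")$y
  out <- cbind(fx(tq), fy(tq))
  structure(out, arc_length = total, class = c("resampled_midline", "matrix"))
}

#' Extract the 11 landmarks and 10 body segments
#'
#' Takes every 10th point of a resampled midline, dividing the body into 10
#' segments of 10% body length each.
#'
#' @param r A `resampled_midline` (101 x 2 matrix) from
#'   [interpolate_midline()].
#' @return A `landmark_set`: list with `points` (11 x 2), `segments`
#'   (list of 10 start/end point pairs), `fractions` (0, 0.1, ..., 1).
#' @export
extract_landmarks <- function(r) {
  r <- unclass(r)
  if (nrow(r) != 101L || ncol(r) != 2L) {
    stop("resampled midline must be a 101 x 2 matrix", call. = FALSE)
  }
  idx <- seq(1L, 101L, by = 10L)
  pts <- r[idx, , drop = FALSE]
  segs <- lapply(seq_len(10L), function(i) {
    rbind(start = pts[i, ], end = pts[i + 1L, ])
  })
  structure(list(points = pts, segments = segs,
                 fractions = seq(0, 1, by = 0.1)),
            class = "landmark_set")
}

#' Instantaneous direction of travel from the head reference points
#'
#' Total-least-squares line (principal axis) through the anterior head
#' reference point's positions over the window, oriented by the net
#' displacement. When the net displacement is below `min_displacement_mm`
#' the head-axis direction (anterior minus posterior head reference point,
#' averaged over frames) is used instead.
#'
#' @param head_ref Either an n x 2 matrix of anterior head point positions,
#'   or an n x 2 x 2 array of the two head reference points per frame
#'   (`[, 1, ]` = anterior, `[, 2, ]` = posterior).
#' @param min_displacement_mm Net-displacement fallback threshold (mm).
#' @return Unit 2-vector of the direction of travel.
#' @export
estimate_travel_direction <- function(head_ref, min_displacement_mm = 0.1) {
  if (length(dim(head_ref)) == 3L) {
    ant <- head_ref[, 1L, ]
    post <- head_ref[, 2L, ]
  } else {
    ant <- as.matrix(head_ref)
    post <- NULL
  }
  if (nrow(ant) < 2L) stop("need at least 2 frames", call. = FALSE)
  net <- ant[nrow(ant), ] - ant[1L, ]
  if (sqrt(sum(net^2)) < min_displacement_mm) {
    if (is.null(post)) {
      stop("stationary, direction undefined (no head-axis reference)",
           call. = FALSE)
    }
    axis <- colMeans(ant - post)
    if (sqrt(sum(axis^2)) == 0) {
      stop("stationary, direction undefined", call. = FALSE)
    }
    return(unitize(axis))
  }
  cc <- sweep(ant, 2L, colMeans(ant))
  ev <- eigen(crossprod(cc) / nrow(ant), symmetric = TRUE)
  dir <- ev$vectors[, 1L]
  if (sum(dir * net) < 0) dir <- -dir
  unitize(dir)
}

#' Angles of the 10 body segments to the direction of travel
#'
#' Unsigned acute angle between each segment vector and the travel
#' direction, folded to \[0, 90\] degrees.
#'
#' @param s A `landmark_set` from [extract_landmarks()].
#' @param travel Unit direction-of-travel vector.
#' @return Numeric vector of 10 angles (degrees).
#' @export
segment_angles <- function(s, travel) {
  stopifnot(inherits(s, "landmark_set"))
  travel <- unitize(travel)
  vapply(s$segments, function(seg) {
    v <- seg["end", ] - seg["start", ]
    len <- sqrt(sum(v^2))
    if (len == 0) stop("zero-length body segment", call. = FALSE)
    acos(pmin(1, abs(sum(v * travel)) / len)) * 180 / pi
  }, 0)
}

#' Undulation amplitudes of the 11 landmarks
#'
#' Signed perpendicular distance of each landmark from the straight
#' reference midline: the travel-direction line through `axis_point`
#' (normally the cycle-mean anterior head position). Positive is to the left
#' of the direction of travel.
#'
#' @param s A `landmark_set`.
#' @param axis_point A point on the reference line (mm).
#' @param travel Unit direction-of-travel vector.
#' @return Numeric vector of 11 signed offsets (mm).
#' @export
midline_amplitudes <- function(s, axis_point, travel) {
  stopifnot(inherits(s, "landmark_set"))
  travel <- unitize(travel)
  nvec <- perp_left(travel)
  as.numeric((s$points[, 1L] - axis_point[1L]) * nvec[1L] +
               (s$points[, 2L] - axis_point[2L]) * nvec[2L])
}

#' Instantaneous landmark velocities
#'
#' Savitzky-Golay smooths each landmark coordinate series over time, takes
#' central differences, and resolves the velocity into axial (along the
#' direction of travel) and lateral (perpendicular) components.
#'
#' @param series n_frames x 11 x 2 array of landmark positions (mm).
#' @param dt Uniform frame interval (s); frame times may deviate from
#'   uniformity by at most 1%.
#' @param travel Unit direction-of-travel vector.
#' @param body_length_mm Body length used for BL/s scaling.
#' @param sg_window,sg_order Savitzky-Golay window (samples) and order.
#' @param times Optional frame times used to check uniformity.
#' @return List of n_frames x 11 matrices `axial_mm_s`, `lateral_mm_s`,
#'   `resultant_mm_s` and their `_bl_s` counterparts.
#' @export
landmark_velocities <- function(series, dt, travel, body_length_mm,
                                sg_window = 11L, sg_order = 3L,
                                times = NULL) {
  if (length(dim(series)) != 3L || dim(series)[2L] != 11L) {
    stop("series must be an n x 11 x 2 array", call. = FALSE)
  }
  n <- dim(series)[1L]
  if (n < 3L) stop("need at least 3 frames for velocities", call. = FALSE)
  if (!is.null(times) && length(times) > 1L) {
    dts <- diff(times)
    if (max(abs(dts - dt)) > 0.01 * dt) {
      stop("frame interval non-uniform beyond 1%", call. = FALSE)
    }
  }
  travel <- unitize(travel)
  nvec <- perp_left(travel)
  vax <- vlat <- matrix(NA_real_, n, 11L)
  for (p in seq_len(11L)) {
    xs <- sg_smooth(series[, p, 1L], sg_window, sg_order)
    ys <- sg_smooth(series[, p, 2L], sg_window, sg_order)
    vx <- central_diff(xs, dt)
    vy <- central_diff(ys, dt)
    vax[, p] <- vx * travel[1L] + vy * travel[2L]
    vlat[, p] <- vx * nvec[1L] + vy * nvec[2L]
  }
  vres <- sqrt(vax^2 + vlat^2)
  list(axial_mm_s = vax, lateral_mm_s = vlat, resultant_mm_s = vres,
       axial_bl_s = vax / body_length_mm, lateral_bl_s = vlat / body_length_mm,
       resultant_bl_s = vres / body_length_mm)
}

#' Full midline kinematics of a crawl recording
#'
#' Runs the midline pipeline frame by frame: resampling to 101 points,
#' extraction of the 11 landmarks / 10 segments, travel-direction
#' estimation from the anterior head reference point, segment angles,
#' amplitudes about the travel-direction line through the mean head
#' position, and smoothed instantaneous velocities.
#'
#' @param recording A `crawl_recording`.
#' @param sg_window,sg_order Savitzky-Golay parameters for the velocity
#'   smoothing.
#' @param body_length_mm Optional body-length override (mm).
#' @return A `kinematic_profile`: list with `travel` (unit vector),
#'   `landmarks` (n x 11 x 2), `segment_angles_deg` (n x 10),
#'   `amplitudes_mm` and `amplitudes_bl` (n x 11), the velocity matrices of
#'   [landmark_velocities()], per-point per-cycle maxima in `summary`, and
#'   `time`.
#' @export
analyze_kinematics <- function(recording, sg_window = 11L, sg_order = 3L,
                               body_length_mm = NULL) {
  stopifnot(inherits(recording, "crawl_recording"))
  n <- length(recording$time)
  bl <- body_length_mm %||% recording$meta$body_length_mm
  landmarks <- array(NA_real_, c(n, 11L, 2L))
  angles <- matrix(NA_real_, n, 10L)
  travel <- estimate_travel_direction(recording$head_ref)
  for (j in seq_len(n)) {
    lm <- extract_landmarks(interpolate_midline(recording$midline[j, , ]))
    landmarks[j, , ] <- lm$points
    angles[j, ] <- segment_angles(lm, travel)
  }
  axis_point <- colMeans(recording$head_ref[, 1L, , drop = FALSE][, 1L, ])
  nvec <- perp_left(travel)
  amp <- (landmarks[, , 1L] - axis_point[1L]) * nvec[1L] +
    (landmarks[, , 2L] - axis_point[2L]) * nvec[2L]
  dt <- if (n > 1L) stats::median(diff(recording$time)) else NA_real_
  vel <- landmark_velocities(landmarks, dt, travel, bl,
                             sg_window = sg_window, sg_order = sg_order,
                             times = recording$time)
  structure(c(list(
    travel = travel,
    time = recording$time,
    landmarks = landmarks,
    segment_angles_deg = angles,
    amplitudes_mm = amp,
    amplitudes_bl = amp / bl,
    body_length_mm = bl
  ), vel, list(summary = list(
    max_segment_angle_deg = apply(angles, 2L, max),
    max_amplitude_mm = apply(abs(amp), 2L, max),
    max_axial_mm_s = apply(abs(vel$axial_mm_s), 2L, max),
    max_lateral_mm_s = apply(abs(vel$lateral_mm_s), 2L, max),
    max_axial_bl_s = apply(abs(vel$axial_bl_s), 2L, max),
    max_lateral_bl_s = apply(abs(vel$lateral_bl_s), 2L, max)
  ))), class = "kinematic_profile")
}

#' Write per-frame kinematics results to CSV
#'
#' Writes the per-point table (`frame, time_s, point_index, amplitude_mm,
#' vax_mm_s, vlat_mm_s, vres_mm_s`) and the per-segment angle table
#' (`frame, segment_index, angle_deg`).
#'
#' @param profile A `kinematic_profile` from [analyze_kinematics()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_kinematics <- function(profile, dir) {
  stopifnot(inherits(profile, "kinematic_profile"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(profile$time)
  pts <- data.frame(
    frame = rep(seq_len(n), each = 11L),
    time_s = rep(profile$time, each = 11L),
    point_index = rep(1:11, times = n),
    amplitude_mm = as.vector(t(profile$amplitudes_mm)),
    vax_mm_s = as.vector(t(profile$axial_mm_s)),
    vlat_mm_s = as.vector(t(profile$lateral_mm_s)),
    vres_mm_s = as.vector(t(profile$resultant_mm_s))
  )
  segs <- data.frame(
    frame = rep(seq_len(n), each = 10L),
    segment_index = rep(1:10, times = n),
    angle_deg = as.vector(t(profile$segment_angles_deg))
  )
  f1 <- file.path(dir, "kinematics_points.csv")
  f2 <- file.path(dir, "kinematics_segments.csv")
  utils::write.csv(pts, f1, row.names = FALSE)
  utils::write.csv(segs, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
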