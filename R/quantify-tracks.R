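#' Construct a kinetochore track
#'
#' Time-stamped 2-D positions of tracked objects in a laser-ablation assay:
#' the two sister kinetochores (`"sister1"` is the sister proximal to the
#' cut, the one whose k-fibre was severed) and optionally the ablated
#' k-fibre stub tip (`"stub_tip"`). The spindle long axis is supplied
#' explicitly as an origin and direction; perpendicular displacements and
#' tilt angles are measured against it.
#'
#' @param data Data frame with columns `time_s`, `object_id`, `x_um`,
#'   `y_um`. Times must be strictly increasing within each object.
#' @param axis_origin Numeric length-2: a point on the spindle long axis.
#' @param axis_direction Numeric length-2: direction of the long axis (need
#'   not be normalised).
#' @param t_cut_s Ablation time (seconds), default 0.
#' @param frame_interval_s Acquisition interval; if `NULL`, the median frame
#'   spacing is used.
#' @return A data frame of class `"kinetochore_track"` with the axis, cut
#'   time and frame interval stored as attributes.
#' @export
kinetochore_track <- function(data, axis_origin = c(0, 0),
                              axis_direction = c(1, 0), t_cut_s = 0,
                              frame_interval_s = NULL) {
  req <- c("time_s", "object_id", "x_um", "y_um")
  if (!all(req %in% names(data)))
    stop("track data needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  for (id in unique(data$object_id)) {
    tt <- data$time_s[data$object_id == id]
    if (any(diff(tt) <= 0))
      stop(sprintf("times must be strictly increasing within object '%s'", id),
           call. = FALSE)
  }
  if (sqrt(sum(axis_direction^2)) == 0)
    stop("axis_direction must be non-zero", call. = FALSE)
  if (is.null(frame_interval_s)) {
    tt <- sort(unique(data$time_s))
    frame_interval_s <- if (length(tt) > 1) stats::median(diff(tt)) else 1
  }
  out <- as.data.frame(data)
  attr(out, "axis_origin") <- axis_origin
  attr(out, "axis_direction") <- axis_direction / sqrt(sum(axis_direction^2))
  attr(out, "t_cut_s") <- t_cut_s
  attr(out, "frame_interval_s") <- frame_interval_s
  class(out) <- c("kinetochore_track", "data.frame")
  out
}

# position of `object` at the frame nearest to `t`, within tol_frames frame
# intervals; errors when absent
.track_pos <- function(track, object, t, tol_frames = 1) {
  rows <- track[track$object_id == object, , drop = FALSE]
  if (nrow(rows) == 0)
    stop(sprintf("object '%s' not present in track", object), call. = FALSE)
  i <- which.min(abs(rows$time_s - t))
  dt_max <- tol_frames * attr(track, "frame_interval_s")
  if (abs(rows$time_s[i] - t) > dt_max + 1e-9)
    stop(sprintf("no frame for object '%s' within %.3g s of t = %.3g s",
                 object, dt_max, t), call. = FALSE)
  c(x = rows$x_um[i], y = rows$y_um[i])
}

# unsigned angle (degrees, in [0, 90]) between a direction and the axis
.angle_to_axis <- function(v, axis) {
  nv <- sqrt(sum(v^2)); na <- sqrt(sum(axis^2))
  ang <- acos(pmin(1, abs(sum(v * axis)) / (nv * na))) * 180 / pi
  ang
}

#' Angle of a fibre contour segment to the spindle axis
#'
#' Fits a line through three consecutive points of a tracked fibre contour
#' (total least squares) and returns its unsigned angle to the spindle long
#' axis, in degrees within \[0, 90\]. Contour points are typically spaced
#' ~250 nm apart.
#'
#' @param points A 3x2 numeric matrix (or data frame) of contour points
#'   (x, y), exactly three rows.
#' @param axis Direction of the spindle long axis, default `c(1, 0)`.
#' @return Angle in degrees.
#' @examples
#' angle_from_contour(rbind(c(0, 0), c(1, 1), c(2, 2)))   # 45
#' @export
angle_from_contour <- function(points, axis = c(1, 0)) {
  pts <- as.matrix(points)
  if (nrow(pts) != 3 || ncol(pts) != 2)
    stop("exactly 3 contour points (x, y) are required", call. = FALSE)
  centred <- scale(pts, scale = FALSE)
  if (all(abs(centred) < 1e-12))
    stop("degenerate fit: contour points coincide", call. = FALSE)
  dir <- svd(centred)$v[, 1]
  .angle_to_axis(dir, axis)
}

#' Tilt of the sister-kinetochore axis
#'
#' Unsigned angle between the segment joining the sister kinetochores and
#' the spindle long axis at time `t`. In an intact metaphase spindle the
#' sisters are roughly parallel to the axis (tilt near 0); after severing a
#' k-fibre the pair tilts as the fibres straighten.
#'
#' @param track A [kinetochore_track()].
#' @param t Time (seconds).
#' @return Tilt angle in degrees, in \[0, 90\].
#' @export
sister_tilt <- function(track, t) {
  p1 <- .track_pos(track, "sister1", t)
  p2 <- .track_pos(track, "sister2", t)
  v <- p2 - p1
  if (sqrt(sum(v^2)) < 1e-12)
    stop("sisters coincide: tilt undefined", call. = FALSE)
  .angle_to_axis(v, attr(track, "axis_direction"))
}

#' Interkinetochore distance
#'
#' Euclidean distance between the sister kinetochores at time `t`.
#'
#' @param track A [kinetochore_track()].
#' @param t Time (seconds).
#' @return Distance in micrometres.
#' @export
interkinetochore_distance <- function(track, t) {
  p1 <- .track_pos(track, "sister1", t)
  p2 <- .track_pos(track, "sister2", t)
  sqrt(sum((p2 - p1)^2))
}

#' Interkinetochore relaxation after ablation
#'
#' Decrease of the interkinetochore distance between the cut and `dt_s`
#' seconds later (default 4 s): `d_k(t_cut) - d_k(t_cut + dt)`. Positive
#' values mean the sisters moved closer, reporting a loss of tension. Frames
#' are matched to the nearest acquired frame within one frame interval.
#'
#' @param track A [kinetochore_track()].
#' @param dt_s Delay after the cut (seconds), default 4.
#' @return Relaxation in micrometres (positive = distance decreased).
#' @export
kk_relaxation <- function(track, dt_s = 4) {
  t0 <- attr(track, "t_cut_s")
  interkinetochore_distance(track, t0) -
    interkinetochore_distance(track, t0 + dt_s)
}

#' Perpendicular displacement of a tracked object
#'
#' Displacement of `object` at time `t`, relative to its position at the
#' cut, projected on the normal of the spindle long axis. The sign is
#' positive for motion away from the axis (outward), on the side where the
#' object sat before the cut.
#'
#' @param track A [kinetochore_track()].
#' @param object Object id, e.g. `"sister1"`.
#' @param t Time (seconds).
#' @return Signed displacement in micrometres.
#' @export
perpendicular_displacement <- function(track, object, t) {
  t0 <- attr(track, "t_cut_s")
  p0 <- .track_pos(track, object, t0)
  p1 <- .track_pos(track, object, t)
  o <- attr(track, "axis_origin"); d <- attr(track, "axis_direction")
  nrm <- c(-d[2], d[1])
  side <- sign(sum((p0 - o) * nrm))
  if (side == 0) side <- 1
  sum((p1 - p0) * nrm) * side
}

#' Length of the ablated k-fibre stub
#'
#' Distance from the centre of the kinetochore attached to the stub
#' (`"sister1"` by convention) to the stub tip, measured in the first frame
#' after the cut unless another time is given.
#'
#' @param track A [kinetochore_track()] containing a `"stub_tip"` object.
#' @param t Time (seconds); default: first acquired frame after the cut.
#' @param kinetochore Object id of the stub's kinetochore, default
#'   `"sister1"`.
#' @return Stub length in micrometres.
#' @export
stub_length <- function(track, t = NULL, kinetochore = "sister1") {
  if (!"stub_tip" %in% track$object_id)
    stop("no 'stub_tip' object in track", call. = FALSE)
  if (is.null(t)) {
    after <- track$time_s[track$object_id == "stub_tip" &
                          track$time_s > attr(track, "t_cut_s")]
    if (length(after) == 0)
      stop("no stub tip frame after the cut", call. = FALSE)
    t <- min(after)
  }
  pk <- .track_pos(track, kinetochore, t)
  pt <- .track_pos(track, "stub_tip", t)
  sqrt(sum((pt - pk)^2))
}
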