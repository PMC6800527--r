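#' 3D swim trajectory
#'
#' Constructs a `trajectory3d`: a uniformly sampled sequence of 3D positions
#' in tank coordinates (cm; origin at a bottom corner, z up). Missing frames
#' (tracking gaps) are represented as rows of `NA` so that timestamps stay on
#' the uniform 1/frame_rate grid.
#'
#' @param t Timestamps (s), strictly increasing on a uniform grid.
#' @param x,y,z Coordinates (cm); `NA` marks a gap frame (all three must be
#'   `NA` together).
#' @param frame_rate Sampling rate (Hz).
#' @param subject_id Subject label.
#' @param tank Optional [tank_geometry()]; when supplied, non-gap positions
#'   are checked against the tank bounds.
#' @param bounds `"strict"` errors on out-of-tank coordinates, `"lenient"`
#'   clamps them into the tank with a warning, `"none"` skips the check.
#' @return An object of class `trajectory3d` (also a data.frame with columns
#'   t, x, y, z).
#' @export
trajectory3d <- function(t, x, y, z, frame_rate = 30, subject_id = "subject",
                         tank = NULL, bounds = c("none", "strict", "lenient")) {
  bounds <- match.arg(bounds)
  n <- length(t)
  stopifnot(length(x) == n, length(y) == n, length(z) == n, n >= 1)
  check_uniform_time(t, frame_rate)
  gap <- is.na(x) | is.na(y) | is.na(z)
  if (any(gap & !(is.na(x) & is.na(y) & is.na(z)))) {
    stop("gap frames must have all of x, y, z missing")
  }
  if (!is.null(tank) && bounds != "none") {
    xyz <- enforce_bounds(cbind(x, y, z),
                          c(tank$length_x, tank$width_y, tank$water_depth_z),
                          bounds)
    x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  }
  out <- data.frame(t = as.numeric(t), x = as.numeric(x),
                    y = as.numeric(y), z = as.numeric(z))
  structure(out, class = c("trajectory3d", "data.frame"),
            frame_rate = frame_rate, subject_id = subject_id)
}

#' Single-view 2D track
#'
#' A 2D projection of a swim trajectory as seen by one camera. The top view
#' records (x, y); the front view records (x, z). Both views share the x
#' axis (the length of the tank), which is what makes cross-view
#' synchronization possible.
#'
#' @param t Timestamps (s), uniform grid.
#' @param a,b View coordinates: (x, y) for `view = "top"`, (x, z) for
#'   `view = "front"`. `NA` marks gaps.
#' @param view `"top"` or `"front"`.
#' @param frame_rate Sampling rate (Hz).
#' @param subject_id Subject label.
#' @param lag_frames Known integer frame offset relative to the partner
#'   stream (0 when unknown or already aligned).
#' @return An object of class `track2d` (also a data.frame). Column names
#'   are t, x, y for the top view and t, x, z for the front view.
#' @export
track2d <- function(t, a, b, view = c("top", "front"), frame_rate = 30,
                    subject_id = "subject", lag_frames = 0L) {
  view <- match.arg(view)
  n <- length(t)
  stopifnot(length(a) == n, length(b) == n, n >= 1)
  check_uniform_time(t, frame_rate)
  gap <- is.na(a) | is.na(b)
  a[gap] <- NA_real_; b[gap] <- NA_real_
  out <- data.frame(t = as.numeric(t), a = as.numeric(a), b = as.numeric(b))
  names(out) <- c("t", "x", if (view == "top") "y" else "z")
  structure(out, class = c("track2d", "data.frame"),
            frame_rate = frame_rate, subject_id = subject_id,
            view = view, lag_frames = as.integer(lag_frames))
}

check_uniform_time <- function(t, frame_rate, tol = 1e-6) {
  if (length(t) >= 2) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing")
    if (any(abs(dt - 1 / frame_rate) > tol)) {
      stop("timestamps must be uniformly spaced at 1/frame_rate")
    }
  }
  invisible(TRUE)
}

enforce_bounds <- function(m, upper, bounds) {
  lower <- rep(0, length(upper))
  bad <- FALSE
  for (j in seq_along(upper)) {
    v <- m[, j]
    out <- !is.na(v) & (v < lower[j] | v > upper[j])
    if (any(out)) bad <- TRUE
  }
  if (bad) {
    if (bounds == "strict") stop("coordinates outside tank bounds")
    warning("coordinates outside tank bounds were clamped")
    for (j in seq_along(upper)) {
      m[, j] <- pmin(pmax(m[, j], lower[j]), upper[j])
    }
  }
  m
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("3D trajectory '%s': %d frames at %g Hz (%d gap frames)\n",
              attr(x, "subject_id"), nrow(x), attr(x, "frame_rate"),
              sum(is.na(x$x))))
  invisible(x)
}

#' @export
print.track2d <- function(x, ...) {
  cat(sprintf("2D %s-view track '%s': %d frames at %g Hz (%d gap frames), lag %d\n",
              attr(x, "view"), attr(x, "subject_id"), nrow(x),
              attr(x, "frame_rate"), sum(is.na(x[[2]])),
              attr(x, "lag_frames")))
  invisible(x)
}

#' Frame coordinates of a track as a numeric matrix
#'
#' @param obj A `trajectory3d` or `track2d`.
#' @return Numeric matrix with one row per frame (3 or 2 columns); gap
#'   frames are rows of `NA`.
#' @export
coords <- function(obj) {
  UseMethod("coords")
}

#' @export
coords.trajectory3d <- function(obj) as.matrix(obj[, c("x", "y", "z")])

#' @export
coords.track2d <- function(obj) as.matrix(obj[, -1])

#' View label of a track
#' @param obj A `trajectory3d` or `track2d`.
#' @return `"3D"`, `"top"` or `"front"`.
#' @export
track_view <- function(obj) {
  if (inherits(obj, "trajectory3d")) "3D" else attr(obj, "view")
}

#' Project a 3D trajectory onto one camera view
#'
#' The top camera sees the x-y plane (z is lost); the front camera sees the
#' x-z plane (y is lost). Timestamps and gaps carry over unchanged and the
#' projected track has zero lag relative to its source.
#'
#' @param traj A [trajectory3d()].
#' @param view `"top"` or `"front"`.
#' @return A [track2d()].
#' @examples
#' tr <- trajectory3d(t = 0, x = 1, y = 2, z = 3)
#' coords(project(tr, "top"))   # 1 2
#' coords(project(tr, "front")) # 1 3
#' @export
project <- function(traj, view = c("top", "front")) {
  view <- match.arg(view)
  stopifnot(inherits(traj, "trajectory3d"))
  b <- if (view == "top") traj$y else traj$z
  track2d(traj$t, traj$x, b, view = view,
          frame_rate = attr(traj, "frame_rate"),
          subject_id = attr(traj, "subject_id"), lag_frames = 0L)
}

#' Total path length of a track
#'
#' Sum of Euclidean step lengths over consecutive non-gap frame pairs.
#' Any 2D projection of a trajectory has path length no greater than the
#' 3D original.
#'
#' @param obj A `trajectory3d` or `track2d`.
#' @return Path length in cm.
#' @export
path_length <- function(obj) {
  m <- coords(obj)
  d <- diff(m)
  step <- sqrt(rowSums(d^2))
  sum(step, na.rm = TRUE)
}
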