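#' Kinematic series from a position track
#'
#' Differentiates a position time series with first-order (forward) finite
#' differences: speed from positions, acceleration magnitude from the
#' velocity series, and angular speed as the heading change between
#' successive velocity vectors divided by the frame interval. Works
#' dimension-generically on 2D and 3D tracks, which is what allows the
#' identical ethogram to be scored from a 3D trajectory or from either
#' camera projection.
#'
#' Angular speed is undefined at near-zero velocity, so frames where either
#' of the two velocity vectors is slower than `speed_floor` are marked
#' invalid. Frames adjacent to tracking gaps are invalid in all series
#' (no interpolation is performed here).
#'
#' @param obj A `trajectory3d`, `track2d`, or numeric matrix of positions
#'   (one row per frame, gap frames as `NA` rows).
#' @param frame_rate Sampling rate (Hz); taken from the track when `obj`
#'   carries one.
#' @param speed_floor Minimum speed (cm/s) at which heading, and hence
#'   angular speed, is considered defined.
#' @param smooth_window Optional odd boxcar width (frames) applied to
#'   positions before differencing; 1 (default) disables smoothing.
#' @return A list of class `kinematic_series` with elements `speed`
#'   (length n-1), `accel` and `ang_speed` (length n-2), matching logical
#'   validity masks, and `frame_rate`. Value k of each series is anchored
#'   at frame k of the input.
#' @examples
#' # uniform motion: constant speed, zero acceleration and turning
#' tr <- trajectory3d(t = (0:99) / 30, x = (0:99) * 5 / 30,
#'                    y = rep(1, 100), z = rep(1, 100))
#' k <- kinematics(tr)
#' range(k$speed) # 5 5
#' @export
kinematics <- function(obj, frame_rate = NULL, speed_floor = 0.5,
                       smooth_window = 1) {
  if (is.matrix(obj)) {
    m <- obj
    if (is.null(frame_rate)) stop("frame_rate required for matrix input")
  } else {
    m <- coords(obj)
    if (is.null(frame_rate)) frame_rate <- attr(obj, "frame_rate")
  }
  n <- nrow(m)
  if (sum(stats::complete.cases(m)) < 3) stop("need at least 3 non-gap frames")
  if (smooth_window > 1) m <- boxcar_smooth(m, smooth_window)
  dt <- 1 / frame_rate

  v <- diff(m) / dt                    # (n-1) x d velocity vectors
  speed <- unname(sqrt(rowSums(v^2)))
  speed_valid <- !is.na(speed)

  a <- diff(v) / dt                    # (n-2) x d
  accel <- unname(sqrt(rowSums(a^2)))
  accel_valid <- !is.na(accel)

  # heading change between successive velocity vectors
  v1 <- v[-nrow(v), , drop = FALSE]
  v2 <- v[-1, , drop = FALSE]
  s1 <- speed[-length(speed)]
  s2 <- speed[-1]
  cosang <- unname(rowSums(v1 * v2)) / (s1 * s2)
  cosang <- pmin(pmax(cosang, -1), 1)
  ang_speed <- acos(cosang) / dt
  ang_valid <- !is.na(ang_speed) & !is.na(s1) & !is.na(s2) &
    s1 >= speed_floor & s2 >= speed_floor
  ang_speed[!ang_valid] <- NA_real_
  speed[!speed_valid] <- NA_real_
  accel[!accel_valid] <- NA_real_

  structure(list(speed = speed, speed_valid = speed_valid,
                 accel = accel, accel_valid = accel_valid,
                 ang_speed = ang_speed, ang_valid = ang_valid,
                 frame_rate = frame_rate, speed_floor = speed_floor),
            class = "kinematic_series")
}

boxcar_smooth <- function(m, w) {
  stopifnot(w >= 1, w %% 2 == 1)
  half <- (w - 1) / 2
  n <- nrow(m)
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    sm <- stats::filter(v, rep(1 / w, w), sides = 2)
    sm <- as.numeric(sm)
    # keep edges unsmoothed rather than shortening the series
    sm[seq_len(half)] <- v[seq_len(half)]
    sm[(n - half + 1):n] <- v[(n - half + 1):n]
    out[, j] <- sm
  }
  out
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("Kinematic series: %d speed frames (%d valid), mean speed %.2f cm/s\n",
              length(x$speed), sum(x$speed_valid),
              mean(x$speed, na.rm = TRUE)))
  invisible(x)
}
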